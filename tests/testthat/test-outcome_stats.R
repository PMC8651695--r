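test_that("Kaplan-Meier median matches a hand-rolled product-limit table", {
  time <- c(3, 5, 5, 7, 9, 11, 12, 13, 15, 16,
            18, 20, 22, 25, 26, 28, 30, 33, 35, 40)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1,
             1, 1, 0, 1, 1, 0, 1, 1, 1, 0)
  rec <- tibble::tibble(time_days = time, event = event, group = "all")
  out <- km_median(rec)
  bf <- km_bruteforce(time, event)
  expect_equal(out$medians$median_days, bf$median)
  expect_equal(out$medians$events, sum(event))
  # all events at one time: median is that time
  same <- tibble::tibble(time_days = rep(42, 6), event = 1, group = "g")
  expect_equal(km_median(same)$medians$median_days, 42)
  # no events: flat curve, undefined median
  none <- tibble::tibble(time_days = 1:6, event = 0, group = "g")
  expect_true(is.na(km_median(none)$medians$median_days))
  expect_error(km_median(rec[0, ]), "empty")
})

test_that("log-rank equals the observed-minus-expected table and is symmetric", {
  set.seed(51)
  a <- tibble::tibble(time_days = rexp(25, 1 / 100), event = rbinom(25, 1, 0.8))
  b <- tibble::tibble(time_days = rexp(30, 1 / 180), event = rbinom(30, 1, 0.8))
  out <- logrank(a, b)
  bf <- logrank_bruteforce(a$time_days, a$event, b$time_days, b$event)
  expect_equal(out$chisq, bf, tolerance = 1e-9)
  expect_equal(out$p_value, logrank(b, a)$p_value)
  # identical groups: statistic 0, p = 1
  same <- logrank(a, a)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_error(logrank(a, a[0, ]), "empty")
})

test_that("log-rank p-values are near-uniform under label permutation", {
  set.seed(52)
  times <- rexp(60, 1 / 100)
  events <- rbinom(60, 1, 0.85)
  p <- replicate(200, {
    grp <- sample(rep(c("A", "B"), 30))
    logrank(tibble::tibble(time_days = times[grp == "A"], event = events[grp == "A"]),
            tibble::tibble(time_days = times[grp == "B"], event = events[grp == "B"]))$p_value
  })
  expect_gt(mean(p < 0.5), 0.38)
  expect_lt(mean(p < 0.5), 0.62)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("Mann-Whitney agrees with exact enumeration at small n", {
  set.seed(53)
  for (i in 1:5) {
    vals <- sample(1:1000, 11)  # distinct values keep the exact test in play
    x <- vals[1:5]
    y <- vals[6:11]
    out <- compare_groups(x, y, test = "mann_whitney")
    expect_equal(out$p_value, mann_whitney_enum(x, y), tolerance = 1e-10)
  }
})

test_that("paired and correlation tests handle the degenerate identities", {
  x <- c(3, 1, 4, 1, 5)
  out <- compare_groups(x, x, test = "wilcoxon_paired")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(compare_groups(x, x[-1], test = "wilcoxon_paired"),
               "equal-length")
  mono <- compare_groups(c(1, 2, 3, 5, 9), c(10, 20, 21, 30, 80),
                         test = "correlation")
  expect_equal(mono$estimate, 1)
  anova <- compare_groups(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3),
                          test = "anova_oneway")
  expect_lt(anova$p_value, 0.01)
})

test_that("group tests are symmetric in group order", {
  set.seed(54)
  x <- stats::rnorm(12); y <- stats::rnorm(15, 0.5)
  expect_equal(compare_groups(x, y, "mann_whitney")$p_value,
               compare_groups(y, x, "mann_whitney")$p_value)
})

test_that("baseline detectability shortens observed time to progression", {
  # shedding-linked progression: detected-at-baseline lines progress earlier
  set.seed(55)
  co <- simulate_cohort(sim_config(rng_seed = 55))
  res <- analyze_cohort(co$variants, co$clinical, tmad_scores = NULL)
  expect_false(is.null(res$survival))
  med <- res$survival$medians
  det <- med$median_days[med$group == "baseline_detected"]
  undet <- med$median_days[med$group == "baseline_undetected"]
  expect_true(is.na(undet) || det < undet)
})
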