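toy_genome <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(5e6, 3.5e6))

test_that("bin template tiles the genome with a short final bin", {
  tpl <- make_bin_template(toy_genome, 1e6)
  expect_equal(nrow(tpl$bins), 9)
  last_chr2 <- tpl$bins[tpl$bins$chrom == "chr2", ]
  expect_equal(last_chr2$end[nrow(last_chr2)] - last_chr2$start[nrow(last_chr2)], 5e5)
  expect_true(all(diff(tpl$bins$start[tpl$bins$chrom == "chr1"]) == 1e6))
})

test_that("fragment binning conserves counts and uses half-open bins", {
  tpl <- make_bin_template(toy_genome, 1e6)
  frags <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                          pos = c(0, 10, 999999, 1e6, 0))
  prof <- bin_fragments(frags, tpl)
  expect_equal(prof$values[1], 3)  # boundary start stays in its own bin
  expect_equal(prof$values[2], 1)  # position 1e6 opens the next bin
  expect_equal(sum(prof$values), nrow(frags))
  set.seed(7)
  rnd <- tibble::tibble(chrom = sample(toy_genome$chrom, 100, TRUE, prob = c(.6, .4)),
                        pos = NA_real_)
  rnd$pos <- floor(stats::runif(100) * toy_genome$length[match(rnd$chrom, toy_genome$chrom)])
  expect_equal(sum(bin_fragments(rnd, tpl)$values), 100)
  expect_error(bin_fragments(tibble::tibble(chrom = "chr1", pos = 6e6), tpl),
               "outside the declared genome")
})

test_that("log2 normalization recovers known depth ratios", {
  tpl <- make_bin_template(tibble::tibble(chrom = "chr1", length = 5e6), 1e6)
  ref <- ctdnatrack:::new_bin_profile(tpl$bins, rep(100, 5), "count")
  prop <- ctdnatrack:::new_bin_profile(tpl$bins, rep(40, 5), "count")
  expect_equal(normalize_to_log2(prop, ref)$values, rep(0, 5), tolerance = 1e-12)
  # doubling one bin's relative depth: log2 ratio +1 after renormalization
  dbl <- ctdnatrack:::new_bin_profile(tpl$bins, c(200, rep(100, 4)), "count")
  out <- normalize_to_log2(dbl, ref)
  expect_equal(out$values[1] - out$values[2], 1, tolerance = 1e-12)
  hlf <- ctdnatrack:::new_bin_profile(tpl$bins, c(50, rep(100, 4)), "count")
  out <- normalize_to_log2(hlf, ref)
  expect_equal(out$values[1] - out$values[2], -1, tolerance = 1e-12)
  # zero-depth reference bins are auto-masked with a warning
  ref0 <- ctdnatrack:::new_bin_profile(tpl$bins, c(0, rep(100, 4)), "count")
  expect_warning(out <- normalize_to_log2(prop, ref0), "auto-masked")
  expect_false(out$mask[1])
})

test_that("trim mask removes the highest-variance control bins", {
  tpl <- make_bin_template(tibble::tibble(chrom = "chr1", length = 2e7), 1e6)
  mk <- function(vals) ctdnatrack:::new_bin_profile(tpl$bins, vals, "log2r")
  same <- list(mk(rep(0.1, 20)), mk(rep(0.1, 20)))
  expect_equal(sum(build_trim_mask(same, trim_fraction = 0)), 20)
  set.seed(11)
  noisy <- lapply(1:4, function(i) {
    v <- stats::rnorm(20, 0, 0.01)
    v[7] <- stats::rnorm(1, 0, 1)  # one bin with far higher variance
    mk(v)
  })
  mask <- build_trim_mask(noisy, trim_fraction = 0.051)
  expect_false(mask[7])
  expect_equal(sum(!mask), 1)
  expect_error(build_trim_mask(noisy[1], 0.05), "at least 2 control")
  expect_error(build_trim_mask(noisy, trim_fraction = 1), "retains no bins")
})

test_that("t-MAD is the median absolute deviation from log2 = 0", {
  expect_equal(compute_tmad(log2_profile(rep(0, 10)))$tmad, 0)
  expect_equal(compute_tmad(log2_profile(c(-0.2, 0, 0.2)))$tmad, 0.2)
  p <- log2_profile(c(-0.3, 0.1, 0.2, -0.05, 0))
  expect_equal(compute_tmad(log2_profile(3 * p$values))$tmad,
               3 * compute_tmad(p)$tmad)
  expect_equal(compute_tmad(log2_profile(-p$values))$tmad, compute_tmad(p)$tmad)
})

test_that("t-MAD ignores sex chromosomes and masked bins", {
  vals <- c(0.1, 0.1, 5, 5)
  p <- log2_profile(vals, chrom = c("chr1", "chr1", "chrX", "chrY"))
  out <- compute_tmad(p)
  expect_equal(out$tmad, 0.1)
  expect_equal(out$n_bins_used, 2)
  p2 <- log2_profile(c(0.1, 0.1, 9))
  expect_equal(compute_tmad(p2, mask = c(TRUE, TRUE, FALSE))$tmad, 0.1)
  expect_error(compute_tmad(log2_profile(1, chrom = "chrX")), "autosomal")
  expect_error(compute_tmad(ctdnatrack:::new_bin_profile(
    p$bins, c(1, 2, 3, 4), "count")), "log2-ratio")
})

test_that("percent t-MAD change matches its definition and composes", {
  expect_equal(pct_delta_tmad(0.010, 0.015), 50)
  expect_equal(pct_delta_tmad(0.42, 0.42), 0)
  expect_equal(pct_delta_tmad(0.010, 0.005), -50)
  expect_warning(out <- pct_delta_tmad(0, 0.1), "previous t-MAD = 0")
  expect_true(is.na(out))
  expect_error(pct_delta_tmad(-0.1, 0.1), "non-negative")
  set.seed(5)
  t1 <- stats::runif(1, 0.01, 0.3); t2 <- stats::runif(1, 0.01, 0.3)
  t3 <- stats::runif(1, 0.01, 0.3)
  d12 <- pct_delta_tmad(t1, t2); d23 <- pct_delta_tmad(t2, t3)
  expect_equal((1 + d12 / 100) * (1 + d23 / 100), t3 / t1, tolerance = 1e-9)
})
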