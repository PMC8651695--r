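test_that("series construction yields n-1 consecutive deltas per patient", {
  s <- toy_series(vaf_mean = c(1, 0.5, 0.6, 2), tmad = c(0.1, 0.05, 0.06, 0.2),
                  status = c("baseline", "response", "stable", "PD_therapy_change"))
  expect_equal(nrow(s$deltas), 3)
  expect_equal(s$deltas$delta_vaf_mean, c(-0.5, 0.1, 1.4))
  expect_equal(s$deltas$pct_delta_tmad, c(-50, 20, 700 / 3), tolerance = 1e-12)
})

test_that("patients with no detectable variants carry a reason code", {
  s <- toy_series(vaf_mean = c(0, 0, 0), tmad = c(0.01, 0.02, 0.01),
                  status = c("baseline", "stable", "stable"))
  expect_true(all(is.na(s$deltas$delta_vaf_mean)))
  expect_equal(unique(s$deltas$dvaf_reason), "no_detectable_variants")
  expect_false(anyNA(s$deltas$pct_delta_tmad))
})

test_that("zero previous t-MAD marks the relative change missing", {
  s <- toy_series(vaf_mean = c(1, 1, 1), tmad = c(0, 0.02, 0.03),
                  status = c("baseline", "stable", "stable"))
  expect_true(is.na(s$deltas$pct_delta_tmad[1]))
  expect_equal(s$deltas$tmad_reason[1], "previous_tmad_zero")
  expect_equal(s$deltas$pct_delta_tmad[2], 50)
})

test_that("duplicate sample dates within a patient are rejected", {
  expect_error(
    toy_series(vaf_mean = c(1, 1), tmad = c(0.1, 0.1),
               status = c("baseline", "stable"), dates = c(0, 0)),
    "duplicate sample dates")
})

test_that("pair labels single out progression with therapy change", {
  s <- toy_series(
    vaf_mean = c(1, 0.5, 0.7, 1.5, 0.2),
    tmad = c(0.1, 0.05, 0.06, 0.2, 0.02),
    status = c("baseline", "stable", "PD_intracranial", "PD_therapy_change", "stable"))
  lp <- label_pairs(s)
  dvaf <- lp[lp$metric == "delta_vaf_mean", ]
  expect_equal(dvaf$label, c(0, 0, 1, 0))
})

test_that("candidates require a stable point, one line, and a threshold hit", {
  thr <- threshold_set()  # 0.0850 pp / 0.5 %
  s <- toy_series(
    vaf_mean = c(0.5, 0.10, 0.23, 1.0),
    tmad = c(0.05, 0.020, 0.025, 0.08),
    status = c("baseline", "stable", "stable", "PD_therapy_change"))
  cand <- call_candidates(s, thr)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$delta_vaf_mean, 0.13)
  expect_true(cand$trigger_tngs)
  expect_true(cand$trigger_swgs)  # +25% t-MAD change
  # below both thresholds: no candidate
  s2 <- toy_series(vaf_mean = c(0.1, 0.15), tmad = c(0.1, 0.1003),
                   status = c("baseline", "stable"))
  expect_equal(nrow(call_candidates(s2, thr)), 0)
  # sWGS-only trigger with no detectable variants
  s3 <- toy_series(vaf_mean = c(0, 0, 0), tmad = c(0.05, 0.073, 0.1),
                   status = c("baseline", "stable", "PD"))
  c3 <- call_candidates(s3, thr)
  expect_equal(nrow(c3), 1)
  expect_false(c3$trigger_tngs)
  expect_true(c3$trigger_swgs)
  # pairs straddling a therapy-line change are never candidates
  s4 <- toy_series(vaf_mean = c(0.1, 0.4), tmad = c(0.01, 0.02),
                   status = c("PD_therapy_change", "stable"), line = c(1L, 2L))
  expect_equal(nrow(call_candidates(s4, thr)), 0)
})

test_that("raising either threshold never increases the candidate count", {
  set.seed(31)
  for (i in 1:10) {
    n <- 8
    s <- toy_series(
      vaf_mean = round(stats::runif(n, 0, 2), 2),
      tmad = round(stats::runif(n, 0.01, 0.2), 3),
      status = c("baseline", sample(c("stable", "response", "PD"), n - 1, TRUE)))
    base <- nrow(call_candidates(s, threshold_set(0.05, 1)))
    expect_lte(nrow(call_candidates(s, threshold_set(0.2, 1))), base)
    expect_lte(nrow(call_candidates(s, threshold_set(0.05, 30))), base)
  }
})

test_that("sustained increase to progression validates and sets the lead time", {
  thr <- threshold_set()
  s <- toy_series(
    vaf_mean = c(0.5, 0.10, 0.25, 0.40, 0.80, 2.0),
    tmad = c(0.05, 0.020, 0.026, 0.030, 0.050, 0.20),
    status = c("baseline", "response", "stable", "stable", "stable",
               "PD_therapy_change"),
    dates = c(0, 47, 112, 150, 200, 241))
  calls <- validate_sustained(call_candidates(s, thr), s)
  expect_true(all(calls$validated))
  first <- calls[calls$is_lead_time, ]
  expect_equal(nrow(first), 1)
  expect_equal(first$candidate_sample_date, 112)
  expect_equal(first$lead_time_days, 129)
})

test_that("a metric falling back below its candidate level blocks validation", {
  thr <- threshold_set()
  s <- toy_series(
    vaf_mean = c(0.5, 0.10, 0.30, 0.15, 0.10),
    tmad = c(0.05, 0.020, 0.020, 0.020, 0.020),
    status = c("baseline", "response", "stable", "stable", "stable"))
  calls <- validate_sustained(call_candidates(s, thr), s)
  expect_equal(nrow(calls), 1)
  expect_false(calls$validated[1])  # also: no progression before line end
  # same shape but with later progression: still blocked by the fall-back
  s2 <- toy_series(
    vaf_mean = c(0.5, 0.10, 0.30, 0.15, 5.0),
    tmad = c(0.05, 0.020, 0.020, 0.020, 0.20),
    status = c("baseline", "response", "stable", "stable", "PD_therapy_change"))
  calls2 <- validate_sustained(call_candidates(s2, thr), s2)
  expect_equal(nrow(calls2), 1)
  expect_false(calls2$validated[1])
})

test_that("a candidate immediately followed by progression is validated", {
  thr <- threshold_set()
  s <- toy_series(
    vaf_mean = c(0.10, 0.30, 1.0),
    tmad = c(0.02, 0.02, 0.09),
    status = c("baseline", "stable", "PD"))
  calls <- validate_sustained(call_candidates(s, thr), s)
  expect_true(calls$validated[1])
  expect_equal(calls$lead_time_days[1], 70)
})

test_that("lead time reproduces the worked day offsets and rejects negatives", {
  expect_equal(lead_time(112, 241), 129)
  expect_equal(lead_time(100, 141), 41)
  expect_equal(lead_time(86, 150), 64)
  expect_error(lead_time(150, 86), "precedes")
})

test_that("call summaries compute per-category validation rates", {
  mk_calls <- function(n, tngs, swgs, n_valid) {
    tibble::tibble(
      patient_id = sprintf("P%02d", seq_len(n)), therapy_line_id = 1L,
      sample_id = "x", candidate_sample_date = 100,
      trigger_tngs = tngs, trigger_swgs = swgs,
      delta_vaf_mean = 0.2, pct_delta_tmad = 10,
      vaf_mean_at_candidate = 1, tmad_at_candidate = 0.1,
      validated = seq_len(n) <= n_valid,
      clinical_pd_date = ifelse(seq_len(n) <= n_valid, 188, NA),
      lead_time_days = ifelse(seq_len(n) <= n_valid, 88, NA),
      is_lead_time = seq_len(n) <= n_valid)
  }
  calls <- dplyr::bind_rows(
    mk_calls(14, TRUE, TRUE, 10),   # both assays
    mk_calls(16, TRUE, FALSE, 6),   # mean-VAF only
    mk_calls(35, FALSE, TRUE, 12))  # t-MAD only
  cs <- summarize_calls(calls)
  pc <- cs$per_category
  expect_equal(pc$validation_rate[pc$category == "both"], 100 * 10 / 14)
  expect_equal(pc$validation_rate[pc$category == "tNGS_only"], 37.5)
  expect_equal(pc$validation_rate[pc$category == "sWGS_only"], 100 * 12 / 35)
  expect_equal(round(pc$validation_rate[pc$category == "both"], 1), 71.4)
  # empty category: rate undefined, not zero
  cs2 <- summarize_calls(mk_calls(3, TRUE, FALSE, 2))
  pc2 <- cs2$per_category
  expect_true(is.na(pc2$validation_rate[pc2$category == "both"]))
  expect_equal(cs2$median_lead_time_days, 88)
})

test_that("derived thresholds come from per-metric Youden analysis", {
  set.seed(33)
  vm <- c(0.5, stats::runif(8, 0, 0.05), 0.9)
  tm <- c(0.05, stats::runif(8, 0.01, 0.02), 0.2)
  s <- toy_series(vaf_mean = vm, tmad = tm,
                  status = c("baseline", rep("stable", 8), "PD_therapy_change"))
  out <- derive_thresholds(s)
  expect_s3_class(out$roc$delta_vaf_mean, "roc_result")
  expect_equal(out$thresholds$theta_dvaf, out$roc$delta_vaf_mean$youden_cutoff)
  expect_equal(out$thresholds$theta_tmad, out$roc$pct_delta_tmad$youden_cutoff)
})
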