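# Independent brute-force oracles used to pin down the analytical code paths.

# AUC as an explicit pairwise concordance count (ties count 1/2)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) {
    total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  }
  total / (length(pos) * length(neg))
}

# Youden cutoff by exhaustive search over all observed thresholds
# (sensitivity-favoring tie-break, then lowest threshold)
youden_bruteforce <- function(scores, labels) {
  thr <- sort(unique(scores))
  best <- NULL
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-15 ||
        (abs(j - best$j) <= 1e-15 &&
         (sens > best$sens + 1e-15 ||
          (abs(sens - best$sens) <= 1e-15 && t < best$t)))) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Product-limit estimator written out step by step; median is the first
# event time at which the survival estimate drops to 0.5 or below.
km_bruteforce <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  at_risk <- length(time)
  s <- 1
  med <- NA_real_
  for (t in unique(time)) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    if (d > 0) {
      s <- s * (1 - d / n)
      if (is.na(med) && s <= 0.5) med <- t
    }
  }
  list(median = med, surv_final = s)
}

# Two-group log-rank chi-square from the 2xk risk tables
logrank_bruteforce <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  grp <- c(rep("A", length(time_a)), rep("B", length(time_b)))
  o_a <- 0; e_a <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t); n_a <- sum(time >= t & grp == "A")
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == "A")
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (o_a - e_a)^2 / v
}

# Exact two-sided Mann-Whitney p-value by enumerating all group assignments
mann_whitney_enum <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pooled), n)
  u_obs <- u_stat(x, y)
  center <- n * length(y) / 2
  u_all <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-12)
}

# small variant-table builder
obs_tbl <- function(vaf, sample_id = "S1", ...) {
  tibble::tibble(sample_id = sample_id, vaf = vaf, ...)
}

# minimal longitudinal series: one patient, one therapy line, given per-visit
# vaf_mean / tmad / status vectors
toy_series <- function(vaf_mean, tmad, status, dates = NULL, line = 1L,
                       patient = "P1") {
  n <- length(vaf_mean)
  if (is.null(dates)) dates <- seq(0, by = 70, length.out = n)
  clin <- tibble::tibble(
    patient_id = patient, sample_id = sprintf("%s_S%02d", patient, seq_len(n)),
    sample_date_days = dates,
    therapy_line_id = if (length(line) == 1) rep(line, n) else line,
    therapy_agent = "tki", recist_status = status, imaging_date_days = dates)
  summaries <- tibble::tibble(
    sample_id = clin$sample_id,
    n_variants = ifelse(vaf_mean > 0, 2L, 0L),
    vaf_mean = vaf_mean, ctdna_positive = vaf_mean > 0)
  tm <- tibble::tibble(sample_id = clin$sample_id, tmad = tmad)
  build_series(summaries, tm, clin)
}

# bin profile straight from a vector of log2 ratios on a toy genome
log2_profile <- function(values, chrom = "chr1", sample_id = "S1") {
  n <- length(values)
  bins <- tibble::tibble(chrom = chrom,
                         start = seq(0, by = 1e6, length.out = n),
                         end = seq(1e6, by = 1e6, length.out = n))
  ctdnatrack:::new_bin_profile(bins, values, "log2r", sample_id = sample_id)
}
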