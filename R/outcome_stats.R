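#' Kaplan-Meier curves and median time-to-event per group
#'
#' Product-limit estimate of time to progression per group (e.g. therapy
#' lines with vs without detectable ctDNA at baseline). The median is the
#' first time at which the survival estimate drops to 0.5 or below, and is
#' undefined (NA) when the curve never reaches 0.5.
#'
#' @param records A data frame of survival records: `time_days` (> 0),
#'   `event` (logical/0-1, TRUE = progression observed), `group` (label).
#'   Each row is one therapy-line instance, treated as independent.
#'
#' @return A list with `fit` (the [survival::survfit] object) and `medians`
#'   (tibble: `group`, `n`, `events`, `median_days`).
#' @export
km_median <- function(records) {
  records <- validate_survival(records)
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ group, data = records)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("all", names(tab)))
  medians <- tibble::tibble(
    group = sub("^group=", "", rownames(tab)),
    n = as.integer(tab[, "records"]),
    events = as.integer(tab[, "events"]),
    median_days = as.numeric(tab[, "median"]))
  list(fit = fit, medians = medians)
}

#' Log-rank test between two survival groups
#'
#' @param group_a,group_b Data frames of survival records (`time_days`,
#'   `event`) for the two groups.
#'
#' @return A list with `chisq` (1 df), `p_value`, and per-group
#'   observed/expected event counts.
#' @export
logrank <- function(group_a, group_b) {
  a <- validate_survival(group_a, default_group = "A")
  b <- validate_survival(group_b, default_group = "B")
  dat <- dplyr::bind_rows(
    dplyr::mutate(a, .arm = "A"), dplyr::mutate(b, .arm = "B"))
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ .arm, data = dat)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p_value = p,
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Two-group and paired comparisons for lead-time and progression analyses
#'
#' Dispatches to the standard tests used for cohort comparisons: Mann-Whitney
#' U (exact where sample sizes permit), Wilcoxon signed-rank for paired days
#' to progression, one-way ANOVA across more than two groups, and rank
#' correlation for the association between lead time and response duration.
#'
#' @param x,y Numeric vectors. For `anova_oneway`, `x` is the response and
#'   `y` the group labels. For `correlation`, paired observations.
#' @param test One of `"mann_whitney"`, `"wilcoxon_paired"`,
#'   `"anova_oneway"`, `"correlation"`.
#' @param cor_method Correlation type when `test = "correlation"`;
#'   Spearman rank correlation by default.
#'
#' @return A list with `statistic`, `p_value`, `test`, and `estimate` for
#'   correlations.
#' @export
compare_groups <- function(x, y,
                           test = c("mann_whitney", "wilcoxon_paired",
                                    "anova_oneway", "correlation"),
                           cor_method = c("spearman", "pearson")) {
  test <- match.arg(test)
  switch(test,
    mann_whitney = {
      ht <- stats::wilcox.test(x, y, exact = NULL, correct = TRUE)
      list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    wilcoxon_paired = {
      if (length(x) != length(y)) {
        stop("paired test requires equal-length vectors (", length(x),
             " vs ", length(y), ")", call. = FALSE)
      }
      if (all(x == y)) {
        # no nonzero differences: no evidence against symmetry
        return(list(test = test, statistic = 0, p_value = 1))
      }
      ht <- stats::wilcox.test(x, y, paired = TRUE)
      list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    anova_oneway = {
      dat <- data.frame(value = x, grp = factor(y))
      fit <- stats::aov(value ~ grp, data = dat)
      s <- summary(fit)[[1]]
      list(test = test, statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1])
    },
    correlation = {
      cor_method <- match.arg(cor_method)
      ht <- stats::cor.test(x, y, method = cor_method, exact = FALSE)
      list(test = test, statistic = unname(ht$statistic),
           estimate = unname(ht$estimate), p_value = ht$p.value)
    })
}

validate_survival <- function(records, default_group = "all") {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("empty survival group", call. = FALSE)
  if (!all(c("time_days", "event") %in% names(records))) {
    stop("survival records need `time_days` and `event` columns", call. = FALSE)
  }
  if (!"group" %in% names(records)) records$group <- default_group
  if (any(records$time_days <= 0)) {
    stop("time_days must be positive", call. = FALSE)
  }
  records$event <- as.integer(as.logical(records$event))
  records
}

#' Baseline-detectability survival table from a longitudinal series
#'
#' Builds one survival record per therapy line: time from the line's first
#' sample (the therapy baseline) to the first extracranial progression in
#' the line, censored at the last sample otherwise, grouped by whether
#' ctDNA (mean VAF > 0) was detectable at baseline.
#'
#' @param series A `longitudinal_series`.
#'
#' @return A tibble of survival records: `unit_id`, `patient_id`, `group`
#'   (`"baseline_detected"` / `"baseline_undetected"`), `time_days`,
#'   `event`.
#' @export
baseline_survival <- function(series) {
  stopifnot(inherits(series, "longitudinal_series"))
  samples <- dplyr::arrange(series$samples, .data$patient_id,
                            .data$sample_date_days)
  out <- dplyr::group_modify(
    dplyr::group_by(samples, .data$patient_id, .data$therapy_line_id),
    function(df, key) {
      t0 <- df$sample_date_days[1]
      pd <- which(df$recist_status %in% pd_statuses())
      end <- if (length(pd) > 0) df$sample_date_days[pd[1]] else
        df$sample_date_days[nrow(df)]
      time <- end - t0
      if (time <= 0) return(tibble::tibble())  # single-visit line: no follow-up
      tibble::tibble(
        group = if (df$vaf_mean[1] > 0) "baseline_detected" else "baseline_undetected",
        time_days = time,
        event = length(pd) > 0)
    })
  out <- dplyr::ungroup(out)
  out$unit_id <- paste(out$patient_id, out$therapy_line_id, sep = "/")
  out
}
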