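#' Build per-patient longitudinal series with between-visit deltas
#'
#' Joins per-sample mean-VAF summaries, t-MAD scores and clinical annotations
#' into ordered per-patient series and computes the two between-visit change
#' metrics for every consecutive sample pair: delta mean VAF (percentage
#' points) and percent change in t-MAD. A delta is missing, with a
#' machine-readable reason, when the patient has no detectable variant at any
#' time point (`"no_detectable_variants"`, mean-VAF arm), when the previous
#' t-MAD is zero (`"previous_tmad_zero"`) or when a t-MAD score is absent
#' (`"tmad_missing"`).
#'
#' @param sample_summaries Tibble from [summarize_samples()]: `sample_id`,
#'   `n_variants`, `vaf_mean`, `ctdna_positive`.
#' @param tmad_scores Tibble with `sample_id`, `tmad` (e.g. rows from
#'   [compute_tmad()]). May omit samples without a usable profile.
#' @param clinical Tibble with `patient_id`, `sample_id`, `sample_date_days`,
#'   `therapy_line_id`, `recist_status` (one of baseline, response, stable,
#'   PD, PD_therapy_change, PD_intracranial); optionally `therapy_agent`,
#'   `imaging_date_days`.
#'
#' @return A `longitudinal_series` object: list of `samples` (ordered tibble)
#'   and `deltas` (one row per consecutive within-patient pair with columns
#'   `delta_vaf_mean`, `dvaf_reason`, `pct_delta_tmad`, `tmad_reason`,
#'   `same_line`, and the later sample's annotation).
#' @export
build_series <- function(sample_summaries, tmad_scores, clinical) {
  clinical <- tibble::as_tibble(clinical)
  req <- c("patient_id", "sample_id", "sample_date_days", "therapy_line_id",
           "recist_status")
  missing_cols <- setdiff(req, names(clinical))
  if (length(missing_cols) > 0) {
    stop("clinical annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_status <- setdiff(unique(clinical$recist_status), recist_levels())
  if (length(bad_status) > 0) {
    stop("unknown recist_status value(s): ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  samples <- dplyr::left_join(clinical,
                              tibble::as_tibble(sample_summaries), by = "sample_id")
  samples <- dplyr::left_join(samples,
                              tibble::as_tibble(tmad_scores)[, c("sample_id", "tmad")],
                              by = "sample_id")
  if (anyNA(samples$vaf_mean)) {
    stop("sample(s) without a variant-metric summary: ",
         paste(utils::head(samples$sample_id[is.na(samples$vaf_mean)], 5),
               collapse = ", "), call. = FALSE)
  }
  samples <- dplyr::arrange(samples, .data$patient_id, .data$sample_date_days)
  dup <- dplyr::filter(
    dplyr::count(samples, .data$patient_id, .data$sample_date_days),
    .data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate sample dates within patient(s): ",
         paste(unique(dup$patient_id), collapse = ", "), call. = FALSE)
  }

  no_var_patients <- dplyr::summarise(
    dplyr::group_by(samples, .data$patient_id),
    none = all(.data$n_variants == 0L), .groups = "drop")
  no_var_patients <- no_var_patients$patient_id[no_var_patients$none]

  deltas <- dplyr::group_modify(
    dplyr::group_by(samples, .data$patient_id),
    function(df, key) these_deltas(df, key$patient_id %in% no_var_patients))
  deltas <- dplyr::ungroup(deltas)

  structure(list(samples = samples, deltas = deltas), class = "longitudinal_series")
}

recist_levels <- function() {
  c("baseline", "response", "stable", "PD", "PD_therapy_change", "PD_intracranial")
}

pd_statuses <- function() c("PD", "PD_therapy_change")

these_deltas <- function(df, patient_excluded_from_dvaf) {
  n <- nrow(df)
  if (n < 2) {
    return(tibble::tibble(
      sample_id_prev = character(0), sample_id = character(0),
      date_prev = numeric(0), sample_date_days = numeric(0),
      therapy_line_id = df$therapy_line_id[0], recist_status = character(0),
      same_line = logical(0),
      vaf_mean_prev = numeric(0), vaf_mean = numeric(0),
      tmad_prev = numeric(0), tmad = numeric(0),
      delta_vaf_mean = numeric(0), dvaf_reason = character(0),
      pct_delta_tmad = numeric(0), tmad_reason = character(0)))
  }
  prev <- df[-n, ]
  nxt <- df[-1, ]
  dvaf <- delta_vaf_mean(prev$vaf_mean, nxt$vaf_mean)
  dvaf_reason <- rep(NA_character_, n - 1)
  if (patient_excluded_from_dvaf) {
    dvaf[] <- NA_real_
    dvaf_reason[] <- "no_detectable_variants"
  }
  tmad_prev <- prev$tmad
  tmad_next <- nxt$tmad
  pdt <- rep(NA_real_, n - 1)
  tmad_reason <- rep(NA_character_, n - 1)
  missing_t <- is.na(tmad_prev) | is.na(tmad_next)
  tmad_reason[missing_t] <- "tmad_missing"
  zero_prev <- !missing_t & tmad_prev == 0
  tmad_reason[zero_prev] <- "previous_tmad_zero"
  ok <- !missing_t & !zero_prev
  if (any(ok)) {
    pdt[ok] <- pct_delta_tmad(tmad_prev[ok], tmad_next[ok])
  }
  tibble::tibble(
    sample_id_prev = prev$sample_id, sample_id = nxt$sample_id,
    date_prev = prev$sample_date_days, sample_date_days = nxt$sample_date_days,
    therapy_line_id = nxt$therapy_line_id, recist_status = nxt$recist_status,
    same_line = prev$therapy_line_id == nxt$therapy_line_id,
    vaf_mean_prev = prev$vaf_mean, vaf_mean = nxt$vaf_mean,
    tmad_prev = tmad_prev, tmad = tmad_next,
    delta_vaf_mean = dvaf, dvaf_reason = dvaf_reason,
    pct_delta_tmad = pdt, tmad_reason = tmad_reason)
}

#' @export
print.longitudinal_series <- function(x, ...) {
  cat(sprintf("<longitudinal_series> %d patients, %d samples, %d consecutive pairs\n",
              dplyr::n_distinct(x$samples$patient_id), nrow(x$samples), nrow(x$deltas)))
  invisible(x)
}

#' Label between-visit pairs for ROC threshold derivation
#'
#' Each consecutive pair is one independent observation; the label is 1 when
#' the later sample of the pair is annotated as extracranial progressive
#' disease with therapy change (`PD_therapy_change`), 0 otherwise
#' (intracranial-only progression is not the event of interest). Pairs with
#' a missing metric value are dropped for that metric.
#'
#' @param series A `longitudinal_series` from [build_series()].
#'
#' @return A tibble with columns `metric` (`"delta_vaf_mean"` or
#'   `"pct_delta_tmad"`), `score`, `label`, `patient_id`, `sample_id`.
#' @export
label_pairs <- function(series) {
  stopifnot(inherits(series, "longitudinal_series"))
  d <- series$deltas
  lab <- as.integer(d$recist_status == "PD_therapy_change")
  out <- dplyr::bind_rows(
    tibble::tibble(metric = "delta_vaf_mean", score = d$delta_vaf_mean,
                   label = lab, patient_id = d$patient_id, sample_id = d$sample_id),
    tibble::tibble(metric = "pct_delta_tmad", score = d$pct_delta_tmad,
                   label = lab, patient_id = d$patient_id, sample_id = d$sample_id))
  out[!is.na(out$score), , drop = FALSE]
}

#' Derive progression thresholds from a cohort by ROC/Youden analysis
#'
#' Runs [roc_curve()] and [youden_cutoff()] per metric on the labeled pairs
#' of a cohort and returns the resulting threshold set alongside the full
#' ROC results.
#'
#' @param series A `longitudinal_series`.
#' @inheritParams roc_curve
#'
#' @return A list with `thresholds` (a [threshold_set()]) and `roc` (named
#'   list of `roc_result` per metric).
#' @export
derive_thresholds <- function(series, ci_method = "delong") {
  lp <- label_pairs(series)
  rocs <- lapply(split(lp, lp$metric), function(df) {
    youden_cutoff(roc_curve(df$score, df$label, ci_method = ci_method))
  })
  list(
    thresholds = threshold_set(
      theta_dvaf = rocs[["delta_vaf_mean"]]$youden_cutoff,
      theta_tmad = rocs[["pct_delta_tmad"]]$youden_cutoff),
    roc = rocs)
}

#' Decision thresholds for the two progression metrics
#'
#' Defaults are the study-derived cutoffs: a rise in mean VAF of 0.0850
#' percentage points and a relative t-MAD increase of 0.5%.
#'
#' @param theta_dvaf Threshold on delta mean VAF, percentage points.
#' @param theta_tmad Threshold on percent change in t-MAD.
#'
#' @return A named list of class `threshold_set`.
#' @export
threshold_set <- function(theta_dvaf = 0.0850, theta_tmad = 0.5) {
  stopifnot(is.numeric(theta_dvaf), theta_dvaf >= 0,
            is.numeric(theta_tmad), theta_tmad >= 0)
  structure(list(theta_dvaf = theta_dvaf, theta_tmad = theta_tmad),
            class = "threshold_set")
}

#' Call candidate early-molecular-progression events
#'
#' A candidate is any radiographically stable sample whose incoming change
#' metric reaches a threshold (`>=`): delta mean VAF at or above
#' `theta_dvaf` and/or percent t-MAD change at or above `theta_tmad`. The
#' pair must lie within a single therapy line; pairs straddling a line
#' change are never candidates.
#'
#' @param series A `longitudinal_series`.
#' @param thresholds A [threshold_set()].
#'
#' @return A tibble of unvalidated calls: `patient_id`, `therapy_line_id`,
#'   `sample_id`, `candidate_sample_date`, `trigger_tngs`, `trigger_swgs`,
#'   candidate-point metric levels, and `validated`/`clinical_pd_date`/
#'   `lead_time_days`/`is_lead_time` placeholders.
#' @export
call_candidates <- function(series, thresholds = threshold_set()) {
  stopifnot(inherits(series, "longitudinal_series"),
            inherits(thresholds, "threshold_set"))
  d <- series$deltas
  trig_t <- !is.na(d$delta_vaf_mean) & d$delta_vaf_mean >= thresholds$theta_dvaf
  trig_s <- !is.na(d$pct_delta_tmad) & d$pct_delta_tmad >= thresholds$theta_tmad
  sel <- d$recist_status == "stable" & d$same_line & (trig_t | trig_s)
  tibble::tibble(
    patient_id = d$patient_id[sel],
    therapy_line_id = d$therapy_line_id[sel],
    sample_id = d$sample_id[sel],
    candidate_sample_date = d$sample_date_days[sel],
    trigger_tngs = trig_t[sel],
    trigger_swgs = trig_s[sel],
    delta_vaf_mean = d$delta_vaf_mean[sel],
    pct_delta_tmad = d$pct_delta_tmad[sel],
    vaf_mean_at_candidate = d$vaf_mean[sel],
    tmad_at_candidate = d$tmad[sel],
    validated = NA, clinical_pd_date = NA_real_,
    lead_time_days = NA_real_, is_lead_time = FALSE)
}

#' Validate candidates by the sustained-increase rule and assign lead times
#'
#' A candidate is validated when (a) every subsequent sampling point in the
#' same therapy line before the next progression keeps each triggering
#' metric at or above its candidate-point level (minus a relative
#' `tolerance`, default 0: non-decreasing), and (b) an extracranial
#' progressive-disease sample (`PD` or `PD_therapy_change`) occurs later in
#' the same line. Intracranial-only progression neither validates nor
#' terminates the window. Only the first validated candidate per therapy
#' line carries the line's lead time (`is_lead_time`).
#'
#' @param candidates Output of [call_candidates()].
#' @param series The `longitudinal_series` the candidates came from.
#' @param tolerance Relative tolerance on the sustained rule; 0 means
#'   strictly non-decreasing levels.
#'
#' @return The candidates tibble with `validated`, `clinical_pd_date`,
#'   `lead_time_days` and `is_lead_time` filled in.
#' @export
validate_sustained <- function(candidates, series, tolerance = 0) {
  stopifnot(inherits(series, "longitudinal_series"), tolerance >= 0)
  samples <- series$samples
  for (i in seq_len(nrow(candidates))) {
    line <- samples[samples$patient_id == candidates$patient_id[i] &
                      samples$therapy_line_id == candidates$therapy_line_id[i] &
                      samples$sample_date_days > candidates$candidate_sample_date[i], ,
                    drop = FALSE]
    line <- dplyr::arrange(line, .data$sample_date_days)
    pd_idx <- which(line$recist_status %in% pd_statuses())
    if (length(pd_idx) == 0) {
      candidates$validated[i] <- FALSE
      next
    }
    interim <- line[seq_len(pd_idx[1] - 1), , drop = FALSE]
    ok <- TRUE
    if (candidates$trigger_tngs[i]) {
      lvl <- candidates$vaf_mean_at_candidate[i] * (1 - tolerance)
      ok <- ok && all(interim$vaf_mean >= lvl)
    }
    if (candidates$trigger_swgs[i]) {
      lvl <- candidates$tmad_at_candidate[i] * (1 - tolerance)
      ok <- ok && all(is.na(interim$tmad) | interim$tmad >= lvl)
    }
    candidates$validated[i] <- ok
    if (ok) {
      candidates$clinical_pd_date[i] <- line$sample_date_days[pd_idx[1]]
      candidates$lead_time_days[i] <- lead_time(
        candidates$candidate_sample_date[i], line$sample_date_days[pd_idx[1]])
    }
  }
  candidates$validated <- as.logical(candidates$validated)
  first_valid <- dplyr::slice_min(
    dplyr::group_by(candidates[which(candidates$validated), , drop = FALSE],
                    .data$patient_id, .data$therapy_line_id),
    .data$candidate_sample_date, n = 1, with_ties = FALSE)
  key <- paste(candidates$patient_id, candidates$therapy_line_id,
               candidates$candidate_sample_date)
  candidates$is_lead_time <- key %in%
    paste(first_valid$patient_id, first_valid$therapy_line_id,
          first_valid$candidate_sample_date)
  candidates
}

#' Lead time from molecular to radiographic progression
#'
#' @param candidate_date Day of the first molecular-progression observation.
#' @param first_pd_date Day of the first subsequent radiographic progression.
#'
#' @return Days between the two (non-negative); errors on a negative
#'   difference, which indicates mislabeled input.
#' @export
#' @examples
#' lead_time(112, 241)  # 129
lead_time <- function(candidate_date, first_pd_date) {
  diff <- first_pd_date - candidate_date
  if (any(diff < 0, na.rm = TRUE)) {
    stop("radiographic progression precedes the molecular candidate; ",
         "check input labeling", call. = FALSE)
  }
  diff
}

#' Summarize progression calls by triggering-assay category
#'
#' Tallies candidates and validated calls per assay combination (tNGS only,
#' sWGS only, both), the validation rate per category (undefined, not 0,
#' when a category has no candidates), lead-time statistics over
#' first-per-line validated calls, and the number of patients with at least
#' one lead time.
#'
#' @param calls Output of [validate_sustained()].
#'
#' @return A list with `per_category` (tibble: category, n_candidates,
#'   n_validated, validation_rate in percent), `lead_times` (tibble of
#'   first-per-line validated calls), `median_lead_time_days`,
#'   `lead_time_range_days`, `n_patients_with_lead_time`.
#' @export
summarize_calls <- function(calls) {
  category <- dplyr::case_when(
    calls$trigger_tngs & calls$trigger_swgs ~ "both",
    calls$trigger_tngs ~ "tNGS_only",
    TRUE ~ "sWGS_only")
  per_cat <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(category = factor(
      category, levels = c("tNGS_only", "sWGS_only", "both")),
      validated = calls$validated), .data$category, .drop = FALSE),
    n_candidates = dplyr::n(),
    n_validated = sum(.data$validated, na.rm = TRUE),
    .groups = "drop")
  per_cat$validation_rate <- ifelse(
    per_cat$n_candidates > 0,
    100 * per_cat$n_validated / per_cat$n_candidates, NA_real_)
  lt <- calls[calls$is_lead_time, , drop = FALSE]
  list(
    per_category = per_cat,
    lead_times = lt,
    median_lead_time_days = if (nrow(lt) > 0) stats::median(lt$lead_time_days) else NA_real_,
    lead_time_range_days = if (nrow(lt) > 0) range(lt$lead_time_days) else c(NA_real_, NA_real_),
    n_patients_with_lead_time = dplyr::n_distinct(lt$patient_id))
}
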