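#' Run configuration for the end-to-end pipeline
#'
#' @param variants Path to the variant TSV (see [read_variant_table()]).
#' @param clinical Path to the clinical CSV (see [read_clinical_table()]).
#' @param bins_dir Directory of per-sample BED-like bin profiles, or NULL to
#'   skip the shallow-WGS arm.
#' @param thresholds Either `"derive"` (ROC/Youden on the input cohort) or a
#'   numeric pair `c(theta_dvaf, theta_tmad)`; default is the study pair
#'   0.0850 pp / 0.5%.
#' @param detection_floor,germline_cutoff VAF filters in percent.
#' @param sustained_tolerance Relative tolerance for the sustained-increase
#'   validation rule (0 = non-decreasing).
#' @param seed RNG seed recorded in the report (the analysis itself is
#'   deterministic; the seed matters for bootstrap CIs).
#' @param out_dir Output directory for tables and the JSON report.
#' @param ... Unknown keys are rejected.
#'
#' @return A named list of class `run_config`.
#' @export
run_config <- function(variants, clinical, bins_dir = NULL,
                       thresholds = c(0.0850, 0.5),
                       detection_floor = 0.01, germline_cutoff = 30,
                       sustained_tolerance = 0, seed = 1L,
                       out_dir = "ctdnatrack_out", ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown run_config key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(thresholds, "derive") &&
      !(is.numeric(thresholds) && length(thresholds) == 2)) {
    stop('`thresholds` must be "derive" or a numeric pair', call. = FALSE)
  }
  structure(list(variants = variants, clinical = clinical, bins_dir = bins_dir,
                 thresholds = thresholds, detection_floor = detection_floor,
                 germline_cutoff = germline_cutoff,
                 sustained_tolerance = sustained_tolerance,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Analyze an in-memory cohort end to end
#'
#' The computational core of [run_pipeline()], also convenient for synthetic
#' cohorts: per-sample metrics, longitudinal series, (optionally derived)
#' thresholds, candidate calling, sustained validation, call summaries, and
#' baseline-detectability survival.
#'
#' @param variants Variant observations with `sample_id` and `vaf` columns
#'   (percent), e.g. `read_variant_table()` output or a simulated cohort's
#'   `variants` with `vaf_percent` renamed.
#' @param clinical Clinical annotation tibble.
#' @param tmad_scores Tibble `sample_id`, `tmad`, or NULL to skip the sWGS
#'   arm.
#' @param thresholds `"derive"` or a [threshold_set()].
#' @param detection_floor,germline_cutoff,sustained_tolerance See
#'   [run_config()].
#'
#' @return A list: `sample_summaries`, `series`, `thresholds`, `roc` (NULL
#'   unless derived), `calls`, `call_summary`, `survival`.
#' @export
analyze_cohort <- function(variants, clinical, tmad_scores = NULL,
                           thresholds = threshold_set(),
                           detection_floor = 0.01, germline_cutoff = 30,
                           sustained_tolerance = 0) {
  clinical <- tibble::as_tibble(clinical)
  variants <- tibble::as_tibble(variants)
  if (!"vaf" %in% names(variants) && "vaf_percent" %in% names(variants)) {
    variants$vaf <- variants$vaf_percent
  }
  orphans <- setdiff(unique(variants$sample_id), clinical$sample_id)
  if (length(orphans) > 0) {
    stop("variant sample id(s) absent from the clinical table: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  summaries <- summarize_samples(variants, sample_ids = clinical$sample_id,
                                 floor = detection_floor,
                                 germline_cutoff = germline_cutoff)
  if (is.null(tmad_scores)) {
    tmad_scores <- tibble::tibble(sample_id = character(0), tmad = numeric(0))
  }
  series <- build_series(summaries, tmad_scores, clinical)
  roc <- NULL
  if (identical(thresholds, "derive")) {
    derived <- derive_thresholds(series)
    thresholds <- derived$thresholds
    roc <- derived$roc
  }
  calls <- validate_sustained(call_candidates(series, thresholds), series,
                              tolerance = sustained_tolerance)
  surv_records <- baseline_survival(series)
  surv <- NULL
  if (nrow(surv_records) > 0 && dplyr::n_distinct(surv_records$group) == 2 &&
      sum(surv_records$event) > 0) {
    km <- km_median(surv_records)
    lr <- logrank(surv_records[surv_records$group == "baseline_detected", ],
                  surv_records[surv_records$group == "baseline_undetected", ])
    surv <- list(records = surv_records, medians = km$medians, logrank = lr)
  }
  list(sample_summaries = summaries, series = series, thresholds = thresholds,
       roc = roc, calls = calls, call_summary = summarize_calls(calls),
       survival = surv)
}

#' Run the full file-to-report pipeline
#'
#' Reads the variant, clinical and (optionally) bin-profile inputs, executes
#' metrics, series construction, threshold handling, progression calling,
#' validation, summaries and survival stratification, and writes the delta
#' table, call table, per-sample summary and a single JSON report to the
#' output directory.
#'
#' @param config A [run_config()].
#'
#' @return The report list, invisibly. Output files: `sample_summaries.tsv`,
#'   `deltas.tsv`, `progression_calls.tsv`, `survival_records.tsv`,
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  variants <- read_variant_table(config$variants)
  clinical <- read_clinical_table(config$clinical)
  tmad_scores <- NULL
  if (!is.null(config$bins_dir)) {
    files <- list.files(config$bins_dir, pattern = "\\.tsv$", full.names = TRUE)
    tmad_scores <- dplyr::bind_rows(lapply(files, function(f) {
      compute_tmad(read_bin_profile(f))
    }))
    orphan_bins <- setdiff(tmad_scores$sample_id, clinical$sample_id)
    if (length(orphan_bins) > 0) {
      stop("bin profile sample id(s) absent from the clinical table: ",
           paste(utils::head(orphan_bins, 5), collapse = ", "), call. = FALSE)
    }
  }
  thresholds <- if (identical(config$thresholds, "derive")) "derive" else
    threshold_set(config$thresholds[1], config$thresholds[2])
  res <- analyze_cohort(variants, clinical, tmad_scores,
                        thresholds = thresholds,
                        detection_floor = config$detection_floor,
                        germline_cutoff = config$germline_cutoff,
                        sustained_tolerance = config$sustained_tolerance)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$sample_summaries,
                   file.path(config$out_dir, "sample_summaries.tsv"), progress = FALSE)
  readr::write_tsv(res$series$deltas, file.path(config$out_dir, "deltas.tsv"),
                   na = "NA", progress = FALSE)
  readr::write_tsv(res$calls, file.path(config$out_dir, "progression_calls.tsv"),
                   na = "NA", progress = FALSE)
  if (!is.null(res$survival)) {
    readr::write_tsv(res$survival$records,
                     file.path(config$out_dir, "survival_records.tsv"), progress = FALSE)
  }
  report <- build_report(res, config)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(report)
}

build_report <- function(res, config) {
  cs <- res$call_summary
  report <- list(
    schema_version = "1.0",
    config = unclass(config),
    n_samples = nrow(res$sample_summaries),
    pct_ctdna_positive = 100 * mean(res$sample_summaries$ctdna_positive),
    n_delta_vaf_mean = sum(!is.na(res$series$deltas$delta_vaf_mean)),
    n_pct_delta_tmad = sum(!is.na(res$series$deltas$pct_delta_tmad)),
    thresholds = unclass(res$thresholds),
    calls = list(
      per_category = cs$per_category,
      median_lead_time_days = cs$median_lead_time_days,
      lead_time_range_days = cs$lead_time_range_days,
      n_patients_with_lead_time = cs$n_patients_with_lead_time))
  if (!is.null(res$roc)) {
    report$roc <- lapply(res$roc, function(r) {
      list(auc = r$auc, auc_ci = r$auc_ci, p_value = r$p_value,
           youden_cutoff = r$youden_cutoff, youden_sens = r$youden_sens,
           youden_spec = r$youden_spec, n_pos = r$n_pos, n_neg = r$n_neg)
    })
  }
  if (!is.null(res$survival)) {
    report$survival <- list(medians = res$survival$medians,
                            logrank_chisq = res$survival$logrank$chisq,
                            logrank_p = res$survival$logrank$p_value)
  }
  report
}
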