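#' Classify variant observations as germline or somatic by VAF
#'
#' Plasma variant calls without a matched normal are classified by allele
#' frequency: calls at or above the germline cutoff (default 30% VAF) are
#' treated as germline polymorphisms and flagged for exclusion from tumor
#' burden metrics; calls below it are treated as somatic.
#'
#' @param observations A data frame of variant observations with at least a
#'   numeric `vaf` column in percent (0--100). Typically the output of
#'   [read_variant_table()], which maps `vaf_percent` to `vaf`.
#' @param germline_cutoff VAF in percent at or above which a call is
#'   classified germline. Default 30.
#'
#' @return The input with an `origin` column set to `"germline"` or
#'   `"somatic"`.
#' @export
#' @examples
#' obs <- tibble::tibble(vaf = c(45, 30, 0.5))
#' classify_germline(obs)$origin
classify_germline <- function(observations, germline_cutoff = 30) {
  observations <- as_variant_tbl(observations)
  validate_vaf(observations$vaf)
  origin <- rep("somatic", nrow(observations))
  origin[observations$vaf >= germline_cutoff] <- "germline"
  observations$origin <- origin
  observations
}

#' Apply the VAF detection floor
#'
#' Retains only observations whose VAF meets the calling threshold of the
#' assay (default 0.01% VAF for ultra-deep targeted sequencing). Row order is
#' preserved.
#'
#' @inheritParams classify_germline
#' @param floor Detection floor in percent VAF; observations with
#'   `vaf < floor` are dropped. Must be non-negative. Default 0.01.
#'
#' @return The filtered data frame.
#' @export
apply_detection_floor <- function(observations, floor = 0.01) {
  observations <- as_variant_tbl(observations)
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) || floor < 0) {
    stop("`floor` must be a single non-negative number, got: ",
         deparse(floor), call. = FALSE)
  }
  validate_vaf(observations$vaf)
  observations[observations$vaf >= floor, , drop = FALSE]
}

#' Per-sample mean variant allele frequency
#'
#' The per-sample ctDNA burden metric from targeted sequencing: the sum of
#' all somatic VAFs divided by the number of detected variants. With no
#' detected variant the mean is defined as 0.
#'
#' @param somatic_observations A data frame of somatic, post-floor variant
#'   observations with a numeric `vaf` column in percent.
#'
#' @return A single number: the mean VAF in percent (0 when no variants).
#' @export
#' @examples
#' compute_vaf_mean(tibble::tibble(vaf = c(0.1, 0.2, 0.3)))  # 0.2
compute_vaf_mean <- function(somatic_observations) {
  somatic_observations <- as_variant_tbl(somatic_observations, allow_empty = TRUE)
  v <- somatic_observations$vaf
  if (length(v) == 0L) return(0)
  validate_vaf(v)
  sum(v) / length(v)
}

#' Change in mean VAF between two successive samples
#'
#' @param vaf_mean_prev Mean VAF in percent at the earlier time point.
#' @param vaf_mean_next Mean VAF in percent at the later time point.
#'
#' @return Signed difference `vaf_mean_next - vaf_mean_prev` in percentage
#'   points; positive values indicate rising ctDNA burden.
#' @export
delta_vaf_mean <- function(vaf_mean_prev, vaf_mean_next) {
  stopifnot(is.numeric(vaf_mean_prev), is.numeric(vaf_mean_next))
  if (any(vaf_mean_prev < 0, na.rm = TRUE) || any(vaf_mean_next < 0, na.rm = TRUE)) {
    stop("mean VAFs must be non-negative", call. = FALSE)
  }
  vaf_mean_next - vaf_mean_prev
}

#' Summarize variant calls into per-sample ctDNA metrics
#'
#' Runs the full targeted-sequencing metric chain per sample: germline
#' classification, detection floor, and mean-VAF computation. A sample is
#' flagged ctDNA-positive when at least one somatic observation survives both
#' filters. Calls without a quantifiable VAF contribute to positivity but
#' are excluded from the mean; copy-number calls carry no VAF in the input
#' schema and are handled this way upstream by the reader.
#'
#' @param observations A data frame of variant observations with columns
#'   `sample_id` and `vaf` (percent). Additional columns are carried along
#'   during filtering but not summarized.
#' @param sample_ids Optional character vector of all sample identifiers that
#'   should appear in the output, including samples with zero calls (which a
#'   variant table cannot represent by itself). Defaults to the samples seen
#'   in `observations`.
#' @param floor Detection floor in percent VAF. Default 0.01.
#' @param germline_cutoff Germline cutoff in percent VAF. Default 30.
#'
#' @return A tibble with one row per sample: `sample_id`, `n_variants`,
#'   `vaf_mean`, `ctdna_positive`.
#' @export
summarize_samples <- function(observations, sample_ids = NULL,
                              floor = 0.01, germline_cutoff = 30) {
  observations <- as_variant_tbl(observations, allow_empty = TRUE)
  if (nrow(observations) > 0 && is.null(observations$sample_id)) {
    stop("`observations` must carry a sample_id column", call. = FALSE)
  }
  somatic <- observations
  if (nrow(somatic) > 0) {
    somatic <- classify_germline(somatic, germline_cutoff)
    somatic <- somatic[somatic$origin == "somatic", , drop = FALSE]
    somatic <- apply_detection_floor(somatic, floor)
  }
  ids <- sample_ids %||% unique(observations$sample_id)
  per_sample <- dplyr::summarise(
    dplyr::group_by(somatic, .data$sample_id),
    n_variants = dplyr::n(),
    vaf_mean = sum(.data$vaf) / dplyr::n(),
    .groups = "drop"
  )
  out <- tibble::tibble(sample_id = as.character(ids))
  out <- dplyr::left_join(out, per_sample, by = "sample_id")
  out$n_variants <- ifelse(is.na(out$n_variants), 0L, out$n_variants)
  out$vaf_mean <- ifelse(is.na(out$vaf_mean), 0, out$vaf_mean)
  out$ctdna_positive <- out$n_variants > 0L
  out
}

# -- internal helpers ---------------------------------------------------------

as_variant_tbl <- function(x, allow_empty = FALSE) {
  if (!is.data.frame(x)) {
    stop("variant observations must be a data frame", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"vaf" %in% names(x) && "vaf_percent" %in% names(x)) {
    x$vaf <- x$vaf_percent
  }
  if (!"vaf" %in% names(x)) {
    if (allow_empty && nrow(x) == 0L) {
      x$vaf <- numeric(0)
    } else {
      stop("variant observations must carry a numeric `vaf` column (percent)",
           call. = FALSE)
    }
  }
  x
}

validate_vaf <- function(vaf) {
  bad <- which(!is.finite(vaf) | vaf < 0 | vaf > 100)
  if (length(bad) > 0) {
    stop("VAF out of [0, 100] or non-finite at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value(s): ", paste(utils::head(vaf[bad], 5), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(vaf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
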