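#' Construct a genome bin template
#'
#' Tiles a genome into fixed-width, 0-based half-open bins (the last bin of
#' each chromosome may be short). Bins are the coordinate system for shallow
#' whole-genome read-count profiles and t-MAD computation.
#'
#' @param genome A data frame with columns `chrom` and `length` (bp).
#' @param bin_width Bin width in bp; 1 Mb by default.
#'
#' @return A `bin_profile` object with `values = NA` and all bins retained.
#' @export
make_bin_template <- function(genome, bin_width = 1e6) {
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (any(genome$length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  bins <- dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_width)
    tibble::tibble(
      chrom = genome$chrom[i],
      start = starts,
      end = pmin(starts + bin_width, genome$length[i])
    )
  }))
  new_bin_profile(bins, values = rep(NA_real_, nrow(bins)), value_kind = "empty")
}

new_bin_profile <- function(bins, values, value_kind,
                            mask = rep(TRUE, nrow(bins)), sample_id = NA_character_) {
  stopifnot(nrow(bins) == length(values), length(mask) == nrow(bins))
  structure(
    list(bins = tibble::as_tibble(bins), values = as.numeric(values),
         value_kind = value_kind, mask = as.logical(mask), sample_id = sample_id),
    class = "bin_profile"
  )
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("<bin_profile> %d bins (%d retained), value_kind=%s, sample=%s\n",
              nrow(x$bins), sum(x$mask), x$value_kind, x$sample_id))
  invisible(x)
}

#' Count fragment midpoints into genome bins
#'
#' Each fragment is assigned to exactly one bin by its midpoint under the
#' 0-based half-open convention, so the total count is conserved.
#'
#' @param fragment_midpoints A data frame with columns `chrom` and `pos`
#'   (0-based midpoint coordinate).
#' @param template A `bin_profile` from [make_bin_template()].
#'
#' @return A `bin_profile` with `value_kind = "count"`.
#' @export
bin_fragments <- function(fragment_midpoints, template) {
  stopifnot(inherits(template, "bin_profile"))
  fm <- tibble::as_tibble(fragment_midpoints)
  stopifnot(all(c("chrom", "pos") %in% names(fm)))
  bins <- template$bins
  counts <- rep(0, nrow(bins))
  chrom_len <- dplyr::summarise(dplyr::group_by(bins, .data$chrom),
                                len = max(.data$end), .groups = "drop")
  for (i in seq_len(nrow(fm))) {
    len <- chrom_len$len[match(fm$chrom[i], chrom_len$chrom)]
    if (is.na(len) || fm$pos[i] < 0 || fm$pos[i] >= len) {
      stop("fragment ", i, " at ", fm$chrom[i], ":", fm$pos[i],
           " lies outside the declared genome", call. = FALSE)
    }
    j <- which(bins$chrom == fm$chrom[i] & bins$start <= fm$pos[i] & fm$pos[i] < bins$end)
    counts[j] <- counts[j] + 1
  }
  new_bin_profile(bins, counts, "count", mask = template$mask)
}

#' Normalize bin counts to log2 copy-number ratios
#'
#' Converts per-bin fragment counts into log2 ratios of depth fractions
#' relative to a (pooled) reference profile: `log2((c_i/sum c)/(r_i/sum r))`
#' per retained bin. Bins with a zero reference fraction cannot be
#' normalized and are masked with a warning.
#'
#' @param counts A `bin_profile` with `value_kind = "count"`.
#' @param reference A `bin_profile` of counts (or expected depth) on the same
#'   bin template, e.g. a pooled panel of healthy controls.
#'
#' @return A `bin_profile` with `value_kind = "log2r"`; masked bins carry NA.
#' @export
normalize_to_log2 <- function(counts, reference) {
  stopifnot(inherits(counts, "bin_profile"), inherits(reference, "bin_profile"))
  if (!identical(counts$bins, reference$bins)) {
    stop("counts and reference must share a bin template", call. = FALSE)
  }
  mask <- counts$mask & reference$mask
  zero_ref <- mask & (reference$values <= 0 | !is.finite(reference$values))
  if (any(zero_ref)) {
    warning(sum(zero_ref), " retained bin(s) have zero reference depth; auto-masked")
    mask[zero_ref] <- FALSE
  }
  c_frac <- counts$values / sum(counts$values[mask])
  r_frac <- reference$values / sum(reference$values[mask])
  vals <- rep(NA_real_, length(mask))
  vals[mask] <- log2(c_frac[mask] / r_frac[mask])
  new_bin_profile(counts$bins, vals, "log2r", mask = mask, sample_id = counts$sample_id)
}

#' Build a variance-trim mask from control log2 profiles
#'
#' Masks the `trim_fraction` of bins with the highest log2-ratio variance
#' across a set of control samples, plus any bin with a missing value in any
#' control. The retained set defines which bins enter t-MAD.
#'
#' @param control_profiles A list of at least two `bin_profile` objects with
#'   `value_kind = "log2r"` on a shared template.
#' @param trim_fraction Fraction of bins (by highest variance) to mask;
#'   default 0.05.
#'
#' @return A logical vector, `TRUE` for retained bins.
#' @export
build_trim_mask <- function(control_profiles, trim_fraction = 0.05) {
  if (!is.list(control_profiles) || length(control_profiles) < 2) {
    stop("need at least 2 control profiles to estimate bin variance; ",
         "with fewer, supply a published static mask instead", call. = FALSE)
  }
  stopifnot(trim_fraction >= 0, trim_fraction <= 1)
  vals <- vapply(control_profiles, function(p) p$values,
                 numeric(length(control_profiles[[1]]$values)))
  v <- apply(vals, 1, stats::var)
  keep <- !apply(vals, 1, anyNA)
  n_trim <- floor(trim_fraction * length(v))
  if (n_trim > 0) {
    # ties at the variance cutoff are broken by bin order (deterministic)
    ord <- order(v, decreasing = TRUE)
    keep[ord[seq_len(n_trim)]] <- FALSE
  }
  if (!any(keep)) stop("trim mask retains no bins", call. = FALSE)
  keep
}

#' t-MAD genomic instability score
#'
#' The trimmed median absolute deviation from the copy-number-neutral state:
#' the median of |log2 ratio| over retained autosomal bins. Sex chromosomes
#' are excluded to avoid sex-dependent neutral-state ambiguity.
#'
#' @param log2_profile A `bin_profile` with `value_kind = "log2r"`.
#' @param mask Optional logical retention mask (e.g. from
#'   [build_trim_mask()]); combined with the profile's own mask.
#'
#' @return A one-row tibble: `sample_id`, `tmad`, `n_bins_used`.
#' @export
compute_tmad <- function(log2_profile, mask = NULL) {
  stopifnot(inherits(log2_profile, "bin_profile"))
  if (!identical(log2_profile$value_kind, "log2r")) {
    stop("t-MAD requires a log2-ratio profile, got value_kind=",
         log2_profile$value_kind, call. = FALSE)
  }
  keep <- log2_profile$mask & !is.na(log2_profile$values)
  if (!is.null(mask)) keep <- keep & mask
  keep <- keep & !is_sex_chrom(log2_profile$bins$chrom)
  if (!any(keep)) stop("no retained autosomal bins for t-MAD", call. = FALSE)
  tibble::tibble(
    sample_id = log2_profile$sample_id,
    tmad = stats::median(abs(log2_profile$values[keep])),
    n_bins_used = sum(keep)
  )
}

is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom)) %in% c("X", "Y")
}

#' Relative change in t-MAD between successive samples
#'
#' @param tmad_prev t-MAD at the earlier time point; must be positive for a
#'   defined relative change.
#' @param tmad_next t-MAD at the later time point.
#'
#' @return Signed percent change `100 * (tmad_next - tmad_prev) / tmad_prev`;
#'   `NA` with a warning when `tmad_prev` is 0 (excluded downstream).
#' @export
pct_delta_tmad <- function(tmad_prev, tmad_next) {
  stopifnot(is.numeric(tmad_prev), is.numeric(tmad_next))
  if (any(tmad_prev < 0 | tmad_next < 0, na.rm = TRUE)) {
    stop("t-MAD scores must be non-negative", call. = FALSE)
  }
  out <- 100 * (tmad_next - tmad_prev) / tmad_prev
  zero <- !is.na(tmad_prev) & tmad_prev == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with previous t-MAD = 0: ",
            "relative change undefined, set to NA")
    out[zero] <- NA_real_
  }
  out
}
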