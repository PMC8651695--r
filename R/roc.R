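#' ROC curve, AUC and confidence interval for a progression metric
#'
#' Sweeps decision thresholds over the observed metric values with the
#' predicate `score >= threshold` calling a pair "progression". The AUC is
#' the normalized rank-sum concordance (ties counted 1/2), identical to the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`. The 95% CI and the
#' p-value against AUC = 0.5 use the DeLong variance by default; a stratified
#' bootstrap is available as an option.
#'
#' @param scores Numeric metric values, one per between-visit pair (e.g.
#'   delta mean VAF in percentage points, or %-change in t-MAD).
#' @param labels Binary labels, 1 for the event of interest (progressive
#'   disease with therapy change at the later visit), 0 otherwise.
#' @param ci_method `"delong"` (default, deterministic) or `"bootstrap"`
#'   (percentile CI; set the RNG seed for reproducibility).
#' @param conf_level Confidence level for the AUC interval. Default 0.95.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#'
#' @return An object of class `roc_result`: a list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, in percent), `auc`,
#'   `auc_ci`, `p_value`, `n_pos`, `n_neg`, plus Youden-cutoff fields filled
#'   by [youden_cutoff()].
#' @export
roc_curve <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                      conf_level = 0.95, n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(labels))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes present (n_pos=", n_pos,
         ", n_neg=", n_neg, ")", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) 100 * sum(scores >= t & labels == 1L) / n_pos, 0)
  spec <- vapply(thr, function(t) 100 * sum(scores < t & labels == 0L) / n_neg, 0)
  auc <- auc_rank(scores, labels)
  if (ci_method == "delong") {
    v <- delong_variance(scores, labels)
    se <- sqrt(v)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
    p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  } else {
    pos <- scores[labels == 1L]
    neg <- scores[labels == 0L]
    boot <- vapply(seq_len(n_boot), function(i) {
      s <- c(sample(pos, n_pos, replace = TRUE), sample(neg, n_neg, replace = TRUE))
      auc_rank(s, c(rep(1L, n_pos), rep(0L, n_neg)))
    }, 0)
    ci <- unname(stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
    se <- stats::sd(boot)
    p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else NA_real_
  }
  structure(
    list(curve = tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec),
         auc = auc, auc_ci = ci, p_value = p, n_pos = n_pos, n_neg = n_neg,
         ci_method = ci_method, conf_level = conf_level,
         youden_cutoff = NA_real_, youden_sens = NA_real_, youden_spec = NA_real_),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f [%.4f-%.4f] (%s), P = %.4g; n = %d pos / %d neg\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method, x$p_value,
              x$n_pos, x$n_neg))
  if (!is.na(x$youden_cutoff)) {
    cat(sprintf("  Youden cutoff %.4g: sensitivity %.2f%%, specificity %.2f%%\n",
                x$youden_cutoff, x$youden_sens, x$youden_spec))
  }
  invisible(x)
}

# AUC as normalized midrank sum (Mann-Whitney concordance, ties = 1/2)
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong AUC variance from placement values
delong_variance <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s10 <- if (length(pos) > 1) stats::var(v10) else 0
  s01 <- if (length(neg) > 1) stats::var(v01) else 0
  s10 / length(pos) + s01 / length(neg)
}

#' Youden-index optimal cutoff
#'
#' Selects the observed threshold maximizing sensitivity + specificity - 1.
#' Ties are broken in favor of higher sensitivity (the more inclusive
#' cutoff), then lower threshold.
#'
#' @param roc An `roc_result` from [roc_curve()].
#'
#' @return The input with `youden_cutoff`, `youden_sens`, `youden_spec`
#'   (percent) filled in.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  cur <- roc$curve[is.finite(roc$curve$threshold), , drop = FALSE]
  j <- cur$sensitivity + cur$specificity - 100
  best <- which(j == max(j))
  if (length(best) > 1) {
    best <- best[cur$sensitivity[best] == max(cur$sensitivity[best])]
    best <- best[which.min(cur$threshold[best])]
  }
  roc$youden_cutoff <- cur$threshold[best]
  roc$youden_sens <- cur$sensitivity[best]
  roc$youden_spec <- cur$specificity[best]
  roc
}
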