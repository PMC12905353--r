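#' Derive the ignition threshold from observed-zero cells
#'
#' The burnt-area model is probabilistic: its fitted values never reach
#' zero, so fire size and intensity need an ignition threshold below which a
#' cell is treated as non-burnable. The threshold is a quantile (the median
#' by default) of the fitted burnt-area values in cells whose *observed*
#' burnt area is zero, computed with the linear-interpolation quantile
#' definition. The returned report carries the classification metrics of the
#' resulting burnable/non-burnable rule (see [tss()]).
#'
#' @param fitted_BA Fitted burnt-area fractions (strictly positive).
#' @param observed_BA Observed burnt-area fractions.
#' @param percentile Quantile of the zero-cell fitted distribution, in
#'   (0, 1).
#' @return One-row data.frame of class `threshold_report`: `percentile`,
#'   `threshold`, `TSS`, `sensitivity`, `specificity`, `maxTSS`,
#'   `n_zero_cells`.
#' @export
#' @examples
#' derive_threshold(c(0.002, 0.0005, 0.0001, 0.3), c(0, 0, 0, 0.2))
derive_threshold <- function(fitted_BA, observed_BA, percentile = 0.5) {
  if (length(fitted_BA) != length(observed_BA))
    stop("fitted and observed fields must be co-registered")
  if (any(percentile <= 0 | percentile >= 1))
    stop("percentile must lie in (0, 1)")
  zero <- observed_BA == 0
  if (!any(zero)) stop("no observed-zero cells: threshold undefined")
  thr <- stats::quantile(fitted_BA[zero], percentile, names = FALSE, type = 7)
  metrics <- tss(fitted_BA, observed_BA, thr)
  out <- data.frame(percentile = percentile, threshold = thr,
                    TSS = metrics$TSS, sensitivity = metrics$sensitivity,
                    specificity = metrics$specificity, maxTSS = metrics$maxTSS,
                    n_zero_cells = sum(zero))
  class(out) <- c("threshold_report", class(out))
  out
}

#' True Skill Statistic of an ignition threshold
#'
#' Cells with observed burnt area > 0 are the positives; a cell is predicted
#' burnable when its fitted burnt area is at or above the threshold.
#' Sensitivity = TP/(TP+FN) measures how well the rule captures observed
#' burning, specificity = TN/(TN+FP) how well it excludes fire-free cells,
#' and TSS = sensitivity + specificity - 1 balances the two independently of
#' prevalence. `maxTSS` is reported as TSS + 1 (equivalently sensitivity +
#' specificity).
#'
#' @inheritParams derive_threshold
#' @param threshold Fractional burnt-area threshold (> 0).
#' @return List with `sensitivity`, `specificity`, `TSS`, `maxTSS`.
#' @export
tss <- function(fitted_BA, observed_BA, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  obs_pos <- observed_BA > 0
  if (!any(obs_pos) || all(obs_pos))
    stop("TSS undefined: need both observed-positive and observed-zero cells")
  pred_pos <- fitted_BA >= threshold
  sens <- sum(pred_pos & obs_pos) / sum(obs_pos)
  spec <- sum(!pred_pos & !obs_pos) / sum(!obs_pos)
  list(sensitivity = sens, specificity = spec,
       TSS = sens + spec - 1, maxTSS = sens + spec)
}

#' Threshold skill across candidate percentiles
#'
#' Evaluates [derive_threshold()] at each percentile, giving the
#' sensitivity/specificity trade-off curve: as the percentile (and hence the
#' threshold) rises, sensitivity is non-increasing and specificity
#' non-decreasing.
#'
#' @inheritParams derive_threshold
#' @param percentiles Sorted vector of percentiles in (0, 1).
#' @return data.frame, one `threshold_report` row per percentile.
#' @export
tss_curve <- function(fitted_BA, observed_BA,
                      percentiles = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  if (is.unsorted(percentiles)) stop("percentiles must be sorted")
  out <- do.call(rbind, lapply(percentiles, function(p) {
    derive_threshold(fitted_BA, observed_BA, p)
  }))
  rownames(out) <- NULL
  out
}

#' Gate fire size and intensity below the ignition threshold
#'
#' Sets fire size and intensity to zero wherever the predicted burnt area
#' falls below the threshold, leaving other cells untouched (the operation
#' is idempotent), and reports the share of cells gated (the "unburnt"
#' percentage).
#'
#' @param BA_pred Predicted burnt-area fractions.
#' @param FS_pred,FI_pred Predicted fire size / intensity fields.
#' @param threshold Ignition threshold (>= 0).
#' @return List with gated `FS`, `FI`, logical `gated` mask and
#'   `unburnt_pct` (percentage of cells gated).
#' @export
apply_threshold <- function(BA_pred, FS_pred, FI_pred, threshold) {
  n <- length(BA_pred)
  if (length(FS_pred) != n || length(FI_pred) != n)
    stop("shape mismatch: BA, FS and FI fields must be co-registered")
  gated <- BA_pred < threshold
  FS_pred[gated] <- 0
  FI_pred[gated] <- 0
  list(FS = FS_pred, FI = FI_pred, gated = gated,
       unburnt_pct = 100 * mean(gated))
}
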