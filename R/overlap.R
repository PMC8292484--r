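# Overlap between a binarized image and its source, and the 0/1/2 quality
# score used to grade binarization thresholds.

#' Subtraction-pipeline overlap between original image and binary mask
#'
#' Emulates the clamped 8-bit subtraction `original - 255 * mask`: signal
#' under the mask is removed, signal left outside survives as the residual.
#' The overlap percentage is the fraction of total image signal captured by
#' the mask, `100 * (1 - sum(residual) / sum(original))`.  A fraction of
#' mask area lying on below-average signal is reported as a diagnostic but
#' plays no role in scoring.
#'
#' @param original integer matrix, 8-bit grayscale.
#' @param mask logical matrix of the same dimensions.
#' @return an `overlap_result` with fields `overlap_pct`, `mode`
#'   (`"signal_residual"`), `residual_sum` and `false_foreground_pct`.
#' @export
subtract_overlap <- function(original, mask) {
  if (!all(dim(original) == dim(mask))) stop("image and mask dimensions differ")
  tot <- sum(as.numeric(original))
  if (tot <= 0) stop("original image has zero total signal; overlap undefined")
  residual <- pmax(original - 255 * mask, 0)
  rs <- sum(as.numeric(residual))
  ff <- if (any(mask)) 100 * sum(original[mask] < mean(original)) / sum(mask) else 0
  structure(list(overlap_pct = 100 * (1 - rs / tot),
                 mode = "signal_residual",
                 residual_sum = rs,
                 false_foreground_pct = ff),
            class = "overlap_result")
}

#' Sensitivity of a mask with respect to a ground-truth mask
#'
#' Fraction of true vessel pixels recovered by the mask,
#' `100 * |mask & truth| / |truth|`.  Used on synthetic eyes where the
#' generator's vessel truth stands in for the original reconstruction.
#'
#' @param truth logical ground-truth mask (non-empty).
#' @param mask logical candidate mask, same dimensions.
#' @return an `overlap_result` with `mode = "truth_sensitivity"`.
#' @export
truth_overlap <- function(truth, mask) {
  if (!all(dim(truth) == dim(mask))) stop("mask dimensions differ")
  nt <- sum(truth)
  if (nt == 0) stop("ground-truth mask is empty; overlap undefined")
  structure(list(overlap_pct = 100 * sum(mask & truth) / nt,
                 mode = "truth_sensitivity",
                 residual_sum = sum(truth & !mask),
                 false_foreground_pct = 100 * sum(mask & !truth) / sum(mask)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %.2f%% (%s)\n", x$overlap_pct, x$mode))
  invisible(x)
}

#' Quality score from an overlap percentage
#'
#' Ordinal 0/1/2 grading of binarized images: 2 for overlap >= 80%,
#' 1 for overlap in [20%, 80%), 0 below 20%.  The bands partition
#' [0, 100], closed on the left of each upper band.
#'
#' @param x an `overlap_result` or a numeric vector of percentages.
#' @return integer vector of scores in {0, 1, 2}.
#' @export
quality_score <- function(x) {
  if (inherits(x, "overlap_result")) x <- x$overlap_pct
  if (anyNA(x)) stop("overlap percentage contains NA")
  ifelse(x >= 80, 2L, ifelse(x >= 20, 1L, 0L))
}
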