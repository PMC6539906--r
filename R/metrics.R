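#' Pixel-level true positive rate
#'
#' Fraction of ground-truth fruit pixels that the prediction also marks as
#' fruit: `TPR = NTDF / NF`, where NTDF counts pixels set in both masks and
#' NF counts fruit pixels in the truth.
#'
#' @param pred,truth binary matrices of matching shape (nonzero = fruit).
#' @return a proportion in \[0, 1\].
#' @export
mask_tpr <- function(pred, truth) {
  check_mask_pair(pred, truth)
  nf <- sum(truth != 0)
  if (nf == 0) stop("truth mask has no fruit pixels; TPR undefined",
                    call. = FALSE)
  sum(pred != 0 & truth != 0) / nf
}

#' Pixel-level false positive rate
#'
#' Fraction of ground-truth background pixels falsely marked as fruit:
#' `FPR = NFDF / NB`.
#'
#' @inheritParams mask_tpr
#' @return a proportion in \[0, 1\].
#' @export
mask_fpr <- function(pred, truth) {
  check_mask_pair(pred, truth)
  nb <- sum(truth == 0)
  if (nb == 0) stop("truth mask has no background pixels; FPR undefined",
                    call. = FALSE)
  sum(pred != 0 & truth == 0) / nb
}

check_mask_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes do not match", call. = FALSE)
  invisible(NULL)
}

#' F-score balancing TPR against FPR
#'
#' `F = 2 * TPR * (1 - FPR) / (TPR + (1 - FPR))` — the harmonic-mean-style
#' balance of the hit rate and the complement of the false-alarm rate,
#' which is the selection criterion used throughout the package (threshold
#' selection, combination selection, stop-condition tuning). Defined as 0
#' when the denominator vanishes (TPR = 0 and FPR = 1, the limiting worst
#' case). Vectorized.
#'
#' @param tpr,fpr proportions in \[0, 1\].
#' @return the F-score in \[0, 1\].
#' @export
f_score <- function(tpr, fpr) {
  stopifnot(all(tpr >= 0 & tpr <= 1), all(fpr >= 0 & fpr <= 1))
  den <- tpr + (1 - fpr)
  ifelse(den == 0, 0, 2 * tpr * (1 - fpr) / den)
}

#' ROC curve of a single color dimension
#'
#' Sweeps `n_levels` evenly spaced candidate thresholds over the channel
#' range and classifies a value as fruit when `value > threshold`
#' (direction `"gt"`) or `value < threshold` (direction `"lt"`, strict
#' inequalities). TPR is computed over the fruit-pixel values and FPR over
#' the background-pixel values.
#'
#' @param fruit_values,bg_values numeric vectors of channel values for
#'   fruit and background pixels.
#' @param direction `"gt"` or `"lt"`.
#' @param n_levels number of candidate thresholds (>= 2); the default 256
#'   matches 8-bit source precision.
#' @param range length-2 numeric, the channel range to sweep; defaults to
#'   the joint range of the supplied values.
#' @return a data frame with columns `threshold`, `tpr`, `fpr`, in
#'   threshold order.
#' @export
roc_curve <- function(fruit_values, bg_values, direction = c("gt", "lt"),
                      n_levels = 256, range = NULL) {
  direction <- match.arg(direction)
  if (length(fruit_values) == 0L || length(bg_values) == 0L)
    stop("empty class value list", call. = FALSE)
  if (n_levels < 2) stop("'n_levels' must be >= 2", call. = FALSE)
  if (is.null(range))
    range <- base::range(c(fruit_values, bg_values))
  th <- seq(range[1], range[2], length.out = n_levels)
  rate <- function(values) {
    s <- sort(values)
    n <- length(s)
    if (direction == "gt") 1 - findInterval(th, s) / n        # P(v > t)
    else findInterval(th, s, left.open = TRUE) / n            # P(v < t)
  }
  data.frame(threshold = th, tpr = rate(fruit_values), fpr = rate(bg_values))
}

#' Write an ROC curve to CSV
#'
#' @param roc a data frame from [roc_curve()].
#' @param path output file path.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(roc[, c("threshold", "tpr", "fpr")], path,
                   row.names = FALSE)
  invisible(path)
}
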