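#' @export
print.fruit_model <- function(x, ...) {
  cat("Adaptive color-thresholding fruit detection model\n")
  cat(sprintf("  color space: %s   combination: %s\n", toupper(x$space),
              format_combination(x$combination)))
  cat(sprintf("  directions: %s\n",
              paste(ifelse(x$directions == "gt", ">", "<"), collapse = " ")))
  cat(sprintf("  anchors (light): low %.1f / medium %.1f / high %.1f\n",
              x$group_levels[1], x$group_levels[2], x$group_levels[3]))
  cat(sprintf("  split: SD stop %.2f, min side %d, T1 %.1f, T2 %.1f, over > %.0f\n",
              x$split_config$std_stop, as.integer(x$split_config$min_side),
              x$split_config$t1, x$split_config$t2, x$split_config$t_over))
  invisible(x)
}

#' Threshold table of a fitted model
#'
#' @param object a `fruit_model`.
#' @param ... unused.
#' @return the 3 x 3 threshold matrix (light groups x color dimensions).
#' @export
coef.fruit_model <- function(object, ...) object$thresholds

#' @export
summary.fruit_model <- function(object, ...) {
  structure(list(model = object), class = "summary.fruit_model")
}

#' @export
print.summary.fruit_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nThresholds (groups x dimensions):\n")
  print(round(m$thresholds, 4))
  if (!is.null(m$training$combination_scores)) {
    cat("\nTraining F-score per mask combination:\n")
    sc <- m$training$combination_scores
    names(sc) <- vapply(names(sc), format_combination, character(1))
    print(round(sc, 4))
  }
  invisible(x)
}

#' Plot the interpolated thresholds of a model across light levels
#'
#' Draws, for each color dimension, the threshold the detector would apply
#' as a function of a region's light level; the anchor light levels are
#' marked. Useful to see the clamping below the low anchor and above the
#' high one.
#'
#' @param x a `fruit_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fruit_model <- function(x, ...) {
  levels <- seq(0, 255, by = 1)
  th <- t(vapply(levels, function(l) interpolate_thresholds(x, l),
                 numeric(3)))
  graphics::matplot(levels, th, type = "l", lty = 1, col = c(2, 3, 4),
                    xlab = "region light level", ylab = "threshold",
                    main = sprintf("Interpolated thresholds (%s)",
                                   toupper(x$space)), ...)
  graphics::abline(v = x$group_levels, lty = 3, col = "grey50")
  graphics::legend("topleft", legend = paste("dimension", 1:3),
                   col = c(2, 3, 4), lty = 1, bty = "n")
  invisible(x)
}

#' Display a detection mask
#'
#' @param x a `fruit_detection`.
#' @param which `"final"`, `"raw"` or a dimension index 1-3.
#' @param ... passed to [graphics::image()].
#' @export
plot.fruit_detection <- function(x, which = "final", ...) {
  m <- if (identical(which, "final")) x$final_mask
  else if (identical(which, "raw")) x$combination_masks[[x$combination]]
  else x$dimension_masks[[which]]
  graphics::image(t(m)[, nrow(m):1], col = c("black", "white"), axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  invisible(x)
}
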