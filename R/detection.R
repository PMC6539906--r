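#' Interpolate per-dimension thresholds at a light level
#'
#' The model stores one threshold per (light group, dimension) and one
#' anchor light level per group. At test time a region's thresholds are
#' obtained by linear interpolation between the two anchor groups
#' bracketing its light level:
#' `T = (T_lo * (LL_hi - level) + T_hi * (level - LL_lo)) / (LL_hi - LL_lo)`,
#' which is exact at the anchors and continuous in between. Levels outside
#' the anchor span clamp to the nearest anchor's thresholds.
#'
#' `interp = "reversed"` swaps the two weights
#' (`T = (T_lo * (level - LL_lo) + T_hi * (LL_hi - level)) / (LL_hi - LL_lo)`),
#' an alternative reading of the interpolation rule that coincides with the
#' standard one only at the bracket midpoint; it is provided for
#' comparison and is not the default.
#'
#' @param model a `fruit_model`.
#' @param level light level in \[0, 255\].
#' @return numeric vector of 3 thresholds.
#' @export
interpolate_thresholds <- function(model, level) {
  ll <- model$group_levels
  tm <- model$thresholds
  if (level <= ll[1]) return(tm[1, ])
  if (level >= ll[3]) return(tm[3, ])
  i <- if (level <= ll[2]) 1L else 2L
  span <- ll[i + 1] - ll[i]
  if (model$interp == "reversed")
    unname((tm[i, ] * (level - ll[i]) + tm[i + 1, ] * (ll[i + 1] - level)) / span)
  else
    unname((tm[i, ] * (ll[i + 1] - level) + tm[i + 1, ] * (level - ll[i])) / span)
}

#' Binarize a color image with per-dimension thresholds
#'
#' Applies `channel > threshold` (direction `"gt"`) or `channel < threshold`
#' (`"lt"`) to each of the three channels.
#'
#' @param pixels a `color_image` (or plain h x w x 3 array).
#' @param thresholds numeric vector of 3 thresholds.
#' @param directions character vector of 3 directions.
#' @return a list of 3 binary matrices.
#' @export
binarize <- function(pixels, thresholds, directions) {
  lapply(1:3, function(d) {
    ch <- pixels[, , d]
    if (directions[d] == "gt") (ch > thresholds[d]) * 1
    else (ch < thresholds[d]) * 1
  })
}

#' Intersect per-dimension masks
#'
#' Elementwise AND of the masks named by the combination label (`"1"`,
#' `"2"`, `"3"`, `"12"`, `"13"`, `"23"`, `"123"`); single dimensions pass
#' through.
#'
#' @param masks list of 3 binary matrices.
#' @param combination a combination label.
#' @return a binary matrix.
#' @export
combine_masks <- function(masks, combination) {
  if (!combination %in% combination_labels())
    stop(sprintf("unknown combination '%s'", combination), call. = FALSE)
  dims <- combination_dims(combination)
  out <- masks[[dims[1]]]
  for (d in dims[-1]) out <- out * masks[[d]]
  out
}

#' Morphological cleanup of a detection mask
#'
#' Opening (erosion then dilation) with an 11 x 11 square structuring
#' element removes small clusters of falsely detected pixels, then closing
#' (dilation then erosion) with a 5 x 5 square reconnects fruit split
#' across nearby clusters. Square elements are used since fruit
#' orientation is unknown a priori.
#'
#' @param mask a binary matrix.
#' @param open_size,close_size structuring-element sides (odd integers).
#' @return the cleaned binary matrix.
#' @export
morphological_cleanup <- function(mask, open_size = 11, close_size = 5) {
  opened <- EBImage::opening(mask, EBImage::makeBrush(open_size, shape = "box"))
  closed <- EBImage::closing(opened, EBImage::makeBrush(close_size, shape = "box"))
  (EBImage::imageData(closed) != 0) * 1
}

#' Detect fruit in an RGB image with a fitted model
#'
#' The test-time pipeline: the image is recursively split with the model's
#' split configuration; each region's light level selects, by
#' interpolation, three thresholds that binarize the region in the model's
#' color space (overexposed regions emit background); region masks are
#' stitched into whole-image per-dimension masks; the seven combination
#' masks are formed; and the model's chosen combination is cleaned
#' morphologically to give the final mask. When ground truth is supplied,
#' pixel metrics are computed for the final mask (`metrics`) and for the
#' pre-morphology combination mask (`metrics_raw`).
#'
#' `predict(model, image)` is equivalent.
#'
#' @param model a `fruit_model` from [fruit_fit()].
#' @param rgb a `color_image` in RGB space.
#' @param truth optional binary ground-truth matrix.
#' @param morphology apply [morphological_cleanup()] to the final mask
#'   (default `TRUE`).
#' @return a `fruit_detection` object: `final_mask`, `dimension_masks`
#'   (list of 3), `combination_masks` (list of 7), `regions`,
#'   `combination`, and `metrics` / `metrics_raw` when truth is given.
#' @export
fruit_detect <- function(model, rgb, truth = NULL, morphology = TRUE) {
  assert_space(rgb, "rgb")
  if (!inherits(model, "fruit_model"))
    stop("'model' must be a fruit_model", call. = FALSE)
  if (!is.null(truth)) {
    truth <- as_binary_mask(truth)
    if (!identical(dim(truth), dim(rgb)[1:2]))
      stop("truth shape does not match image", call. = FALSE)
  }
  gray <- to_gray(rgb)
  conv <- convert_space(rgb, model$space, hsi_variant = model$hsi_variant)
  regions <- split_recursive(gray, model$split_config)
  d2 <- dim(rgb)[1:2]
  masks <- lapply(1:3, function(d) matrix(0, d2[1], d2[2]))
  for (k in seq_len(nrow(regions))) {
    if (regions$group[k] == "overexposed") next  # emit background
    rr <- (regions$row_start[k] + 1):regions$row_end[k]
    cc <- (regions$col_start[k] + 1):regions$col_end[k]
    th <- interpolate_thresholds(model, regions$light_level[k])
    sub <- binarize(conv[rr, cc, , drop = FALSE], th, model$directions)
    for (d in 1:3) masks[[d]][rr, cc] <- sub[[d]]
  }
  combos <- stats::setNames(lapply(combination_labels(), function(cb)
    combine_masks(masks, cb)), combination_labels())
  raw <- combos[[model$combination]]
  final <- if (morphology) morphological_cleanup(raw) else raw
  out <- structure(list(
    final_mask = final, dimension_masks = masks, combination_masks = combos,
    regions = regions, combination = model$combination,
    morphology = morphology
  ), class = "fruit_detection")
  if (!is.null(truth)) {
    tp <- mask_tpr(final, truth); fp <- mask_fpr(final, truth)
    out$metrics <- list(tpr = tp, fpr = fp, f = f_score(tp, fp))
    tpr_ <- mask_tpr(raw, truth); fpr_ <- mask_fpr(raw, truth)
    out$metrics_raw <- list(tpr = tpr_, fpr = fpr_, f = f_score(tpr_, fpr_))
  }
  out
}

#' @rdname fruit_detect
#' @param object a `fruit_model`.
#' @param ... unused.
#' @export
predict.fruit_model <- function(object, rgb, truth = NULL, morphology = TRUE,
                                ...) {
  fruit_detect(object, rgb, truth = truth, morphology = morphology)
}

#' @export
print.fruit_detection <- function(x, ...) {
  cat(sprintf("<fruit_detection> %d x %d, combination %s, %d regions, %.0f fruit px\n",
              nrow(x$final_mask), ncol(x$final_mask),
              format_combination(x$combination), nrow(x$regions),
              sum(x$final_mask)))
  if (!is.null(x$metrics))
    cat(sprintf("  TPR %.4f  FPR %.4f  F %.4f\n", x$metrics$tpr,
                x$metrics$fpr, x$metrics$f))
  invisible(x)
}

format_combination <- function(cb) {
  paste(combination_dims(cb), collapse = "\u2229")
}
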