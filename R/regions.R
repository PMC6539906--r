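#' Splitting and light-level configuration
#'
#' Bundles the parameters controlling the recursive split and the
#' light-level grouping: the standard-deviation stop value (a region whose
#' grayscale SD is at or below `std_stop` is considered
#' illumination-homogeneous and is not split further), the minimum region
#' side, the tuned light-level cutoffs `t1 < t2`, and the overexposure
#' cutoff `t_over` above which regions are treated as washed out.
#'
#' @param std_stop grayscale standard deviation stop value, `>= 0`.
#' @param min_side minimum region side in pixels (a region is split only if
#'   both sides are at least `2 * min_side`). Small minimum sides risk
#'   sub-images that contain only one class.
#' @param t1,t2 light-level cutoffs in \[0, 255\], `0 < t1 < t2`.
#' @param t_over overexposure cutoff, `t2 <= t_over <= 255`.
#' @return a `split_config` object.
#' @export
split_config <- function(std_stop, min_side = 16, t1 = 84, t2 = 140,
                         t_over = 250) {
  if (!is.numeric(std_stop) || length(std_stop) != 1L || std_stop < 0)
    stop("'std_stop' must be a single value >= 0", call. = FALSE)
  if (min_side < 1) stop("'min_side' must be >= 1", call. = FALSE)
  if (!(0 < t1 && t1 < t2 && t2 <= t_over && t_over <= 255))
    stop("need 0 < t1 < t2 <= t_over <= 255", call. = FALSE)
  structure(list(std_stop = std_stop, min_side = min_side,
                 t1 = t1, t2 = t2, t_over = t_over),
            class = "split_config")
}

#' Light-level groups
#' @return the group labels in increasing light order.
#' @export
fruit_groups <- function() c("low", "medium", "high", "overexposed")

#' Mean light level of a rectangular region
#'
#' @param gray grayscale matrix (values in \[0, 255\]).
#' @param box integer vector `(row_start, col_start, row_end, col_end)`,
#'   0-based, half-open.
#' @return the arithmetic mean of the grayscale pixels inside the box.
#' @export
light_level <- function(gray, box) {
  if (box[3] <= box[1] || box[4] <= box[2])
    stop("empty box", call. = FALSE)
  if (box[1] < 0 || box[2] < 0 || box[3] > nrow(gray) || box[4] > ncol(gray))
    stop("box outside image bounds", call. = FALSE)
  mean(gray[(box[1] + 1):box[3], (box[2] + 1):box[4]])
}

#' Assign a light level to an illumination group
#'
#' Levels below `t1` are low, in `[t1, t2)` medium, in `[t2, t_over]` high,
#' and above `t_over` overexposed (almost completely white; such regions
#' are ignored when training and emit background when detecting).
#'
#' @param level light level in \[0, 255\] (vectorized).
#' @param cfg a [split_config()].
#' @return character vector of group labels.
#' @export
categorize <- function(level, cfg) {
  ifelse(level > cfg$t_over, "overexposed",
    ifelse(level >= cfg$t2, "high",
      ifelse(level >= cfg$t1, "medium", "low")))
}

#' Recursively split an image into illumination-homogeneous regions
#'
#' Top-down quadtree splitting: a region is split into its four quadrants
#' (midpoint split, floor division for odd sizes) while its grayscale
#' standard deviation exceeds `cfg$std_stop` and both its sides are at
#' least `2 * cfg$min_side`. The returned regions are pairwise disjoint
#' and cover every pixel of the image.
#'
#' @param gray grayscale matrix.
#' @param cfg a [split_config()].
#' @return a data frame with one row per region: the 0-based half-open box
#'   (`row_start`, `col_start`, `row_end`, `col_end`), the region's mean
#'   `light_level`, and its light `group`.
#' @export
split_recursive <- function(gray, cfg) {
  if (!is.matrix(gray) || nrow(gray) == 0L || ncol(gray) == 0L)
    stop("empty image", call. = FALSE)
  boxes <- list()
  stack <- list(c(0L, 0L, nrow(gray), ncol(gray)))
  while (length(stack)) {
    b <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    h <- b[3] - b[1]; w <- b[4] - b[2]
    px <- gray[(b[1] + 1):b[3], (b[2] + 1):b[4]]
    if (stats::sd(px) > cfg$std_stop &&
        h >= 2 * cfg$min_side && w >= 2 * cfg$min_side) {
      rm_ <- b[1] + h %/% 2L
      cm_ <- b[2] + w %/% 2L
      stack <- c(stack, list(
        c(b[1], b[2], rm_, cm_), c(b[1], cm_, rm_, b[4]),
        c(rm_, b[2], b[3], cm_), c(rm_, cm_, b[3], b[4])))
    } else {
      boxes[[length(boxes) + 1L]] <- b
    }
  }
  bm <- do.call(rbind, boxes)
  lv <- vapply(boxes, function(b) light_level(gray, b), numeric(1))
  data.frame(row_start = bm[, 1], col_start = bm[, 2],
             row_end = bm[, 3], col_end = bm[, 4],
             light_level = lv, group = categorize(lv, cfg),
             stringsAsFactors = FALSE)
}

#' Tile an image into fixed-size sub-images covering a pixel fraction
#'
#' Produces square-ish tiles whose area is approximately
#' `fraction * height * width` (side = rounded square root of that area,
#' at least 1 px), truncating tiles at the right and bottom edges so the
#' tiles partition the image exactly. Used by the tuning stage, which
#' samples light levels from tiles of 1% of the image's pixels.
#'
#' @param gray grayscale matrix.
#' @param fraction tile area as a fraction of the image area, in (0, 1).
#' @return a data frame of regions as in [split_recursive()], without the
#'   `group` column.
#' @export
grid_tiles <- function(gray, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  h <- nrow(gray); w <- ncol(gray)
  side <- max(1L, as.integer(round(sqrt(fraction * h * w))))
  r0 <- seq(0L, h - 1L, by = side)
  c0 <- seq(0L, w - 1L, by = side)
  g <- expand.grid(row_start = r0, col_start = c0)
  g$row_end <- pmin(g$row_start + side, h)
  g$col_end <- pmin(g$col_start + side, w)
  g$light_level <- apply(as.matrix(g[, c("row_start", "col_start",
                                         "row_end", "col_end")]), 1,
                         function(b) light_level(gray, b))
  g
}
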