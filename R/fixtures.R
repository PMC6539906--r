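#' Specification of a synthetic labeled scene
#'
#' Describes a scene of elliptical "fruit" blobs on a differently colored
#' textured background, under a spatial illumination gradient and additive
#' per-pixel Gaussian noise — the controllable stand-in for field images
#' that lets every stage of the pipeline be exercised without external
#' image databases.
#'
#' The illumination field multiplies all RGB channels by a gain varying
#' from `min_gain` to `max_gain` along `orientation`; with `zones` set, the
#' gain is piecewise constant over that many equal bands (dark / medium /
#' bright zones for `zones = 3`) instead of a smooth ramp, and `gains` /
#' `breaks` allow explicit band gains and band boundaries (fractions of
#' the image extent). An optional additive `offset` (grayscale units)
#' stresses detectors that rely on purely multiplicative illumination
#' invariance.
#'
#' Default fruit sizes (semi-axes 18-26 px) make fruits span roughly
#' 40-50 px, large relative to the 11 x 11 cleanup element, as real fruit
#' are at typical camera resolutions. Fruits are placed with a small
#' separation margin so they remain distinct connected components.
#'
#' @param size `c(height, width)` in pixels.
#' @param n_fruits number of ellipses.
#' @param fruit_color,bg_color RGB triples in \[0, 255\].
#' @param color_jitter per-channel uniform jitter half-width applied to
#'   each fruit's color and the background color (default 10).
#' @param axes range `c(min, max)` of ellipse semi-axes in pixels.
#' @param illumination list with `orientation` (`"horizontal"` varies the
#'   gain across columns, `"vertical"` across rows), `min_gain`, `max_gain`
#'   in (0, 2\], optional `zones` (integer), `gains` (explicit band gains),
#'   `breaks` (band boundaries as fractions) and `offset` (additive,
#'   default 0).
#' @param texture_std background brightness texture standard deviation.
#' @param noise_percent additive Gaussian pixel noise as a fraction of full
#'   scale, see [add_noise()].
#' @param seed RNG seed making the scene deterministic.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(size = c(160, 220), n_fruits = 4,
                       fruit_color = c(200, 30, 30),
                       bg_color = c(40, 160, 40), color_jitter = 10,
                       axes = c(18, 26),
                       illumination = list(orientation = "horizontal",
                                           min_gain = 1, max_gain = 1),
                       texture_std = 0, noise_percent = 0, seed = 0) {
  stopifnot(length(size) == 2, all(size >= 16), n_fruits >= 0,
            length(fruit_color) == 3, length(bg_color) == 3,
            axes[1] >= 2, axes[2] >= axes[1])
  if (all(fruit_color == bg_color))
    stop("fruit and background colors must be distinct", call. = FALSE)
  ill <- utils::modifyList(list(orientation = "horizontal", min_gain = 1,
                                max_gain = 1, zones = NULL, gains = NULL,
                                breaks = NULL, offset = 0),
                           illumination)
  if (!(ill$min_gain > 0 && ill$max_gain <= 2 && ill$min_gain <= ill$max_gain))
    stop("gains must satisfy 0 < min_gain <= max_gain <= 2", call. = FALSE)
  if (!is.null(ill$gains) && !all(ill$gains > 0 & ill$gains <= 2))
    stop("explicit band gains must lie in (0, 2]", call. = FALSE)
  structure(list(size = size, n_fruits = n_fruits, fruit_color = fruit_color,
                 bg_color = bg_color, color_jitter = color_jitter,
                 axes = axes, illumination = ill, texture_std = texture_std,
                 noise_percent = noise_percent, seed = seed),
            class = "scene_spec")
}

illumination_gain <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  ill <- spec$illumination
  n <- if (ill$orientation == "horizontal") w else h
  gains <- ill$gains
  if (is.null(gains) && !is.null(ill$zones))
    gains <- seq(ill$min_gain, ill$max_gain, length.out = as.integer(ill$zones))
  if (is.null(gains)) {
    ramp <- if (n == 1) rep(ill$min_gain, 1)
    else seq(ill$min_gain, ill$max_gain, length.out = n)
  } else {
    z <- length(gains)
    breaks <- if (is.null(ill$breaks)) seq_len(z - 1) / z else ill$breaks
    stopifnot(length(breaks) == z - 1)
    pos <- (seq_len(n) - 0.5) / n
    ramp <- gains[findInterval(pos, breaks) + 1L]
  }
  if (ill$orientation == "horizontal")
    matrix(ramp, h, w, byrow = TRUE)
  else matrix(ramp, h, w)
}

#' Generate one synthetic labeled scene
#'
#' Places `n_fruits` non-overlapping ellipses of jittered fruit color on a
#' jittered, optionally textured background, applies the multiplicative
#' illumination field, rounds to 8-bit-like integers, then adds Gaussian
#' pixel noise. The ground-truth mask marks exactly the ellipse pixels.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return a [labeled_image()].
#' @export
generate_scene <- function(spec) {
  with_seed(spec$seed, {
    h <- spec$size[1]; w <- spec$size[2]
    jit <- function(col) pmin(255, pmax(0, col +
      stats::runif(3, -spec$color_jitter, spec$color_jitter)))
    bg <- jit(spec$bg_color)
    img <- array(rep(bg, each = h * w), c(h, w, 3))
    if (spec$texture_std > 0) {
      tex <- matrix(stats::rnorm(h * w, 0, spec$texture_std), h, w)
      for (d in 1:3) img[, , d] <- img[, , d] + tex
    }
    truth <- matrix(0, h, w)
    rowg <- matrix(seq_len(h), h, w)
    colg <- matrix(seq_len(w), h, w, byrow = TRUE)
    placed <- 0L
    tries <- 0L
    while (placed < spec$n_fruits) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, spec$n_fruits))
        stop("could not place all fruits without overlap", call. = FALSE)
      a <- stats::runif(1, spec$axes[1], spec$axes[2])
      b <- stats::runif(1, spec$axes[1], spec$axes[2])
      theta <- stats::runif(1, 0, pi)
      m <- max(a, b)
      if (2 * m + 2 >= min(h, w))
        stop("fruits cannot fit in the scene", call. = FALSE)
      cy <- stats::runif(1, m + 1, h - m)
      cx <- stats::runif(1, m + 1, w - m)
      dy <- rowg - cy; dx <- colg - cx
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      near <- (u / (a + 4))^2 + (v / (b + 4))^2 <= 1  # separation margin
      if (any(truth[near] != 0)) next
      fc <- jit(spec$fruit_color)
      for (d in 1:3) {
        ch <- img[, , d]
        ch[inside] <- fc[d]
        img[, , d] <- ch
      }
      truth[inside] <- 1
      placed <- placed + 1L
    }
    gain <- illumination_gain(spec)
    for (d in 1:3)
      img[, , d] <- img[, , d] * gain + spec$illumination$offset
    img <- round(pmax(pmin(img, 255), 0))
    rgb <- color_image(img, "rgb")
    if (spec$noise_percent > 0)
      rgb <- add_noise(rgb, spec$noise_percent,
                       seed = spec$seed + 104729L)
    labeled_image(rgb, truth, id = sprintf("scene-%d", spec$seed))
  })
}

#' Generate a dataset of synthetic labeled scenes
#'
#' Varies the per-image seed (`spec$seed + i`) so the scenes differ but the
#' dataset as a whole is reproducible.
#'
#' @param spec a [scene_spec()].
#' @param n_images number of scenes (>= 1).
#' @return a list of [labeled_image()] objects.
#' @export
generate_dataset <- function(spec, n_images) {
  stopifnot(n_images >= 1)
  lapply(seq_len(n_images), function(i) {
    s <- spec
    s$seed <- spec$seed + i
    generate_scene(s)
  })
}

#' Read an image (and optional mask) from disk
#'
#' Loads PNG/JPEG/TIFF into the 0-255 RGB array convention (an alpha
#' channel, if present, is dropped; grayscale images are replicated across
#' channels). Masks are binarized at nonzero.
#'
#' @param image_path path to the RGB image.
#' @param mask_path optional path to a single-channel mask image.
#' @param id identifier; defaults to the image file name.
#' @return a [labeled_image()].
#' @export
read_labeled <- function(image_path, mask_path = NULL,
                         id = basename(image_path)) {
  px <- EBImage::imageData(EBImage::readImage(image_path)) * 255
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px <- aperm(px, c(2, 1, 3))  # EBImage stores x (width) first
  rgb <- color_image(px, "rgb")
  truth <- NULL
  if (!is.null(mask_path)) {
    m <- EBImage::imageData(EBImage::readImage(mask_path))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    truth <- t(m)
    if (!identical(dim(truth), dim(px)[1:2]))
      stop("mask shape does not match image shape", call. = FALSE)
    truth <- (truth != 0) * 1
  }
  labeled_image(rgb, truth, id = id)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a binary matrix.
#' @param path output path (`.png`).
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(as_binary_mask(mask))), path)
  invisible(path)
}

#' Write an RGB `color_image` as PNG
#'
#' @param rgb a `color_image` in RGB space.
#' @param path output path (`.png`).
#' @export
write_rgb <- function(rgb, path) {
  assert_space(rgb, "rgb")
  px <- aperm(unclass(rgb), c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(px, colormode = "Color"), path)
  invisible(path)
}
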