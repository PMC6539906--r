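#' Normalized Difference Index (NDI) transform
#'
#' Maps an RGB image to the three pairwise normalized differences
#' `(R-G)/(R+G)`, `(R-B)/(R+B)`, `(B-G)/(B+G)`. Each channel is bounded in
#' \[-1, 1\] and is invariant to a positive multiplicative gain applied to
#' the RGB channels, which is what makes NDI robust to shading and
#' illumination changes. Pixels whose denominator is zero (both source
#' channels zero) map to 0, the symmetric "no difference" value.
#'
#' @param rgb a `color_image` in RGB space.
#' @return a `color_image` in NDI space.
#' @export
to_ndi <- function(rgb) {
  assert_space(rgb, "rgb")
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  nd <- function(x, y) {
    s <- x + y
    out <- (x - y) / s
    out[s == 0] <- 0
    out
  }
  out <- array(0, dim(rgb))
  out[, , 1] <- nd(r, g)
  out[, , 2] <- nd(r, b)
  out[, , 3] <- nd(b, g)
  color_image(out, "ndi")
}

#' Hue-Saturation-Intensity transform
#'
#' Converts RGB to HSI with all three channels scaled to \[0, 1\] (hue as a
#' fraction of the full circle). The default is the classical HSI model:
#' intensity is the channel mean, saturation is `1 - min/intensity`, and hue
#' comes from the geometric angle formula. `variant = "hsv"` instead uses
#' the hexcone HSV model (value = max, saturation = 1 - min/max), since the
#' two are often conflated; both share the \[0, 1\] scaling. Achromatic
#' pixels get hue 0 and saturation 0.
#'
#' @param rgb a `color_image` in RGB space.
#' @param variant `"hsi"` (default) or `"hsv"`.
#' @return a `color_image` in HSI space.
#' @export
to_hsi <- function(rgb, variant = c("hsi", "hsv")) {
  assert_space(rgb, "rgb")
  variant <- match.arg(variant)
  d <- dim(rgb)
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  out <- array(0, d)
  if (variant == "hsv") {
    hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g),
                              b = as.vector(b), maxColorValue = 255)
    out[, , 1] <- hsv[1, ]
    out[, , 2] <- hsv[2, ]
    out[, , 3] <- hsv[3, ]
  } else {
    i <- (r + g + b) / 3
    mn <- pmin(r, g, b)
    s <- ifelse(i > 0, 1 - mn / i, 0)
    num <- 0.5 * ((r - g) + (r - b))
    den <- sqrt((r - g)^2 + (r - b) * (g - b))
    theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1))
    h <- ifelse(b > g, 2 * pi - theta, theta) / (2 * pi)
    h[s == 0] <- 0
    out[, , 1] <- h
    out[, , 2] <- s
    out[, , 3] <- i / 255
  }
  color_image(out, "hsi")
}

#' CIELAB transform
#'
#' Standard sRGB to CIELAB conversion under the D65 white point
#' (via [grDevices::convertColor()]). L is in \[0, 100\]; a and b span
#' roughly \[-128, 127\], with a = b = 0 on the neutral axis.
#'
#' @param rgb a `color_image` in RGB space.
#' @return a `color_image` in LAB space.
#' @export
to_lab <- function(rgb) {
  assert_space(rgb, "rgb")
  d <- dim(rgb)
  m <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
             as.vector(rgb[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  out <- array(0, d)
  out[, , 1] <- lab[, 1]
  out[, , 2] <- lab[, 2]
  out[, , 3] <- lab[, 3]
  color_image(out, "lab")
}

#' Grayscale transform
#'
#' ITU-R BT.601 luminance, `0.299 R + 0.587 G + 0.114 B`, in \[0, 255\]
#' (0 completely dark, 255 completely white). Light levels of sub-images
#' are means over this image.
#'
#' @param rgb a `color_image` in RGB space.
#' @return a numeric matrix (height x width).
#' @export
to_gray <- function(rgb) {
  assert_space(rgb, "rgb")
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  dim(g) <- dim(rgb)[1:2]  # single-row/column images must stay matrices
  g
}

#' Convert an RGB image into a working color space
#'
#' Dispatches to [to_ndi()], [to_hsi()] or [to_lab()]; `target = "rgb"`
#' returns the input unchanged.
#'
#' @param rgb a `color_image` in RGB space.
#' @param target a space tag, see [fruit_spaces()].
#' @param hsi_variant passed to [to_hsi()] when `target = "hsi"`.
#' @return a `color_image` in the target space.
#' @export
convert_space <- function(rgb, target, hsi_variant = "hsi") {
  if (!is.character(target) || length(target) != 1L ||
      !(tolower(target) %in% fruit_spaces()))
    stop(sprintf("unknown color space '%s'", paste(target, collapse = ",")),
         call. = FALSE)
  switch(tolower(target),
    rgb = { assert_space(rgb, "rgb"); rgb },
    ndi = to_ndi(rgb),
    hsi = to_hsi(rgb, variant = hsi_variant),
    lab = to_lab(rgb)
  )
}
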