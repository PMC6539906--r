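#' Color image container
#'
#' A `color_image` is a height x width x 3 numeric array tagged with the
#' color space it lives in. Channel value conventions are fixed per space:
#' RGB channels in \[0, 255\], NDI channels in \[-1, 1\], HSI channels in
#' \[0, 1\] (hue as a fraction of the full circle), and CIELAB with L in
#' \[0, 100\] and a, b in \[-128, 127\].
#'
#' @param pixels numeric array of dimension `c(height, width, 3)`.
#' @param space one of `"rgb"`, `"ndi"`, `"hsi"`, `"lab"`.
#' @return a `color_image` object.
#' @export
color_image <- function(pixels, space = "rgb") {
  space <- match.arg(tolower(space), fruit_spaces())
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be a height x width x 3 array", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(pixels, space = space, class = "color_image")
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image> %d x %d pixels, space: %s\n",
              d[1], d[2], toupper(attr(x, "space"))))
  invisible(x)
}

#' Supported color spaces
#' @return character vector of space tags.
#' @export
fruit_spaces <- function() c("rgb", "ndi", "hsi", "lab")

#' Per-dimension channel ranges of a color space
#'
#' @param space a space tag, see [fruit_spaces()].
#' @return a 3 x 2 matrix; row d holds `(min, max)` of channel d.
#' @export
channel_ranges <- function(space) {
  space <- match.arg(tolower(space), fruit_spaces())
  switch(space,
    rgb = matrix(c(0, 255, 0, 255, 0, 255), ncol = 2, byrow = TRUE),
    ndi = matrix(c(-1, 1, -1, 1, -1, 1), ncol = 2, byrow = TRUE),
    hsi = matrix(c(0, 1, 0, 1, 0, 1), ncol = 2, byrow = TRUE),
    lab = matrix(c(0, 100, -128, 127, -128, 127), ncol = 2, byrow = TRUE)
  )
}

image_space <- function(x) {
  s <- attr(x, "space")
  if (is.null(s)) "rgb" else s
}

assert_space <- function(x, space) {
  if (!inherits(x, "color_image"))
    stop("expected a 'color_image' object", call. = FALSE)
  if (image_space(x) != space)
    stop(sprintf("expected an image in %s space, got %s",
                 toupper(space), toupper(image_space(x))), call. = FALSE)
  invisible(x)
}

#' Labeled image: an RGB image with an aligned binary ground-truth mask
#'
#' @param rgb a `color_image` in RGB space.
#' @param truth binary matrix (0/1) with the image's height and width, or
#'   `NULL` when no ground truth exists.
#' @param id an identifier string.
#' @return a `labeled_image` object (list with elements `rgb`, `truth`, `id`).
#' @export
labeled_image <- function(rgb, truth = NULL, id = "") {
  assert_space(rgb, "rgb")
  if (!is.null(truth)) {
    truth <- as_binary_mask(truth)
    if (!identical(dim(truth), dim(rgb)[1:2]))
      stop("mask shape does not match image shape", call. = FALSE)
  }
  structure(list(rgb = rgb, truth = truth, id = as.character(id)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<labeled_image> '%s' %d x %d, %s\n", x$id, d[1], d[2],
              if (is.null(x$truth)) "unlabeled"
              else sprintf("%d fruit pixels", sum(x$truth))))
  invisible(x)
}

# Coerce to a strict 0/1 matrix (nonzero = fruit).
as_binary_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix", call. = FALSE)
  storage.mode(m) <- "double"
  (m != 0) * 1
}
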