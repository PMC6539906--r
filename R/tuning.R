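# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Light-level cutoffs from an empirical light distribution
#'
#' Chooses `t1` and `t2` as the 15th and 85th percentiles of the sampled
#' light levels, so that 15% of sub-images fall in the low group, 70% in
#' the medium group and 15% in the high group. Percentiles use linear
#' interpolation between order statistics.
#'
#' @param levels numeric vector of sub-image light levels in \[0, 255\].
#' @return named numeric vector `c(t1 = ..., t2 = ...)`.
#' @export
tune_light_thresholds <- function(levels) {
  if (length(unique(levels)) < 2L)
    stop("degenerate light-level distribution: need >= 2 distinct levels",
         call. = FALSE)
  q <- stats::quantile(levels, c(0.15, 0.85), names = FALSE, type = 7)
  c(t1 = q[1], t2 = q[2])
}

#' Descriptive statistics of a light-level sample
#'
#' Sample mean, standard deviation, moment skewness, excess kurtosis and
#' median. For a constant sample the shape statistics are undefined and
#' reported as 0 with `degenerate = TRUE`.
#'
#' @param levels numeric vector with at least two values.
#' @return a list with `mean`, `std`, `skewness`, `kurtosis`, `median`,
#'   `degenerate`.
#' @export
light_statistics <- function(levels) {
  if (length(levels) < 2L) stop("need at least two values", call. = FALSE)
  degenerate <- stats::sd(levels) == 0
  list(
    mean = mean(levels),
    std = stats::sd(levels),
    skewness = if (degenerate) 0 else e1071::skewness(levels, type = 1),
    kurtosis = if (degenerate) 0 else e1071::kurtosis(levels, type = 1),
    median = stats::median(levels),
    degenerate = degenerate
  )
}

#' Learn the classification-rule direction of one color dimension
#'
#' Thresholding needs to know on which side of the cutoff the fruit lies.
#' The heuristic assumes images contain mostly background: classify
#' `value > threshold` as fruit; if the pixels left as background
#' (`value <= threshold`) are less than 70% of all pixels, the direction is
#' reversed to `value < threshold`.
#'
#' @param values pooled channel values of the training images.
#' @param threshold probe threshold; by default the midpoint of `range`.
#' @param range the channel's `(min, max)`; used for the default probe.
#' @param bg_majority background-majority fraction of the rule (default 0.70).
#' @return `"gt"` or `"lt"`.
#' @export
learn_direction <- function(values, threshold = NULL, range = NULL,
                            bg_majority = 0.70) {
  if (length(values) == 0L) stop("no pixel values", call. = FALSE)
  if (is.null(threshold)) {
    if (is.null(range)) range <- base::range(values)
    threshold <- mean(range)
  }
  if (mean(values <= threshold) < bg_majority) "lt" else "gt"
}

#' Select the stop-splitting standard deviation by F-score maximization
#'
#' For each candidate stop value, repeatedly (a) samples a fraction of the
#' labeled images, (b) splits the sample 70/30 into training and testing,
#' (c) fits a model with that stop value on the training part, and
#' (d) measures the mean F-score on the testing part. The candidate with
#' the highest mean F across repeats wins; ties are broken toward the
#' larger candidate (fewer splits, faster).
#'
#' The same random folds are used for every candidate (common random
#' numbers), so candidates that lead to identical models — for instance
#' stop values so large the image is never split — score identically and
#' comparisons between candidates are not blurred by fold noise.
#'
#' @param images list of [labeled_image()] objects with ground truth.
#' @param grid numeric vector of candidate stop values.
#' @param tuning a `fruit_tuning` object carrying `t1`, `t2`, `t_over` and
#'   `directions` (its `std_stop` is ignored).
#' @param space color-space tag.
#' @param sample_fraction fraction of images drawn before each 70/30 split
#'   (default 0.30).
#' @param repeats number of random cycles per candidate (default 5).
#' @param seed RNG seed.
#' @param morphology passed to [fruit_detect()]; the F maximized is the
#'   final-mask F.
#' @return the selected stop value, with the per-candidate mean F-scores
#'   attached as attribute `"scores"`.
#' @export
tune_std_stop <- function(images, grid, tuning, space = "ndi",
                          sample_fraction = 0.30, repeats = 5, seed = 0,
                          morphology = TRUE) {
  if (length(grid) == 0L) stop("empty candidate grid", call. = FALSE)
  if (length(images) < 2L || any(vapply(images, function(im) is.null(im$truth),
                                        logical(1))))
    stop("need >= 2 labeled images with ground truth", call. = FALSE)
  if (length(grid) == 1L) return(structure(grid, scores = NA_real_))
  folds <- with_seed(seed, lapply(seq_len(repeats), function(r) {
    n_pick <- max(2L, round(sample_fraction * length(images)))
    picked <- sample(length(images), n_pick)
    n_train <- max(1L, min(n_pick - 1L, round(0.7 * n_pick)))
    idx <- sample(n_pick)
    list(train = picked[idx[seq_len(n_train)]],
         test = picked[idx[-seq_len(n_train)]])
  }))
  scores <- vapply(grid, function(s) {
    fs <- vapply(folds, function(fold) {
      tun <- tuning
      tun$std_stop <- s
      model <- fruit_fit(images[fold$train], tun, space = space)
      mean(vapply(images[fold$test], function(im) {
        rep_ <- fruit_detect(model, im$rgb, truth = im$truth,
                             morphology = morphology)
        if (morphology) rep_$metrics$f else rep_$metrics_raw$f
      }, numeric(1)))
    }, numeric(1))
    mean(fs)
  }, numeric(1))
  # ties toward the larger candidate
  best <- max(grid[scores >= max(scores) - 1e-12])
  structure(best, scores = stats::setNames(scores, grid))
}

#' Automatic parameter tuning for a database of labeled images
#'
#' Runs the tuning pipeline on a (training) image set: samples light levels
#' from grid tiles covering `tile_fraction` of each image's pixels and sets
#' `t1`/`t2` by the 15/70/15 percentile rule; learns the per-dimension
#' classification-rule directions from the pooled converted pixels; and,
#' when a `std_grid` is supplied, selects the stop-splitting standard
#' deviation by F-score maximization ([tune_std_stop()]). When `std_stop`
#' is given directly the grid search is skipped.
#'
#' @param images list of [labeled_image()] objects (ground truth is only
#'   required when tuning `std_stop` by grid search).
#' @param space color-space tag the detector will run in.
#' @param std_stop fixed stop value, or `NULL` to tune from `std_grid`.
#' @param std_grid candidate stop values (default `seq(0, 100, by = 10)`,
#'   used only when `std_stop` is `NULL`).
#' @param tile_fraction tile area fraction for light-level sampling
#'   (default 0.01).
#' @param t_over overexposure cutoff (default 250).
#' @param min_side minimum region side for splitting (default 16).
#' @param sample_fraction,repeats,seed passed to [tune_std_stop()].
#' @param hsi_variant passed to [convert_space()].
#' @return a `fruit_tuning` object: `t1`, `t2`, `t_over`, `std_stop`,
#'   `directions` (length 3, `"gt"`/`"lt"`), `light_stats`, `space`,
#'   `min_side`.
#' @export
fruit_tune <- function(images, space = "ndi", std_stop = NULL,
                       std_grid = seq(0, 100, by = 10), tile_fraction = 0.01,
                       t_over = 250, min_side = 16, sample_fraction = 0.30,
                       repeats = 5, seed = 0, hsi_variant = "hsi") {
  if (length(images) == 0L) stop("no images", call. = FALSE)
  levels <- unlist(lapply(images, function(im)
    grid_tiles(to_gray(im$rgb), tile_fraction)$light_level))
  tt <- tune_light_thresholds(levels)
  rng <- channel_ranges(space)
  pooled <- lapply(1:3, function(d) unlist(lapply(images, function(im) {
    conv <- convert_space(im$rgb, space, hsi_variant = hsi_variant)
    as.vector(conv[, , d])
  })))
  directions <- vapply(1:3, function(d)
    learn_direction(pooled[[d]], range = rng[d, ]), character(1))
  tun <- structure(list(
    t1 = unname(tt["t1"]), t2 = unname(tt["t2"]), t_over = t_over,
    std_stop = std_stop, directions = directions,
    light_stats = light_statistics(levels), space = space,
    min_side = min_side, hsi_variant = hsi_variant
  ), class = "fruit_tuning")
  if (is.null(std_stop)) {
    picked <- tune_std_stop(images, std_grid, tun, space = space,
                            sample_fraction = sample_fraction,
                            repeats = repeats, seed = seed)
    tun$std_stop <- as.numeric(picked)
    tun$std_scores <- attr(picked, "scores")
  }
  tun
}

#' @export
print.fruit_tuning <- function(x, ...) {
  cat("Tuned adaptive-thresholding parameters\n")
  cat(sprintf("  light cutoffs: T1 = %.2f, T2 = %.2f (overexposure > %.0f)\n",
              x$t1, x$t2, x$t_over))
  cat(sprintf("  stop-splitting SD: %s\n",
              if (is.null(x$std_stop)) "<not set>"
              else format(x$std_stop)))
  cat(sprintf("  directions (%s): %s\n", toupper(x$space),
              paste(ifelse(x$directions == "gt", ">", "<"), collapse = " ")))
  invisible(x)
}
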