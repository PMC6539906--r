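#' Evaluation-protocol configuration
#'
#' @param train_fraction fraction of images used for training (default 0.70).
#' @param repeats number of random train/test splits (default 5).
#' @param seed base RNG seed.
#' @param std_stop stop-splitting standard deviation held fixed across
#'   repeats (light cutoffs and directions are re-tuned on each training
#'   fold).
#' @param tile_fraction,t_over,min_side tuning settings, see [fruit_tune()].
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(train_fraction = 0.70, repeats = 5, seed = 0,
                              std_stop = 10, tile_fraction = 0.01,
                              t_over = 250, min_side = 16) {
  stopifnot(train_fraction > 0, train_fraction < 1, repeats >= 1)
  structure(list(train_fraction = train_fraction, repeats = repeats,
                 seed = seed, std_stop = std_stop,
                 tile_fraction = tile_fraction, t_over = t_over,
                 min_side = min_side),
            class = "experiment_config")
}

#' Repeated random train/test cross-validation
#'
#' For each repeat: shuffle the images with a seeded generator, split by
#' `train_fraction`, tune the light cutoffs and classification directions
#' on the training fold only, fit the model, and detect on the held-out
#' images. Reported per repeat are the mean test TPR and FPR and two
#' F summaries: the mean of per-image F-scores and the F of the mean
#' rates (both with and without morphology), since the two aggregates
#' differ whenever per-image rates vary.
#'
#' @param images list of [labeled_image()] objects with ground truth.
#' @param space color-space tag.
#' @param cfg an [experiment_config()].
#' @param objective_weight passed to [fruit_fit()].
#' @return a list with `per_repeat` (data frame) and `mean` (named vector
#'   of column means).
#' @export
cross_validate <- function(images, space = "ndi", cfg = experiment_config(),
                           objective_weight = NULL) {
  if (length(images) < 2L) stop("need >= 2 images", call. = FALSE)
  rows <- lapply(seq_len(cfg$repeats), function(r) {
    with_seed(cfg$seed + r, {
      idx <- sample(length(images))
      n_train <- max(1L, min(length(images) - 1L,
                             round(cfg$train_fraction * length(images))))
      train <- images[idx[seq_len(n_train)]]
      test <- images[idx[-seq_len(n_train)]]
      tun <- fruit_tune(train, space = space, std_stop = cfg$std_stop,
                        tile_fraction = cfg$tile_fraction,
                        t_over = cfg$t_over, min_side = cfg$min_side)
      model <- fruit_fit(train, tun, space = space,
                         objective_weight = objective_weight)
      m <- vapply(test, function(im) {
        rep_ <- fruit_detect(model, im$rgb, truth = im$truth)
        c(tpr = rep_$metrics$tpr, fpr = rep_$metrics$fpr,
          f = rep_$metrics$f, tpr_raw = rep_$metrics_raw$tpr,
          fpr_raw = rep_$metrics_raw$fpr, f_raw = rep_$metrics_raw$f)
      }, numeric(6))
      mm <- rowMeans(m)
      data.frame(repeat_ = r, tpr = mm["tpr"], fpr = mm["fpr"],
                 f_mean = mm["f"],
                 f_of_means = f_score(mm["tpr"], mm["fpr"]),
                 tpr_raw = mm["tpr_raw"], fpr_raw = mm["fpr_raw"],
                 f_mean_raw = mm["f_raw"],
                 f_of_means_raw = f_score(mm["tpr_raw"], mm["fpr_raw"]),
                 row.names = NULL)
    })
  })
  per_repeat <- do.call(rbind, rows)
  list(per_repeat = per_repeat,
       mean = colMeans(per_repeat[, -1, drop = FALSE]))
}

#' Add Gaussian pixel noise to an RGB image
#'
#' Adds independent zero-mean Gaussian noise with standard deviation
#' `percent * 255` to every pixel of every channel, then clips to
#' \[0, 255\]. Emulates noisier cameras or other capture settings.
#'
#' @param rgb a `color_image` in RGB space.
#' @param percent noise scale as a fraction of full scale, in \[0, 0.5\].
#' @param seed optional RNG seed for reproducible noise.
#' @return the noisy `color_image`.
#' @export
add_noise <- function(rgb, percent, seed = NULL) {
  assert_space(rgb, "rgb")
  stopifnot(percent >= 0, percent <= 0.5)
  if (percent == 0) return(rgb)
  noisify <- function() {
    noise <- array(stats::rnorm(length(rgb), 0, percent * 255), dim(rgb))
    color_image(pmax(pmin(unclass(rgb) + noise, 255), 0), "rgb")
  }
  if (is.null(seed)) noisify() else with_seed(seed, noisify())
}

#' Perturb a model's learned thresholds
#'
#' Scales every threshold by `1 + delta` (clipped to its channel range),
#' for sensitivity analysis of detection performance against training
#' error in the thresholds.
#'
#' @param model a `fruit_model`.
#' @param delta relative change, `|delta| < 1` (e.g. `0.05` for +5%).
#' @return the perturbed model.
#' @export
perturb_thresholds <- function(model, delta) {
  stopifnot(abs(delta) < 1)
  rng <- channel_ranges(model$space)
  for (d in 1:3)
    model$thresholds[, d] <- pmin(rng[d, 2], pmax(rng[d, 1],
      model$thresholds[, d] * (1 + delta)))
  model
}

#' Contribution of the morphological cleanup
#'
#' Mean F-score over labeled images with and without the morphological
#' cleanup of the final mask.
#'
#' @param images list of [labeled_image()] objects with ground truth.
#' @param model a `fruit_model`.
#' @return named vector `c(f_with = ..., f_without = ...)`.
#' @export
ablate_morphology <- function(images, model) {
  m <- vapply(images, function(im) {
    rep_ <- fruit_detect(model, im$rgb, truth = im$truth, morphology = TRUE)
    c(rep_$metrics$f, rep_$metrics_raw$f)
  }, numeric(2))
  c(f_with = mean(m[1, ]), f_without = mean(m[2, ]))
}
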