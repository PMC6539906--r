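#' Pool training pixel values per light group and color dimension
#'
#' Each labeled image is converted to grayscale and recursively split
#' ([split_recursive()]); every region is assigned to a light group and
#' overexposed regions are discarded. The channel values of the converted
#' color image inside each remaining region are pooled into
#' (group, dimension) buckets, separated into fruit and background by the
#' ground-truth mask.
#'
#' @param images list of [labeled_image()] objects with ground truth.
#' @param cfg a [split_config()].
#' @param space color-space tag.
#' @param hsi_variant passed to [convert_space()].
#' @return a list with `buckets[[group]][[dim]] = list(fruit, bg)`,
#'   `group_levels` (pixel-weighted mean light level of each populated
#'   group) and `group_pixels` (pixel counts per group).
#' @export
collect_training_pixels <- function(images, cfg, space = "ndi",
                                    hsi_variant = "hsi") {
  if (length(images) == 0L) stop("no training images", call. = FALSE)
  groups <- c("low", "medium", "high")
  buckets <- stats::setNames(lapply(groups, function(g)
    lapply(1:3, function(d) list(fruit = list(), bg = list()))), groups)
  lv_sum <- stats::setNames(numeric(3), groups)
  px_sum <- stats::setNames(numeric(3), groups)
  for (im in images) {
    if (is.null(im$truth))
      stop("training requires ground-truth masks", call. = FALSE)
    gray <- to_gray(im$rgb)
    conv <- convert_space(im$rgb, space, hsi_variant = hsi_variant)
    regions <- split_recursive(gray, cfg)
    for (k in seq_len(nrow(regions))) {
      g <- regions$group[k]
      if (g == "overexposed") next
      rr <- (regions$row_start[k] + 1):regions$row_end[k]
      cc <- (regions$col_start[k] + 1):regions$col_end[k]
      tr <- im$truth[rr, cc] != 0
      npx <- length(tr)
      lv_sum[g] <- lv_sum[g] + regions$light_level[k] * npx
      px_sum[g] <- px_sum[g] + npx
      for (d in 1:3) {
        v <- conv[rr, cc, d]
        buckets[[g]][[d]]$fruit[[length(buckets[[g]][[d]]$fruit) + 1L]] <- v[tr]
        buckets[[g]][[d]]$bg[[length(buckets[[g]][[d]]$bg) + 1L]] <- v[!tr]
      }
    }
  }
  for (g in groups) for (d in 1:3) {
    buckets[[g]][[d]]$fruit <- unlist(buckets[[g]][[d]]$fruit)
    buckets[[g]][[d]]$bg <- unlist(buckets[[g]][[d]]$bg)
  }
  list(buckets = buckets,
       group_levels = ifelse(px_sum > 0, lv_sum / px_sum, NA_real_),
       group_pixels = px_sum)
}

#' Select a threshold by sweeping the ROC curve
#'
#' Sweeps `n_levels` candidates over the channel range and returns the one
#' maximizing either the F-score of its operating point (the default) or,
#' when `objective_weight` is supplied, the linear score
#' `w * TPR + (1 - w) * (1 - FPR)` — which lets a deployment trade hit
#' rate against false alarms in real time. When several candidates tie for
#' the best score — for separable classes every threshold inside the gap
#' between the class supports ties at F = 1 — the middle of the tied
#' plateau is returned, placing the cutoff centrally in the gap, where it
#' generalizes best to unseen images.
#'
#' @param fruit_values,bg_values channel values of the two classes.
#' @param direction `"gt"` or `"lt"`.
#' @param range channel `(min, max)` to sweep.
#' @param objective_weight `NULL` (maximize F) or a weight `w` in \[0, 1\].
#' @param n_levels candidate count (default 256).
#' @return a list `threshold`, `tpr`, `fpr`, `score`.
#' @export
select_threshold <- function(fruit_values, bg_values, direction = "gt",
                             range = NULL, objective_weight = NULL,
                             n_levels = 256) {
  roc <- roc_curve(fruit_values, bg_values, direction, n_levels, range)
  score <- if (is.null(objective_weight)) f_score(roc$tpr, roc$fpr)
  else objective_weight * roc$tpr + (1 - objective_weight) * (1 - roc$fpr)
  tied <- which(score >= max(score) - 1e-12)
  i <- tied[ceiling(length(tied) / 2)]  # center of the tied plateau
  list(threshold = roc$threshold[i], tpr = roc$tpr[i], fpr = roc$fpr[i],
       score = score[i])
}

combination_labels <- function() c("1", "2", "3", "12", "13", "23", "123")

combination_dims <- function(combination) {
  as.integer(strsplit(combination, "")[[1]])
}

#' Select the best mask combination on training data
#'
#' Seven candidate masks exist per image: the three per-dimension masks and
#' the four intersections 1∩2, 1∩3, 2∩3, 1∩2∩3.
#' Intersections can only lower both TPR and FPR, so they pay off when the
#' dimensions' false positives are independent. The candidate with the
#' highest mean F-score over the training images wins; ties go to the
#' candidate intersecting fewer dimensions.
#'
#' @param dimension_masks list (one element per image) of lists of the 3
#'   per-dimension binary masks.
#' @param truths list of ground-truth masks, aligned with `dimension_masks`.
#' @return the winning combination label, with the per-combination mean
#'   F-scores attached as attribute `"scores"`.
#' @export
select_combination <- function(dimension_masks, truths) {
  combos <- combination_labels()
  scores <- vapply(combos, function(cb) {
    mean(mapply(function(masks, truth) {
      m <- combine_masks(masks, cb)
      f_score(mask_tpr(m, truth), mask_fpr(m, truth))
    }, dimension_masks, truths))
  }, numeric(1))
  best <- combos[which.max(scores)]  # label order favors fewer dimensions
  structure(best, scores = scores)
}

#' Fit the adaptive-thresholding detection model
#'
#' The central fitting routine. From labeled RGB images and tuned
#' parameters it learns the complete detector: nine thresholds (three
#' illumination groups x three color dimensions) selected by ROC sweep on
#' the pooled per-bucket pixel values, the per-dimension classification
#' directions, the anchor light level of each group (the mean observed
#' light level of its training regions, used for interpolation at test
#' time), and the best of the seven mask combinations.
#'
#' A light group that ends up without two-class data (for instance no
#' fruit was ever observed in low light) falls back to the nearest
#' populated group's thresholds, with a warning.
#'
#' @param images list of [labeled_image()] objects with ground truth.
#' @param tuning a `fruit_tuning` object ([fruit_tune()]), or a list
#'   providing `t1`, `t2`, `t_over`, `std_stop`, `min_side` and optionally
#'   `directions`.
#' @param space color-space tag; defaults to the tuning's space.
#' @param objective_weight,n_levels passed to [select_threshold()].
#' @param hsi_variant HSI model variant, see [to_hsi()].
#' @param interp threshold interpolation rule, see
#'   [interpolate_thresholds()].
#' @return a `fruit_model` object with components `space`, `group_levels`
#'   (named, strictly increasing), `thresholds` (3 x 3 matrix,
#'   groups x dimensions), `directions`, `combination`, `split_config`,
#'   `interp` and a `training` list (per-combination training F-scores,
#'   per-threshold operating points).
#' @export
fruit_fit <- function(images, tuning, space = NULL, objective_weight = NULL,
                      n_levels = 256, hsi_variant = NULL,
                      interp = c("standard", "reversed")) {
  if (length(images) == 0L) stop("empty image list", call. = FALSE)
  interp <- match.arg(interp)
  if (is.null(space)) space <- if (!is.null(tuning$space)) tuning$space else "ndi"
  if (is.null(hsi_variant))
    hsi_variant <- if (!is.null(tuning$hsi_variant)) tuning$hsi_variant else "hsi"
  cfg <- split_config(std_stop = tuning$std_stop,
                      min_side = if (is.null(tuning$min_side)) 16 else tuning$min_side,
                      t1 = tuning$t1, t2 = tuning$t2, t_over = tuning$t_over)
  rng <- channel_ranges(space)

  pooled <- collect_training_pixels(images, cfg, space, hsi_variant)
  groups <- c("low", "medium", "high")

  directions <- tuning$directions
  if (is.null(directions)) {
    directions <- vapply(1:3, function(d) {
      v <- unlist(lapply(groups, function(g)
        c(pooled$buckets[[g]][[d]]$fruit, pooled$buckets[[g]][[d]]$bg)))
      learn_direction(v, range = rng[d, ])
    }, character(1))
  }

  populated <- vapply(groups, function(g)
    length(pooled$buckets[[g]][[1]]$fruit) > 0 &&
      length(pooled$buckets[[g]][[1]]$bg) > 0, logical(1))
  if (!any(populated))
    stop("no light group has both fruit and background training pixels",
         call. = FALSE)

  thresholds <- matrix(NA_real_, 3, 3, dimnames = list(groups, NULL))
  points <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    src <- g
    if (!populated[gi]) {
      src <- groups[which(populated)[which.min(abs(which(populated) - gi))]]
      warning(sprintf(
        "light group '%s' has no two-class training data; using '%s' thresholds",
        g, src), call. = FALSE)
    }
    for (d in 1:3) {
      sel <- select_threshold(pooled$buckets[[src]][[d]]$fruit,
                              pooled$buckets[[src]][[d]]$bg,
                              direction = directions[d], range = rng[d, ],
                              objective_weight = objective_weight,
                              n_levels = n_levels)
      thresholds[gi, d] <- sel$threshold
      points[[paste(g, d, sep = ".")]] <- sel
    }
  }

  # Anchor light levels: observed pixel-weighted means; empty groups take
  # the midpoint of their light band so the anchors stay strictly increasing.
  band_mid <- c(cfg$t1 / 2, (cfg$t1 + cfg$t2) / 2, (cfg$t2 + cfg$t_over) / 2)
  group_levels <- pooled$group_levels
  group_levels[is.na(group_levels)] <- band_mid[is.na(group_levels)]
  names(group_levels) <- groups

  model <- structure(list(
    space = space, group_levels = group_levels, thresholds = thresholds,
    directions = directions, combination = "1", split_config = cfg,
    interp = interp, hsi_variant = hsi_variant,
    training = list(threshold_points = points)
  ), class = "fruit_model")

  # Pick the combination on the training set (pre-morphology masks).
  dim_masks <- lapply(images, function(im)
    fruit_detect(model, im$rgb, morphology = FALSE)$dimension_masks)
  truths <- lapply(images, `[[`, "truth")
  comb <- select_combination(dim_masks, truths)
  model$combination <- as.character(comb)
  model$training$combination_scores <- attr(comb, "scores")
  model
}
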