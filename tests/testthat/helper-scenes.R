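# Shared fixture builders. All fixtures are generated in code; seeds are
# fixed so every run sees the same data.

uniform_rgb <- function(h, w, col) {
  color_image(array(rep(col, each = h * w), c(h, w, 3)), "rgb")
}

random_rgb <- function(h, w, seed) {
  fruitseg:::with_seed(seed, color_image(array(runif(h * w * 3, 0, 255),
                                               c(h, w, 3)), "rgb"))
}

random_mask <- function(h, w, p, seed) {
  fruitseg:::with_seed(seed, matrix(rbinom(h * w, 1, p), h, w))
}

# Separable red-on-green scenes under a smooth multiplicative gradient;
# NDI dimension 1 separates fruit from background exactly by construction.
separable_spec <- function(seed = 42, ...) {
  scene_spec(illumination = list(orientation = "horizontal",
                                 min_gain = 0.7, max_gain = 1.0),
             seed = seed, ...)
}

# Three-zone step illumination (dark / medium / bright bands at 25%/50%/25%
# of the width, aligned with quadtree midpoints). In RGB space a single
# global threshold cannot separate fruit from background across the zones,
# but per-zone thresholds can.
three_zone_spec <- function(seed = 42, size = c(160, 224), ...) {
  scene_spec(size = size,
             illumination = list(orientation = "horizontal",
                                 gains = c(0.25, 0.7, 1.4),
                                 breaks = c(0.25, 0.75)),
             seed = seed, ...)
}

# Quick tuning for fitted-model tests: fixed stop value, no grid search.
quick_tuning <- function(images, space = "ndi", std_stop = 10)
  fruit_tune(images, space = space, std_stop = std_stop)

# Independent threshold-selection oracle: direct mean() sweeps instead of
# the implementation's sorted findInterval path, same plateau-center tie
# rule.
oracle_select <- function(fruit, bg, dir, range, n_levels = 256) {
  th <- seq(range[1], range[2], length.out = n_levels)
  sc <- vapply(th, function(t) {
    tpr <- if (dir == "gt") mean(fruit > t) else mean(fruit < t)
    fpr <- if (dir == "gt") mean(bg > t) else mean(bg < t)
    den <- tpr + (1 - fpr)
    if (den == 0) 0 else 2 * tpr * (1 - fpr) / den
  }, numeric(1))
  tied <- which(sc >= max(sc) - 1e-12)
  i <- tied[ceiling(length(tied) / 2)]
  list(threshold = th[i], score = sc[i])
}

# Brute-force pixel-loop rates.
loop_tpr <- function(pred, truth) {
  hit <- 0; nf <- 0
  for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth))) {
    if (truth[i, j] != 0) {
      nf <- nf + 1
      if (pred[i, j] != 0) hit <- hit + 1
    }
  }
  hit / nf
}

loop_fpr <- function(pred, truth) {
  fa <- 0; nb <- 0
  for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth))) {
    if (truth[i, j] == 0) {
      nb <- nb + 1
      if (pred[i, j] != 0) fa <- fa + 1
    }
  }
  fa / nb
}

# A hand-assembled model for detection-stage tests.
stub_model <- function(thresholds, group_levels = c(low = 10, medium = 70,
                                                    high = 130),
                       directions = c("gt", "gt", "gt"), space = "ndi",
                       combination = "1", std_stop = 10,
                       t1 = 84, t2 = 140, t_over = 250,
                       interp = "standard") {
  structure(list(space = space, group_levels = group_levels,
                 thresholds = thresholds, directions = directions,
                 combination = combination,
                 split_config = split_config(std_stop, t1 = t1, t2 = t2,
                                             t_over = t_over),
                 interp = interp, hsi_variant = "hsi", training = list()),
            class = "fruit_model")
}
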