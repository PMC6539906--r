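test_that("the 15/70/15 percentile rule places the light cutoffs", {
  tt <- tune_light_thresholds(0:99)
  expect_equal(unname(tt), c(14.85, 84.15))  # type-7 percentiles of 0..99
  expect_error(tune_light_thresholds(rep(10, 50)), "degenerate")
  # resulting group shares are ~15/70/15 up to quantization
  set.seed(21)
  lv <- runif(2000, 0, 255)
  tt2 <- tune_light_thresholds(lv)
  cfg <- split_config(10, t1 = tt2["t1"], t2 = tt2["t2"])
  g <- categorize(lv, cfg)
  expect_equal(mean(g == "low"), 0.15, tolerance = 0.02)
  expect_equal(mean(g == "medium"), 0.70, tolerance = 0.02)
})

test_that("light statistics match the moment definitions", {
  s <- light_statistics(c(0, 0, 0, 10))
  # hand-computed: m2 = 18.75, m3 = 93.75, m4 = 820.3125
  expect_equal(s$mean, 2.5)
  expect_equal(s$std, 5)                       # sample (n-1) standard deviation
  expect_equal(s$skewness, 93.75 / 18.75^1.5)  # 2/sqrt(3)
  expect_equal(s$kurtosis, 820.3125 / 18.75^2 - 3)
  expect_equal(s$median, 0)
  sym <- light_statistics(c(1, 2, 3))
  expect_equal(sym$skewness, 0)
  expect_equal(sym$median, 2)
  flat <- light_statistics(c(7, 7, 7))
  expect_true(flat$degenerate)
  expect_equal(flat$std, 0)
  expect_equal(flat$skewness, 0)
  expect_error(light_statistics(5), "two values")
})

test_that("classification direction follows the background-majority rule", {
  # 90% of values below the probe: background is above-threshold minority
  expect_equal(learn_direction(c(rep(0.1, 90), rep(0.9, 10)),
                               threshold = 0.5), "gt")
  # only 20% below: reverse the rule
  expect_equal(learn_direction(c(rep(0.1, 20), rep(0.9, 80)),
                               threshold = 0.5), "lt")
  # default probe is the channel-range midpoint
  expect_equal(learn_direction(rep(-0.5, 10), range = c(-1, 1)), "gt")
  # order invariance
  v <- c(rep(0.2, 30), rep(0.8, 70))
  expect_equal(learn_direction(v, threshold = 0.5),
               learn_direction(rev(v), threshold = 0.5))
})

test_that("stop-condition selection maximizes test F and is reproducible", {
  imgs <- generate_dataset(three_zone_spec(seed = 5, size = c(80, 112),
                                           n_fruits = 2, axes = c(10, 14)),
                           8)
  tun <- fruit_tune(imgs, space = "rgb", std_stop = 15)
  picked <- suppressWarnings(tune_std_stop(imgs, grid = c(15, 255), tun,
                                           space = "rgb", repeats = 3,
                                           seed = 2, sample_fraction = 0.5))
  # with a strong zone gradient, splitting must beat never splitting
  expect_equal(as.numeric(picked), 15)
  sc <- attr(picked, "scores")
  expect_gt(sc["15"], sc["255"])
  again <- suppressWarnings(tune_std_stop(imgs, grid = c(15, 255), tun,
                                          space = "rgb", repeats = 3,
                                          seed = 2, sample_fraction = 0.5))
  expect_identical(as.numeric(picked), as.numeric(again))
  # single-candidate grids short-circuit
  expect_equal(as.numeric(tune_std_stop(imgs, 30, tun, space = "rgb")), 30)
})

test_that("flat-illumination scenes plateau across large stop values", {
  flat <- generate_dataset(scene_spec(size = c(80, 112), n_fruits = 2,
                                      axes = c(10, 14), seed = 9), 6)
  tun <- fruit_tune(flat, space = "ndi", std_stop = 10)
  picked <- suppressWarnings(tune_std_stop(flat, grid = c(120, 200, 255), tun,
                                           space = "ndi", repeats = 2,
                                           seed = 4, sample_fraction = 0.6))
  sc <- attr(picked, "scores")
  # none of these stop values ever split a flat scene: identical F
  expect_equal(max(sc) - min(sc), 0, tolerance = 1e-12)
  # ties resolve to the largest candidate
  expect_equal(as.numeric(picked), 255)
})

test_that("the full tuning pipeline returns coherent parameters", {
  imgs <- generate_dataset(separable_spec(seed = 3), 6)
  tun <- fruit_tune(imgs, space = "ndi", std_stop = 10)
  expect_s3_class(tun, "fruit_tuning")
  expect_lt(tun$t1, tun$t2)
  expect_length(tun$directions, 3)
  expect_true(all(tun$directions %in% c("gt", "lt")))
  expect_false(tun$light_stats$degenerate)
  tun2 <- fruit_tune(imgs, space = "ndi", std_stop = 10)
  expect_identical(tun[c("t1", "t2", "directions")],
                   tun2[c("t1", "t2", "directions")])
})
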