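test_that("threshold selection equals the exhaustive oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:400, 1)
    fruit <- runif(n, -1, 1)
    bg <- runif(n, -1, 1) - seed / 10
    dir <- if (seed %% 2) "gt" else "lt"
    got <- select_threshold(fruit, bg, dir, range = c(-1, 1))
    want <- oracle_select(fruit, bg, dir, range = c(-1, 1))
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$score, want$score)
  }
})

test_that("threshold selection behaves at the separable and uninformative
           extremes", {
  sep <- select_threshold(c(0.8, 0.9), c(0.1, 0.2), "gt", range = c(0, 1))
  expect_equal(sep$tpr, 1)
  expect_equal(sep$fpr, 0)
  expect_gt(sep$threshold, 0.2)
  expect_lt(sep$threshold, 0.8)
  set.seed(12)
  v <- runif(2000)
  flat <- select_threshold(v, v, "gt", range = c(0, 1),
                           objective_weight = 0.5)
  expect_equal(flat$score, 0.5, tolerance = 0.02)
  expect_error(select_threshold(numeric(0), 1, "gt"), "empty class")
})

test_that("training pixels are pooled per light group with conservation", {
  # uniform mid-gray image: everything lands in the medium bucket
  img <- labeled_image(uniform_rgb(40, 40, c(100, 100, 100)),
                       matrix(0, 40, 40))
  cfg <- split_config(10, t1 = 50, t2 = 150)
  pooled <- collect_training_pixels(list(img), cfg, "rgb")
  expect_equal(unname(pooled$group_pixels),
               c(0, 1600, 0))
  expect_length(pooled$buckets$medium[[1]]$fruit, 0)  # truth all-zero
  expect_length(pooled$buckets$medium[[1]]$bg, 1600)

  # three-zone scene: all groups populated, pixel counts conserved
  scn <- generate_scene(three_zone_spec(seed = 8))
  tun <- fruit_tune(list(scn), space = "rgb", std_stop = 15)
  cfg2 <- split_config(15, t1 = tun$t1, t2 = tun$t2)
  p2 <- collect_training_pixels(list(scn), cfg2, "rgb")
  expect_true(all(p2$group_pixels > 0))
  n_buckets <- sum(vapply(p2$buckets, function(g)
    length(g[[1]]$fruit) + length(g[[1]]$bg), numeric(1)))
  expect_equal(n_buckets, prod(dim(scn$rgb)[1:2]))  # nothing overexposed here
  expect_error(collect_training_pixels(list(), cfg, "rgb"), "no training")
})

test_that("intersections dominate their factors in both rates", {
  for (seed in 1:5) {
    a <- random_mask(12, 12, 0.5, seed)
    b <- random_mask(12, 12, 0.5, seed + 50)
    truth <- random_mask(12, 12, 0.4, seed + 99)
    ab <- combine_masks(list(a, b, b), "12")
    expect_lte(mask_tpr(ab, truth), min(mask_tpr(a, truth), mask_tpr(b, truth)))
    expect_lte(mask_fpr(ab, truth), min(mask_fpr(a, truth), mask_fpr(b, truth)))
  }
})

test_that("combination selection rewards clean intersections and breaks ties
           toward fewer dimensions", {
  truth <- matrix(0, 30, 30); truth[10:20, 10:20] <- 1
  set.seed(33)
  noise_a <- matrix(0, 30, 30); noise_a[1:5, 1:5] <- 1
  noise_b <- matrix(0, 30, 30); noise_b[25:30, 25:30] <- 1
  rand <- random_mask(30, 30, 0.5, 4)
  # dimension 1 perfect, 2-3 random: the single dimension wins
  got <- select_combination(list(list(truth, rand, rand)), list(truth))
  expect_equal(as.character(got), "1")
  # independent false positives vanish under intersection
  got2 <- select_combination(list(list(pmax(truth, noise_a),
                                       pmax(truth, noise_b), rand)),
                             list(truth))
  expect_equal(as.character(got2), "12")
  # identical masks tie; fewer dimensions preferred
  got3 <- select_combination(list(list(truth, truth, truth)), list(truth))
  expect_equal(as.character(got3), "1")
})

test_that("fitting a separable scene yields a perfectly separating model", {
  imgs <- generate_dataset(separable_spec(seed = 61), 6)
  tun <- quick_tuning(imgs)
  model <- fruit_fit(imgs, tun, space = "ndi")
  expect_s3_class(model, "fruit_model")
  expect_equal(max(model$training$combination_scores), 1)
  expect_true(all(diff(model$group_levels) > 0))
  rng <- channel_ranges("ndi")
  expect_true(all(model$thresholds >= rng[, 1] & model$thresholds <= rng[, 2]))
  # learned dimension-1 thresholds lie between the class supports
  ndi1 <- lapply(imgs, function(im) to_ndi(im$rgb)[, , 1])
  sup_bg <- max(unlist(mapply(function(v, im) v[im$truth == 0], ndi1, imgs)))
  inf_fruit <- min(unlist(mapply(function(v, im) v[im$truth == 1], ndi1, imgs)))
  expect_true(all(model$thresholds[, 1] > sup_bg &
                  model$thresholds[, 1] < inf_fruit))
  # self-consistency: detecting a training image reproduces training F
  rep_ <- fruit_detect(model, imgs[[1]]$rgb, truth = imgs[[1]]$truth,
                       morphology = FALSE)
  expect_equal(rep_$metrics_raw$f, 1)
  # determinism
  model2 <- fruit_fit(imgs, tun, space = "ndi")
  expect_identical(model$thresholds, model2$thresholds)
  expect_identical(model$combination, model2$combination)
  expect_error(fruit_fit(list(), tun), "empty image list")
})

test_that("light groups without two-class data fall back to a populated
           neighbor", {
  # flat illumination: only one light group is ever observed
  imgs <- generate_dataset(scene_spec(size = c(80, 112), n_fruits = 2,
                                      axes = c(10, 14), seed = 17), 3)
  tun <- list(t1 = 5, t2 = 250, t_over = 254, std_stop = 10, min_side = 16,
              space = "ndi", directions = NULL)
  warns <- capture_warnings(model <- fruit_fit(imgs, tun, space = "ndi"))
  expect_gte(length(warns), 2)  # both empty groups fall back
  expect_true(all(grepl("no two-class training data", warns)))
  expect_true(all(is.finite(model$thresholds)))
  expect_true(all(diff(model$group_levels) > 0))
})

test_that("a fitted model survives a JSON round trip losslessly", {
  imgs <- generate_dataset(separable_spec(seed = 61), 4)
  model <- fruit_fit(imgs, quick_tuning(imgs), space = "ndi")
  f <- tempfile(fileext = ".json")
  write_fruit_model(model, f)
  back <- read_fruit_model(f)
  expect_identical(back$thresholds, model$thresholds)
  expect_identical(back$group_levels, model$group_levels)
  expect_identical(back$directions, model$directions)
  expect_identical(back$combination, model$combination)
  expect_identical(unclass(back$split_config), unclass(model$split_config))
  # a re-read model detects identically
  r1 <- fruit_detect(model, imgs[[1]]$rgb)
  r2 <- fruit_detect(back, imgs[[1]]$rgb)
  expect_identical(r1$final_mask, r2$final_mask)
  unlink(f)
})
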