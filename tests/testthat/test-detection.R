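test_that("threshold interpolation is exact at anchors, continuous between
           them, and clamps outside", {
  th <- matrix(c(0.2, 0.4, 0.6), 3, 3,
               dimnames = list(c("low", "medium", "high"), NULL))
  m <- stub_model(th)
  expect_equal(interpolate_thresholds(m, 10), unname(th[1, ]))
  expect_equal(interpolate_thresholds(m, 70), unname(th[2, ]))
  expect_equal(interpolate_thresholds(m, 130), unname(th[3, ]))
  # worked mid-bracket case: anchors 10/70, T = 0.2/0.4, level 40 -> 0.3
  expect_equal(interpolate_thresholds(m, 40)[1], 0.3)
  # the reversed weighting agrees at the bracket midpoint only
  mr <- stub_model(th, interp = "reversed")
  expect_equal(interpolate_thresholds(mr, 40)[1], 0.3)
  expect_equal(interpolate_thresholds(m, 25)[1], 0.25)
  expect_equal(interpolate_thresholds(mr, 25)[1], 0.35)
  # clamping
  expect_equal(interpolate_thresholds(m, 0), unname(th[1, ]))
  expect_equal(interpolate_thresholds(m, 255), unname(th[3, ]))
  # continuity across a fine grid
  lv <- seq(0, 255, by = 0.5)
  v <- vapply(lv, function(l) interpolate_thresholds(m, l)[1], numeric(1))
  expect_lt(max(abs(diff(v))), 0.005)
})

test_that("binarization follows threshold and direction", {
  px <- color_image(array(0.9, c(2, 2, 3)), "ndi")
  up <- binarize(px, rep(0.5, 3), rep("gt", 3))
  expect_true(all(up[[1]] == 1))
  down <- binarize(px, rep(0.5, 3), rep("lt", 3))
  expect_true(all(down[[1]] == 0))
  board <- matrix(c(0.2, 0.8), 4, 4)  # alternating rows
  px2 <- color_image(array(board, c(4, 4, 3)), "ndi")
  expect_equal(binarize(px2, rep(0.5, 3), rep("gt", 3))[[1]],
               (board > 0.5) * 1)
})

test_that("mask combination is elementwise conjunction", {
  ones <- matrix(1, 8, 8)
  b <- random_mask(8, 8, 0.5, 2)
  expect_equal(combine_masks(list(ones, b, b), "12"), b)
  a <- matrix(0, 8, 8); a[1:4, ] <- 1
  d <- matrix(0, 8, 8); d[5:8, ] <- 1
  expect_true(all(combine_masks(list(a, d, d), "12") == 0))
  # brute-force conjunction on random masks
  for (seed in 1:3) {
    m <- lapply(1:3, function(d) random_mask(8, 8, 0.5, seed * 10 + d))
    want <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8)
      want[i, j] <- as.numeric(m[[1]][i, j] & m[[2]][i, j] & m[[3]][i, j])
    expect_equal(combine_masks(m, "123"), want)
  }
  expect_error(combine_masks(list(a, d, d), "21"), "unknown combination")
})

test_that("morphological cleanup removes sub-element blobs and keeps large
           structures", {
  expect_equal(morphological_cleanup(matrix(0, 40, 40)), matrix(0, 40, 40))
  blob <- matrix(0, 40, 40); blob[18:22, 18:22] <- 1  # 5x5 < 11x11
  expect_equal(sum(morphological_cleanup(blob)), 0)
  big <- matrix(0, 80, 80); big[11:60, 11:60] <- 1    # 50x50 square
  kept <- morphological_cleanup(big)
  expect_gte(sum(kept * big), 0.95 * sum(big))
  expect_equal(sum(kept * (1 - big)), 0)
})

test_that("detection stitches regions, zeroes overexposed areas and honors
           the intersection subset property", {
  th <- matrix(0, 3, 3, dimnames = list(c("low", "medium", "high"), NULL))
  m <- stub_model(th, space = "rgb", combination = "12",
                  directions = c("gt", "gt", "gt"),
                  group_levels = c(low = 40, medium = 100, high = 200),
                  t1 = 60, t2 = 150, t_over = 250)
  m$thresholds <- matrix(c(50, 50, 50), 3, 3,
                         dimnames = list(c("low", "medium", "high"), NULL))
  # uniform 255: a single overexposed region, all-zero output
  over <- fruit_detect(m, uniform_rgb(40, 40, c(255, 255, 255)))
  expect_equal(sum(over$final_mask), 0)
  expect_equal(over$regions$group[1], "overexposed")
  # subset property of the chosen intersection, pre-morphology
  img <- random_rgb(64, 64, 31)
  rep_ <- fruit_detect(m, img, morphology = FALSE)
  expect_true(all(rep_$final_mask <= rep_$dimension_masks[[1]]))
  expect_true(all(rep_$final_mask <= rep_$dimension_masks[[2]]))
  # stitched per-dimension masks agree with direct whole-image binarization
  # when every region interpolates to the same thresholds
  direct <- binarize(img, c(50, 50, 50), rep("gt", 3))
  expect_identical(rep_$dimension_masks[[1]], direct[[1]])
  # determinism
  rep2 <- fruit_detect(m, img, morphology = FALSE)
  expect_identical(rep_$dimension_masks, rep2$dimension_masks)
  # predict() is the same entry point
  p <- predict(m, img, morphology = FALSE)
  expect_identical(p$dimension_masks, rep_$dimension_masks)
  expect_error(fruit_detect(m, img, truth = matrix(0, 3, 3)), "shape")
})
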