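test_that("preprocessing converts to grey and blurs with mass conservation", {
  cfg <- test_config()
  const <- array(0L, dim = c(20, 20, 3))
  const[, , 1] <- 90L; const[, , 2] <- 90L; const[, , 3] <- 90L
  g <- preprocess_frame(const, cfg)
  expect_true(all(g == 90))
  # single bright pixel: blur spreads over the 3x3 neighbourhood, total
  # intensity conserved up to rounding
  fr <- matrix(0, 21, 21); fr[11, 11] <- 255
  b <- preprocess_frame(fr, cfg)
  expect_true(all(b[abs(row(b) - 11) > 1 | abs(col(b) - 11) > 1] == 0))
  kern <- bactrack:::bt_gaussian_kernel(3)
  expect_equal(b[10:12, 10:12], round(kern * 255), ignore_attr = TRUE)
  expect_lt(abs(sum(b) - 255), 5)
  # grey input: conversion is identity, then blur
  grey <- matrix(77, 10, 10)
  expect_true(all(preprocess_frame(grey, cfg) == 77))
  expect_error(preprocess_frame(array(0, c(4, 4, 2)), cfg), "channel")
})

test_that("a uniform image yields an empty mask", {
  cfg <- test_config()
  img <- matrix(128, 40, 40)
  expect_equal(sum(marker_gated_threshold(img, cfg)), 0)
  expect_equal(sum(adaptive_simple_threshold(img, cfg)), 0)
})

test_that("marker gating keeps only regions containing a marker pixel", {
  cfg <- test_config(adaptive_offset = 5, marker_offset = 30)
  img <- matrix(128, 40, 60)
  img[10:13, 10:13] <- 60    # strong blob: survives both thresholds
  img[25:28, 40:43] <- 115   # faint blob: candidate only, no marker
  cand <- adaptive_simple_threshold(img, cfg)
  gated <- marker_gated_threshold(img, cfg)
  det_cand <- extract_detections(cand, 0, cfg)
  det_gated <- extract_detections(gated, 0, cfg)
  expect_equal(nrow(det_cand), 2)
  expect_equal(nrow(det_gated), 1)
  expect_lt(abs(det_gated$centre_x - 11.5), 2)
  # with equal offsets the marker mask equals the candidate mask and the
  # gate passes everything
  cfg2 <- test_config(adaptive_offset = 5, marker_offset = 5)
  expect_identical(marker_gated_threshold(img, cfg2),
                   adaptive_simple_threshold(img, cfg2))
})

test_that("marker-gated regions are a subset of simple-adaptive regions", {
  cfg <- test_config()
  set.seed(31)
  for (i in 1:10) {
    img <- matrix(round(runif(60 * 60, 60, 200)), 60, 60)
    gated <- marker_gated_threshold(img, cfg)
    simple <- adaptive_simple_threshold(img, cfg)
    expect_true(all(simple[gated == 1L] == 1L))
  }
})

test_that("rolling global threshold averages frame statistics", {
  cfg <- test_config(detection_mode = "global_rolling", global_offset = 1,
                     rolling_window_s = 0.1)  # 3-frame window at 30 fps
  st <- new_rolling_state(cfg)
  f1 <- matrix(c(rep(100, 50), rep(200, 50)), 10, 10)
  r1 <- global_rolling_threshold(f1, st, cfg)
  expect_equal(r1$threshold, mean(f1) - sd(f1))  # window of one frame
  # constant video: threshold constant
  r2 <- global_rolling_threshold(f1, r1$state, cfg)
  expect_equal(r2$threshold, r1$threshold)
  # step change in illumination moves the threshold gradually
  f2 <- f1 + 40
  r3 <- global_rolling_threshold(f2, r2$state, cfg)
  exp3 <- mean(c(mean(f1) - sd(f1), mean(f1) - sd(f1), mean(f2) - sd(f2)))
  expect_equal(r3$threshold, exp3)
  expect_lt(r3$threshold, mean(f2) - sd(f2))  # not an instant jump
  # window caps at rolling_window_s * fps frames
  r4 <- global_rolling_threshold(f2, r3$state, cfg)
  expect_equal(length(r4$state$means), 3)
})

test_that("extraction matches the brute-force oracle on random masks", {
  cfg <- test_config(rod_shaped = FALSE)
  set.seed(7)
  for (i in 1:25) {
    mask <- matrix(as.integer(runif(32 * 32) < 0.2), 32, 32)
    det <- extract_detections(mask, 0, cfg)
    orc <- oracle_detections(mask)
    expect_equal(nrow(det), nrow(orc))
    expect_equal(det$centre_x, orc$centre_x)
    expect_equal(det$centre_y, orc$centre_y)
    expect_equal(det$width, orc$width)
    expect_equal(det$height, orc$height)
  }
})

test_that("extraction handles empty masks and known rectangles", {
  cfg <- test_config(rod_shaped = FALSE)
  expect_equal(nrow(extract_detections(matrix(0L, 10, 10), 0, cfg)), 0)
  mask <- matrix(0L, 20, 20)
  mask[6:8, 4:8] <- 1L   # rows y = 5..7, cols x = 3..7
  det <- extract_detections(mask, 3, cfg)
  expect_equal(det$width, 5)
  expect_equal(det$height, 3)
  expect_equal(det$centre_x, 5)
  expect_equal(det$centre_y, 6)
  expect_equal(det$frame_index, 3)
  expect_equal(det$area_px2, 15)
  # rod mode on the axis-aligned block agrees
  cfg_rod <- test_config(rod_shaped = TRUE)
  det_rod <- extract_detections(mask, 0, cfg_rod)
  expect_equal(sort(c(det_rod$width, det_rod$height)), c(3, 5))
  expect_equal(det_rod$area_px2, 15, tolerance = 1e-9)
})

test_that("rod-mode rectangles recover a rotated bar's orientation", {
  cfg <- test_config(rod_shaped = TRUE)
  mask <- matrix(0L, 30, 30)
  for (k in 0:9) mask[10 + k, 10 + k] <- 1L   # 45-degree diagonal bar
  det <- extract_detections(mask, 0, cfg)
  expect_equal(nrow(det), 1)
  expect_equal(det$angle_deg %% 90, 45, tolerance = 1)
  expect_gt(det$width, det$height)
})

test_that("two disjoint blobs come out in deterministic order", {
  cfg <- test_config(rod_shaped = FALSE)
  mask <- matrix(0L, 20, 20)
  mask[3:4, 15:16] <- 1L   # upper right
  mask[15:16, 3:4] <- 1L   # lower left
  det <- extract_detections(mask, 0, cfg)
  expect_equal(nrow(det), 2)
  expect_true(det$centre_y[1] < det$centre_y[2])
})

test_that("detect_frame dispatches and fails loudly on polarity mismatch", {
  cfg <- test_config()
  p <- motion_params(n_bacteria = 1, duration_s = 0.1, seed = 3)
  truth <- simulate_tracks(p, cfg)
  fr <- render_frame(truth[truth$frame == 0, ], p, cfg)
  det <- detect_frame(fr, 0, NULL, cfg)$detections
  expect_equal(nrow(det), 1)
  # inverted polarity: the dark cell cannot be found as a bright object;
  # the result is zero detections or spurious halo fragments, never the
  # clean single-cell detection
  cfg_inv <- test_config(bacteria_brighter_than_background = TRUE)
  det_inv <- detect_frame(fr, 0, NULL, cfg_inv)$detections
  correct <- nrow(det_inv) == 1 &&
    abs(det_inv$centre_x - det$centre_x) < 1 &&
    abs(det_inv$width - det$width) < 1
  expect_false(correct)
  # adaptive_simple is a superset of marker_gated
  cfg_simple <- test_config(detection_mode = "adaptive_simple")
  det_simple <- detect_frame(fr, 0, NULL, cfg_simple)$detections
  expect_gte(nrow(det_simple), nrow(det))
})
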