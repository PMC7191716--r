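test_that("coarse selection applies the 20% / 5x area rule of thumb", {
  cfg <- bt_default_config(avg_bacterial_area_px2 = 100,
                           min_track_time_s = 0)
  small <- make_track(1, 0:30, 50, 50, w = 2, h = 5)      # area 10 < 20
  big <- make_track(2, 0:30, 80, 50, w = 30, h = 20)      # area 600 > 500
  ok <- make_track(3, 0:30, 120, 50, w = 10, h = 10)      # area 100
  # a short detection burst followed by a second of gap zeros averages
  # close to zero and is discarded
  burst <- rbind(make_track(4, 0:2, 160, 50, w = 8, h = 8),
                 make_track(4, 3:32, 160, 50, w = 0, h = 0))
  cs <- coarse_select(as_raw_tracks(small, big, ok, burst), cfg)
  expect_equal(length(cs$tracks), 1)
  expect_equal(cs$tracks[[1]]$track_id[1], 3)
  expect_equal(unname(cs$report$exclusions["coarse_size"]), 3L)
  expect_error(coarse_select(as_raw_tracks(ok)[c(2, 1, 3), ], cfg),
               "sorted")
})

test_that("scrubbing removes gap placeholders and area outliers", {
  cfg <- bt_default_config(point_area_outlier_mult = 1.5)
  tk <- rbind(make_track(1, 0:9, 50, 50, w = 10, h = 10),
              make_track(1, 10:14, 50, 50, w = 0, h = 0),
              make_track(1, 15:19, 50, 50, w = 10, h = 10))
  s <- scrub_points(tk, cfg)
  expect_equal(nrow(s), 15)
  expect_true(all(s$width > 0))
  # an overlap event doubles one bounding rectangle
  tk2 <- make_track(2, 0:9, 50, 50, w = 10, h = 10)
  tk2$width[5] <- 20   # area 200 > 1.5 x mean(110)
  s2 <- scrub_points(tk2, cfg)
  expect_equal(nrow(s2), 9)
  expect_false(any(s2$width == 20))
  # disabled multiplier: identity on a gapless track
  cfg_off <- bt_default_config(point_area_outlier_mult = 0)
  expect_equal(nrow(scrub_points(tk2, cfg_off)), 10)
})

test_that("the Tukey outer fence splits at a single outlier distance", {
  cfg <- bt_default_config(max_consecutive_gaps = 5L,
                           distance_outlier_enabled = TRUE)
  # step distances 1,1,1,1,1,1,10: Q1 = Q3 = 1, IQR = 0, fence = 1
  x <- cumsum(c(0, 1, 1, 1, 1, 1, 1, 10))
  tk <- make_track(1, 0:7, x, 50)
  sp <- split_track(tk, cfg)
  expect_equal(sp$cause, "distance_outlier_split")
  expect_equal(vapply(sp$segments, nrow, 0L), c(7L, 1L))
  # a 2-frame gap run under the limit does not split
  tk2 <- make_track(2, c(0:10, 13:20), 60, 60)
  expect_null(split_track(tk2, cfg)$cause)
  # gap run over the limit splits there
  tk3 <- make_track(3, c(0:10, 20:30), 60, 60)
  sp3 <- split_track(tk3, cfg)
  expect_equal(sp3$cause, "consecutive_gaps")
  expect_equal(vapply(sp3$segments, nrow, 0L), c(11L, 11L))
})

test_that("distance splitting disables itself on outlier-heavy tables", {
  cfg <- bt_default_config(
    px_per_um = 1, fps = 30, avg_bacterial_area_px2 = 100,
    min_track_time_s = 0, max_consecutive_gaps = 0L, max_gap_fraction = 1,
    size_percentile = 0, edge_margin_frac = 0,
    distance_outlier_enabled = TRUE,
    distance_outlier_auto_disable_frac = 0.15)
  # 10 steps, 8 of length 0 and 2 of length 5: fence 0, 20% outliers
  x <- cumsum(c(0, rep(0, 4), 5, rep(0, 4), 5))
  tk <- make_track(1, 0:10, x, 200)
  tk$x <- tk$x + 100
  sel <- select_tracks(as_raw_tracks(tk), cfg)
  expect_true(sel$report$distance_outlier_auto_disabled)
  expect_equal(sel$report$split_events, 0L)
  expect_equal(length(sel$tracks), 1)
  # with a higher tolerance the same table does split
  cfg2 <- cfg; cfg2$distance_outlier_auto_disable_frac <- 0.25
  sel2 <- select_tracks(as_raw_tracks(tk), cfg2)
  expect_false(sel2$report$distance_outlier_auto_disabled)
  expect_gte(sel2$report$split_events, 1L)
})

test_that("fine criteria reject in documented order", {
  cfg <- bt_default_config(
    px_per_um = 1, fps = 30, frame_width = 640L, frame_height = 480L,
    min_track_time_s = 5, max_consecutive_gaps = 5L, max_gap_fraction = 0.2,
    size_percentile = 10, edge_margin_frac = 0.05)
  short <- make_track(1, 0:60, 320, 240)     # 2 s < 5 s
  expect_equal(fine_select(short, 100, cfg), "min_time_fine")
  cfg$min_track_time_s <- 1
  gappy <- make_track(1, seq(0, 90, by = 3), 320, 240)  # 2/3 missing
  expect_equal(fine_select(gappy, 100, cfg), "gap_fraction")
  edge <- make_track(1, 0:60, 12, 240)       # 2% from the left edge
  expect_equal(fine_select(edge, 100, cfg), "edge_margin")
  centred <- make_track(1, 0:60, 320, 240)
  expect_equal(fine_select(centred, 100, cfg), "pass")
  # two-sided percentile band
  dist <- c(rep(100, 9), 450)
  fat <- make_track(1, 0:60, 320, 240, w = 30, h = 15)
  expect_equal(fine_select(fat, dist, cfg), "size_percentile")
})

test_that("maximum-duration truncation lands on the exact time or below", {
  cfg <- bt_default_config(px_per_um = 1, fps = 30, max_track_time_s = 10)
  cont <- make_track(1, 0:360, 100, 100)
  out <- enforce_max_duration(cont, cfg)
  expect_equal(max(out$time_s) - min(out$time_s), 10)
  gap <- make_track(1, c(0:290, 310:360), 100, 100)
  out2 <- enforce_max_duration(gap, cfg)
  expect_equal(round(max(out2$time_s) * 30), 290)  # closest point below
  cfg_off <- bt_default_config(max_track_time_s = 0)
  expect_identical(enforce_max_duration(cont, cfg_off), cont)
  cfg$drop_short_after_truncation <- TRUE
  expect_null(enforce_max_duration(gap, cfg))
})

test_that("the ledger fixture hits every exclusion counter exactly", {
  fx <- ledger_fixture()
  sel <- select_tracks(fx$table, fx$config)
  expect_equal(length(sel$tracks), 0)
  expect_equal(sel$report$tracks_in, 10L)
  expect_equal(sel$report$exclusions[names(fx$expected)], fx$expected)
  expect_equal(sel$report$tracks_in,
               sel$report$tracks_accepted + sum(sel$report$exclusions))
})

test_that("a clean table is accepted in full with zero counters", {
  fx <- clean_fixture()
  sel <- select_tracks(fx$table, fx$config)
  expect_equal(length(sel$tracks), 8)
  expect_equal(sum(sel$report$exclusions), 0L)
  expect_equal(sel$report$split_events, 0L)
})

test_that("of several passing parts of a split track only the longest wins", {
  cfg <- bt_default_config(
    px_per_um = 1, fps = 30, frame_width = 640L, frame_height = 480L,
    avg_bacterial_area_px2 = 100, min_track_time_s = 2,
    max_consecutive_gaps = 5L, max_gap_fraction = 0.2,
    size_percentile = 0, edge_margin_frac = 0.05)
  tk <- make_track(1, c(0:240, 261:381), 320, 240)
  sel <- select_tracks(as_raw_tracks(tk), cfg)
  expect_equal(length(sel$tracks), 1)
  expect_equal(sel$report$split_events, 1L)
  expect_equal(bactrack:::bt_track_duration(sel$tracks[[1]]), 8)
  expect_equal(round(min(sel$tracks[[1]]$time_s) * 30), 0)
})

test_that("report conservation holds on random fixtures", {
  set.seed(99)
  for (rep_i in 1:5) {
    n <- 12
    tracks <- lapply(seq_len(n), function(i) {
      len <- sample(30:240, 1)
      frames <- sort(sample(0:(len + 40), len))
      area_w <- stats::rnorm(1, 10, 3)
      mk <- make_track(i, frames,
                       runif(1, 0, 640) + cumsum(runif(len, -1, 1)),
                       runif(1, 0, 480), w = max(2, area_w), h = 10)
      gaps <- runif(len) < 0.08
      mk$width[gaps] <- 0; mk$height[gaps] <- 0
      mk
    })
    tab <- do.call(as_raw_tracks, tracks)
    cfg <- bt_default_config(
      px_per_um = 1, fps = 30, frame_width = 640L, frame_height = 480L,
      avg_bacterial_area_px2 = 100, min_track_time_s = 2,
      max_consecutive_gaps = 5L, max_gap_fraction = 0.3,
      size_percentile = 10, edge_margin_frac = 0.05)
    sel <- select_tracks(tab, cfg)
    expect_equal(sel$report$tracks_in,
                 sel$report$tracks_accepted + sum(sel$report$exclusions))
    expect_lte(length(sel$tracks), n)  # at most one segment per origin id
    expect_equal(anyDuplicated(vapply(sel$tracks, function(s)
      s$track_id[1], 0)), 0)
  }
})

test_that("no accepted track violates any enabled criterion", {
  fx <- clean_fixture()
  bad <- ledger_fixture()$table
  bad$track_id <- bad$track_id + 100L
  mixed <- rbind(as.data.frame(fx$table), as.data.frame(bad))
  mixed <- mixed[order(mixed$track_id, mixed$time_s), ]
  class(mixed) <- c("bt_raw_tracks", "data.frame")
  cfg <- fx$config
  sel <- select_tracks(mixed, cfg)
  lo <- cfg$coarse_area_lower_frac * cfg$avg_bacterial_area_px2
  hi <- cfg$coarse_area_upper_mult * cfg$avg_bacterial_area_px2
  for (tk in sel$tracks) {
    m <- mean(tk$width * tk$height)
    expect_gte(m, lo); expect_lte(m, hi)
    expect_gte(bactrack:::bt_track_duration(tk), cfg$min_track_time_s)
    st <- bactrack:::bt_track_steps(tk, cfg$fps)
    if (length(st$gap_frames))
      expect_lte(max(st$gap_frames), cfg$max_consecutive_gaps)
    frames <- round(tk$time_s * cfg$fps)
    span <- max(frames) - min(frames) + 1
    expect_lte((span - nrow(tk)) / span, cfg$max_gap_fraction)
    mx <- cfg$edge_margin_frac * cfg$frame_width
    my <- cfg$edge_margin_frac * cfg$frame_height
    expect_gte(mean(tk$x), mx)
    expect_lte(mean(tk$x), cfg$frame_width - 1 - mx)
    expect_gte(mean(tk$y), my)
    expect_lte(mean(tk$y), cfg$frame_height - 1 - my)
  }
})

test_that("disabling a pure-rejection criterion never loses tracks", {
  fx <- ledger_fixture()
  base <- select_tracks(fx$table, fx$config)
  n0 <- length(base$tracks)
  variants <- list(
    min_track_time_s = 0, max_gap_fraction = 1, size_percentile = 0,
    edge_margin_frac = 0, max_track_time_s = 0)
  for (k in names(variants)) {
    cfg <- fx$config
    cfg[[k]] <- variants[[k]]
    expect_gte(length(select_tracks(fx$table, cfg)$tracks), n0)
  }
})
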