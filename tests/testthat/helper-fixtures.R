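# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (flood fill, exhaustive scans, brute-force assignment)
# so they stay independent of the implementation they check.

test_config <- function(...) {
  bt_default_config(frame_width = 320L, frame_height = 240L,
                    min_track_time_s = 1, ...)
}

# Brute-force 8-connected component labelling by flood fill.
oracle_label8 <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Brute-force detections: per 8-connected component, the axis-aligned
# bounding box over white pixels (0-based coordinates), sorted by centre.
oracle_detections <- function(mask) {
  lab <- oracle_label8(mask)
  n <- max(lab)
  if (n == 0)
    return(data.frame(centre_x = numeric(0), centre_y = numeric(0),
                      width = numeric(0), height = numeric(0)))
  rows <- lapply(seq_len(n), function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    x <- w[, 2] - 1; y <- w[, 1] - 1
    data.frame(centre_x = (max(x) + min(x)) / 2,
               centre_y = (max(y) + min(y)) / 2,
               width = max(x) - min(x) + 1, height = max(y) - min(y) + 1)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$centre_y, out$centre_x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force optimal assignment for small matching problems: minimum total
# distance over all injections of predictions into detections.
oracle_min_sum_assignment <- function(px, py, dx, dy, gate = Inf) {
  np <- length(px); nd <- length(dx)
  best <- NULL; best_cost <- Inf
  dets <- seq_len(nd)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(dets)) {
    k <- min(np, nd)
    cost <- 0; ok <- TRUE
    for (i in seq_len(k)) {
      d <- sqrt((px[i] - dx[p[i]])^2 + (py[i] - dy[p[i]])^2)
      if (d > gate) { ok <- FALSE; break }
      cost <- cost + d
    }
    if (ok && cost < best_cost) { best_cost <- cost; best <- p[seq_len(k)] }
  }
  list(assignment = best, cost = best_cost)
}

# Track-table builder: one id, given frame indices and positions; gap rows
# get width = height = 0.
make_track <- function(id, frames, x, y, w = 10, h = 10, fps = 30,
                       angle = 0) {
  n <- length(frames)
  data.frame(track_id = id, time_s = round(frames / fps, 6),
             x = rep_len(x, n), y = rep_len(y, n),
             width = rep_len(w, n), height = rep_len(h, n),
             angle_deg = rep_len(angle, n))
}

as_raw_tracks <- function(...) {
  tab <- do.call(rbind, list(...))
  tab <- tab[order(tab$track_id, tab$time_s), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("bt_raw_tracks", "data.frame")
  tab
}

# Ground truth for well-separated, near-parallel straight swimmers on a
# grid; headings fan out by +/- 4 degrees so tracks are not identical.
straight_truth <- function(n, n_frames, config, speed_um_s = 2,
                           x0_step = 64, y0_step = 104, per_row = 10) {
  step_px <- speed_um_s * config$px_per_um / config$fps
  rows <- lapply(seq_len(n) - 1L, function(i) {
    cx <- 40 + (i %% per_row) * x0_step
    cy <- 48 + (i %/% per_row) * y0_step
    th <- (-4 + 8 * i / max(1, n - 1)) * pi / 180
    k <- seq_len(n_frames) - 1L
    data.frame(frame = k, true_id = i + 1L,
               x = cx + k * step_px * cos(th),
               y = cy + k * step_px * sin(th),
               angle_deg = (th * 180 / pi) %% 360, motile = 1L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$true_id), ]
  rownames(out) <- NULL
  class(out) <- c("bt_ground_truth", "data.frame")
  out
}

# Selection-ledger fixture: ten constructed tracks, each violating exactly
# one selection criterion. The expected exclusion counters are part of the
# fixture (coarse_size fires twice: once below the lower area limit, once
# above the upper one).
ledger_fixture <- function() {
  config <- bt_default_config(
    px_per_um = 1, fps = 30, frame_width = 640L, frame_height = 480L,
    avg_bacterial_area_px2 = 100, min_track_time_s = 2,
    max_track_time_s = 8, drop_short_after_truncation = TRUE,
    max_consecutive_gaps = 5L, max_gap_fraction = 0.2,
    point_area_outlier_mult = 1.5, distance_outlier_enabled = TRUE,
    distance_outlier_auto_disable_frac = 0.5, size_percentile = 10,
    edge_margin_frac = 0.05)
  # (1) mean area 10 < 20: coarse lower limit
  t1 <- make_track(1, 0:90, 320, 100, w = 2, h = 5)
  # (2) mean area 600 > 500: coarse upper limit
  t2 <- make_track(2, 0:90, 320, 380, w = 30, h = 20)
  # (3) 0.97 s < 2 s: initial minimum time
  t3 <- make_track(3, 0:29, 100, 240)
  # (4) passes the initial time check, but scrubbing the trailing gap
  # points leaves 1.67 s: fine minimum time
  t4 <- rbind(make_track(4, 0:50, 160, 240),
              make_track(4, 51:66, 160, 240, w = 0, h = 0))
  # (5) 10 missing frames in a row: split on consecutive gaps; both halves
  # are too short afterwards
  t5 <- make_track(5, c(0:47, 58:105), 480, 240)
  # (6) one 50 px jump above the outer fence: distance-outlier split;
  # both halves too short afterwards
  t6 <- make_track(6, 0:105, c(rep(240, 53), rep(290, 53)), 120)
  # (7) 27 of 91 frames missing (runs of 3): gap fraction
  drop7 <- unlist(lapply(seq(5, 85, 10), function(b) b + 0:2))
  t7 <- make_track(7, setdiff(0:90, drop7), 320, 300)
  # (8) mean area 450, extreme within the candidate size distribution:
  # size percentile
  t8 <- make_track(8, 0:90, 320, 160, w = 30, h = 15)
  # (9) mean position 12 px from the left edge (margin 32 px): edge margin
  t9 <- make_track(9, 0:90, 12, 240)
  # (10) 10 s track with a gap at relative time 8 s: truncation falls
  # short of the limit and drop_short_after_truncation rejects it
  t10 <- make_track(10, c(0:237, 243:300), 320, 240)
  expected <- c(coarse_size = 2L, min_time_initial = 1L,
                min_time_fine = 1L, consecutive_gaps = 1L,
                distance_outlier_split = 1L, gap_fraction = 1L,
                size_percentile = 1L, edge_margin = 1L,
                max_duration_drop = 1L)
  list(table = as_raw_tracks(t1, t2, t3, t4, t5, t6, t7, t8, t9, t10),
       config = config, expected = expected)
}

# A clean fixture: slowly drifting, well-sized, central tracks that violate
# nothing.
clean_fixture <- function(n = 8) {
  config <- bt_default_config(
    px_per_um = 1, fps = 30, frame_width = 640L, frame_height = 480L,
    avg_bacterial_area_px2 = 100, min_track_time_s = 2,
    max_consecutive_gaps = 5L, max_gap_fraction = 0.2,
    size_percentile = 10, edge_margin_frac = 0.05)
  tracks <- lapply(seq_len(n), function(i)
    make_track(i, 0:90, 100 + i * 40 + 0.5 * (0:90), 180 + 10 * i))
  list(table = do.call(as_raw_tracks, tracks), config = config)
}

# Run detection + tracking over a rendered video file, returning the raw
# track table.
track_video_raw <- function(video, config) {
  vid <- avi_open(video)
  on.exit(avi_close(vid))
  tracker <- new_tracker(config)
  state <- new_rolling_state(config)
  for (k in seq_len(vid$n_frames) - 1L) {
    r <- detect_frame(avi_read_frame(vid, k + 1L), k, state, config)
    state <- r$state
    tracker_step(tracker, r$detections, k)
  }
  flush_tracker(tracker)
}

# Match raw tracks to ground truth: fraction of truth positions with a
# track point within `tol` px at the same frame, plus id-consistency.
match_to_truth <- function(raw, truth, config, tol = 2) {
  raw$frame <- round(raw$time_s * config$fps)
  matched <- 0L
  assign_all <- list()
  for (k in unique(truth$frame)) {
    tt <- truth[truth$frame == k, ]
    rr <- raw[raw$frame == k & !(raw$width == 0 & raw$height == 0), ]
    if (!nrow(rr)) next
    for (i in seq_len(nrow(tt))) {
      d <- sqrt((rr$x - tt$x[i])^2 + (rr$y - tt$y[i])^2)
      j <- which.min(d)
      if (d[j] <= tol) {
        matched <- matched + 1L
        assign_all[[length(assign_all) + 1L]] <-
          c(tt$true_id[i], rr$track_id[j])
      }
    }
  }
  pairs <- do.call(rbind, assign_all)
  # id switches: a tracker id matched to more than one true id, or a true
  # id matched by more than one tracker id
  switches <- 0L
  if (!is.null(pairs)) {
    by_tracker <- tapply(pairs[, 1], pairs[, 2],
                         function(v) length(unique(v)))
    by_truth <- tapply(pairs[, 2], pairs[, 1],
                       function(v) length(unique(v)))
    switches <- sum(by_tracker > 1) + sum(by_truth > 1)
  }
  list(frac_matched = matched / nrow(truth), id_switches = switches)
}
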