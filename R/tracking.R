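# Track linking: a constant-velocity finite-impulse-response filter supplies
# filtered positions and next-frame predictions; per frame, detections are
# bound to predictions by greedy least-distance assignment inside a speed
# gate; unmatched tracks coast on their prediction (gap points with width =
# height = 0) and expire after track_expiry_s without a detection.

# Least-squares linear-trend fit of one coordinate over the filter window,
# optionally with one Gaussian residual re-weighting pass (shared weights
# are computed by the caller from the joint x/y residuals).
bt_fir_fit <- function(t, z, w = NULL) {
  n <- length(t)
  if (n == 1) return(c(a = z, b = 0))
  if (is.null(w)) w <- rep(1, n)
  sw <- sum(w)
  tm <- sum(w * t) / sw; zm <- sum(w * z) / sw
  den <- sum(w * (t - tm)^2)
  b <- if (den < 1e-12) 0 else sum(w * (t - tm) * (z - zm)) / den
  c(a = zm - b * tm, b = b)
}

#' Initialise a constant-velocity filter from a first detection
#'
#' @param x,y First measured position (px).
#' @param t Time of the measurement in frame units.
#' @return A `cv_filter_state` list.
#' @export
cv_filter_init <- function(x, y, t = 0) {
  s <- list(win_t = t, win_x = x, win_y = y,
            x = x, y = y, vx = 0, vy = 0,
            pred_x = x, pred_y = y, frames_since = 0L)
  class(s) <- "cv_filter_state"
  s
}

#' One step of the constant-velocity FIR filter
#'
#' With a measurement: the measurement is appended to the window (most
#' recent `filter_window` measurements), position and velocity are
#' re-estimated by the least-squares constant-velocity (linear-trend)
#' smoother over the window, optionally with one Gaussian down-weighting
#' pass of window entries by their residual to the fitted trend; the
#' filtered position is the trend evaluated at `t` and the prediction the
#' trend at `t + 1`. Without a measurement the last prediction becomes the
#' position and the prediction advances by the velocity estimate.
#'
#' The smoother is exact on linear signals: on noiseless constant-velocity
#' input both filtered positions and predictions reproduce the true line.
#'
#' @param state A `cv_filter_state`.
#' @param measurement `c(x, y)` in px, or `NULL` for a missed frame.
#' @param t Time of this frame in frame units.
#' @param window Window length (number of measurements retained).
#' @param reweight Logical; apply the Gaussian re-weighting pass.
#' @return List with `position` (filtered, this frame), `prediction` (next
#'   frame), `velocity` (px/frame), and the updated `state`.
#' @export
cv_filter_step <- function(state, measurement, t, window = 5,
                           reweight = TRUE) {
  if (is.null(measurement)) {
    state$x <- state$pred_x; state$y <- state$pred_y
    state$pred_x <- state$pred_x + state$vx
    state$pred_y <- state$pred_y + state$vy
    state$frames_since <- state$frames_since + 1L
  } else {
    state$win_t <- c(state$win_t, t)
    state$win_x <- c(state$win_x, measurement[1])
    state$win_y <- c(state$win_y, measurement[2])
    if (length(state$win_t) > window) {
      keep <- seq.int(length(state$win_t) - window + 1, length(state$win_t))
      state$win_t <- state$win_t[keep]
      state$win_x <- state$win_x[keep]
      state$win_y <- state$win_y[keep]
    }
    tt <- state$win_t
    fx <- bt_fir_fit(tt, state$win_x)
    fy <- bt_fir_fit(tt, state$win_y)
    if (reweight && length(tt) >= 3) {
      rx <- state$win_x - (fx[1] + fx[2] * tt)
      ry <- state$win_y - (fy[1] + fy[2] * tt)
      r <- sqrt(rx^2 + ry^2)
      s <- 1.4826 * stats::median(r)
      if (s > 1e-9) {
        w <- exp(-0.5 * (r / s)^2)
        fx <- bt_fir_fit(tt, state$win_x, w)
        fy <- bt_fir_fit(tt, state$win_y, w)
      }
    }
    fx <- unname(fx); fy <- unname(fy)
    state$x <- fx[1] + fx[2] * t
    state$y <- fy[1] + fy[2] * t
    state$vx <- fx[2]; state$vy <- fy[2]
    state$pred_x <- fx[1] + fx[2] * (t + 1)
    state$pred_y <- fy[1] + fy[2] * (t + 1)
    state$frames_since <- 0L
  }
  list(position = c(state$x, state$y),
       prediction = c(state$pred_x, state$pred_y),
       velocity = c(state$vx, state$vy), state = state)
}

#' Greedy least-distance assignment of detections to predictions
#'
#' Repeatedly binds the (prediction, detection) pair with the smallest
#' Euclidean distance, removing both, until the lists are exhausted or the
#' smallest remaining distance exceeds the gating radius. Ties break by
#' prediction order then detection order, so the assignment is
#' deterministic.
#'
#' @param predictions data.frame with columns `id`, `x`, `y`, and optionally
#'   `gate` (per-id gating radius in px; defaults to the speed gate implied
#'   by `gate_speed_um_s`).
#' @param detections Detection data.frame from [extract_detections()].
#' @param config A `tracker_config`.
#' @return List with `matches` (data.frame `id`, `det` row index),
#'   `unmatched_ids`, `unmatched_dets` (row indices).
#' @export
match_detections <- function(predictions, detections, config) {
  np <- nrow(predictions); nd <- nrow(detections)
  base_gate <- config$gate_speed_um_s * config$px_per_um / config$fps
  if (np == 0 || nd == 0)
    return(list(matches = data.frame(id = integer(0), det = integer(0)),
                unmatched_ids = if (np) predictions$id else integer(0),
                unmatched_dets = seq_len(nd)))
  gate <- if ("gate" %in% names(predictions)) predictions$gate
          else rep(base_gate, np)
  dx <- outer(predictions$x, detections$centre_x, "-")
  dy <- outer(predictions$y, detections$centre_y, "-")
  dist <- sqrt(dx^2 + dy^2)
  ok <- dist <= gate   # gate recycles over rows (per-prediction)
  cand <- which(ok, arr.ind = TRUE)
  res_id <- integer(0); res_det <- integer(0)
  if (nrow(cand)) {
    d <- dist[cand]
    ord <- order(d, cand[, 1], cand[, 2])
    used_p <- logical(np); used_d <- logical(nd)
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_d[j]) next
      used_p[i] <- TRUE; used_d[j] <- TRUE
      res_id <- c(res_id, predictions$id[i]); res_det <- c(res_det, j)
    }
  } else {
    used_p <- logical(np); used_d <- logical(nd)
  }
  list(matches = data.frame(id = res_id, det = res_det),
       unmatched_ids = predictions$id[!used_p],
       unmatched_dets = which(!used_d))
}

#' Create a tracker
#'
#' @param config A `tracker_config`.
#' @return A `bt_tracker` environment holding live and retired tracks.
#' @export
new_tracker <- function(config) {
  tr <- new.env(parent = emptyenv())
  tr$config <- config
  tr$next_id <- 0L
  tr$live <- list()
  tr$done <- list()
  tr$last_frame <- -1L
  tr$expiry_frames <- floor(config$track_expiry_s * config$fps + 1e-9)
  class(tr) <- "bt_tracker"
  tr
}

# Points are kept as a list of per-frame rows c(t, x, y, w, h, angle) and
# assembled once at finalisation; appending to growing vectors instead
# would make long runs quadratic in track length.
bt_track_new <- function(id, det, frame_index, fps) {
  list(id = id,
       filt = cv_filter_init(det$centre_x, det$centre_y, t = frame_index),
       pts = list(c(frame_index, det$centre_x, det$centre_y, det$width,
                    det$height, det$angle_deg)),
       last_angle = det$angle_deg)
}

#' Advance the tracker by one frame
#'
#' Matched tracks get a filter update and a point carrying the detection's
#' rectangle; unmatched tracks get a gap point (width = height = 0, angle
#' carried over, position = prediction); tracks unmatched for longer than
#' `track_expiry_s` are retired with their trailing gap points removed;
#' unmatched detections open fresh, never-reused ids.
#'
#' @param tracker A `bt_tracker`.
#' @param detections Detections for this frame.
#' @param frame_index 0-based frame index; must exceed the previous one.
#' @return The tracker, invisibly.
#' @export
tracker_step <- function(tracker, detections, frame_index) {
  stopifnot(inherits(tracker, "bt_tracker"))
  if (frame_index <= tracker$last_frame)
    stop("frames must be presented in increasing order (got ", frame_index,
         " after ", tracker$last_frame, ")")
  tracker$last_frame <- as.integer(frame_index)
  cfg <- tracker$config
  ids <- names(tracker$live)
  base_gate <- cfg$gate_speed_um_s * cfg$px_per_um / cfg$fps
  preds <- if (length(ids)) {
    data.frame(
      id = as.integer(ids),
      x = vapply(tracker$live, function(tk) tk$filt$pred_x, 0),
      y = vapply(tracker$live, function(tk) tk$filt$pred_y, 0),
      gate = base_gate *
        (vapply(tracker$live, function(tk) tk$filt$frames_since, 0L) + 1))
  } else data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  m <- match_detections(preds, detections, cfg)

  for (r in seq_len(nrow(m$matches))) {
    id <- as.character(m$matches$id[r]); j <- m$matches$det[r]
    tk <- tracker$live[[id]]
    det <- detections[j, ]
    st <- cv_filter_step(tk$filt, c(det$centre_x, det$centre_y),
                         t = frame_index, window = cfg$filter_window,
                         reweight = cfg$filter_reweight)
    tk$filt <- st$state
    tk$pts[[length(tk$pts) + 1L]] <-
      c(frame_index, st$position[1], st$position[2], det$width,
        det$height, det$angle_deg)
    tk$last_angle <- det$angle_deg
    tracker$live[[id]] <- tk
  }
  for (id in as.character(m$unmatched_ids)) {
    tk <- tracker$live[[id]]
    st <- cv_filter_step(tk$filt, NULL, t = frame_index)
    tk$filt <- st$state
    tk$pts[[length(tk$pts) + 1L]] <-
      c(frame_index, st$position[1], st$position[2], 0, 0, tk$last_angle)
    if (tk$filt$frames_since > tracker$expiry_frames) {
      tracker$done[[length(tracker$done) + 1L]] <- bt_track_finalise(tk)
      tracker$live[[id]] <- NULL
    } else tracker$live[[id]] <- tk
  }
  for (j in m$unmatched_dets) {
    id <- tracker$next_id
    tracker$next_id <- id + 1L
    tracker$live[[as.character(id)]] <-
      bt_track_new(id, detections[j, ], frame_index, cfg$fps)
  }
  invisible(tracker)
}

# Trailing gap points beyond the last real detection are pure extrapolation
# and are dropped when a track is finalised.
bt_track_finalise <- function(tk) {
  m <- do.call(rbind, tk$pts)
  real <- which(!(m[, 4] == 0 & m[, 5] == 0))
  last <- if (length(real)) max(real) else 0L
  m <- m[seq_len(last), , drop = FALSE]
  data.frame(track_id = tk$id, frame = m[, 1], x = m[, 2], y = m[, 3],
             width = m[, 4], height = m[, 5], angle_deg = m[, 6])
}

#' Finish tracking and emit the raw track table
#'
#' Retires all live tracks, drops trailing gap points, sorts by id then
#' time, and optionally writes the table as a CSV with header
#' `track_id,time_s,x,y,width,height,angle_deg`.
#'
#' @param tracker A `bt_tracker`.
#' @param out_path Optional CSV path.
#' @return A `bt_raw_tracks` data.frame.
#' @export
flush_tracker <- function(tracker, out_path = NULL) {
  stopifnot(inherits(tracker, "bt_tracker"))
  parts <- c(tracker$done, lapply(tracker$live, bt_track_finalise))
  tracker$live <- list()
  tab <- if (length(parts)) do.call(rbind, parts)
         else data.frame(track_id = integer(0), frame = integer(0),
                         x = numeric(0), y = numeric(0), width = numeric(0),
                         height = numeric(0), angle_deg = numeric(0))
  tab$time_s <- round(tab$frame / tracker$config$fps, 6)
  tab <- tab[order(tab$track_id, tab$time_s),
             c("track_id", "time_s", "x", "y", "width", "height",
               "angle_deg")]
  tab$x <- round(tab$x, 4); tab$y <- round(tab$y, 4)
  tab$width <- round(tab$width, 4); tab$height <- round(tab$height, 4)
  tab$angle_deg <- round(tab$angle_deg, 4)
  rownames(tab) <- NULL
  class(tab) <- c("bt_raw_tracks", "data.frame")
  if (!is.null(out_path)) write_tracks_csv(tab, out_path)
  tab
}

#' Write / read a track table CSV
#'
#' Comma separator, "." decimal, UNIX newlines, header
#' `track_id,time_s,x,y,width,height,angle_deg`; rows sorted by id then
#' time. Reading a written file reproduces the in-memory table exactly.
#'
#' @param tracks A track table data.frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `bt_raw_tracks` data.frame (reader).
#' @export
write_tracks_csv <- function(tracks, path) {
  ok <- tryCatch({
    utils::write.csv(as.data.frame(tracks), path, row.names = FALSE,
                     quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write track CSV: ", path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("track_id", "time_s", "x", "y", "width", "height", "angle_deg")
  if (!all(need %in% names(df)))
    stop("not a track table CSV (missing columns): ", path)
  class(df) <- c("bt_raw_tracks", "data.frame")
  df
}
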