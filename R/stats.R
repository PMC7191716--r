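# Per-track motility statistics: total travelled distance, mean speed,
# duration, maximum displacement, percentage of time motile, turn points
# per second, and arc-chord ratio.
#
# Statistics use the points as stored (filtered positions); steps across
# gaps use their actual time difference and count toward distance and
# speed, but are excluded from turn-point detection since heading across a
# gap is unreliable.

bt_step_geometry <- function(track, config) {
  dx <- diff(track$x); dy <- diff(track$y)
  dt <- diff(track$time_s)
  dist_px <- sqrt(dx^2 + dy^2)
  adjacent <- round(dt * config$fps) == 1
  list(dx = dx, dy = dy, dt = dt, dist_px = dist_px, adjacent = adjacent)
}

#' Percentage of time a bacterium was motile
#'
#' Fraction of inter-point steps whose instantaneous speed (step length
#' over step time, in micrometres per second) reaches
#' `motile_speed_threshold_um_s`, times 100.
#'
#' @param track Per-id data.frame with at least 2 points.
#' @param config A `tracker_config`.
#' @return A percentage in `[0, 100]`.
#' @export
percent_motile <- function(track, config) {
  stopifnot(nrow(track) >= 2)
  g <- bt_step_geometry(track, config)
  speeds <- (g$dist_px / config$px_per_um) / g$dt
  100 * mean(speeds >= config$motile_speed_threshold_um_s)
}

#' Turn points per second
#'
#' A turn point is an interior point where the absolute heading change
#' between the incoming and outgoing displacement vectors exceeds
#' `turn_angle_threshold_deg`, both displacements span adjacent frames (no
#' gap on either side), and both exceed the `turn_min_step_px` noise floor.
#' The result is the number of such points divided by the track duration.
#' Note this is a point count, not an event count: a sharp reorientation
#' spread over a few filtered points can contribute more than one turn
#' point, while reorientations below the angle threshold contribute none.
#'
#' @param track Per-id data.frame with at least 3 points.
#' @param config A `tracker_config`.
#' @return Turn points divided by track duration (1/s).
#' @export
turn_points_per_second <- function(track, config) {
  if (nrow(track) < 3) stop("turn-point detection needs at least 3 points")
  g <- bt_step_geometry(track, config)
  n <- length(g$dx)
  i <- seq_len(n - 1)          # incoming step i, outgoing step i + 1
  dot <- g$dx[i] * g$dx[i + 1] + g$dy[i] * g$dy[i + 1]
  cross <- g$dx[i] * g$dy[i + 1] - g$dy[i] * g$dx[i + 1]
  dang <- abs(atan2(cross, dot)) * 180 / pi
  qual <- g$adjacent[i] & g$adjacent[i + 1] &
    g$dist_px[i] >= config$turn_min_step_px &
    g$dist_px[i + 1] >= config$turn_min_step_px &
    dang > config$turn_angle_threshold_deg
  sum(qual) / bt_track_duration(track)
}

#' Compute the seven motility parameters for one track
#'
#' Total travelled distance (um), mean speed (um/s, total distance over
#' duration), duration (s), maximum distance between tracked positions
#' (um), percentage of time motile, turn points per second, and arc-chord
#' ratio (total path over the straight line from first to last point; `NaN`
#' for a closed track with zero chord).
#'
#' @param track Per-id data.frame with at least 2 points.
#' @param config A `tracker_config`.
#' @return A one-row data.frame (class `bt_track_stats`).
#' @export
compute_track_stats <- function(track, config) {
  if (nrow(track) < 2) stop("track statistics need at least 2 points")
  g <- bt_step_geometry(track, config)
  ppu <- config$px_per_um
  total_um <- sum(g$dist_px) / ppu
  duration <- bt_track_duration(track)
  # max pairwise distance: exact via the convex hull (antipodal pairs)
  hull <- grDevices::chull(track$x, track$y)
  hx <- track$x[hull]; hy <- track$y[hull]
  maxd_px <- if (length(hull) == 1) 0 else
    max(stats::dist(cbind(hx, hy)))
  n <- nrow(track)
  chord_px <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  arc_chord <- if (chord_px < 1e-12) NaN else sum(g$dist_px) / chord_px
  out <- data.frame(
    track_id = track$track_id[1],
    total_distance_um = total_um,
    mean_speed_um_s = total_um / duration,
    duration_s = duration,
    max_displacement_um = maxd_px / ppu,
    percent_motile = percent_motile(track, config),
    turn_points_per_s = if (n >= 3) turn_points_per_second(track, config)
                        else 0,
    arc_chord_ratio = arc_chord)
  class(out) <- c("bt_track_stats", "data.frame")
  out
}

#' Statistics table over accepted tracks
#'
#' @param tracks List of accepted per-id data.frames (from
#'   [select_tracks()]) or a `bt_selection`.
#' @param config A `tracker_config`.
#' @return A `bt_track_stats` data.frame, one row per track.
#' @export
compute_stats_table <- function(tracks, config) {
  if (inherits(tracks, "bt_selection")) tracks <- tracks$tracks
  rows <- lapply(tracks, compute_track_stats, config = config)
  out <- if (length(rows)) do.call(rbind, rows)
         else compute_track_stats(
           data.frame(track_id = 0L, time_s = c(0, 1), x = c(0, 1),
                      y = 0, width = 1, height = 1, angle_deg = 0),
           config)[0, ]
  rownames(out) <- NULL
  class(out) <- c("bt_track_stats", "data.frame")
  out
}

#' Write the statistics CSV
#'
#' One row per accepted track: `track_id` plus the seven motility
#' parameters in micrometre/second units.
#'
#' @param stats A `bt_track_stats` data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  df <- as.data.frame(stats)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "track_id"
  df[num] <- lapply(df[num], round, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
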