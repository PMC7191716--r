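# Track selection: coarse whole-track exclusion, point scrubbing, splitting
# on gap runs and distance outliers (each segment re-examined from the
# coarse stage), fine per-criterion checks, longest-part selection and
# maximum-duration truncation, with per-criterion exclusion counts.
#
# A track enters as the raw tracker output for one id. Terminal rejection of
# an original id is attributed once, to the reason of its longest terminal
# candidate segment; a candidate produced by a split that then fails the
# minimum-time check (or has < 2 points) inherits the split cause, since the
# split destroyed its viability.

bt_report_keys <- c("coarse_size", "min_time_initial", "min_time_fine",
                    "consecutive_gaps", "distance_outlier_split",
                    "gap_fraction", "size_percentile", "edge_margin",
                    "max_duration_drop")

bt_new_report <- function() {
  rep <- list(tracks_in = 0L, tracks_accepted = 0L, split_events = 0L,
              distance_outlier_auto_disabled = FALSE,
              exclusions = stats::setNames(integer(length(bt_report_keys)),
                                           bt_report_keys))
  class(rep) <- "bt_filter_report"
  rep
}

#' @export
print.bt_filter_report <- function(x, ...) {
  cat("<bt_filter_report>\n")
  cat(sprintf("  tracks in: %d, accepted: %d, split events: %d\n",
              x$tracks_in, x$tracks_accepted, x$split_events))
  if (x$distance_outlier_auto_disabled)
    cat("  distance-outlier splitting auto-disabled\n")
  ex <- x$exclusions[x$exclusions > 0]
  if (length(ex))
    for (k in names(ex)) cat(sprintf("  excluded by %s: %d\n", k, ex[k]))
  invisible(x)
}

bt_track_area <- function(track) track$width * track$height
bt_track_duration <- function(track)
  if (nrow(track) < 2) 0 else max(track$time_s) - min(track$time_s)

#' Coarse whole-track exclusion
#'
#' Drops tracks whose mean bounding-rectangle area — gap points included at
#' area zero, so a short detection burst followed by coasting averages close
#' to zero — lies below `coarse_area_lower_frac` or above
#' `coarse_area_upper_mult` times the expected cell area, and tracks shorter
#' than `min_track_time_s`.
#'
#' @param table A `bt_raw_tracks` table, sorted by id then time.
#' @param config A `tracker_config`.
#' @return List with `tracks` (list of per-id data.frames that passed) and
#'   `report` (partial `bt_filter_report`).
#' @export
coarse_select <- function(table, config) {
  bt_check_sorted(table)
  rep <- bt_new_report()
  tracks <- split(as.data.frame(table), table$track_id)
  rep$tracks_in <- length(tracks)
  lo <- config$coarse_area_lower_frac * config$avg_bacterial_area_px2
  hi <- config$coarse_area_upper_mult * config$avg_bacterial_area_px2
  keep <- list()
  for (tk in tracks) {
    m <- mean(bt_track_area(tk))
    if (m < lo || m > hi) {
      rep$exclusions["coarse_size"] <- rep$exclusions["coarse_size"] + 1L
    } else if (config$min_track_time_s > 0 &&
               bt_track_duration(tk) < config$min_track_time_s) {
      rep$exclusions["min_time_initial"] <-
        rep$exclusions["min_time_initial"] + 1L
    } else keep[[length(keep) + 1L]] <- tk
  }
  list(tracks = keep, report = rep)
}

bt_check_sorted <- function(table) {
  if (nrow(table) < 2) return(invisible(TRUE))
  o <- order(table$track_id, table$time_s)
  if (!identical(o, seq_len(nrow(table))))
    stop("track table must be sorted by track_id then time_s")
  if (anyDuplicated(table[c("track_id", "time_s")]))
    stop("duplicate (track_id, time_s) rows in track table")
  invisible(TRUE)
}

#' Scrub erroneous single points from a track
#'
#' Removes every zero-area point (the tracker's gap placeholders at
#' predicted positions) and, when `point_area_outlier_mult` is enabled,
#' points whose area exceeds that multiple of the track's mean non-gap area
#' (overlap events inflate the bounding rectangle). Remaining points keep
#' their original times, so removal creates gaps by timestamp.
#'
#' @param track Per-id data.frame.
#' @param config A `tracker_config`.
#' @return The scrubbed track.
#' @export
scrub_points <- function(track, config) {
  area <- bt_track_area(track)
  keep <- area > 0
  if (config$point_area_outlier_mult > 0 && any(keep)) {
    m <- mean(area[keep])
    keep <- keep & area <= config$point_area_outlier_mult * m
  }
  track[keep, , drop = FALSE]
}

# Per-step distances and the per-step frame gaps of a (scrubbed) track.
bt_track_steps <- function(track, fps) {
  n <- nrow(track)
  if (n < 2) return(list(dist = numeric(0), gap_frames = integer(0)))
  dx <- diff(track$x); dy <- diff(track$y)
  frames <- round(track$time_s * fps)
  list(dist = sqrt(dx^2 + dy^2), gap_frames = as.integer(diff(frames) - 1L))
}

# Tukey outer fence (Q3 + 3 IQR, quartiles by linear interpolation).
bt_outer_fence <- function(d) {
  q <- stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + 3 * (q[2] - q[1])
}

#' Split a track at oversized gap runs and distance outliers
#'
#' Gap runs longer than `max_consecutive_gaps` missing frames cut the track;
#' if distance-outlier splitting is active, steps above the Tukey outer
#' fence (Q3 + 3 IQR) of the track's step-distance distribution cut it too.
#' Every resulting segment is re-examined from the coarse stage by
#' [select_tracks()].
#'
#' @param track Scrubbed per-id data.frame.
#' @param config A `tracker_config`.
#' @param distance_active Logical; distance splitting active (may have been
#'   auto-disabled at table level).
#' @return List with `segments` (list of data.frames) and `cause` (`NULL`
#'   if no split happened, else `"consecutive_gaps"` or
#'   `"distance_outlier_split"`).
#' @export
split_track <- function(track, config, distance_active =
                          config$distance_outlier_enabled) {
  st <- bt_track_steps(track, config$fps)
  if (config$max_consecutive_gaps > 0) {
    cut <- which(st$gap_frames > config$max_consecutive_gaps)
    if (length(cut))
      return(list(segments = bt_cut_at(track, cut),
                  cause = "consecutive_gaps"))
  }
  if (distance_active && length(st$dist) >= 2) {
    fence <- bt_outer_fence(st$dist)
    cut <- which(st$dist > fence)
    if (length(cut))
      return(list(segments = bt_cut_at(track, cut),
                  cause = "distance_outlier_split"))
  }
  list(segments = list(track), cause = NULL)
}

# Cut a track after the rows indexed by `cut` (step i joins rows i, i+1).
bt_cut_at <- function(track, cut) {
  bounds <- c(0L, sort(unique(cut)), nrow(track))
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    rows <- (bounds[i] + 1L):bounds[i + 1L]
    out[[i]] <- track[rows, , drop = FALSE]
  }
  out
}

#' Fine per-segment criterion checks
#'
#' Applies, in order: minimum duration; maximum consecutive-gap run; gap
#' fraction (missing frames over the segment's span at the frame cadence);
#' mean area within the `[p, 100 - p]` percentile band of the candidate
#' size distribution (one-sided optional); mean position at least
#' `edge_margin_frac` of the frame dimension away from every edge. The
#' first failure wins.
#'
#' @param segment Scrubbed, split-stable per-id data.frame.
#' @param size_dist Numeric vector: mean areas of all candidate tracks.
#' @param config A `tracker_config`.
#' @return `"pass"` or the name of the failed criterion.
#' @export
fine_select <- function(segment, size_dist, config) {
  if (config$min_track_time_s > 0 &&
      bt_track_duration(segment) < config$min_track_time_s)
    return("min_time_fine")
  st <- bt_track_steps(segment, config$fps)
  if (config$max_consecutive_gaps > 0 && length(st$gap_frames) &&
      max(st$gap_frames) > config$max_consecutive_gaps)
    return("consecutive_gaps")
  frames <- round(segment$time_s * config$fps)
  span <- max(frames) - min(frames) + 1
  missing <- span - nrow(segment)
  if (missing / span > config$max_gap_fraction) return("gap_fraction")
  if (config$size_percentile > 0 && length(size_dist)) {
    p <- config$size_percentile / 100
    hi <- stats::quantile(size_dist, 1 - p, type = 7, names = FALSE)
    lo <- if (config$size_percentile_two_sided)
      stats::quantile(size_dist, p, type = 7, names = FALSE) else -Inf
    m <- mean(bt_track_area(segment))
    if (m < lo || m > hi) return("size_percentile")
  }
  if (config$edge_margin_frac > 0) {
    mx <- config$edge_margin_frac * config$frame_width
    my <- config$edge_margin_frac * config$frame_height
    cx <- mean(segment$x); cy <- mean(segment$y)
    if (cx < mx || cx > config$frame_width - 1 - mx ||
        cy < my || cy > config$frame_height - 1 - my)
      return("edge_margin")
  }
  "pass"
}

#' Truncate a track to the maximum duration
#'
#' Cuts at the exact relative time or, when a gap sits at that position, at
#' the closest data point below the limit. With
#' `drop_short_after_truncation`, tracks that fall short of the limit after
#' truncation are rejected.
#'
#' @param track Accepted per-id data.frame.
#' @param config A `tracker_config` with `max_track_time_s` set.
#' @return The truncated track, or `NULL` for a rejection.
#' @export
enforce_max_duration <- function(track, config) {
  if (config$max_track_time_s <= 0) return(track)
  rel <- track$time_s - track$time_s[1]
  out <- track[rel <= config$max_track_time_s + 1e-9, , drop = FALSE]
  if (config$drop_short_after_truncation &&
      bt_track_duration(out) < config$max_track_time_s - 1e-9)
    return(NULL)
  out
}

# longest by duration; tie -> more points; tie -> earlier start
bt_pick_longest <- function(cands) {
  dur <- vapply(cands, bt_track_duration, 0)
  np <- vapply(cands, nrow, 0L)
  t0 <- vapply(cands, function(s) s$time_s[1], 0)
  cands[[order(-dur, -np, t0)[1]]]
}

#' Run the full track-selection ledger
#'
#' Orchestrates coarse exclusion, point scrubbing, recursive splitting
#' (each segment re-entering at the coarse stage), fine criterion checks,
#' per-original-id longest-passing-part selection, and maximum-duration
#' enforcement. Exclusion counts satisfy the conservation law
#' `tracks_in = tracks_accepted + sum(exclusions)`.
#'
#' @param table A `bt_raw_tracks` table.
#' @param config A `tracker_config`.
#' @return A `bt_selection` list: `tracks` (accepted per-id data.frames),
#'   `table` (their row-bound `bt_raw_tracks`), `report`
#'   (`bt_filter_report`).
#' @export
select_tracks <- function(table, config) {
  cs <- coarse_select(table, config)
  rep <- cs$report
  scrubbed <- lapply(cs$tracks, scrub_points, config = config)

  # size distribution for the percentile criterion: mean non-gap area per
  # coarse-surviving track, fixed before any splitting
  size_dist <- vapply(scrubbed, function(tk)
    if (nrow(tk)) mean(bt_track_area(tk)) else NA_real_, 0)
  size_dist <- size_dist[!is.na(size_dist)]

  # table-level auto-disable of distance-outlier splitting
  distance_active <- config$distance_outlier_enabled
  if (distance_active) {
    tot <- 0L; out <- 0L
    for (tk in scrubbed) {
      st <- bt_track_steps(tk, config$fps)
      if (length(st$dist) >= 2) {
        fence <- bt_outer_fence(st$dist)
        out <- out + sum(st$dist > fence)
      }
      tot <- tot + length(st$dist)
    }
    if (tot > 0 && out / tot > config$distance_outlier_auto_disable_frac) {
      distance_active <- FALSE
      rep$distance_outlier_auto_disabled <- TRUE
    }
  }

  lo <- config$coarse_area_lower_frac * config$avg_bacterial_area_px2
  hi <- config$coarse_area_upper_mult * config$avg_bacterial_area_px2
  accepted <- list()
  for (tk in scrubbed) {
    queue <- list(list(seg = tk, cause = NULL))
    acc <- list(); rejected <- list()
    while (length(queue)) {
      item <- queue[[1]]; queue <- queue[-1]
      seg <- item$seg
      inherit <- function(base) if (!is.null(item$cause)) item$cause else base
      if (nrow(seg) < 2) {
        rejected[[length(rejected) + 1L]] <-
          list(seg = seg, reason = inherit("min_time_fine"))
        next
      }
      m <- mean(bt_track_area(seg))
      if (m < lo || m > hi) {
        rejected[[length(rejected) + 1L]] <-
          list(seg = seg, reason = "coarse_size")
        next
      }
      if (config$min_track_time_s > 0 &&
          bt_track_duration(seg) < config$min_track_time_s) {
        rejected[[length(rejected) + 1L]] <-
          list(seg = seg, reason = inherit("min_time_fine"))
        next
      }
      sp <- split_track(seg, config, distance_active)
      if (!is.null(sp$cause)) {
        rep$split_events <- rep$split_events + 1L
        for (piece in sp$segments)
          queue[[length(queue) + 1L]] <- list(seg = piece, cause = sp$cause)
        next
      }
      verdict <- fine_select(seg, size_dist, config)
      if (identical(verdict, "pass")) acc[[length(acc) + 1L]] <- seg
      else rejected[[length(rejected) + 1L]] <-
        list(seg = seg, reason = verdict)
    }
    if (length(acc)) {
      winner <- bt_pick_longest(acc)
      winner <- enforce_max_duration(winner, config)
      if (is.null(winner)) {
        rep$exclusions["max_duration_drop"] <-
          rep$exclusions["max_duration_drop"] + 1L
      } else {
        rep$tracks_accepted <- rep$tracks_accepted + 1L
        accepted[[length(accepted) + 1L]] <- winner
      }
    } else if (length(rejected)) {
      segs <- lapply(rejected, `[[`, "seg")
      dur <- vapply(segs, bt_track_duration, 0)
      np <- vapply(segs, nrow, 0L)
      t0 <- vapply(segs, function(s)
        if (nrow(s)) s$time_s[1] else Inf, 0)
      why <- rejected[[order(-dur, -np, t0)[1]]]$reason
      rep$exclusions[why] <- rep$exclusions[why] + 1L
    }
  }
  sel_table <- if (length(accepted)) do.call(rbind, accepted)
               else as.data.frame(table)[0, , drop = FALSE]
  rownames(sel_table) <- NULL
  class(sel_table) <- c("bt_raw_tracks", "data.frame")
  out <- list(tracks = accepted, table = sel_table, report = rep)
  class(out) <- "bt_selection"
  out
}

#' @export
print.bt_selection <- function(x, ...) {
  cat("<bt_selection> ", length(x$tracks), " accepted track(s)\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Write the filter report as a CSV
#'
#' Two-column `criterion,count` file, with the summary counts included.
#'
#' @param report A `bt_filter_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- data.frame(
    criterion = c("tracks_in", "tracks_accepted", "split_events",
                  "distance_outlier_auto_disabled",
                  names(report$exclusions)),
    count = c(report$tracks_in, report$tracks_accepted, report$split_events,
              as.integer(report$distance_outlier_auto_disabled),
              unname(report$exclusions)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
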