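# Persistent run artefacts: the annotated overlay video and the three plot
# families (coordinate graph, rose graph, violin plots).

# 3x5 bitmap digit font for ID labels, rows top-down.
bt_digit_font <- list(
  "0" = c(7, 5, 5, 5, 7), "1" = c(2, 6, 2, 2, 7), "2" = c(7, 1, 7, 4, 7),
  "3" = c(7, 1, 7, 1, 7), "4" = c(5, 5, 7, 1, 1), "5" = c(7, 4, 7, 1, 7),
  "6" = c(7, 4, 7, 5, 7), "7" = c(7, 1, 2, 2, 2), "8" = c(7, 5, 7, 5, 7),
  "9" = c(7, 5, 7, 1, 7))

bt_draw_digits <- function(fr, x, y, text, value) {
  h <- nrow(fr); w <- ncol(fr)
  chars <- strsplit(as.character(text), "")[[1]]
  for (ci in seq_along(chars)) {
    glyph <- bt_digit_font[[chars[ci]]]
    if (is.null(glyph)) next
    for (r in 1:5) {
      bits <- glyph[r]
      for (c in 1:3) {
        if (bitwAnd(bits, bitwShiftL(1L, 3L - c)) != 0) {
          px <- round(x) + (ci - 1) * 4 + (c - 1)
          py <- round(y) + (r - 1)
          if (px >= 0 && px < w && py >= 0 && py < h)
            fr[py + 1, px + 1] <- value
        }
      }
    }
  }
  fr
}

bt_draw_line <- function(fr, x0, y0, x1, y1, value) {
  n <- max(abs(x1 - x0), abs(y1 - y0), 1)
  xs <- round(seq(x0, x1, length.out = n + 1))
  ys <- round(seq(y0, y1, length.out = n + 1))
  ok <- xs >= 0 & xs < ncol(fr) & ys >= 0 & ys < nrow(fr)
  fr[cbind(ys[ok] + 1, xs[ok] + 1)] <- value
  fr
}

bt_draw_rect <- function(fr, cx, cy, w, h, angle_deg, value) {
  th <- angle_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  hw <- max(w, 2) / 2; hh <- max(h, 2) / 2
  cx4 <- cx + c(-hw, hw, hw, -hw) * ux - c(-hh, -hh, hh, hh) * uy
  cy4 <- cy + c(-hw, hw, hw, -hw) * uy + c(-hh, -hh, hh, hh) * ux
  for (i in 1:4) {
    j <- i %% 4 + 1
    fr <- bt_draw_line(fr, cx4[i], cy4[i], cx4[j], cy4[j], value)
  }
  fr
}

#' Write the annotated overlay video
#'
#' Re-encodes the input frames with each live track's bounding rectangle,
#' its id label, and a trail of its recent positions (last 2 seconds) drawn
#' on top, as an MJPEG AVI. The output has exactly as many frames as the
#' input.
#'
#' @param frames Source frames: a list of matrices/arrays, or an
#'   `avi_video` handle (streamed).
#' @param tracks A track table (raw or selected) with positions to draw.
#' @param out_path Output AVI path.
#' @param config A `tracker_config`.
#' @param trail_s Trail length in seconds.
#' @return `out_path`, invisibly.
#' @export
write_overlay_video <- function(frames, tracks, out_path, config,
                                trail_s = 2) {
  streamed <- inherits(frames, "avi_video")
  n <- if (streamed) frames$n_frames else length(frames)
  if (n == 0) stop("no frames to annotate")
  get_frame <- function(i) if (streamed) avi_read_frame(frames, i)
                           else frames[[i]]
  f1 <- get_frame(1)
  ink <- if (config$bacteria_brighter_than_background) 255 else 0
  w <- avi_writer(out_path, width = dim(f1)[2], height = dim(f1)[1],
                  fps = config$fps, codec = "MJPG", quality = 0.9)
  tr <- as.data.frame(tracks)
  tr$frame <- round(tr$time_s * config$fps)
  trail_frames <- round(trail_s * config$fps)
  by_frame <- if (nrow(tr)) split(seq_len(nrow(tr)), tr$frame) else list()
  for (k in seq_len(n) - 1L) {
    fr <- get_frame(k + 1L)
    fr <- bt_to_grey(fr)
    rows <- by_frame[[as.character(k)]]
    if (!is.null(rows)) {
      live <- tr[rows, , drop = FALSE]
      recent <- tr[tr$frame <= k & tr$frame > k - trail_frames &
                   tr$track_id %in% live$track_id, , drop = FALSE]
      ok <- recent$x >= 0 & recent$x < ncol(fr) &
            recent$y >= 0 & recent$y < nrow(fr)
      fr[cbind(round(recent$y[ok]) + 1, round(recent$x[ok]) + 1)] <- ink
      for (i in seq_len(nrow(live))) {
        fr <- bt_draw_rect(fr, live$x[i], live$y[i], live$width[i] + 2,
                           live$height[i] + 2, live$angle_deg[i], ink)
        fr <- bt_draw_digits(fr, live$x[i] + live$width[i] / 2 + 3,
                             live$y[i] - live$height[i] / 2 - 6,
                             live$track_id[i], ink)
      }
    }
    avi_write_frame(w, matrix(as.integer(pmin(pmax(round(fr), 0), 255)),
                              nrow = nrow(fr)))
  }
  avi_writer_close(w)
  invisible(out_path)
}

bt_distance_colours <- function(dists, palette = "viridis") {
  cols <- grDevices::hcl.colors(256, palette)
  rng <- range(dists)
  idx <- if (diff(rng) < 1e-12) rep(128L, length(dists))
         else as.integer(round(1 + 255 * (dists - rng[1]) / diff(rng)))
  cols[idx]
}

#' Plot tracks as a coordinate or rose graph
#'
#' Coordinate mode draws each track at its native position with a marker at
#' the start; rose mode translates every track so its first point is
#' (0, 0). Tracks are coloured by total travelled distance (viridis,
#' min-max normalised over the plotted set).
#'
#' @param tracks List of per-id data.frames, or a `bt_selection`.
#' @param mode `"coordinate"` or `"rose"`.
#' @param out_path Optional PNG path; `NULL` draws on the active device.
#' @param config A `tracker_config` (calibration for the distance colours).
#' @return Invisibly, the plotted data: per-track coordinates, distances
#'   and assigned colours.
#' @export
plot_tracks <- function(tracks, mode = c("coordinate", "rose"),
                        out_path = NULL, config = bt_default_config()) {
  mode <- match.arg(mode)
  if (inherits(tracks, "bt_selection")) tracks <- tracks$tracks
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  dists <- vapply(tracks, function(tk)
    if (nrow(tk) < 2) 0
    else sum(sqrt(diff(tk$x)^2 + diff(tk$y)^2)) / config$px_per_um, 0)
  cols <- if (length(tracks)) bt_distance_colours(dists) else character(0)
  plotted <- vector("list", length(tracks))
  if (mode == "coordinate") {
    graphics::plot(NA, xlim = c(0, config$frame_width),
                   ylim = c(config$frame_height, 0), asp = 1,
                   xlab = "x (px)", ylab = "y (px)",
                   main = "Tracks (start markers)")
    for (i in seq_along(tracks)) {
      tk <- tracks[[i]]
      graphics::lines(tk$x, tk$y, col = cols[i])
      graphics::points(tk$x[1], tk$y[1], col = cols[i], pch = 16,
                       cex = 0.7)
      plotted[[i]] <- list(x = tk$x, y = tk$y, col = cols[i],
                           distance_um = dists[i])
    }
  } else {
    xs <- lapply(tracks, function(tk) tk$x - tk$x[1])
    ys <- lapply(tracks, function(tk) tk$y - tk$y[1])
    lim <- max(1, unlist(lapply(xs, function(v) max(abs(v)))),
               unlist(lapply(ys, function(v) max(abs(v)))))
    graphics::plot(NA, xlim = c(-lim, lim), ylim = c(lim, -lim), asp = 1,
                   xlab = "x (px)", ylab = "y (px)",
                   main = "Rose graph (tracks from origin)")
    graphics::abline(h = 0, v = 0, col = "grey80")
    for (i in seq_along(tracks)) {
      graphics::lines(xs[[i]], ys[[i]], col = cols[i])
      plotted[[i]] <- list(x = xs[[i]], y = ys[[i]], col = cols[i],
                           distance_um = dists[i])
    }
  }
  invisible(list(mode = mode, tracks = plotted, distances_um = dists,
                 colours = cols))
}

bt_param_labels <- c(
  total_distance_um = "total distance (um)",
  mean_speed_um_s = "speed (um/s)",
  duration_s = "duration (s)",
  max_displacement_um = "max displacement (um)",
  percent_motile = "time motile (%)",
  turn_points_per_s = "turn points (1/s)",
  arc_chord_ratio = "arc-chord ratio")

bt_draw_violin <- function(v, label) {
  v <- v[is.finite(v)]
  graphics::plot(NA, xlim = c(-1, 1),
                 ylim = range(v) + c(-1, 1) * max(1e-6, diff(range(v)) * 0.05),
                 xaxt = "n", xlab = "", ylab = label)
  if (length(unique(v)) > 1) {
    d <- stats::density(v)
    s <- 0.9 * d$y / max(d$y)
    graphics::polygon(c(s, -rev(s)), c(d$x, rev(d$x)),
                      col = "lightsteelblue", border = "grey30")
  } else {
    graphics::segments(-0.45, v[1], 0.45, v[1], col = "grey30", lwd = 2)
  }
  graphics::points(0, stats::median(v), pch = 19)
}

#' Violin plots of the motility statistics
#'
#' One violin per requested parameter over all tracks; axis labels carry
#' units.
#'
#' @param stats A `bt_track_stats` data.frame.
#' @param parameters Character vector of stat columns to plot; defaults to
#'   all seven.
#' @param out_path Optional PNG path.
#' @return Invisibly, the per-parameter value vectors plotted.
#' @export
plot_violin <- function(stats, parameters = names(bt_param_labels),
                        out_path = NULL) {
  if (nrow(stats) == 0) stop("no statistics rows to plot")
  parameters <- match.arg(parameters, names(bt_param_labels),
                          several.ok = TRUE)
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = 260 * length(parameters) + 80,
                   height = 420)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, length(parameters)),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  data <- list()
  for (p in parameters) {
    bt_draw_violin(stats[[p]], bt_param_labels[[p]])
    data[[p]] <- stats[[p]]
  }
  invisible(data)
}
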