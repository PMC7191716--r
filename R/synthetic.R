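# Run-and-tumble trajectory simulation and synthetic video rendering.
#
# The simulator produces the ground truth every downstream module is tested
# against: straight runs at constant speed, tumbles as a Poisson process that
# instantaneously reorients the heading, an optional immotile fraction with
# positional jitter only, and truncation of tracks at the frame boundary.

#' Motion parameters for the run-and-tumble simulator
#'
#' @param n_bacteria Number of simulated cells.
#' @param speed_um_s Run speed in micrometres per second.
#' @param tumble_rate_hz Poisson rate of tumble events per second.
#' @param tumble_angle_dispersion_deg Half-width in degrees of the uniform
#'   reorientation draw at a tumble; 180 gives isotropic tumbles.
#' @param frac_immotile Fraction of cells that only jitter in place.
#' @param body_length_px,body_width_px Ellipse axes of the rendered body.
#' @param duration_s Simulated duration in seconds.
#' @param jitter_px Positional jitter (s.d., px/frame) of immotile cells.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `motion_params` object (named list).
#' @export
motion_params <- function(n_bacteria = 50, speed_um_s = 20,
                          tumble_rate_hz = 0.5,
                          tumble_angle_dispersion_deg = 180,
                          frac_immotile = 0, body_length_px = 4,
                          body_width_px = 2, duration_s = 30,
                          jitter_px = 0.1, seed = 1L) {
  p <- list(n_bacteria = as.integer(n_bacteria), speed_um_s = speed_um_s,
            tumble_rate_hz = tumble_rate_hz,
            tumble_angle_dispersion_deg = tumble_angle_dispersion_deg,
            frac_immotile = frac_immotile,
            body_length_px = body_length_px, body_width_px = body_width_px,
            duration_s = duration_s, jitter_px = jitter_px,
            seed = as.integer(seed))
  stopifnot(p$n_bacteria >= 0, p$speed_um_s >= 0, p$tumble_rate_hz >= 0,
            p$frac_immotile >= 0, p$frac_immotile <= 1,
            p$body_length_px > 0, p$body_width_px > 0, p$duration_s > 0)
  class(p) <- "motion_params"
  p
}

# Run body with a private RNG stream; restores the caller's stream.
bt_with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate run-and-tumble ground-truth trajectories
#'
#' Motile cells move in straight runs at `speed_um_s` (converted to px/frame
#' through the configuration's calibration); tumbles occur per frame with
#' probability `tumble_rate_hz / fps` and instantaneously rotate the heading
#' by a uniform draw from +/- the dispersion half-width. Immotile cells keep
#' a fixed anchor with Gaussian positional jitter. A cell whose centre
#' leaves the frame has its track truncated there; identities are never
#' reused.
#'
#' @param params A `motion_params` object.
#' @param config A `tracker_config` (supplies fps, px_per_um, frame size).
#' @return A `data.frame` (class `bt_ground_truth`) with columns `frame`
#'   (0-based), `true_id`, `x`, `y` (px), `angle_deg` (heading in [0, 360)),
#'   `motile` (0/1).
#' @examples
#' cfg <- bt_default_config()
#' p <- motion_params(n_bacteria = 3, duration_s = 1, seed = 7)
#' truth <- simulate_tracks(p, cfg)
#' head(truth)
#' @export
simulate_tracks <- function(params, config) {
  stopifnot(inherits(params, "motion_params"))
  n_frames <- floor(params$duration_s * config$fps)
  if (n_frames < 2) stop("duration_s * fps must cover at least 2 frames")
  n <- params$n_bacteria
  if (n == 0) {
    out <- data.frame(frame = integer(0), true_id = integer(0),
                      x = numeric(0), y = numeric(0),
                      angle_deg = numeric(0), motile = integer(0))
    class(out) <- c("bt_ground_truth", "data.frame")
    return(out)
  }
  step_px <- params$speed_um_s * config$px_per_um / config$fps
  p_tumble <- min(1, params$tumble_rate_hz / config$fps)
  disp <- params$tumble_angle_dispersion_deg * pi / 180
  w <- config$frame_width; h <- config$frame_height
  margin <- max(params$body_length_px, 4)

  bt_with_seed(params$seed, {
    x <- runif(n, margin, w - 1 - margin)
    y <- runif(n, margin, h - 1 - margin)
    heading <- runif(n, 0, 2 * pi)
    motile <- rep(1L, n)
    n_imm <- round(params$frac_immotile * n)
    if (n_imm > 0) motile[sample.int(n, n_imm)] <- 0L
    ax <- x; ay <- y   # anchors for immotile jitter
    alive <- rep(TRUE, n)
    rows <- vector("list", n_frames)
    for (k in seq_len(n_frames) - 1L) {
      if (k > 0) {
        mm <- alive & motile == 1L
        if (any(mm)) {
          tum <- mm & (runif(n) < p_tumble)
          if (any(tum))
            heading[tum] <- (heading[tum] +
                             runif(sum(tum), -disp, disp)) %% (2 * pi)
          x[mm] <- x[mm] + step_px * cos(heading[mm])
          y[mm] <- y[mm] + step_px * sin(heading[mm])
        }
        im <- alive & motile == 0L
        if (any(im)) {
          x[im] <- ax[im] + rnorm(sum(im), 0, params$jitter_px)
          y[im] <- ay[im] + rnorm(sum(im), 0, params$jitter_px)
        }
        # truncate tracks whose centre leaves the frame; ids never reused
        alive <- alive & x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
      }
      idx <- which(alive)
      rows[[k + 1L]] <- data.frame(
        frame = k, true_id = idx, x = x[idx], y = y[idx],
        angle_deg = (heading[idx] * 180 / pi) %% 360, motile = motile[idx])
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$frame, out$true_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("bt_ground_truth", "data.frame")
    out
  })
}

# Linear indices (into a [h, w] frame matrix) of the pixels inside a
# rotated ellipse with 0-based centre coordinates; top-left origin.
bt_ellipse_idx <- function(h, w, cx, cy, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  r <- ceiling(max(a, b)) + 1
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  nx <- length(xs); ny <- length(ys)
  dx <- matrix(xs - cx, nrow = ny, ncol = nx, byrow = TRUE)
  dy <- matrix(ys - cy, nrow = ny, ncol = nx)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- which((u / a)^2 + (v / b)^2 <= 1)
  ri <- (inside - 1L) %% ny; ci <- (inside - 1L) %/% ny
  (ys[ri + 1L] + 1L) + (xs[ci + 1L]) * h
}

#' Render one ground-truth frame
#'
#' @param truth_k Rows of the ground truth for one frame.
#' @param params A `motion_params` (body geometry).
#' @param config A `tracker_config` (frame geometry, polarity).
#' @param noise_sd Additive Gaussian pixel noise s.d. in grey levels.
#' @return Integer matrix `[frame_height, frame_width]` of grey values.
#' @export
render_frame <- function(truth_k, params, config, noise_sd = 0) {
  bright <- config$bacteria_brighter_than_background
  bg <- if (bright) 60 else 170
  fg <- if (bright) 170 else 60
  fr <- matrix(bg, nrow = config$frame_height, ncol = config$frame_width)
  if (nrow(truth_k)) {
    a <- params$body_length_px / 2
    b <- params$body_width_px / 2
    idx <- lapply(seq_len(nrow(truth_k)), function(i)
      bt_ellipse_idx(nrow(fr), ncol(fr), truth_k$x[i], truth_k$y[i], a, b,
                     truth_k$angle_deg[i]))
    fr[unlist(idx)] <- fg
  }
  if (noise_sd > 0)
    fr <- fr + matrix(rnorm(length(fr), 0, noise_sd), nrow = nrow(fr))
  matrix(as.integer(pmin(pmax(round(fr), 0), 255)), nrow = nrow(fr))
}

#' Render ground truth as a synthetic microscopy video
#'
#' Draws each cell as a filled rotated ellipse (darker or brighter than the
#' background per the configuration polarity), adds Gaussian pixel noise,
#' and writes an AVI plus the ground truth as a CSV beside it.
#'
#' @param truth Ground truth from [simulate_tracks()].
#' @param params The `motion_params` used to simulate it.
#' @param config A `tracker_config`.
#' @param noise_sd Additive Gaussian pixel noise s.d. in grey levels.
#' @param out_path Output AVI path; the ground-truth CSV is written beside
#'   it with suffix `_truth.csv`.
#' @param codec,quality Passed to [avi_writer()].
#' @param noise_seed Seed for the pixel-noise stream.
#' @return List with `video` and `truth_csv` paths.
#' @export
render_video <- function(truth, params, config, noise_sd = 0, out_path,
                         codec = "MJPG", quality = 1, noise_seed = 1L) {
  stopifnot(inherits(truth, "data.frame"))
  n_frames <- if (nrow(truth)) max(truth$frame) + 1L
              else floor(params$duration_s * config$fps)
  w <- avi_writer(out_path, width = config$frame_width,
                  height = config$frame_height, fps = config$fps,
                  codec = codec, quality = quality)
  by_frame <- split(truth, factor(truth$frame, levels = seq_len(n_frames) - 1L))
  bt_with_seed(noise_seed, {
    for (k in seq_len(n_frames))
      avi_write_frame(w, render_frame(by_frame[[k]], params, config,
                                      noise_sd = noise_sd))
  })
  avi_writer_close(w)
  truth_csv <- paste0(tools::file_path_sans_ext(out_path), "_truth.csv")
  write_truth_csv(truth, truth_csv)
  list(video = out_path, truth_csv = truth_csv)
}

#' Write / read the ground-truth CSV
#'
#' Header `frame,true_id,x,y,angle_deg,motile`, comma-separated, "." decimal.
#'
#' @param truth Ground-truth data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_truth_csv <- function(truth, path) {
  df <- as.data.frame(truth)
  df$x <- round(df$x, 4); df$y <- round(df$y, 4)
  df$angle_deg <- round(df$angle_deg, 4)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("bt_ground_truth", "data.frame")
  df
}
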