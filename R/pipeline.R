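# Full per-video pipeline (decode -> detect -> track -> select -> stats ->
# outputs) and the multi-video run plan with one-video-per-worker
# parallelism. Videos are processed independently with no shared mutable
# state, so a parallel run writes byte-identical artefacts to a serial one.

#' Track one video end to end
#'
#' Streams the video frame by frame through detection and tracking, runs
#' the track-selection ledger, computes per-track motility statistics, and
#' writes every artefact enabled by the configuration's output flags next
#' to `outdir`.
#'
#' @param video_path Path to an AVI video (MJPEG or uncompressed 8-bit).
#' @param config A `tracker_config`.
#' @param outdir Output directory (created if missing).
#' @param debug Logical; write per-frame detection-count diagnostics into
#'   the log.
#' @return A `bt_run` object: raw and selected track tables, the filter
#'   report, the statistics table, per-frame detection counts, and the
#'   paths of all written artefacts.
#' @export
track_video <- function(video_path, config, outdir = dirname(video_path),
                        debug = FALSE) {
  t0 <- Sys.time()
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  base <- tools::file_path_sans_ext(basename(video_path))
  log_path <- file.path(outdir, paste0(base, "_log.txt"))
  cat("", file = log_path)   # truncate any previous run's log
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ",
                   sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  vid <- avi_open(video_path)
  on.exit(try(avi_close(vid), silent = TRUE), add = TRUE)
  logf("opened %s: %d frames, %dx%d px, %.3g fps, codec %s",
       basename(video_path), vid$n_frames, vid$width, vid$height,
       vid$fps, vid$codec)
  if (is.finite(vid$fps) && abs(vid$fps - config$fps) > 0.01)
    warning("video reports ", vid$fps, " fps but configuration says ",
            config$fps, " fps; using the configuration")
  tracker <- new_tracker(config)
  state <- new_rolling_state(config)
  det_counts <- integer(vid$n_frames)
  for (k in seq_len(vid$n_frames) - 1L) {
    frame <- avi_read_frame(vid, k + 1L)
    r <- detect_frame(frame, k, state, config)
    state <- r$state
    det_counts[k + 1L] <- nrow(r$detections)
    tracker_step(tracker, r$detections, k)
    if (debug) logf("frame %d: %d detections", k, nrow(r$detections))
  }
  logf("detections per frame: min %d, median %.1f, max %d",
       if (length(det_counts)) min(det_counts) else 0L,
       stats::median(det_counts),
       if (length(det_counts)) max(det_counts) else 0L)
  artifacts <- list(log = log_path)
  raw_path <- NULL
  if (config$save_raw_csv)
    raw_path <- artifacts$raw_csv <- file.path(outdir,
                                               paste0(base, "_raw.csv"))
  raw <- flush_tracker(tracker, raw_path)
  logf("raw tracks: %d ids, %d points", length(unique(raw$track_id)),
       nrow(raw))
  sel <- select_tracks(raw, config)
  logf("selection: %d in, %d accepted, %d split events",
       sel$report$tracks_in, sel$report$tracks_accepted,
       sel$report$split_events)
  ex <- sel$report$exclusions
  for (k in names(ex[ex > 0])) logf("excluded by %s: %d", k, ex[[k]])
  if (config$save_selected_csv) {
    artifacts$selected_csv <- file.path(outdir, paste0(base,
                                                       "_selected.csv"))
    write_tracks_csv(sel$table, artifacts$selected_csv)
    artifacts$report_csv <- file.path(outdir, paste0(base, "_report.csv"))
    write_report_csv(sel$report, artifacts$report_csv)
  }
  stats <- compute_stats_table(sel, config)
  if (config$save_stats_csv) {
    artifacts$stats_csv <- file.path(outdir, paste0(base, "_stats.csv"))
    write_stats_csv(stats, artifacts$stats_csv)
  }
  if (config$save_overlay_video) {
    artifacts$overlay_video <- file.path(outdir,
                                         paste0(base, "_overlay.avi"))
    ov <- avi_open(video_path)
    write_overlay_video(ov, raw, artifacts$overlay_video, config)
    avi_close(ov)
  }
  if (config$save_coordinate_plot && length(sel$tracks)) {
    artifacts$coordinate_plot <- file.path(outdir,
                                           paste0(base, "_tracks.png"))
    plot_tracks(sel, "coordinate", artifacts$coordinate_plot, config)
  }
  if (config$save_rose_plot && length(sel$tracks)) {
    artifacts$rose_plot <- file.path(outdir, paste0(base, "_rose.png"))
    plot_tracks(sel, "rose", artifacts$rose_plot, config)
  }
  if (config$save_violin_plot && nrow(stats)) {
    artifacts$violin_plot <- file.path(outdir, paste0(base, "_violin.png"))
    plot_violin(stats, out_path = artifacts$violin_plot)
  }
  logf("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  run <- list(video = video_path, n_frames = vid$n_frames,
              detections_per_frame = det_counts, raw = raw,
              selection = sel, stats = stats, artifacts = artifacts)
  class(run) <- "bt_run"
  run
}

#' @export
print.bt_run <- function(x, ...) {
  cat(sprintf("<bt_run> %s: %d frames, %d raw track(s), %d accepted\n",
              basename(x$video), x$n_frames,
              length(unique(x$raw$track_id)),
              length(x$selection$tracks)))
  invisible(x)
}

#' @export
summary.bt_run <- function(object, ...) {
  print(object)
  print(object$selection$report)
  if (nrow(object$stats)) {
    cat("statistics over accepted tracks (means):\n")
    m <- colMeans(object$stats[setdiff(names(object$stats), "track_id")],
                  na.rm = TRUE)
    for (k in names(m)) cat(sprintf("  %s: %.4g\n", k, m[k]))
  }
  invisible(object)
}

#' Build a run plan
#'
#' Resolves the videos to process (paths given directly take precedence
#' over `video_paths` in the configuration) and the worker count.
#'
#' @param paths Character vector of video paths (may be empty).
#' @param config A `tracker_config`.
#' @param outdir Output directory.
#' @param workers Number of parallel workers (one video per worker).
#' @param debug Passed to [track_video()].
#' @return A `bt_run_plan`.
#' @export
build_plan <- function(paths = character(0), config, outdir = ".",
                       workers = 1L, debug = FALSE) {
  videos <- if (length(paths)) paths else config$video_paths
  if (!length(videos))
    stop("no input videos: give paths directly or set video_paths in the ",
         "configuration file")
  missing <- videos[!file.exists(videos)]
  if (length(missing))
    warning("video file(s) not found (will fail individually): ",
            paste(missing, collapse = ", "))
  plan <- list(videos = videos, config = config, outdir = outdir,
               workers = as.integer(workers), debug = isTRUE(debug))
  class(plan) <- "bt_run_plan"
  plan
}

#' Process every video in a plan
#'
#' Each video runs through the full pipeline independently; failures are
#' isolated per video and reported in the result instead of aborting the
#' run. With `workers > 1`, videos are distributed over forked workers
#' (one video per worker); since videos share no state, the persisted
#' artefacts are byte-identical to a serial run.
#'
#' @param plan A `bt_run_plan` from [build_plan()].
#' @return A list, in plan order: each element a `bt_run` or a
#'   `bt_run_error` (fields `video`, `error`).
#' @export
process_videos <- function(plan) {
  stopifnot(inherits(plan, "bt_run_plan"))
  one <- function(v) {
    tryCatch(track_video(v, plan$config, plan$outdir, plan$debug),
             error = function(e) {
               err <- list(video = v, error = conditionMessage(e))
               class(err) <- "bt_run_error"
               err
             })
  }
  if (plan$workers > 1 && length(plan$videos) > 1 &&
      .Platform$OS.type == "unix") {
    parallel::mclapply(plan$videos, one, mc.cores = plan$workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(plan$videos, one)
  }
}

#' @export
print.bt_run_error <- function(x, ...) {
  cat("<bt_run_error>", basename(x$video), "-", x$error, "\n")
  invisible(x)
}
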