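# Registry of every tracking.ini key: section, type, default, and the comment
# written above it in a generated file. Order here is file order; the [basic]
# section comes first so the essential calibration values are easy to find.
bt_field_registry <- function(rod_shaped = TRUE) {
  f <- function(section, name, type, default, comment) {
    list(section = section, name = name, type = type, default = default,
         comment = comment)
  }
  list(
    f("basic", "px_per_um", "num", 2.0,
      "calibration: pixels per micrometre of the recording"),
    f("basic", "fps", "num", 30,
      "frames per second of the recording"),
    f("basic", "frame_width", "int", 640L, "frame width in pixels"),
    f("basic", "frame_height", "int", 480L, "frame height in pixels"),
    f("basic", "bacteria_brighter_than_background", "bool", FALSE,
      "true for darkfield-like videos (bright cells), false for brightfield"),
    f("basic", "rod_shaped", "bool", rod_shaped,
      "true: rod-shaped cells, rotated bounding rectangles; false: coccoid"),
    f("basic", "avg_bacterial_area_px2", "num", if (rod_shaped) 8 else 12,
      "expected bounding-rectangle area of a single cell, px^2"),
    f("detection", "detection_mode", "chr", "marker_gated",
      "one of: marker_gated, adaptive_simple, global_rolling"),
    f("detection", "blur_kernel", "int", 3L,
      "Gaussian blur kernel size (odd, >= 3)"),
    f("detection", "adaptive_kernel", "int", 11L,
      "adaptive threshold Gaussian kernel size (odd, >= 3)"),
    f("detection", "adaptive_offset", "num", 5,
      "grey levels beyond the local mean for the candidate threshold"),
    f("detection", "marker_offset", "num", 10,
      "stricter offset for the marker threshold (>= adaptive_offset)"),
    f("detection", "global_offset", "num", 1.0,
      "global_rolling mode: threshold = mean -/+ global_offset * sd"),
    f("detection", "rolling_window_s", "num", 5,
      "global_rolling mode: moving-average window in seconds"),
    f("tracking", "filter_window", "int", 5L,
      "measurements in the constant-velocity FIR filter window"),
    f("tracking", "filter_reweight", "bool", TRUE,
      "Gaussian residual down-weighting pass in the FIR filter"),
    f("tracking", "gate_speed_um_s", "num", 50,
      "matching gate: top plausible speed in um/s"),
    f("tracking", "track_expiry_s", "num", 1.0,
      "drop a track not re-detected within this many seconds"),
    f("selection", "coarse_area_lower_frac", "num", 0.20,
      "coarse lower size limit as a fraction of avg_bacterial_area_px2"),
    f("selection", "coarse_area_upper_mult", "num", 5.0,
      "coarse upper size limit as a multiple of avg_bacterial_area_px2"),
    f("selection", "min_track_time_s", "num", 5,
      "minimum track duration in seconds (0 = disabled)"),
    f("selection", "max_track_time_s", "num", 0,
      "truncate tracks to this duration in seconds (0 = disabled)"),
    f("selection", "drop_short_after_truncation", "bool", FALSE,
      "reject tracks that fall short of max_track_time_s after truncation"),
    f("selection", "max_consecutive_gaps", "int", 5L,
      "split tracks at runs of more than this many missing frames (0 = off)"),
    f("selection", "max_gap_fraction", "num", 0.2,
      "maximum fraction of missing frames over a track's span"),
    f("selection", "point_area_outlier_mult", "num", 1.5,
      "drop points larger than this multiple of the track mean area (0 = off)"),
    f("selection", "distance_outlier_enabled", "bool", TRUE,
      "split tracks at per-step distances above the Tukey outer fence"),
    f("selection", "distance_outlier_auto_disable_frac", "num", 0.2,
      "disable distance splitting when this fraction of steps are outliers"),
    f("selection", "size_percentile", "num", 10,
      "exclude tracks with mean area outside [p, 100-p] percentiles (0 = off)"),
    f("selection", "size_percentile_two_sided", "bool", TRUE,
      "false: exclude only above the 100-p percentile"),
    f("selection", "edge_margin_frac", "num", 0.05,
      "exclude tracks whose mean position is within this fraction of an edge"),
    f("statistics", "motile_speed_threshold_um_s", "num", 4,
      "instantaneous speed in um/s above which a step counts as motile"),
    f("statistics", "turn_angle_threshold_deg", "num", 30,
      "heading change in degrees above which a point is a turn point"),
    f("statistics", "turn_min_step_px", "num", 0.5,
      "both steps at a turn point must be at least this long, px"),
    f("output", "display_video", "bool", FALSE, "show frames during analysis"),
    f("output", "save_overlay_video", "bool", FALSE,
      "write an annotated MJPEG AVI next to the input"),
    f("output", "save_raw_csv", "bool", TRUE, "write the raw track table"),
    f("output", "save_selected_csv", "bool", TRUE,
      "write the selected track table"),
    f("output", "save_stats_csv", "bool", TRUE,
      "write the per-track statistics table"),
    f("output", "save_coordinate_plot", "bool", FALSE,
      "write the coordinate track plot"),
    f("output", "save_rose_plot", "bool", FALSE, "write the rose track plot"),
    f("output", "save_violin_plot", "bool", FALSE,
      "write the statistics violin plot"),
    f("video", "video_paths", "paths", character(0),
      "comma-separated list of video files to process")
  )
}

bt_basic_fields <- c("px_per_um", "fps", "frame_width", "frame_height",
                     "bacteria_brighter_than_background", "rod_shaped")

#' Default tracker configuration
#'
#' Builds a `tracker_config` object holding every user-settable parameter of
#' the pipeline: calibration, detection thresholds, tracking filter and gate,
#' track-selection limits, statistics thresholds and output flags.
#'
#' @param rod_shaped Logical; rod-shaped cells get rotated bounding
#'   rectangles and a shape-appropriate default expected area, coccoid cells
#'   axis-aligned boxes.
#' @param ... Named overrides for any configuration field.
#' @return A `tracker_config` object (named list).
#' @examples
#' cfg <- bt_default_config(fps = 25, px_per_um = 1.6)
#' cfg$fps
#' @export
bt_default_config <- function(rod_shaped = TRUE, ...) {
  reg <- bt_field_registry(rod_shaped)
  cfg <- stats::setNames(lapply(reg, `[[`, "default"),
                         vapply(reg, `[[`, "", "name"))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg <- bt_coerce_config(cfg)
  class(cfg) <- "tracker_config"
  validate_config(cfg)
  cfg
}

# Coerce registry types after defaults/overrides/parsing.
bt_coerce_config <- function(cfg) {
  reg <- bt_field_registry()
  for (fld in reg) {
    nm <- fld$name
    if (is.null(cfg[[nm]])) next
    v <- cfg[[nm]]
    cfg[[nm]] <- switch(fld$type,
      num = as.numeric(v),
      int = as.integer(v),
      bool = as.logical(v),
      chr = as.character(v),
      paths = as.character(v))
  }
  cfg
}

#' Validate a tracker configuration
#'
#' Checks every invariant of the configuration (positive calibration values,
#' odd kernels, threshold ordering, limits within their ranges) and stops
#' with a message naming each violated field.
#'
#' @param config A `tracker_config` object or named list.
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  c_ <- config
  chk(num1(c_$px_per_um) && c_$px_per_um > 0, "px_per_um: must be > 0")
  chk(num1(c_$fps) && c_$fps > 0, "fps: must be > 0")
  chk(num1(c_$frame_width) && c_$frame_width >= 1,
      "frame_width: must be a positive integer")
  chk(num1(c_$frame_height) && c_$frame_height >= 1,
      "frame_height: must be a positive integer")
  for (k in c("bacteria_brighter_than_background", "rod_shaped",
              "filter_reweight", "distance_outlier_enabled",
              "drop_short_after_truncation", "size_percentile_two_sided"))
    chk(is.logical(c_[[k]]) && length(c_[[k]]) == 1 && !is.na(c_[[k]]),
        paste0(k, ": must be true or false"))
  chk(is.character(c_$detection_mode) &&
      c_$detection_mode %in% c("marker_gated", "adaptive_simple",
                               "global_rolling"),
      "detection_mode: must be marker_gated, adaptive_simple or global_rolling")
  for (k in c("blur_kernel", "adaptive_kernel")) {
    v <- c_[[k]]
    chk(num1(v) && v >= 3 && v %% 2 == 1,
        paste0(k, ": must be an odd integer >= 3"))
  }
  chk(num1(c_$marker_offset) && num1(c_$adaptive_offset) &&
      c_$marker_offset >= c_$adaptive_offset,
      "marker_offset: must be at least adaptive_offset (stricter threshold)")
  chk(num1(c_$rolling_window_s) && c_$rolling_window_s > 0,
      "rolling_window_s: must be > 0")
  chk(num1(c_$filter_window) && c_$filter_window >= 2,
      "filter_window: must be an integer >= 2")
  chk(num1(c_$gate_speed_um_s) && c_$gate_speed_um_s > 0,
      "gate_speed_um_s: must be > 0")
  chk(num1(c_$track_expiry_s) && c_$track_expiry_s > 0,
      "track_expiry_s: must be > 0")
  chk(num1(c_$avg_bacterial_area_px2) && c_$avg_bacterial_area_px2 > 0,
      "avg_bacterial_area_px2: must be > 0")
  chk(num1(c_$coarse_area_lower_frac) && c_$coarse_area_lower_frac > 0 &&
      c_$coarse_area_lower_frac < 1,
      "coarse_area_lower_frac: must be in (0, 1)")
  chk(num1(c_$coarse_area_upper_mult) && c_$coarse_area_upper_mult > 1,
      "coarse_area_upper_mult: must be > 1")
  if (num1(c_$coarse_area_lower_frac) && num1(c_$coarse_area_upper_mult))
    chk(c_$coarse_area_lower_frac < c_$coarse_area_upper_mult,
        "coarse_area_lower_frac: lower area bound must be below upper bound")
  chk(num1(c_$min_track_time_s) && c_$min_track_time_s >= 0,
      "min_track_time_s: must be >= 0")
  chk(num1(c_$max_track_time_s) && c_$max_track_time_s >= 0,
      "max_track_time_s: must be >= 0")
  chk(num1(c_$max_consecutive_gaps) && c_$max_consecutive_gaps >= 0,
      "max_consecutive_gaps: must be >= 0")
  chk(num1(c_$max_gap_fraction) && c_$max_gap_fraction >= 0 &&
      c_$max_gap_fraction <= 1, "max_gap_fraction: must be in [0, 1]")
  chk(num1(c_$point_area_outlier_mult) &&
      (c_$point_area_outlier_mult == 0 || c_$point_area_outlier_mult > 1),
      "point_area_outlier_mult: must be > 1, or 0 to disable")
  chk(num1(c_$distance_outlier_auto_disable_frac) &&
      c_$distance_outlier_auto_disable_frac > 0 &&
      c_$distance_outlier_auto_disable_frac <= 1,
      "distance_outlier_auto_disable_frac: must be in (0, 1]")
  chk(num1(c_$size_percentile) && c_$size_percentile >= 0 &&
      c_$size_percentile <= 50,
      "size_percentile: must be in (0, 50], or 0 to disable")
  chk(num1(c_$edge_margin_frac) && c_$edge_margin_frac >= 0 &&
      c_$edge_margin_frac < 0.5, "edge_margin_frac: must be in [0, 0.5)")
  chk(num1(c_$motile_speed_threshold_um_s) &&
      c_$motile_speed_threshold_um_s > 0,
      "motile_speed_threshold_um_s: must be > 0")
  chk(num1(c_$turn_angle_threshold_deg) && c_$turn_angle_threshold_deg > 0 &&
      c_$turn_angle_threshold_deg < 180,
      "turn_angle_threshold_deg: must be in (0, 180)")
  chk(num1(c_$turn_min_step_px) && c_$turn_min_step_px >= 0,
      "turn_min_step_px: must be >= 0")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(config)
}

#' Write a configuration to a tracking.ini file
#'
#' @param config A `tracker_config` object.
#' @param path File path to write.
#' @param overwrite Logical; overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, overwrite = FALSE) {
  validate_config(config)
  if (file.exists(path) && !overwrite)
    stop("configuration file already exists (use overwrite = TRUE): ", path)
  reg <- bt_field_registry()
  lines <- c("# bactrack settings file (tracking.ini dialect)",
             "# keys are case-insensitive; '#' and ';' start comment lines")
  cur <- ""
  for (fld in reg) {
    if (fld$section != cur) {
      cur <- fld$section
      lines <- c(lines, "", paste0("[", cur, "]"))
    }
    v <- config[[fld$name]]
    vs <- if (is.logical(v)) tolower(as.character(v))
          else if (fld$type == "paths") paste(v, collapse = ", ")
          else as.character(v)
    lines <- c(lines, paste0("# ", fld$comment),
               paste0(fld$name, " = ", vs))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write configuration file: ", path)
  invisible(path)
}

#' Generate a default tracking.ini settings file
#'
#' Writes a fully commented settings file holding the package defaults, with
#' the basic calibration values (pixels per micrometre, frames per second,
#' frame dimensions, brightness polarity, cell shape) in the first section so
#' they are simple to set.
#'
#' @param path File path for the new settings file.
#' @param overwrite Logical; overwrite an existing file.
#' @param rod_shaped Passed to [bt_default_config()].
#' @return `path`, invisibly.
#' @examples
#' p <- file.path(tempdir(), "tracking.ini")
#' generate_default_config(p, overwrite = TRUE)
#' cfg <- load_config(p)
#' cfg$blur_kernel
#' @export
generate_default_config <- function(path, overwrite = FALSE,
                                    rod_shaped = TRUE) {
  write_config(bt_default_config(rod_shaped = rod_shaped), path,
               overwrite = overwrite)
}

# Minimal INI parser for the tracking.ini dialect: '[section]' headers,
# 'key = value' pairs, '#'/';' comment lines, case-insensitive keys.
bt_parse_ini <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^﻿", "", lines)
  out <- list()
  for (ln in lines) {
    s <- trimws(ln)
    if (s == "" || startsWith(s, "#") || startsWith(s, ";")) next
    if (grepl("^\\[.*\\]$", s)) next   # sections are cosmetic
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 0) stop("malformed line in ", path, ": ", ln)
    key <- tolower(trimws(substr(s, 1, eq - 1)))
    val <- trimws(substr(s, eq + 1, nchar(s)))
    out[[key]] <- val
  }
  out
}

bt_parse_value <- function(raw, type, key) {
  switch(type,
    bool = {
      v <- tolower(raw)
      if (!v %in% c("true", "false"))
        stop("configuration error: field '", key,
             "' must be true or false, got '", raw, "'", call. = FALSE)
      v == "true"
    },
    num = {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v))
        stop("configuration error: field '", key,
             "' must be a number, got '", raw, "'", call. = FALSE)
      v
    },
    int = {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v) || v != round(v))
        stop("configuration error: field '", key,
             "' must be an integer, got '", raw, "'", call. = FALSE)
      as.integer(v)
    },
    chr = raw,
    paths = {
      if (raw == "") character(0)
      else trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    })
}

#' Load and validate a tracking.ini settings file
#'
#' Missing non-basic keys fall back to package defaults; missing basic keys
#' (calibration, frame geometry, polarity, shape) are configuration errors.
#' Unknown keys produce a warning and are ignored.
#'
#' @param path Path to an INI-format settings file.
#' @return A validated `tracker_config`.
#' @export
load_config <- function(path) {
  kv <- bt_parse_ini(path)
  reg <- bt_field_registry()
  names(reg) <- vapply(reg, `[[`, "", "name")
  unknown <- setdiff(names(kv), names(reg))
  if (length(unknown))
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  missing_basic <- setdiff(bt_basic_fields, names(kv))
  if (length(missing_basic))
    stop("configuration error: missing required basic field(s): ",
         paste(missing_basic, collapse = ", "), call. = FALSE)
  cfg <- stats::setNames(lapply(reg, `[[`, "default"), names(reg))
  for (key in intersect(names(kv), names(reg)))
    cfg[[key]] <- bt_parse_value(kv[[key]], reg[[key]]$type, key)
  class(cfg) <- "tracker_config"
  validate_config(cfg)
  cfg
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("<tracker_config>\n")
  cat(sprintf("  calibration: %.4g px/um, %.4g fps, %d x %d px\n",
              x$px_per_um, x$fps, x$frame_width, x$frame_height))
  cat(sprintf("  cells: %s, %s than background, ~%.3g px^2\n",
              if (x$rod_shaped) "rod-shaped" else "coccoid",
              if (x$bacteria_brighter_than_background) "brighter" else "darker",
              x$avg_bacterial_area_px2))
  cat(sprintf("  detection: %s (blur %d, adaptive %d, offsets %g/%g)\n",
              x$detection_mode, x$blur_kernel, x$adaptive_kernel,
              x$adaptive_offset, x$marker_offset))
  cat(sprintf("  tracking: FIR window %d, gate %g um/s, expiry %g s\n",
              x$filter_window, x$gate_speed_um_s, x$track_expiry_s))
  invisible(x)
}
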