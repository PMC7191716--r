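# Per-frame detection: grey conversion, Gaussian blur, adaptive thresholding
# with marker gating (or the two simpler threshold modes), 8-connected
# component labelling, and bounding-rectangle extraction.
#
# Coordinate convention: origin at the centre of the top-left pixel, x
# rightward, y downward, 0-based frame indices; time = frame_index / fps.

# Luma conversion for colour frames (ITU-R BT.601 weights).
bt_to_grey <- function(frame) {
  if (length(dim(frame)) == 3)
    frame <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] +
             0.114 * frame[, , 3]
  frame
}

# Discrete Gaussian kernel with the conventional size-derived sigma
# (sigma = 0.3 * ((k - 1)/2 - 1) + 0.8), separable, normalised to sum 1.
bt_gaussian_kernel <- function(k) {
  stopifnot(k >= 1, k %% 2 == 1)
  sigma <- 0.3 * ((k - 1) * 0.5 - 1) + 0.8
  c0 <- (k - 1) / 2
  g <- exp(-((0:(k - 1)) - c0)^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

bt_gaussian_kernel_1d <- function(k) {
  g <- bt_gaussian_kernel(k)
  colSums(g)   # the kernel is an outer product of this vector with itself
}

# Separable 2-D convolution with replicate (nearest-edge) borders; exact on
# outer-product kernels and much cheaper than an FFT at these frame sizes.
bt_sepconv <- function(m, g) {
  k <- length(g)
  k2 <- as.integer((k - 1) / 2)
  nr <- nrow(m); nc <- ncol(m)
  # vertical pass: shifted-row accumulation over a replicate-padded matrix
  ap <- m[c(rep.int(1L, k2), seq_len(nr), rep.int(nr, k2)), , drop = FALSE]
  v <- g[1] * ap[seq_len(nr), , drop = FALSE]
  for (j in seq_len(k)[-1])
    v <- v + g[j] * ap[j:(j + nr - 1L), , drop = FALSE]
  # horizontal pass: shifted-column accumulation
  vp <- v[, c(rep.int(1L, k2), seq_len(nc), rep.int(nc, k2)), drop = FALSE]
  out <- g[1] * vp[, seq_len(nc), drop = FALSE]
  for (j in seq_len(k)[-1])
    out <- out + g[j] * vp[, j:(j + nc - 1L), drop = FALSE]
  out
}

#' Convert a frame to blurred grey scale
#'
#' Colour frames are converted to luminance, then a Gaussian blur with a
#' `blur_kernel` x `blur_kernel` kernel is applied and the result rounded
#' back to 8-bit grey values.
#'
#' @param frame Frame matrix (grey) or array (colour), values 0..255.
#' @param config A `tracker_config`.
#' @return Numeric matrix of integer-valued grey levels, same geometry.
#' @export
preprocess_frame <- function(frame, config) {
  d <- dim(frame)
  if (is.null(d) || length(d) < 2 || any(d[1:2] < 1))
    stop("empty or malformed frame")
  if (!(length(d) == 2 || (length(d) == 3 && d[3] %in% c(1, 3))))
    stop("frame must be single- or 3-channel")
  g <- bt_to_grey(frame)
  b <- bt_sepconv(g, bt_gaussian_kernel_1d(config$blur_kernel))
  round(pmin(pmax(b, 0), 255))
}

# Local Gaussian-weighted mean threshold. Bacteria become white (TRUE):
# darker-than-background cells are pixels below (local mean - offset),
# brighter cells pixels above (local mean + offset).
bt_adaptive_mask <- function(img, kernel_size, offset, bright) {
  local_mean <- bt_sepconv(img, bt_gaussian_kernel_1d(kernel_size))
  if (bright) img > local_mean + offset else img < local_mean - offset
}

# 8-connected labelling: EBImage::bwlabel is 4-connective, so labels that
# touch diagonally are merged with a union-find pass.
bt_label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow = nrow(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2 || nc < 2 || max(lab) <= 1) return(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # / diagonal
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  # compact to consecutive labels
  uroot <- sort(unique(root))
  remap <- integer(length(parent)); remap[uroot] <- seq_along(uroot)
  lut <- c(0L, remap[root])
  matrix(lut[lab + 1L], nrow = nr)
}

#' Marker-gated dual adaptive threshold
#'
#' Applies the adaptive Gaussian threshold twice: once with
#' `adaptive_offset` to produce candidate regions, once with the stricter
#' `marker_offset` to produce markers. Only candidate regions containing at
#' least one marker pixel (inside the region's pixel set) are kept.
#'
#' @param img Blurred grey matrix from [preprocess_frame()].
#' @param config A `tracker_config`.
#' @return Integer 0/1 mask matrix.
#' @export
marker_gated_threshold <- function(img, config) {
  lab <- bt_marker_gated_labels(img, config)
  matrix(as.integer(lab > 0L), nrow = nrow(lab))
}

# Labelled marker-gated regions: candidate components (8-connected) that
# contain at least one marker pixel, all other labels zeroed.
bt_marker_gated_labels <- function(img, config) {
  if (length(dim(img)) != 2) stop("marker_gated_threshold needs a grey image")
  bright <- config$bacteria_brighter_than_background
  # both thresholds share the same local Gaussian-weighted mean
  lm <- bt_sepconv(img, bt_gaussian_kernel_1d(config$adaptive_kernel))
  cand <- if (bright) img > lm + config$adaptive_offset
          else img < lm - config$adaptive_offset
  mark <- if (bright) img > lm + config$marker_offset
          else img < lm - config$marker_offset
  lab <- bt_label8(cand)
  keep <- unique(lab[mark & lab > 0L])
  lut <- integer(max(lab, 1L) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  matrix(lut[lab + 1L], nrow = nrow(lab))
}

#' Plain adaptive threshold (no marker gating)
#'
#' @inheritParams marker_gated_threshold
#' @return Integer 0/1 mask matrix.
#' @export
adaptive_simple_threshold <- function(img, config) {
  if (length(dim(img)) != 2) stop("adaptive threshold needs a grey image")
  m <- bt_adaptive_mask(img, config$adaptive_kernel, config$adaptive_offset,
                        config$bacteria_brighter_than_background)
  matrix(as.integer(m), nrow = nrow(m))
}

#' Rolling-threshold state for global_rolling mode
#'
#' Ring buffer of per-frame mean grey value and standard deviation covering
#' `rolling_window_s` seconds.
#'
#' @param config A `tracker_config`.
#' @return A `rolling_threshold_state` object.
#' @export
new_rolling_state <- function(config) {
  s <- list(means = numeric(0), sds = numeric(0),
            max_len = ceiling(config$rolling_window_s * config$fps))
  class(s) <- "rolling_threshold_state"
  s
}

#' Global threshold from a rolling frame-statistics window
#'
#' The per-frame threshold candidate is the frame's mean grey value offset
#' by `global_offset` standard deviations towards the bacteria side; the
#' applied threshold is the moving average of these candidates over the
#' rolling window (the current frame included, so the first frame uses its
#' own statistics alone).
#'
#' @param img Grey image matrix.
#' @param state A `rolling_threshold_state`.
#' @param config A `tracker_config`.
#' @return List with `mask` (integer 0/1 matrix), `threshold`, and the
#'   updated `state`.
#' @export
global_rolling_threshold <- function(img, state, config) {
  if (length(dim(img)) != 2) stop("global threshold needs a grey image")
  bright <- config$bacteria_brighter_than_background
  m <- mean(img); s <- stats::sd(img)
  state$means <- c(state$means, m); state$sds <- c(state$sds, s)
  if (length(state$means) > state$max_len) {
    state$means <- state$means[-1]; state$sds <- state$sds[-1]
  }
  cand <- if (bright) state$means + config$global_offset * state$sds
          else state$means - config$global_offset * state$sds
  thr <- mean(cand)
  mask <- if (bright) img > thr else img < thr
  list(mask = matrix(as.integer(mask), nrow = nrow(mask)),
       threshold = thr, state = state)
}

# Minimum-area rotated rectangle over a point set (rotating calipers on the
# convex hull). Returns c(cx, cy, w, h, angle_deg) with the angle of the
# longer side in [0, 180).
bt_min_area_rect <- function(px, py) {
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  n <- length(hx)
  if (n == 1) return(c(hx, hy, 0, 0, 0))
  if (n == 2) {
    w <- sqrt(diff(hx)^2 + diff(hy)^2)
    ang <- atan2(diff(hy), diff(hx)) * 180 / pi
    return(c(mean(hx), mean(hy), w, 0, ang %% 180))
  }
  best <- NULL; best_area <- Inf
  ex <- c(hx[-1], hx[1]) - hx; ey <- c(hy[-1], hy[1]) - hy
  for (i in seq_len(n)) {
    len <- sqrt(ex[i]^2 + ey[i]^2)
    if (len < 1e-12) next
    ux <- ex[i] / len; uy <- ey[i] / len
    u <- hx * ux + hy * uy
    v <- -hx * uy + hy * ux
    w <- max(u) - min(u); h <- max(v) - min(v)
    if (w * h < best_area - 1e-12) {
      best_area <- w * h
      cu <- (max(u) + min(u)) / 2; cv <- (max(v) + min(v)) / 2
      cx <- cu * ux - cv * uy; cy <- cu * uy + cv * ux
      ang <- atan2(uy, ux) * 180 / pi
      if (h > w) { tmp <- w; w <- h; h <- tmp; ang <- ang + 90 }
      best <- c(cx, cy, w, h, ang %% 180)
    }
  }
  best
}

#' Extract detections from a binary mask
#'
#' One detection per 8-connected white region. Rod-shaped mode fits the
#' minimum-area rotated rectangle of the region (over the pixel corners, so
#' an axis-aligned n x m pixel block reports width n and height m); coccoid
#' mode uses the axis-aligned bounding box with angle 0. The list is ordered
#' by centre y, then centre x.
#'
#' @param mask Binary matrix (white = nonzero).
#' @param frame_index 0-based frame index stored on each detection.
#' @param config A `tracker_config`.
#' @return A data.frame with columns `frame_index`, `centre_x`, `centre_y`,
#'   `width`, `height`, `angle_deg`, `area_px2`.
#' @export
extract_detections <- function(mask, frame_index, config) {
  bt_extract_from_labels(bt_label8(mask), frame_index, config)
}

bt_extract_from_labels <- function(lab, frame_index, config) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(frame_index = integer(0), centre_x = numeric(0),
                      centre_y = numeric(0), width = numeric(0),
                      height = numeric(0), angle_deg = numeric(0),
                      area_px2 = numeric(0)))
  nr <- nrow(lab)
  ys <- (idx - 1L) %% nr          # 0-based pixel centre coordinates
  xs <- (idx - 1L) %/% nr
  groups <- split(seq_along(idx), lab[idx])
  rod <- config$rod_shaped
  m <- vapply(groups, function(g) {
    x <- xs[g]; y <- ys[g]
    if (rod && length(g) > 1) {
      # rectangle over the pixel corner points
      bt_min_area_rect(c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
                       c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
    } else {
      c((max(x) + min(x)) / 2, (max(y) + min(y)) / 2,
        max(x) - min(x) + 1, max(y) - min(y) + 1, 0)
    }
  }, numeric(5))
  out <- data.frame(frame_index = frame_index, centre_x = m[1, ],
                    centre_y = m[2, ], width = m[3, ], height = m[4, ],
                    angle_deg = if (rod) m[5, ] else 0,
                    area_px2 = m[3, ] * m[4, ])
  out <- out[order(out$centre_y, out$centre_x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect bacteria in one video frame
#'
#' Composition of the per-frame detection chain: grey conversion and blur,
#' thresholding per `detection_mode` (`marker_gated`, `adaptive_simple`, or
#' `global_rolling`), then rectangle extraction.
#'
#' @param frame Frame matrix or colour array, values 0..255.
#' @param frame_index 0-based frame index.
#' @param state A `rolling_threshold_state` (used and updated only in
#'   `global_rolling` mode; pass `NULL` otherwise).
#' @param config A `tracker_config`.
#' @return List with `detections` (see [extract_detections()]) and `state`.
#' @export
detect_frame <- function(frame, frame_index, state = NULL, config) {
  img <- preprocess_frame(frame, config)
  lab <- switch(config$detection_mode,
    marker_gated = bt_marker_gated_labels(img, config),
    adaptive_simple = bt_label8(adaptive_simple_threshold(img, config)),
    global_rolling = {
      r <- global_rolling_threshold(img, state, config)
      state <- r$state
      bt_label8(r$mask)
    },
    stop("unknown detection_mode: ", config$detection_mode))
  list(detections = bt_extract_from_labels(lab, frame_index, config),
       state = state)
}
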