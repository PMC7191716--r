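# Minimal AVI (RIFF) container I/O.
#
# Frames are grey-scale matrices [ny, nx] of integers 0..255 (origin at the
# top-left pixel, rows = y downward, columns = x rightward), or ny x nx x 3
# arrays for colour. Two codecs are supported:
#   "MJPG"  - motion JPEG, one baseline JPEG per frame (via the jpeg package)
#   "DIB "  - uncompressed 8-bit palettised device-independent bitmaps
# Both are written with an idx1 index and are self-round-tripping.

bt_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                               endian = "little")
bt_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")
bt_fourcc <- function(s) charToRaw(s)

bt_read_u32 <- function(con) readBin(con, "integer", size = 4,
                                     endian = "little")

# fourcc bytes to string, tolerating NUL padding
bt_fourcc_str <- function(r) {
  r[r == as.raw(0)] <- charToRaw(" ")
  rawToChar(r)
}

#' Open an AVI video for streaming reads
#'
#' Scans the RIFF structure once, records the codec, geometry, frame rate and
#' the byte offset of every video frame chunk, and returns a handle for
#' random access with [avi_read_frame()].
#'
#' @param path Path to an AVI file (MJPEG or uncompressed 8-bit).
#' @return An `avi_video` handle with fields `width`, `height`, `fps`,
#'   `n_frames`, `codec`.
#' @export
avi_open <- function(path) {
  if (!file.exists(path)) stop("video file not found: ", path)
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 12)
  if (length(hdr) < 12 || !identical(rawToChar(hdr[1:4]), "RIFF") ||
      !identical(rawToChar(hdr[9:12]), "AVI "))
    { close(con); stop("not an AVI (RIFF) file: ", path) }
  fps <- NA_real_; width <- NA_integer_; height <- NA_integer_
  codec <- ""; bitcount <- NA_integer_; palette <- NULL
  frames <- list(offset = numeric(0), size = numeric(0))
  file_size <- file.size(path)

  parse_list <- function(end_at) {
    while (seek(con, where = NA) < end_at) {
      pos <- seek(con, where = NA)
      idr <- readBin(con, "raw", 4)
      if (length(idr) < 4) break
      id <- bt_fourcc_str(idr)
      sz <- bt_read_u32(con)
      if (!length(sz)) break
      if (id == "LIST") {
        ltype <- rawToChar(readBin(con, "raw", 4))
        parse_list(pos + 8 + sz)
      } else if (id == "strh") {
        dat <- readBin(con, "raw", sz)
        if (bt_fourcc_str(dat[1:4]) == "vids") {
          codec <<- bt_fourcc_str(dat[5:8])
          scale <- readBin(dat[21:24], "integer", size = 4,
                           endian = "little")
          rate <- readBin(dat[25:28], "integer", size = 4,
                          endian = "little")
          if (scale > 0) fps <<- rate / scale
        }
      } else if (id == "strf" && is.na(width)) {
        dat <- readBin(con, "raw", sz)
        width <<- readBin(dat[5:8], "integer", size = 4, endian = "little")
        height <<- abs(readBin(dat[9:12], "integer", size = 4,
                               endian = "little"))
        bitcount <<- readBin(dat[15:16], "integer", size = 2,
                             endian = "little")
        if (length(dat) >= 40 + 4) palette <<- dat[-(1:40)]
      } else if (grepl("^..(db|dc)$", id)) {
        frames$offset[length(frames$offset) + 1] <<- pos + 8
        frames$size[length(frames$size) + 1] <<- sz
        seek(con, where = pos + 8 + sz + (sz %% 2))
      } else {
        seek(con, where = pos + 8 + sz + (sz %% 2))
      }
      # chunks are word-aligned
      p <- seek(con, where = NA)
      if (p %% 2 == 1) seek(con, where = p + 1)
    }
  }
  parse_list(min(file_size, 8 + readBin(hdr[5:8], "integer", size = 4,
                                        endian = "little")))
  if (codec == "") { close(con); stop("no video stream found in: ", path) }
  codec_norm <- toupper(trimws(codec))
  if (identical(codec_norm, "") || bitcount == 0) codec_norm <- "DIB"
  if (!codec_norm %in% c("MJPG", "DIB"))
    { close(con); stop("unsupported AVI codec '", codec, "' in: ", path) }
  vid <- list(con = con, path = path, width = width, height = height,
              fps = fps, codec = codec_norm, bitcount = bitcount,
              palette = palette, offsets = frames$offset,
              sizes = frames$size, n_frames = length(frames$offset))
  class(vid) <- "avi_video"
  vid
}

#' @export
print.avi_video <- function(x, ...) {
  cat(sprintf("<avi_video> %s: %d frames, %dx%d, %.3g fps, codec %s\n",
              basename(x$path), x$n_frames, x$width, x$height, x$fps,
              x$codec))
  invisible(x)
}

bt_decode_dib <- function(dat, width, height, palette) {
  stride <- (width + 3) %/% 4 * 4
  idx <- as.integer(dat[seq_len(stride * height)])
  m <- matrix(idx, nrow = stride)[seq_len(width), , drop = FALSE]
  # DIB rows are bottom-up; transpose to [ny, nx] top-down
  m <- t(m[, rev(seq_len(height)), drop = FALSE])
  if (!is.null(palette) && length(palette) >= 4) {
    lut <- as.integer(palette[seq(1, length(palette), by = 4)])  # blue plane
    m <- matrix(lut[m + 1L], nrow = height)
  }
  m
}

#' Read one frame from an open AVI
#'
#' @param vid An `avi_video` handle from [avi_open()].
#' @param i Frame index, 1-based.
#' @return An integer matrix `[height, width]` of grey values 0..255, or a
#'   `[height, width, 3]` array for colour MJPEG frames.
#' @export
avi_read_frame <- function(vid, i) {
  stopifnot(inherits(vid, "avi_video"))
  if (i < 1 || i > vid$n_frames)
    stop("frame index out of range: ", i, " of ", vid$n_frames)
  seek(vid$con, where = vid$offsets[i])
  dat <- readBin(vid$con, "raw", vid$sizes[i])
  if (vid$codec == "MJPG") {
    img <- jpeg::readJPEG(dat)
    if (length(dim(img)) == 3) {
      if (dim(img)[3] >= 3) {
        arr <- array(as.integer(round(img[, , 1:3] * 255)),
                     dim = c(dim(img)[1], dim(img)[2], 3))
        return(arr)
      }
      img <- img[, , 1]
    }
    matrix(as.integer(round(img * 255)), nrow = nrow(img))
  } else {
    bt_decode_dib(dat, vid$width, vid$height, vid$palette)
  }
}

#' @export
avi_close <- function(vid) {
  stopifnot(inherits(vid, "avi_video"))
  close(vid$con)
  invisible(NULL)
}

#' Read all frames of an AVI into a list
#'
#' Convenience for small fixtures; large videos should be streamed with
#' [avi_open()] / [avi_read_frame()].
#'
#' @param path Path to an AVI file.
#' @return List with `frames` (list of matrices/arrays), `fps`, `width`,
#'   `height`, `codec`.
#' @export
read_avi <- function(path) {
  vid <- avi_open(path)
  on.exit(avi_close(vid))
  frames <- lapply(seq_len(vid$n_frames), function(i) avi_read_frame(vid, i))
  list(frames = frames, fps = vid$fps, width = vid$width,
       height = vid$height, codec = vid$codec)
}

bt_encode_dib <- function(frame) {
  if (length(dim(frame)) == 3) frame <- bt_to_grey(frame)
  height <- nrow(frame); width <- ncol(frame)
  stride <- (width + 3) %/% 4 * 4
  m <- matrix(0L, nrow = stride, ncol = height)
  # bottom-up rows
  m[seq_len(width), ] <- t(frame[rev(seq_len(height)), , drop = FALSE])
  as.raw(pmin(pmax(as.integer(m), 0L), 255L))
}

bt_encode_mjpg <- function(frame, quality) {
  img <- if (length(dim(frame)) == 3) frame / 255 else frame / 255
  jpeg::writeJPEG(img, raw(), quality = quality)
}

#' Open an AVI file for streaming writes
#'
#' Writes a provisional header immediately; [avi_writer_close()] patches the
#' RIFF sizes, frame count and index once all frames are written.
#'
#' @param path Output file path.
#' @param width,height Frame geometry in pixels.
#' @param fps Frames per second (may be fractional).
#' @param codec `"MJPG"` (motion JPEG) or `"DIB"` (uncompressed 8-bit grey).
#' @param quality JPEG quality in (0, 1], MJPG only.
#' @return An `avi_writer` handle.
#' @export
avi_writer <- function(path, width, height, fps, codec = c("MJPG", "DIB"),
                       quality = 1) {
  codec <- match.arg(codec)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open video for writing: ", path, call. = FALSE))
  w <- new.env(parent = emptyenv())
  w$con <- con; w$path <- path; w$width <- as.integer(width)
  w$height <- as.integer(height); w$fps <- fps; w$codec <- codec
  w$quality <- quality; w$n <- 0L
  w$index <- list(offset = numeric(0), size = numeric(0))
  # header skeleton with placeholder sizes, patched on close
  hdr <- bt_avi_header(w, n_frames = 0L, max_bytes = 0L)
  writeBin(hdr, con)
  w$movi_start <- seek(con, where = NA)
  writeBin(c(bt_fourcc("LIST"), bt_u32(4), bt_fourcc("movi")), con)
  class(w) <- "avi_writer"
  w
}

bt_avi_header <- function(w, n_frames, max_bytes) {
  fourcc_id <- if (w$codec == "MJPG") "MJPG" else "DIB "
  frame_bytes <- if (w$codec == "MJPG") max_bytes
                 else (w$width + 3) %/% 4 * 4 * w$height
  scale <- 1000L; rate <- as.integer(round(w$fps * 1000))
  strh <- c(bt_fourcc("vids"), bt_fourcc(fourcc_id),
            bt_u32(0), bt_u16(0), bt_u16(0), bt_u32(0),
            bt_u32(scale), bt_u32(rate), bt_u32(0), bt_u32(n_frames),
            bt_u32(frame_bytes), bt_u32(-1), bt_u32(0),
            bt_u16(0), bt_u16(0), bt_u16(w$width), bt_u16(w$height))
  if (w$codec == "MJPG") {
    strf <- c(bt_u32(40), bt_u32(w$width), bt_u32(w$height), bt_u16(1),
              bt_u16(24), bt_fourcc("MJPG"), bt_u32(w$width * w$height * 3),
              bt_u32(0), bt_u32(0), bt_u32(0), bt_u32(0))
  } else {
    pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
    strf <- c(bt_u32(40 + 1024), bt_u32(w$width), bt_u32(w$height),
              bt_u16(1), bt_u16(8), bt_u32(0),
              bt_u32((w$width + 3) %/% 4 * 4 * w$height),
              bt_u32(0), bt_u32(0), bt_u32(256), bt_u32(256), pal)
  }
  strl_body <- c(bt_fourcc("strl"),
                 bt_fourcc("strh"), bt_u32(length(strh)), strh,
                 bt_fourcc("strf"), bt_u32(length(strf)), strf)
  avih <- c(bt_u32(round(1e6 / w$fps)), bt_u32(max_bytes * ceiling(w$fps)),
            bt_u32(0), bt_u32(0x10),  # AVIF_HASINDEX
            bt_u32(n_frames), bt_u32(0), bt_u32(1),
            bt_u32(frame_bytes), bt_u32(w$width), bt_u32(w$height),
            bt_u32(0), bt_u32(0), bt_u32(0), bt_u32(0))
  hdrl_body <- c(bt_fourcc("hdrl"),
                 bt_fourcc("avih"), bt_u32(length(avih)), avih,
                 bt_fourcc("LIST"), bt_u32(length(strl_body)), strl_body)
  c(bt_fourcc("RIFF"), bt_u32(0), bt_fourcc("AVI "),
    bt_fourcc("LIST"), bt_u32(length(hdrl_body)), hdrl_body)
}

#' Append one frame to an open AVI writer
#'
#' @param w An `avi_writer` handle.
#' @param frame Integer matrix `[height, width]` (grey 0..255) or
#'   `[height, width, 3]` array.
#' @return The writer, invisibly.
#' @export
avi_write_frame <- function(w, frame) {
  stopifnot(inherits(w, "avi_writer"))
  d <- dim(frame)
  if (d[1] != w$height || d[2] != w$width)
    stop("frame is ", d[1], "x", d[2], ", writer expects ",
         w$height, "x", w$width)
  payload <- if (w$codec == "MJPG") bt_encode_mjpg(frame, w$quality)
             else bt_encode_dib(frame)
  id <- if (w$codec == "MJPG") "00dc" else "00db"
  pos <- seek(w$con, where = NA)
  writeBin(c(bt_fourcc(id), bt_u32(length(payload)), payload), w$con)
  if (length(payload) %% 2 == 1) writeBin(as.raw(0), w$con)
  w$index$offset <- c(w$index$offset, pos - w$movi_start - 8)
  w$index$size <- c(w$index$size, length(payload))
  w$n <- w$n + 1L
  invisible(w)
}

#' Finalise an AVI file
#'
#' Writes the idx1 index and patches the RIFF/list sizes and frame counts.
#'
#' @param w An `avi_writer` handle.
#' @return The output path, invisibly.
#' @export
avi_writer_close <- function(w) {
  stopifnot(inherits(w, "avi_writer"))
  id <- if (w$codec == "MJPG") "00dc" else "00db"
  movi_end <- seek(w$con, where = NA)
  # idx1: one entry per frame, offsets relative to the 'movi' fourcc
  n <- w$n
  idx <- vector("list", n)
  for (i in seq_len(n))
    idx[[i]] <- c(bt_fourcc(id), bt_u32(0x10),
                  bt_u32(w$index$offset[i] + 4), bt_u32(w$index$size[i]))
  idx_raw <- do.call(c, c(idx, list(raw(0))))
  writeBin(c(bt_fourcc("idx1"), bt_u32(length(idx_raw)), idx_raw), w$con)
  riff_end <- seek(w$con, where = NA)
  max_bytes <- if (n) max(w$index$size) else 0
  # patch header with real counts, movi list size, RIFF size
  seek(w$con, where = 0, rw = "write")
  writeBin(bt_avi_header(w, n_frames = n, max_bytes = max_bytes), w$con)
  seek(w$con, where = 4, rw = "write")
  writeBin(bt_u32(riff_end - 8), w$con)
  seek(w$con, where = w$movi_start + 4, rw = "write")
  writeBin(bt_u32(movi_end - w$movi_start - 8 + 4), w$con)
  close(w$con)
  invisible(w$path)
}

#' Write a list of frames as an AVI file
#'
#' @param frames List of frame matrices/arrays.
#' @inheritParams avi_writer
#' @return `path`, invisibly.
#' @export
write_avi <- function(frames, path, fps, codec = c("MJPG", "DIB"),
                      quality = 1) {
  codec <- match.arg(codec)
  stopifnot(length(frames) > 0)
  d <- dim(frames[[1]])
  w <- avi_writer(path, width = d[2], height = d[1], fps = fps,
                  codec = codec, quality = quality)
  for (f in frames) avi_write_frame(w, f)
  avi_writer_close(w)
}
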