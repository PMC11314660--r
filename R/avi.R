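# Minimal RIFF/AVI container support for uncompressed 8-bit grayscale video
# (palettized DIB frames, biCompression = 0). This covers the codec-free
# setting used for round-trip storage of B-mode sequences; compressed AVIs
# are rejected with an explicit error.

u32le <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")
u16le <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
fourcc <- function(con, s) writeBin(charToRaw(s), con)

#' Write a frame sequence as an uncompressed AVI file
#'
#' Stores 8-bit grayscale frames as palettized device-independent bitmaps in
#' a RIFF/AVI container with no compression, readable by [read_avi()] and by
#' standard players.
#'
#' @param seq A [frame_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_avi <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames[[1L]])
  h <- d[1]; w <- d[2]
  stride <- ceiling(w / 4) * 4
  frame_bytes <- stride * h
  n <- length(seq$frames)
  fps <- seq$frame_rate

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  hdrl_size <- 4 + (8 + 56) + (8 + 4 + (8 + 56) + (8 + 40 + 1024))
  movi_size <- 4 + n * (8 + frame_bytes)
  riff_size <- 4 + (8 + hdrl_size) + (8 + movi_size)

  fourcc(con, "RIFF"); u32le(con, riff_size); fourcc(con, "AVI ")

  fourcc(con, "LIST"); u32le(con, hdrl_size); fourcc(con, "hdrl")
  fourcc(con, "avih"); u32le(con, 56)
  u32le(con, round(1e6 / fps))          # dwMicroSecPerFrame
  u32le(con, frame_bytes * ceiling(fps))# dwMaxBytesPerSec
  u32le(con, 0)                         # dwPaddingGranularity
  u32le(con, 0)                         # dwFlags
  u32le(con, n)                         # dwTotalFrames
  u32le(con, 0)                         # dwInitialFrames
  u32le(con, 1)                         # dwStreams
  u32le(con, frame_bytes)               # dwSuggestedBufferSize
  u32le(con, w); u32le(con, h)
  u32le(con, 0); u32le(con, 0); u32le(con, 0); u32le(con, 0)

  strl_size <- 4 + (8 + 56) + (8 + 40 + 1024)
  fourcc(con, "LIST"); u32le(con, strl_size); fourcc(con, "strl")
  fourcc(con, "strh"); u32le(con, 56)
  fourcc(con, "vids"); fourcc(con, "DIB ")
  u32le(con, 0)                         # dwFlags
  u32le(con, 0)                         # wPriority + wLanguage
  u32le(con, 0)                         # dwInitialFrames
  u32le(con, 1000)                      # dwScale
  u32le(con, round(fps * 1000))         # dwRate
  u32le(con, 0)                         # dwStart
  u32le(con, n)                         # dwLength
  u32le(con, frame_bytes)               # dwSuggestedBufferSize
  u32le(con, -1)                        # dwQuality
  u32le(con, 0)                         # dwSampleSize
  u16le(con, c(0, 0, w, h))             # rcFrame

  fourcc(con, "strf"); u32le(con, 40 + 1024)
  u32le(con, 40)                        # biSize
  u32le(con, w); u32le(con, h)
  u16le(con, c(1, 8))                   # biPlanes, biBitCount
  u32le(con, 0)                         # biCompression (BI_RGB)
  u32le(con, frame_bytes)               # biSizeImage
  u32le(con, 0); u32le(con, 0)          # pels per meter
  u32le(con, 256); u32le(con, 0)        # biClrUsed, biClrImportant
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))  # B,G,R,reserved
  writeBin(pal, con)

  fourcc(con, "LIST"); u32le(con, movi_size); fourcc(con, "movi")
  pad <- raw(stride - w)
  for (fr in seq$frames) {
    fourcc(con, "00db"); u32le(con, frame_bytes)
    m <- as.integer(round_half_up(clip8(fr)))
    dim(m) <- d
    # bottom-up rows, each padded to the 4-byte stride
    rows <- m[h:1, , drop = FALSE]
    if (stride > w) {
      buf <- matrix(raw(1), stride, h)
      buf[seq_len(w), ] <- as.raw(t(rows))
      writeBin(as.vector(buf), con)
    } else {
      writeBin(as.raw(as.vector(t(rows))), con)
    }
  }
  invisible(path)
}

avi_u32 <- function(bytes, pos) {
  v <- as.integer(bytes[pos + 0:3])
  v[1] + v[2] * 256 + v[3] * 65536 + v[4] * 16777216
}
avi_id <- function(bytes, pos) rawToChar(bytes[pos + 0:3])

#' Read an uncompressed AVI file into a frame sequence
#'
#' Parses the RIFF container and decodes uncompressed 8-bit DIB frames.
#' Compressed streams or other bit depths raise an error.
#'
#' @param path Path to an AVI file.
#' @return A [frame_sequence()].
#' @export
read_avi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 12 || avi_id(bytes, 1) != "RIFF" ||
      avi_id(bytes, 9) != "AVI ") {
    stop("not an AVI (RIFF) file: ", path, call. = FALSE)
  }
  info <- new.env(parent = emptyenv())
  info$fps <- NA_real_; info$w <- NA_integer_; info$h <- NA_integer_
  info$bits <- NA_integer_; info$comp <- NA_integer_; info$movi <- NULL

  walk <- function(from, to) {
    pos <- from
    while (pos + 8 <= to + 1) {
      id <- avi_id(bytes, pos)
      size <- avi_u32(bytes, pos + 4)
      body <- pos + 8
      if (id == "LIST") {
        ltype <- avi_id(bytes, body)
        if (ltype == "movi") {
          info$movi <- c(body + 4, body + size - 1)
        } else {
          walk(body + 4, body + size - 1)
        }
      } else if (id == "strh") {
        if (avi_id(bytes, body) == "vids") {
          scale <- avi_u32(bytes, body + 20)
          rate <- avi_u32(bytes, body + 24)
          if (scale > 0 && rate > 0) info$fps <- rate / scale
        }
      } else if (id == "strf" && is.na(info$w)) {
        info$w <- avi_u32(bytes, body + 4)
        info$h <- avi_u32(bytes, body + 8)
        info$bits <- as.integer(bytes[body + 14]) +
          256L * as.integer(bytes[body + 15])
        info$comp <- avi_u32(bytes, body + 16)
      } else if (id == "avih" && is.na(info$fps)) {
        mspf <- avi_u32(bytes, body)
        if (mspf > 0) info$fps <- 1e6 / mspf
      }
      pos <- body + size + size %% 2
    }
  }
  walk(13, length(bytes))

  if (is.null(info$movi)) stop("AVI has no movi list", call. = FALSE)
  if (is.na(info$w) || is.na(info$bits)) {
    stop("AVI stream format not found", call. = FALSE)
  }
  if (info$comp != 0 || info$bits != 8) {
    stop("unsupported AVI codec: only uncompressed 8-bit DIB is readable",
         call. = FALSE)
  }
  w <- info$w; h <- info$h
  stride <- ceiling(w / 4) * 4
  frames <- list()
  pos <- info$movi[1]
  while (pos + 8 <= info$movi[2] + 1) {
    id <- avi_id(bytes, pos)
    size <- avi_u32(bytes, pos + 4)
    body <- pos + 8
    if (grepl("^..d[bc]$", id)) {
      if (size < stride * h) stop("truncated AVI frame", call. = FALSE)
      d <- as.integer(bytes[body + seq_len(stride * h) - 1])
      m <- matrix(d, nrow = stride)[seq_len(w), , drop = FALSE]
      img <- t(m)[h:1, , drop = FALSE]
      frames[[length(frames) + 1L]] <- img
    }
    pos <- body + size + size %% 2
  }
  if (length(frames) == 0L) stop("no frames in AVI", call. = FALSE)
  fps <- if (is.na(info$fps)) stop("AVI frame rate missing", call. = FALSE)
         else info$fps
  frame_sequence(frames, fps)
}
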