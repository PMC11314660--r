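#' Read an ultrasound sequence from an AVI file or a frame directory
#'
#' Directories are scanned for PNG/TIFF frames, sorted by file name; color
#' frames are converted to gray with ITU-R BT.601 luma weights. AVI input is
#' decoded by [read_avi()] (uncompressed 8-bit only) and carries its own
#' frame rate; directories require `frame_rate`.
#'
#' @param path AVI file or directory of image frames.
#' @param frame_rate Frames per second; required for directories, ignored
#'   for AVI input.
#' @param t0 Acquisition start time in seconds.
#' @return A [frame_sequence()].
#' @export
read_sequence <- function(path, frame_rate = NULL, t0 = 0) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0L) stop("no frames in directory: ", path,
                                  call. = FALSE)
    if (is.null(frame_rate)) {
      stop("frame_rate is required for frame directories", call. = FALSE)
    }
    frames <- lapply(files, read_gray_image)
    seq <- frame_sequence(frames, frame_rate, t0 = t0)
  } else if (file.exists(path)) {
    if (!grepl("\\.avi$", path, ignore.case = TRUE)) {
      stop("unsupported input: expected an .avi file or a frame directory",
           call. = FALSE)
    }
    seq <- read_avi(path)
    seq$t0 <- t0
  } else {
    stop("path does not exist: ", path, call. = FALSE)
  }
  seq
}

read_gray_image <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required for TIFF frames", call. = FALSE)
    }
    tiff::readTIFF(file)
  }
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    img <- if (ch >= 3) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  round_half_up(img * 255)
}

#' Write a frame sequence as zero-padded 8-bit PNG frames
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default `"frame"`).
#' @return The directory path, invisibly.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    f <- file.path(dir, sprintf("%s_%06d.png", prefix, i - 1L))
    png::writePNG(clip8(seq$frames[[i]]) / 255, f)
  }
  invisible(dir)
}

#' Fuse frames down to the temperature sampling rate
#'
#' Averages non-overlapping blocks of `round(frame_rate / target_rate)`
#' consecutive frames pixelwise, rounding half-up to 8 bits; a trailing
#' partial block is dropped. Fusion aligns the imaging rate with the 1 Hz
#' temperature trace and pre-suppresses speckle.
#'
#' @param seq A [frame_sequence()].
#' @param target_rate Output frame rate in Hz (default 1).
#' @return A [frame_sequence()] at `target_rate`; fused frame timestamps are
#'   the start times of their source blocks.
#' @export
temporal_fuse <- function(seq, target_rate = 1) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (target_rate > seq$frame_rate) {
    stop("target_rate exceeds the sequence frame rate", call. = FALSE)
  }
  ratio <- seq$frame_rate / target_rate
  m <- round(ratio)
  if (abs(ratio - m) > 0.5 || m < 1) {
    stop("frame_rate / target_rate is not close to an integer", call. = FALSE)
  }
  n_out <- length(seq$frames) %/% m
  if (n_out == 0L) stop("sequence shorter than one fusion block", call. = FALSE)
  fused <- vector("list", n_out)
  for (b in seq_len(n_out)) {
    idx <- ((b - 1L) * m + 1L):(b * m)
    acc <- Reduce(`+`, seq$frames[idx])
    fused[[b]] <- round_half_up(acc / m)
  }
  frame_sequence(fused, target_rate, t0 = seq$t0)
}

#' Box (mean) filter with replicate edge padding
#'
#' @param frame Numeric matrix.
#' @param kernel Odd kernel size, >= 1; 1 is the identity.
#' @return Filtered matrix (floating point; quantization happens later).
#' @export
mean_filter <- function(frame, kernel = 3) {
  if (kernel %% 2 != 1 || kernel < 1) {
    stop("kernel must be an odd positive integer", call. = FALSE)
  }
  if (kernel == 1) return(frame + 0)
  nr <- nrow(frame); nc <- ncol(frame)
  half <- (kernel - 1L) %/% 2L
  acc <- matrix(0, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  for (di in -half:half) {
    rows <- pmin(pmax(ri + di, 1L), nr)
    for (dj in -half:half) {
      cols <- pmin(pmax(ci + dj, 1L), nc)
      acc <- acc + frame[rows, cols]
    }
  }
  acc / kernel^2
}

#' Extract a square region of interest
#'
#' Uses the 0-based, half-open convention of [roi_spec()]; an ROI that does
#' not fit entirely inside the frame raises an error rather than being
#' clamped.
#'
#' @param frame Numeric matrix.
#' @param roi A [roi_spec()].
#' @return A `size` x `size` matrix.
#' @export
extract_roi <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  half <- roi$size %/% 2L
  r0 <- roi$center_row - half
  c0 <- roi$center_col - half
  if (r0 < 0 || c0 < 0 || r0 + roi$size > nrow(frame) ||
      c0 + roi$size > ncol(frame)) {
    stop("ROI extends outside the frame", call. = FALSE)
  }
  frame[(r0 + 1L):(r0 + roi$size), (c0 + 1L):(c0 + roi$size), drop = FALSE]
}

#' Align a 1 Hz frame sequence with a temperature trace
#'
#' Matches each fused frame to the nearest trace sample. Pairing stops at
#' the shorter of the two inputs; a timestamp mismatch above 0.5 s is an
#' error.
#'
#' @param seq_1hz A [frame_sequence()] at (nominally) 1 Hz.
#' @param trace A [temperature_trace()].
#' @return A data frame with columns `frame`, `trace_idx`, `time_s`,
#'   `temp_C`.
#' @export
align_with_trace <- function(seq_1hz, trace) {
  stopifnot(inherits(seq_1hz, "frame_sequence"),
            inherits(trace, "temperature_trace"))
  if (abs(seq_1hz$frame_rate - 1) > 1e-6) {
    stop("sequence must be fused to 1 Hz before alignment", call. = FALSE)
  }
  ft <- frame_times(seq_1hz)
  n <- min(length(ft), length(trace$times))
  if (n == 0L) stop("empty inputs", call. = FALSE)
  frame_idx <- seq_len(n)
  trace_idx <- vapply(ft[frame_idx], function(t) {
    which.min(abs(trace$times - t))
  }, integer(1))
  mism <- abs(trace$times[trace_idx] - ft[frame_idx])
  if (any(mism > 0.5)) {
    stop("frame/trace timestamp mismatch exceeds 0.5 s", call. = FALSE)
  }
  data.frame(frame = frame_idx, trace_idx = trace_idx,
             time_s = ft[frame_idx], temp_C = trace$temps[trace_idx])
}

#' Preprocess a raw sequence into per-second ROI patches
#'
#' Convenience chain: temporal fusion to the trace rate, mean filtering and
#' ROI extraction, followed by alignment with the trace.
#'
#' @param seq A [frame_sequence()].
#' @param trace A [temperature_trace()].
#' @param roi A [roi_spec()], or `NULL` for a centered ROI of size
#'   `min(dim)` capped at 64.
#' @param kernel Mean-filter kernel (default 3).
#' @param target_rate Fusion target rate in Hz (default 1).
#' @return List with `patches` (list of filtered ROI matrices), `temps`,
#'   `times` and the alignment table.
#' @export
preprocess_sequence <- function(seq, trace, roi = NULL, kernel = 3,
                                target_rate = 1) {
  fused <- temporal_fuse(seq, target_rate)
  d <- dim(fused$frames[[1L]])
  if (is.null(roi)) {
    size <- min(64L, min(d))
    roi <- roi_spec(d[1] %/% 2L, d[2] %/% 2L, size)
  }
  align <- align_with_trace(fused, trace)
  patches <- lapply(align$frame, function(i) {
    extract_roi(mean_filter(fused$frames[[i]], kernel), roi)
  })
  list(patches = patches, temps = align$temp_C, times = align$time_s,
       alignment = align)
}
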