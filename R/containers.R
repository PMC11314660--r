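#' Temperature trace
#'
#' Ground-truth tissue temperatures sampled (nominally at 1 Hz) by an
#' invasive point probe such as a thermocouple. The trace is the training
#' target for the temperature-regression model.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param temps Numeric vector of temperatures in degrees Celsius, same
#'   length as `times`.
#' @return An object of class `temperature_trace`: a list with elements
#'   `times` and `temps`.
#' @export
temperature_trace <- function(times, temps) {
  times <- as.numeric(times)
  temps <- as.numeric(temps)
  if (length(times) != length(temps)) {
    stop("`times` and `temps` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) stop("trace must be non-empty", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(temps)) stop("`temps` contains NA", call. = FALSE)
  structure(list(times = times, temps = temps), class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "<temperature_trace> %d samples, %.0f..%.0f s, %.2f..%.2f degC\n",
    length(x$times), min(x$times), max(x$times), min(x$temps), max(x$temps)
  ))
  invisible(x)
}

#' Ultrasound frame sequence
#'
#' An ordered stack of single-channel 8-bit frames with a frame rate and an
#' acquisition start time. Pixel (1,1) is the top-left corner; frame `i`
#' carries timestamp `t0 + (i - 1) / frame_rate`.
#'
#' @param frames List of numeric matrices sharing one shape, values in
#'   0..255.
#' @param frame_rate Frames per second, positive.
#' @param t0 Acquisition start time in seconds (default 0).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate, t0 = 0) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("no frames", call. = FALSE)
  }
  dims <- lapply(frames, dim)
  d1 <- dims[[1L]]
  if (is.null(d1) || length(d1) != 2L) {
    stop("frames must be 2D matrices", call. = FALSE)
  }
  same <- vapply(dims, function(d) identical(d, d1), logical(1))
  if (!all(same)) stop("inconsistent frame shapes", call. = FALSE)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a positive scalar", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         t0 = as.numeric(t0)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf(
    "<frame_sequence> %d frames of %dx%d at %.3g fps (t0 = %.3g s)\n",
    length(x$frames), d[1], d[2], x$frame_rate, x$t0
  ))
  invisible(x)
}

#' Frame timestamps of a sequence
#'
#' @param seq A [frame_sequence()].
#' @return Numeric vector of per-frame times in seconds.
#' @export
frame_times <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  seq$t0 + (seq_along(seq$frames) - 1) / seq$frame_rate
}

#' Region-of-interest specification
#'
#' A square patch, `size` x `size` pixels, centered at a 0-based pixel
#' index. The patch spans the half-open ranges
#' `[center - size/2, center + size/2)` in rows and columns.
#'
#' @param center_row,center_col 0-based center pixel indices.
#' @param size Patch edge length in pixels (default 64).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_row, center_col, size = 64) {
  if (size < 1) stop("roi size must be positive", call. = FALSE)
  structure(
    list(center_row = as.integer(center_row),
         center_col = as.integer(center_col),
         size = as.integer(size)),
    class = "roi_spec"
  )
}

#' Multichannel feature time series
#'
#' Per-second texture feature values aligned to a temperature trace; the
#' model input. Channels are named; the default channel set is the six
#' descriptors with the strongest temperature correlation: average gray
#' level, gray-level entropy, gray-temperature gradient, mixture entropy,
#' inertia and inverse difference moment.
#'
#' @param times Sample times in seconds.
#' @param channels Numeric matrix, one row per time sample, named columns.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(times, channels) {
  channels <- as.matrix(channels)
  if (length(times) != nrow(channels)) {
    stop("times and channels disagree in length", call. = FALSE)
  }
  if (is.null(colnames(channels))) {
    stop("channels must be named", call. = FALSE)
  }
  if (anyNA(channels)) stop("channels contain NA after finalization", call. = FALSE)
  structure(list(times = as.numeric(times), channels = channels),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d samples x %d channels: %s\n",
              nrow(x$channels), ncol(x$channels),
              paste(colnames(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.feature_series <- function(x, ...) {
  data.frame(time_s = x$times, x$channels, check.names = FALSE)
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

round_half_up <- function(x) floor(x + 0.5)
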