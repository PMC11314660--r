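#' Select dominant periods of a multichannel series by FFT
#'
#' Computes each channel's DFT amplitude spectrum at frequency indices
#' `1..floor(T/2)` (the DC component is excluded so the trend cannot consume
#' the selection), normalizes every channel's spectrum by its own maximum,
#' averages across channels, and returns the `k` frequencies with the
#' largest averaged amplitude. Ties break toward the lower frequency. A
#' frequency index `f` corresponds to the period `p = ceiling(T / f)`
#' samples; the pair drives the 1D-to-2D reshape.
#'
#' @param x Numeric vector or T x C matrix (one column per channel).
#' @param k Number of periods to select, `1 <= k <= floor(T/2)`.
#' @return An object of class `period_decomposition` with fields
#'   `frequencies`, `periods`, `amplitudes` and `series_length`.
#' @export
fft_period_select <- function(x, k) {
  x <- as.matrix(x)
  T_len <- nrow(x)
  if (T_len < 4) stop("series must have at least 4 samples", call. = FALSE)
  hmax <- T_len %/% 2L
  if (k < 1 || k > hmax) stop("k must lie in 1..floor(T/2)", call. = FALSE)
  sp <- Mod(stats::mvfft(x))[2:(hmax + 1L), , drop = FALSE]
  mx <- apply(sp, 2, max)
  pos <- mx > 0
  sp[, pos] <- sweep(sp[, pos, drop = FALSE], 2, mx[pos], "/")
  sp[, !pos] <- 0
  A <- rowMeans(sp)
  if (all(A == 0)) stop("no periodicity: series is constant", call. = FALSE)
  ord <- order(-A, seq_along(A))
  f <- ord[seq_len(k)]
  structure(list(frequencies = f, periods = ceiling(T_len / f),
                 amplitudes = A[f], series_length = T_len),
            class = "period_decomposition")
}

#' @export
print.period_decomposition <- function(x, ...) {
  cat(sprintf("<period_decomposition> T = %d\n", x$series_length))
  print(data.frame(frequency = x$frequencies, period = x$periods,
                   amplitude = signif(x$amplitudes, 4)))
  invisible(x)
}

#' Reshape a 1D series into a period x frequency tensor
#'
#' Zero-pads the series to length `p * f` and fills column-major: row =
#' position within a period (`p` rows), column = period index (`f`
#' columns). Consecutive samples run down a column.
#'
#' @param x Numeric series of length T.
#' @param f Frequency index (number of periods / columns).
#' @param p Period length in samples (rows); normally `ceiling(T / f)`.
#' @return An object of class `tensor2d` with fields `values` (p x f
#'   matrix), `pad_length` and `series_length`.
#' @export
reshape_2d <- function(x, f, p) {
  T_len <- length(x)
  if (p * f < T_len) stop("p * f must cover the series length", call. = FALSE)
  pad <- p * f - T_len
  structure(list(values = matrix(c(x, numeric(pad)), nrow = p, ncol = f),
                 pad_length = pad, series_length = T_len),
            class = "tensor2d")
}

#' Invert the period-wise reshape
#'
#' Reads the tensor back in column-major order and truncates the zero
#' padding, recovering the original series exactly:
#' `inverse_reshape(reshape_2d(x, f, p)) == x`.
#'
#' @param t2 A [reshape_2d()] result (or a plain matrix).
#' @param T_len Series length to recover; defaults to the tensor's recorded
#'   `series_length`.
#' @return Numeric series of length `T_len`.
#' @export
inverse_reshape <- function(t2, T_len = NULL) {
  vals <- if (inherits(t2, "tensor2d")) t2$values else as.matrix(t2)
  if (is.null(T_len)) {
    if (!inherits(t2, "tensor2d")) {
      stop("T_len is required for a plain matrix", call. = FALSE)
    }
    T_len <- t2$series_length
  }
  if (T_len > length(vals)) {
    stop("T_len exceeds the tensor capacity", call. = FALSE)
  }
  as.vector(vals)[seq_len(T_len)]
}
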