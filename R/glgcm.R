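#' Sobel gradient magnitude image
#'
#' Applies the 3x3 Sobel operators with replicate edge padding and returns
#' the gradient magnitude `sqrt(Gx^2 + Gy^2)`. This is the gradient image
#' paired with the gray image in the gray-level gradient co-occurrence
#' matrix.
#'
#' @param frame Numeric matrix, at least 3x3.
#' @return Nonnegative matrix of the same shape.
#' @export
gradient_image <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (is.null(nr) || nr < 3 || nc < 3) {
    stop("frame must be at least 3x3", call. = FALSE)
  }
  ri <- seq_len(nr); ci <- seq_len(nc)
  sh <- function(di, dj) {
    frame[pmin(pmax(ri + di, 1L), nr), pmin(pmax(ci + dj, 1L), nc)]
  }
  # gx: derivative along columns, gy: along rows
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Quantize a gray image and its gradient image to discrete levels
#'
#' Gray levels are min-max scaled to `{0..N-1}` with floor-and-clip (a
#' constant image maps to all zeros); gradient levels are scaled by the
#' gradient maximum to `{0..M-1}` (an all-zero gradient maps to all zeros).
#' The extrema actually used are recorded.
#'
#' @param f Gray image matrix.
#' @param g Gradient image matrix, same shape.
#' @param N,M Level counts, >= 2 (default 16).
#' @return An object of class `quantized_pair` with integer matrices `F`
#'   and `G`, the level counts and the normalization extrema.
#' @export
quantize_pair <- function(f, g, N = 16, M = 16) {
  if (!identical(dim(f), dim(g))) {
    stop("gray and gradient images differ in shape", call. = FALSE)
  }
  if (N < 2 || M < 2) stop("N and M must be at least 2", call. = FALSE)
  f_min <- min(f); f_max <- max(f)
  g_max <- max(g)
  Fq <- if (f_max > f_min) {
    pmin(floor((f - f_min) / (f_max - f_min) * N), N - 1)
  } else {
    f * 0
  }
  Gq <- if (g_max > 0) pmin(floor(g / g_max * M), M - 1) else g * 0
  structure(list(F = matrix(as.integer(Fq), nrow(f), ncol(f)),
                 G = matrix(as.integer(Gq), nrow(g), ncol(g)),
                 N = as.integer(N), M = as.integer(M),
                 f_min = f_min, f_max = f_max, g_max = g_max),
            class = "quantized_pair")
}

#' Build the gray-level gradient co-occurrence matrix
#'
#' `h[x, y]` counts pixels whose quantized gray level is `x` and quantized
#' gradient level is `y` (0-based levels); `H = h / sum(h)` is the
#' normalized joint distribution all texture descriptors are computed from.
#'
#' @param q A [quantize_pair()] result.
#' @return An object of class `glgcm` with integer count matrix `h` (N x M)
#'   and normalized matrix `H`.
#' @export
build_glgcm <- function(q) {
  stopifnot(inherits(q, "quantized_pair"))
  idx <- as.vector(q$F) * q$M + as.vector(q$G) + 1L
  counts <- tabulate(idx, nbins = q$N * q$M)
  h <- matrix(counts, nrow = q$N, ncol = q$M, byrow = TRUE)
  structure(list(h = h, H = h / sum(h), N = q$N, M = q$M), class = "glgcm")
}

#' @export
print.glgcm <- function(x, ...) {
  cat(sprintf("<glgcm> %d x %d levels, %d pixels\n", x$N, x$M, sum(x$h)))
  invisible(x)
}

#' Texture descriptors of a GLGCM
#'
#' Computes the descriptors used as model channels: average gray level,
#' gray-level (marginal) entropy, mixture (joint) entropy, inertia and
#' inverse difference moment; `all_features = TRUE` adds the remaining
#' standard second-order GLGCM descriptors. Entropies use the natural log
#' with the convention `0 * log 0 = 0`.
#'
#' @param glg A [build_glgcm()] result.
#' @param all_features Also return the full 15-descriptor set.
#' @return Named numeric vector of descriptor values.
#' @export
compute_features <- function(glg, all_features = FALSE) {
  stopifnot(inherits(glg, "glgcm"))
  H <- glg$H
  if (abs(sum(H) - 1) > 1e-8) stop("H is not normalized", call. = FALSE)
  x <- 0:(glg$N - 1L)
  y <- 0:(glg$M - 1L)
  px <- rowSums(H)
  py <- colSums(H)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  D2 <- outer(x, y, function(a, b) (a - b)^2)
  out <- c(
    average_gray_level = sum(x * px),
    gray_level_entropy = -sum(xlogx(px)),
    mixture_entropy = -sum(xlogx(H)),
    inertia = sum(D2 * H),
    inverse_difference_moment = sum(H / (1 + D2))
  )
  if (all_features) {
    mx <- sum(x * px); my <- sum(y * py)
    sx <- sqrt(sum((x - mx)^2 * px)); sy <- sqrt(sum((y - my)^2 * py))
    corr <- if (sx > 0 && sy > 0) {
      sum(outer(x - mx, y - my) * H) / (sx * sy)
    } else 0
    out <- c(out,
      small_gradient_advantage = sum(sweep(H, 2, (y + 1)^2, "/")),
      big_gradient_advantage = sum(sweep(H, 2, y^2, "*")),
      gray_asymmetry = sum(px^2),
      gradient_asymmetry = sum(py^2),
      energy = sum(H^2),
      gradient_mean = my,
      gray_sd = sx,
      gradient_sd = sy,
      correlation = corr,
      gradient_entropy = -sum(xlogx(py))
    )
  }
  out
}

#' GLGCM descriptors of a single image patch
#'
#' Convenience chain: Sobel gradient, quantization, GLGCM and descriptors.
#'
#' @inheritParams quantize_pair
#' @param patch Gray-level image matrix.
#' @param all_features Also return the full descriptor set.
#' @return Named numeric vector of descriptor values.
#' @export
glgcm_features <- function(patch, N = 16, M = 16, all_features = FALSE) {
  g <- gradient_image(patch)
  compute_features(build_glgcm(quantize_pair(patch, g, N, M)),
                   all_features = all_features)
}

#' Gray-temperature gradient channel
#'
#' The lagged ratio of temperature change to average-gray-level change,
#' `(T[t+lag] - T[t]) / (AVGL[t+lag] - AVGL[t])`. When the gray-level change
#' is numerically zero the previous value is carried forward (0 at the
#' series start); the final `lag` positions carry the last computed value so
#' the output matches the input length. Because this channel consumes
#' measured temperature (the prediction target), it is disabled by default
#' at pure inference time.
#'
#' @param avgl Average-gray-level series.
#' @param temps Temperature series, same length.
#' @param lag Lag in samples, >= 1 (default 5, i.e. 5 s at a 1 Hz trace).
#' @param eps Degenerate-denominator threshold (default 1e-9).
#' @return Numeric series of the input length.
#' @export
gray_temperature_grad <- function(avgl, temps, lag = 5, eps = 1e-9) {
  n <- length(avgl)
  if (length(temps) != n) stop("series lengths differ", call. = FALSE)
  if (lag < 1) stop("lag must be at least 1", call. = FALSE)
  if (n <= lag) stop("series shorter than lag + 1", call. = FALSE)
  out <- numeric(n)
  prev <- 0
  for (t in seq_len(n - lag)) {
    dA <- avgl[t + lag] - avgl[t]
    if (abs(dA) < eps) {
      out[t] <- prev
    } else {
      out[t] <- (temps[t + lag] - temps[t]) / dA
      prev <- out[t]
    }
  }
  out[(n - lag + 1L):n] <- out[n - lag]
  out
}

#' Extract the multichannel feature series of an experiment
#'
#' Runs gradient, quantization, GLGCM and descriptor extraction on each
#' per-second patch and appends the gray-temperature gradient channel. Raw
#' (un-normalized) values are returned; z-scoring with training-set
#' statistics happens inside model training.
#'
#' @param patches List of ROI matrices, one per trace sample.
#' @param trace A [temperature_trace()] of matching length.
#' @param N,M Quantization levels (default 16).
#' @param lag Gray-temperature-gradient lag in samples (default 5).
#' @param all_features Include the full descriptor set as extra channels.
#' @return A [feature_series()].
#' @export
extract_feature_series <- function(patches, trace, N = 16, M = 16, lag = 5,
                                   all_features = FALSE) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (length(patches) != length(trace$times)) {
    stop("one patch per trace sample is required", call. = FALSE)
  }
  feats <- t(vapply(
    patches,
    function(p) glgcm_features(p, N = N, M = M, all_features = all_features),
    glgcm_features(patches[[1L]], N = N, M = M, all_features = all_features)
  ))
  gtg <- gray_temperature_grad(feats[, "average_gray_level"], trace$temps,
                               lag = lag)
  core <- c("average_gray_level", "gray_level_entropy")
  rest <- setdiff(colnames(feats), core)
  channels <- cbind(feats[, core, drop = FALSE],
                    gray_temperature_grad = gtg,
                    feats[, rest, drop = FALSE])
  feature_series(trace$times, channels)
}

#' Rank feature channels by Pearson correlation with temperature
#'
#' @param fs A [feature_series()].
#' @param trace A [temperature_trace()] aligned with `fs`.
#' @return A data frame with columns `feature`, `r` and `zero_variance`,
#'   sorted by `|r|` descending. Zero-variance channels get a correlation
#'   of 0 and a warning flag.
#' @export
pearson_rank <- function(fs, trace) {
  stopifnot(inherits(fs, "feature_series"), inherits(trace, "temperature_trace"))
  if (nrow(fs$channels) != length(trace$temps)) {
    stop("feature series and trace differ in length", call. = FALSE)
  }
  if (nrow(fs$channels) < 3L) stop("need at least 3 samples", call. = FALSE)
  temps <- trace$temps
  rs <- numeric(ncol(fs$channels))
  flag <- logical(ncol(fs$channels))
  for (j in seq_along(rs)) {
    ch <- fs$channels[, j]
    if (stats::sd(ch) == 0 || stats::sd(temps) == 0) {
      rs[j] <- 0
      flag[j] <- TRUE
    } else {
      rs[j] <- stats::cor(ch, temps)
    }
  }
  if (any(flag)) {
    warning("zero-variance channel(s): ",
            paste(colnames(fs$channels)[flag], collapse = ", "),
            call. = FALSE)
  }
  out <- data.frame(feature = colnames(fs$channels), r = rs,
                    zero_variance = flag)
  out[order(-abs(out$r)), , drop = FALSE]
}
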