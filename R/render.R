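#' Render predicted-vs-measured temperature curves
#'
#' Writes one PNG per held-out experiment with the measured trace and the
#' model's per-second prediction.
#'
#' @param report An [evaluate()] report (carries the predictions).
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
render_prediction_curves <- function(report, out_dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(report$predictions)) {
    pr <- report$predictions[[i]]
    path <- file.path(out_dir, sprintf("prediction_exp%02d.png", i))
    grDevices::png(path, width = 900, height = 500)
    graphics::plot(pr$times, pr$obs, type = "l", lwd = 2, col = "black",
                   xlab = "time (s)", ylab = "temperature (degC)",
                   main = sprintf("Experiment %d: measured vs predicted", i),
                   ylim = range(c(pr$obs, pr$pred)))
    graphics::lines(pr$times, pr$pred, col = "red", lwd = 2, lty = 2)
    graphics::legend("bottomright", legend = c("measured", "predicted"),
                     col = c("black", "red"), lty = c(1, 2), lwd = 2)
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}

# fixed 25-65 degC color scale (blue -> cyan -> yellow -> red)
temp_colormap <- function(values, t_min = 25, t_max = 65) {
  ramp <- grDevices::colorRamp(c("navy", "blue", "cyan", "yellow", "red"))
  z <- pmin(pmax((values - t_min) / (t_max - t_min), 0), 1)
  ramp(z) / 255
}

#' Render pseudocolor temperature maps
#'
#' Slides the model's ROI across each fused frame on a stride grid,
#' extracts per-tile feature series, predicts per-tile temperature curves,
#' and renders the tile temperatures at the requested times on a fixed
#' 25-65 degC color scale with a color bar. The tile-and-predict
#' construction is this package's convention for spatial maps.
#'
#' @param model A trained model.
#' @param seq A [frame_sequence()] (raw rate; fused internally).
#' @param trace The matching [temperature_trace()].
#' @param out_dir Output directory.
#' @param grid_stride Tile stride in pixels (default 16).
#' @param roi_size Tile edge (default 64).
#' @param at_times Seconds at which to render maps (default: five equally
#'   spaced instants).
#' @param kernel,N,M,lag Preprocessing/feature settings (defaults 3, 16,
#'   16, 5).
#' @param t_range Color-scale limits in degC (default `c(25, 65)`).
#' @return Character vector of written file paths, invisibly.
#' @export
render_pseudocolor_map <- function(model, seq, trace, out_dir,
                                   grid_stride = 16, roi_size = 64,
                                   at_times = NULL, kernel = 3, N = 16,
                                   M = 16, lag = 5, t_range = c(25, 65)) {
  d <- dim(seq$frames[[1L]])
  if (any(d < roi_size)) stop("frame smaller than the ROI", call. = FALSE)
  fused <- temporal_fuse(seq, 1)
  align <- align_with_trace(fused, trace)
  half <- roi_size %/% 2L
  centers_r <- seq(half, d[1] - roi_size + half, by = grid_stride)
  centers_c <- seq(half, d[2] - roi_size + half, by = grid_stride)
  tile_temp <- array(NA_real_, c(length(centers_r), length(centers_c),
                                 nrow(align)))
  for (i in seq_along(centers_r)) {
    for (j in seq_along(centers_c)) {
      roi <- roi_spec(centers_r[i], centers_c[j], roi_size)
      patches <- lapply(align$frame, function(k) {
        extract_roi(mean_filter(fused$frames[[k]], kernel), roi)
      })
      fs <- extract_feature_series(
        patches, temperature_trace(align$time_s, align$temp_C),
        N = N, M = M, lag = lag
      )
      tile_temp[i, j, ] <- predict_temperature(model, fs)
    }
  }
  if (is.null(at_times)) {
    at_times <- align$time_s[round(seq(1, nrow(align), length.out = 5))]
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  upscale <- 24L
  for (tt in at_times) {
    k <- which.min(abs(align$time_s - tt))
    grid <- tile_temp[, , k, drop = FALSE]
    dim(grid) <- dim(tile_temp)[1:2]
    img_h <- nrow(grid) * upscale
    img_w <- ncol(grid) * upscale
    rgbv <- temp_colormap(as.vector(grid[rep(seq_len(nrow(grid)),
                                             each = upscale),
                                         rep(seq_len(ncol(grid)),
                                             each = upscale)]),
                          t_range[1], t_range[2])
    img <- array(0, c(img_h, img_w + 40L, 3))
    for (ch in 1:3) img[, seq_len(img_w), ch] <- rgbv[, ch]
    # color bar: top = hot
    bar_vals <- seq(t_range[2], t_range[1], length.out = img_h)
    barc <- temp_colormap(bar_vals, t_range[1], t_range[2])
    for (ch in 1:3) img[, img_w + 11:30, ch] <- barc[, ch]
    path <- file.path(out_dir, sprintf("tempmap_t%04.0fs.png", tt))
    png::writePNG(img, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
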