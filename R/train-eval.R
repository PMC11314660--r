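#' Training configuration
#'
#' Optimization settings for the temperature regressor: Adam with an
#' initial learning rate of 0.001 and weight decay of 1e-5, mean squared
#' error loss, up to 1000 epochs, and an experiment-level 7:3
#' train/test split. Early stopping (patience on a held-out fold of
#' training experiments) is provided because synthetic data converges far
#' sooner than the default epoch budget.
#'
#' @param lr Learning rate (default 0.001).
#' @param weight_decay Weight decay (default 1e-5).
#' @param epochs Maximum epochs (default 1000).
#' @param split_ratio Train fraction for experiment-level splits
#'   (default 0.7).
#' @param batch_size Windows per batch (default 32).
#' @param patience Early-stopping patience in epochs (default 50); 0
#'   disables early stopping.
#' @param stride Training-window stride in samples (default 24).
#' @param val_fraction Fraction of training experiments held out for early
#'   stopping (default 0.2).
#' @param use_temp_grad Feed the gray-temperature-gradient channel to the
#'   model. It consumes measured temperature, so the honest default is
#'   `FALSE`; enabling it matches protocols that use the probe trace at
#'   feature time and is a documented leakage risk.
#' @param seed Training seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, weight_decay = 1e-5, epochs = 1000,
                         split_ratio = 0.7, batch_size = 32, patience = 50,
                         stride = 24, val_fraction = 0.2,
                         use_temp_grad = FALSE, seed = 0) {
  if (split_ratio <= 0 || split_ratio >= 1) {
    stop("split_ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  if (epochs < 1) stop("epochs must be at least 1", call. = FALSE)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs), split_ratio = split_ratio,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), stride = as.integer(stride),
                 val_fraction = val_fraction, use_temp_grad = use_temp_grad,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split experiments into train and test sets
#'
#' Whole experiments are assigned to exactly one side so that no heating
#' run contributes windows to both splits. The train side gets
#' `round(ratio * n)` experiments, with at least one experiment on each
#' side; the assignment is deterministic under the seed.
#'
#' @param experiments List of experiments (any type).
#' @param ratio Train fraction (default 0.7).
#' @param seed Assignment seed.
#' @return List with `train`, `test`, `train_idx`, `test_idx`.
#' @export
split_experiments <- function(experiments, ratio = 0.7, seed = 0) {
  n <- length(experiments)
  if (n < 2) stop("need at least 2 experiments to split", call. = FALSE)
  n_train <- min(max(round(ratio * n), 1L), n - 1L)
  set.seed(seed)
  perm <- sample.int(n)
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[(n_train + 1L):n])
  list(train = experiments[train_idx], test = experiments[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' Per-experiment feature extraction
#'
#' Preprocesses one experiment (fusion, mean filter, ROI) and extracts its
#' GLGCM feature series.
#'
#' @param exp A `synthetic_experiment`, or a list with elements `frames`
#'   (a [frame_sequence()]) and `trace` (a [temperature_trace()]).
#' @param roi A [roi_spec()] or `NULL` for a centered default.
#' @param kernel Mean-filter kernel (default 3).
#' @param N,M Quantization levels (default 16).
#' @param lag Gray-temperature-gradient lag (default 5).
#' @return List with `features` (a [feature_series()]), `temps`, `times`
#'   and, when present, `injected_periods`.
#' @export
experiment_features <- function(exp, roi = NULL, kernel = 3, N = 16, M = 16,
                                lag = 5) {
  prep <- preprocess_sequence(exp$frames, exp$trace, roi = roi,
                              kernel = kernel)
  tr <- temperature_trace(prep$times, prep$temps)
  fs <- extract_feature_series(prep$patches, tr, N = N, M = M, lag = lag)
  list(features = fs, temps = prep$temps, times = prep$times,
       injected_periods = exp$injected_periods)
}

#' Feature extraction over an experiment set
#'
#' @param experiments List of experiments (see [experiment_features()]).
#' @param ... Passed to [experiment_features()].
#' @return List of per-experiment feature items.
#' @export
dataset_features <- function(experiments, ...) {
  lapply(experiments, experiment_features, ...)
}

#' Default model input channels
#'
#' The five texture channels fed to the model by default; the
#' gray-temperature gradient is added only when explicitly requested, since
#' it consumes the measured temperature (the prediction target).
#'
#' @param use_temp_grad Include the gray-temperature-gradient channel.
#' @return Character vector of channel names.
#' @export
default_model_channels <- function(use_temp_grad = FALSE) {
  ch <- c("average_gray_level", "gray_level_entropy", "mixture_entropy",
          "inertia", "inverse_difference_moment")
  if (use_temp_grad) append(ch, "gray_temperature_grad", after = 2) else ch
}

# ---- Adam -------------------------------------------------------------------

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero) else p * 0
}

adam_apply <- function(params, grads, m, v, lr, wd, step,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  rec <- function(p, g, m, v, nm) {
    if (is.list(p)) {
      nms <- names(p)
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        gi <- if (is.null(nms)) g[[i]] else g[[nms[i]]]
        r <- rec(p[[i]], gi, m[[i]], v[[i]],
                 if (is.null(nms)) "" else nms[i])
        out_p[[i]] <- r[[1]]; out_m[[i]] <- r[[2]]; out_v[[i]] <- r[[3]]
      }
      list(out_p, out_m, out_v)
    } else {
      if (wd > 0 && nzchar(nm) && substr(nm, 1, 1) %in% c("W", "K")) {
        g <- g + wd * p
      }
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      p <- p - lr * (m / (1 - b1^step)) / (sqrt(v / (1 - b2^step)) + eps)
      list(p, m, v)
    }
  }
  r <- rec(params, grads, m, v, "")
  list(params = r[[1]], m = r[[2]], v = r[[3]])
}

# ---- generic fit loop -------------------------------------------------------

eval_loss <- function(forward, params, X, Y, batch_size) {
  n <- dim(X)[2]
  tot <- 0
  for (ids in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    pred <- forward(params, X[, ids, , drop = FALSE], FALSE)$pred
    tot <- tot + sum((pred - Y[, ids, drop = FALSE])^2)
  }
  tot / (n * dim(X)[1])
}

fit_network <- function(forward, backward, params, Xtr, Ytr,
                        Xval = NULL, Yval = NULL, tc) {
  nw <- dim(Xtr)[2]
  m <- tree_zero(params); v <- tree_zero(params)
  step <- 0L
  best <- Inf; best_params <- params; bad <- 0L
  hist_tr <- numeric(0); hist_val <- numeric(0)
  for (epoch in seq_len(tc$epochs)) {
    perm <- sample.int(nw)
    loss_sum <- 0
    for (ids in split(perm, ceiling(seq_along(perm) / tc$batch_size))) {
      Xb <- Xtr[, ids, , drop = FALSE]
      Yb <- Ytr[, ids, drop = FALSE]
      fw <- forward(params, Xb, TRUE)
      err <- fw$pred - Yb
      l <- mean(err^2)
      if (!is.finite(l)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
             call. = FALSE)
      }
      grads <- backward(params, fw$cache, 2 * err / length(err))
      step <- step + 1L
      upd <- adam_apply(params, grads, m, v, tc$lr, tc$weight_decay, step)
      params <- upd$params; m <- upd$m; v <- upd$v
      loss_sum <- loss_sum + l * length(ids)
    }
    tr_loss <- loss_sum / nw
    val_loss <- if (!is.null(Xval)) {
      eval_loss(forward, params, Xval, Yval, tc$batch_size)
    } else tr_loss
    hist_tr <- c(hist_tr, tr_loss)
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best - 1e-10) {
      best <- val_loss; best_params <- params; bad <- 0L
    } else {
      bad <- bad + 1L
      if (tc$patience > 0 && bad >= tc$patience) break
    }
  }
  list(params = best_params,
       history = data.frame(epoch = seq_along(hist_tr), train_loss = hist_tr,
                            val_loss = hist_val))
}

# windows of length T with the given stride (the final window is always
# included so the series end is covered)
window_starts <- function(n, T_len, stride) {
  if (n < T_len) stop("series shorter than one window", call. = FALSE)
  unique(c(seq(1L, n - T_len + 1L, by = stride), n - T_len + 1L))
}

build_windows <- function(items, channels, norm, T_len, stride) {
  xs <- list(); ys <- list()
  for (it in items) {
    mat <- it$features$channels[, channels, drop = FALSE]
    mat <- normalize_channels(mat, norm)
    tn <- (it$temps - norm$t_mean) / norm$t_sd
    for (s in window_starts(nrow(mat), T_len, stride)) {
      xs[[length(xs) + 1L]] <- mat[s:(s + T_len - 1L), , drop = FALSE]
      ys[[length(ys) + 1L]] <- tn[s:(s + T_len - 1L)]
    }
  }
  nw <- length(xs)
  X <- array(0, c(T_len, nw, length(channels)))
  Y <- matrix(0, T_len, nw)
  for (i in seq_len(nw)) {
    X[, i, ] <- xs[[i]]
    Y[, i] <- ys[[i]]
  }
  list(X = X, Y = Y)
}

norm_stats <- function(items, channels) {
  all_mat <- do.call(rbind, lapply(items, function(it) {
    it$features$channels[, channels, drop = FALSE]
  }))
  all_t <- unlist(lapply(items, function(it) it$temps))
  ch_sd <- apply(all_mat, 2, stats::sd)
  ch_sd[ch_sd == 0] <- 1
  t_sd <- stats::sd(all_t)
  if (t_sd == 0) t_sd <- 1
  list(ch_mean = colMeans(all_mat), ch_sd = ch_sd,
       t_mean = mean(all_t), t_sd = t_sd)
}

prepare_training <- function(train_data, channels, T_len, tc) {
  n_exp <- length(train_data)
  set.seed(tc$seed)
  val_items <- NULL
  fit_items <- train_data
  if (tc$patience > 0 && n_exp >= 4) {
    n_val <- max(1L, round(tc$val_fraction * n_exp))
    perm <- sample.int(n_exp)
    val_items <- train_data[perm[seq_len(n_val)]]
    fit_items <- train_data[perm[(n_val + 1L):n_exp]]
  }
  norm <- norm_stats(fit_items, channels)
  tr <- build_windows(fit_items, channels, norm, T_len, tc$stride)
  val <- if (!is.null(val_items)) {
    build_windows(val_items, channels, norm, T_len, tc$stride)
  }
  list(norm = norm, Xtr = tr$X, Ytr = tr$Y,
       Xval = if (is.null(val)) NULL else val$X,
       Yval = if (is.null(val)) NULL else val$Y)
}

#' Train the temporal temperature-regression model
#'
#' Sequence-to-sequence regression over sliding feature windows: the loss
#' is the mean squared error of per-time-step temperature predictions
#' (z-scored with training statistics), optimized with Adam. A fraction of
#' the training experiments is held out for early stopping; the returned
#' checkpoint carries the weights with the best held-out loss, plus the
#' normalization statistics and full configuration.
#'
#' @param train_data List of feature items from [dataset_features()].
#' @param model_cfg A [model_config()], or `NULL` for defaults over the
#'   standard channel set.
#' @param train_cfg A [train_config()].
#' @return An object of class `temporal_model` with elements `cfg`,
#'   `params`, `norm`, `channels`, `history` and `train_cfg`.
#' @export
train_temporal_model <- function(train_data, model_cfg = NULL,
                                 train_cfg = train_config()) {
  if (length(train_data) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(model_cfg)) {
    model_cfg <- model_config(
      channels = default_model_channels(train_cfg$use_temp_grad),
      seed = train_cfg$seed + 1L
    )
  }
  prep <- prepare_training(train_data, model_cfg$channels,
                           model_cfg$window_length, train_cfg)
  params <- init_tin_params(model_cfg)
  set.seed(train_cfg$seed + 2L)
  fwd <- function(p, X, train) net_fwd(p, model_cfg, X, train)
  bwd <- function(p, cache, dY) net_bwd(p, model_cfg, cache, dY)
  fit <- fit_network(fwd, bwd, params, prep$Xtr, prep$Ytr, prep$Xval,
                     prep$Yval, train_cfg)
  structure(list(cfg = model_cfg, params = fit$params, norm = prep$norm,
                 channels = model_cfg$channels, history = fit$history,
                 train_cfg = train_cfg, seed = train_cfg$seed),
            class = "temporal_model")
}

#' @export
print.temporal_model <- function(x, ...) {
  pc <- count_parameters(x$cfg)
  cat(sprintf(
    "<temporal_model> %d channels, %d blocks, k = %d, %d parameters (%.4f MB)\n",
    length(x$channels), x$cfg$n_blocks, x$cfg$k_periods, pc$count, pc$mb))
  if (nrow(x$history) > 0) {
    cat(sprintf("  trained %d epochs, best held-out loss %.4g\n",
                nrow(x$history), min(x$history$val_loss)))
  }
  invisible(x)
}

model_predict_fn <- function(model) {
  if (inherits(model, "temporal_model")) {
    function(p, X, train) net_fwd(p, model$cfg, X, train)
  } else if (inherits(model, "lstm_model")) {
    function(p, X, train) lstm_fwd(p, X, train)
  } else {
    stop("unknown model type", call. = FALSE)
  }
}

#' Predict a temperature curve for one experiment
#'
#' Slides windows of the model's training length across the feature series
#' (stride 1 by default), forwards them in evaluation mode and averages the
#' per-time-step predictions where windows overlap.
#'
#' @param model A trained `temporal_model` or `lstm_model`.
#' @param features A [feature_series()] or raw channel matrix with named
#'   columns.
#' @param stride Window stride in samples (default 1).
#' @param batch_size Windows forwarded per batch (default 128).
#' @return Numeric vector of temperature estimates, degC, one per time
#'   step.
#' @export
predict_temperature <- function(model, features, stride = 1,
                                batch_size = 128) {
  if (inherits(features, "feature_series")) features <- features$channels
  T_len <- model$cfg$window_length
  mat <- normalize_channels(features[, model$channels, drop = FALSE],
                            model$norm)
  n <- nrow(mat)
  starts <- window_starts(n, T_len, stride)
  X <- array(0, c(T_len, length(starts), ncol(mat)))
  for (i in seq_along(starts)) {
    X[, i, ] <- mat[starts[i]:(starts[i] + T_len - 1L), ]
  }
  fwd <- model_predict_fn(model)
  acc <- numeric(n); cnt <- numeric(n)
  for (ids in split(seq_along(starts), ceiling(seq_along(starts) / batch_size))) {
    pred <- fwd(model$params, X[, ids, , drop = FALSE], FALSE)$pred
    for (j in seq_along(ids)) {
      pos <- starts[ids[j]]:(starts[ids[j]] + T_len - 1L)
      acc[pos] <- acc[pos] + pred[, j]
      cnt[pos] <- cnt[pos] + 1
    }
  }
  (acc / cnt) * model$norm$t_sd + model$norm$t_mean
}

#' Evaluate a trained model on held-out experiments
#'
#' Computes MSE, RMSE and MAE over all per-step predictions, with
#' per-experiment and per-temperature-band breakdowns (default bands
#' 25-30, 30-45 and 45-65 degC, the regimes where estimation behaves
#' differently).
#'
#' @param model A trained model.
#' @param test_data List of feature items from [dataset_features()].
#' @param stride Prediction window stride (default 1).
#' @param band_edges Interior band edges in degC (default `c(30, 45)`).
#' @return An object of class `eval_report`.
#' @export
evaluate <- function(model, test_data, stride = 1, band_edges = c(30, 45)) {
  if (length(test_data) == 0L) stop("empty test set", call. = FALSE)
  preds <- list()
  for (i in seq_along(test_data)) {
    it <- test_data[[i]]
    p <- predict_temperature(model, it$features, stride = stride)
    preds[[i]] <- list(pred = p, obs = it$temps, times = it$times)
  }
  eval_report(preds, band_edges)
}

eval_report <- function(preds, band_edges = c(30, 45)) {
  p_all <- unlist(lapply(preds, `[[`, "pred"))
  y_all <- unlist(lapply(preds, `[[`, "obs"))
  err <- p_all - y_all
  mse <- mean(err^2)
  per_exp <- data.frame(
    experiment = seq_along(preds),
    n = vapply(preds, function(x) length(x$obs), integer(1)),
    mse = vapply(preds, function(x) mean((x$pred - x$obs)^2), numeric(1)),
    mae = vapply(preds, function(x) mean(abs(x$pred - x$obs)), numeric(1))
  )
  per_exp$rmse <- sqrt(per_exp$mse)
  breaks <- c(-Inf, band_edges, Inf)
  labels <- c(sprintf("<%g", band_edges[1]),
              if (length(band_edges) > 1) {
                sprintf("%g-%g", band_edges[-length(band_edges)],
                        band_edges[-1])
              },
              sprintf(">=%g", band_edges[length(band_edges)]))
  band <- cut(y_all, breaks = breaks, labels = labels, right = FALSE)
  per_band <- do.call(rbind, lapply(levels(band), function(lv) {
    sel <- band == lv
    data.frame(band_degC = lv, n = sum(sel),
               mse = if (any(sel)) mean(err[sel]^2) else NA_real_,
               mae = if (any(sel)) mean(abs(err[sel])) else NA_real_)
  }))
  per_band$rmse <- sqrt(per_band$mse)
  structure(list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
                 per_experiment = per_exp, per_band = per_band,
                 predictions = preds, n = length(y_all)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d steps: MSE %.4f degC^2, RMSE %.4f, MAE %.4f degC\n",
              x$n, x$mse, x$rmse, x$mae))
  print(x$per_band[, c("band_degC", "n", "rmse", "mae")], row.names = FALSE)
  invisible(x)
}
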