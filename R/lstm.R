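# Minimal single-layer LSTM regressor used only as the ordering baseline:
# same input channels and training protocol as the temporal model, with the
# hidden width chosen so its parameter count is at least the primary
# model's budget.

lstm_param_count <- function(C, H) 4 * (C * H + H * H + H) + H + 1

init_lstm_params <- function(C, H, seed) {
  set.seed(seed)
  list(W = xavier_mat(C, 4L * H), U = xavier_mat(H, 4L * H),
       b = numeric(4L * H), W_out = xavier_mat(H, 1L), b_out = numeric(1L))
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(params, X, train = FALSE) {
  d <- dim(X)
  T_len <- d[1]; B <- d[2]
  H <- nrow(params$U)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Y <- matrix(0, T_len, B)
  steps <- if (train) vector("list", T_len) else NULL
  Hs <- if (train) array(0, c(T_len, B, H)) else NULL
  for (t in seq_len(T_len)) {
    xt <- matrix(X[t, , ], B, d[3])
    G <- xt %*% params$W + h %*% params$U + rep(params$b, each = B)
    i <- sigm(G[, seq_len(H), drop = FALSE])
    f <- sigm(G[, H + seq_len(H), drop = FALSE])
    g <- tanh(G[, 2L * H + seq_len(H), drop = FALSE])
    o <- sigm(G[, 3L * H + seq_len(H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc_ <- tanh(cc)
    h_prev <- h
    h <- o * tc_
    Y[t, ] <- h %*% params$W_out + params$b_out
    if (train) {
      steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc_, h_prev = h_prev)
      Hs[t, , ] <- h
    }
  }
  list(pred = Y, cache = if (train) list(steps = steps, Hs = Hs, dims = d))
}

lstm_bwd <- function(params, cache, dY) {
  d <- cache$dims
  T_len <- d[1]; B <- d[2]; C <- d[3]
  H <- nrow(params$U)
  g <- list(W = params$W * 0, U = params$U * 0, b = numeric(4L * H),
            W_out = params$W_out * 0, b_out = 0)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_len))) {
    st <- cache$steps[[t]]
    ht <- matrix(cache$Hs[t, , ], B, H)
    dyt <- dY[t, ]
    g$W_out <- g$W_out + crossprod(ht, matrix(dyt, B, 1))
    g$b_out <- g$b_out + sum(dyt)
    dh <- dh_next + matrix(dyt, B, H) * rep(as.numeric(params$W_out), each = B)
    do_ <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    g$W <- g$W + crossprod(st$xt, dG)
    g$U <- g$U + crossprod(st$h_prev, dG)
    g$b <- g$b + colSums(dG)
    dh_next <- dG %*% t(params$U)
  }
  g
}

#' Train and evaluate the LSTM ordering baseline
#'
#' A single-layer recurrent regressor with the same input channels,
#' normalization and training protocol as the temporal model. Its hidden
#' width is the smallest for which the parameter count is at least
#' `budget_params` (defaulting to the primary model's count), so the
#' comparison cannot favor the primary model through capacity.
#'
#' @param train_data,test_data Feature items from [dataset_features()].
#' @param train_cfg A [train_config()].
#' @param budget_params Minimum parameter count (default: the primary
#'   default configuration's count).
#' @param window_length Window length in samples (default 96).
#' @param seed Seed for initialization and batching.
#' @return List with `model` (class `lstm_model`) and `report`
#'   (an [evaluate()] report on `test_data`).
#' @export
baseline_lstm <- function(train_data, test_data, train_cfg = train_config(),
                          budget_params = NULL, window_length = 96,
                          seed = train_cfg$seed) {
  channels <- default_model_channels(train_cfg$use_temp_grad)
  if (is.null(budget_params)) {
    budget_params <- count_parameters(
      model_config(channels = channels)
    )$count
  }
  C <- length(channels)
  H <- 2L
  while (lstm_param_count(C, H) < budget_params) H <- H + 1L
  tc <- train_cfg
  tc$seed <- as.integer(seed)
  prep <- prepare_training(train_data, channels, window_length, tc)
  params <- init_lstm_params(C, H, tc$seed + 1L)
  set.seed(tc$seed + 2L)
  fit <- fit_network(lstm_fwd, lstm_bwd, params, prep$Xtr, prep$Ytr,
                     prep$Xval, prep$Yval, tc)
  model <- structure(
    list(cfg = list(window_length = as.integer(window_length), hidden = H),
         params = fit$params, norm = prep$norm, channels = channels,
         history = fit$history, train_cfg = tc),
    class = "lstm_model"
  )
  list(model = model, report = evaluate(model, test_data))
}
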