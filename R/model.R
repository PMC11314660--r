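#' Temporal-network configuration
#'
#' Hyperparameters of the temperature-regression network: a channel
#' embedding, `n_blocks` period-decomposition blocks (FFT top-k period
#' selection, period-wise 1D-to-2D reshape, a dual-branch attention module,
#' amplitude-weighted aggregation, residual connection) and a linear
#' per-time-step output head. The dual-branch module splits the embedding
#' channels equally between a local branch (depthwise attention-convolution
#' on the period x frequency grid) and a global branch (multi-head scaled
#' dot-product attention over all grid positions).
#'
#' @param channels Character vector of input channel names.
#' @param k_periods Number of periods selected per block (default 5, the
#'   value found to minimize test MSE).
#' @param embed_dim Embedding width (default 16); must be even and the
#'   global half divisible by `n_heads`.
#' @param n_blocks Number of period blocks (default 2).
#' @param n_heads Global-attention heads (default 2).
#' @param local_kernel Depthwise kernel size, odd (default 3).
#' @param window_length Input window length in samples (default 96; at
#'   least twice the longest expected sub-period is recommended).
#' @param dropout Dropout rate on the embedding during training
#'   (default 0.1).
#' @param kv_pool Mean-pooling factor on the global branch's keys and
#'   values (default 4; 1 disables pooling). The global branch targets
#'   low-frequency structure, so pooled keys/values lose little while
#'   cutting the attention cost.
#' @param seed Parameter-initialization seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(channels, k_periods = 5, embed_dim = 16,
                         n_blocks = 2, n_heads = 2, local_kernel = 3,
                         window_length = 96, dropout = 0.1, kv_pool = 4,
                         seed = 1) {
  if (k_periods < 1) stop("k_periods must be at least 1", call. = FALSE)
  if (embed_dim %% 2 != 0) stop("embed_dim must be even", call. = FALSE)
  d_half <- embed_dim %/% 2L
  if (d_half %% n_heads != 0) {
    stop("embed_dim / 2 must be divisible by n_heads", call. = FALSE)
  }
  if (local_kernel %% 2 != 1) stop("local_kernel must be odd", call. = FALSE)
  if (window_length < 4) stop("window_length must be at least 4", call. = FALSE)
  structure(list(channels = channels, k_periods = as.integer(k_periods),
                 embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 local_kernel = as.integer(local_kernel),
                 window_length = as.integer(window_length),
                 dropout = dropout, kv_pool = as.integer(max(1, kv_pool)),
                 seed = as.integer(seed)),
            class = "model_config")
}

xavier_mat <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

cloblock_init_one <- function(D, kl) {
  Dl <- D %/% 2L
  Dg <- D - Dl
  a <- sqrt(6 / (2 * kl * kl))
  list(
    Wq_l = xavier_mat(Dl, Dl), bq_l = numeric(Dl),
    Kk = array(stats::runif(kl * kl * Dl, -a, a), c(kl, kl, Dl)),
    bk = numeric(Dl),
    Kv = array(stats::runif(kl * kl * Dl, -a, a), c(kl, kl, Dl)),
    bv = numeric(Dl),
    Wq_g = xavier_mat(Dg, Dg), Wk_g = xavier_mat(Dg, Dg),
    Wv_g = xavier_mat(Dg, Dg),
    Wf = xavier_mat(D, D), bf = numeric(D)
  )
}

#' Initialize dual-branch attention block weights
#'
#' @param cfg A [model_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return Named list of weight arrays for one block.
#' @export
cloblock_init <- function(cfg, seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed else seed)
  cloblock_init_one(cfg$embed_dim, cfg$local_kernel)
}

init_tin_params <- function(cfg) {
  set.seed(cfg$seed)
  C <- length(cfg$channels)
  D <- cfg$embed_dim
  list(
    W_emb = xavier_mat(C, D), b_emb = numeric(D),
    blocks = lapply(seq_len(cfg$n_blocks), function(i) {
      cloblock_init_one(D, cfg$local_kernel)
    }),
    W_out = xavier_mat(D, 1L), b_out = numeric(1L)
  )
}

# ---- array primitives -------------------------------------------------------
# The depthwise convolution and multi-head attention inner loops live in
# src/kernels.cpp; the R side handles shapes, caching and everything else.

# matrix multiply over the last dimension of an array
last_mm <- function(x, W, b = NULL) {
  d <- dim(x)
  nd <- length(d)
  m <- x
  dim(m) <- c(prod(d[-nd]), d[nd])
  y <- m %*% W
  if (!is.null(b)) y <- y + rep(b, each = nrow(y))
  dim(y) <- c(d[-nd], ncol(W))
  y
}

last_mm_bwd <- function(dY, x, W) {
  d <- dim(x)
  nd <- length(d)
  m <- x; dim(m) <- c(prod(d[-nd]), d[nd])
  dm <- dY; dim(dm) <- c(prod(d[-nd]), ncol(W))
  dx <- dm %*% t(W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(m, dm), db = colSums(dm))
}

dwconv_fwd <- function(x, K, b) .dwconv_fwd_cpp(x, K, b)
dwconv_bwd <- function(dY, x, K) .dwconv_bwd_cpp(dY, x, K)

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, "first"))]
  e <- exp(S - mx)
  e / rowSums(e)
}

# non-overlapping mean pooling along the token (first) dimension of an
# (L, B, D) array; the trailing partial block averages its true count
pool_tokens <- function(x, pool) {
  d <- dim(x)
  L <- d[1]
  Lk <- ceiling(L / pool)
  counts <- rep(pool, Lk)
  counts[Lk] <- L - (Lk - 1L) * pool
  xp <- array(0, c(Lk * pool, d[2], d[3]))
  xp[seq_len(L), , ] <- x
  m <- matrix(xp, pool, Lk * d[2] * d[3])
  s <- colSums(m)
  dim(s) <- c(Lk, d[2], d[3])
  s / counts
}

unpool_grad <- function(ds, pool, L) {
  Lk <- dim(ds)[1]
  counts <- rep(pool, Lk)
  counts[Lk] <- L - (Lk - 1L) * pool
  idx <- ceiling(seq_len(L) / pool)
  ds[idx, , , drop = FALSE] / counts[idx]
}

# ---- dual-branch attention block -------------------------------------------

clo_fwd <- function(x4, pb, n_heads, kv_pool = 1L, train = FALSE,
                    keep_attn = FALSE) {
  d <- dim(x4)
  p <- d[1]; f <- d[2]; B <- d[3]; D <- d[4]
  Dl <- D %/% 2L; Dg <- D - Dl
  L <- p * f
  dh <- Dg %/% n_heads
  Xl <- x4[, , , seq_len(Dl), drop = FALSE]
  Xg <- x4[, , , (Dl + 1L):D, drop = FALSE]

  Ql <- last_mm(Xl, pb$Wq_l, pb$bq_l)
  Kl <- dwconv_fwd(Xl, pb$Kk, pb$bk)
  Vl <- dwconv_fwd(Xl, pb$Kv, pb$bv)
  Sl <- Ql * Kl / sqrt(Dl)
  Al <- 1 / (1 + exp(-Sl))
  Ol <- Al * Vl

  Qg <- last_mm(Xg, pb$Wq_g)
  Kg <- last_mm(Xg, pb$Wk_g)
  Vg <- last_mm(Xg, pb$Wv_g)
  dim(Qg) <- c(L, B, Dg); dim(Kg) <- c(L, B, Dg); dim(Vg) <- c(L, B, Dg)
  if (kv_pool > 1L) {
    Kp <- pool_tokens(Kg, kv_pool)
    Vp <- pool_tokens(Vg, kv_pool)
  } else {
    Kp <- Kg; Vp <- Vg
  }
  Og <- .mha_fwd_cpp(Qg, Kp, Vp, n_heads)
  attn <- NULL
  if (keep_attn) {
    Lk <- dim(Kp)[1]
    attn <- vector("list", B * n_heads)
    for (b in seq_len(B)) {
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        q <- matrix(Qg[, b, cols], L, dh)
        k <- matrix(Kp[, b, cols], Lk, dh)
        attn[[(b - 1L) * n_heads + h]] <-
          softmax_rows(tcrossprod(q, k) / sqrt(dh))
      }
    }
  }
  Og4 <- Og; dim(Og4) <- c(p, f, B, Dg)
  O <- array(c(Ol, Og4), c(p, f, B, D))
  Y <- last_mm(O, pb$Wf, pb$bf)
  cache <- if (train) {
    list(Xl = Xl, Xg = Xg, Ql = Ql, Kl = Kl, Vl = Vl, Al = Al,
         Qg = Qg, Kp = Kp, Vp = Vp, kv_pool = kv_pool, O = O, dims = d)
  } else if (keep_attn) list(attn = attn, dims = d) else NULL
  list(y = Y, cache = cache)
}

clo_bwd <- function(dY, cache, pb, n_heads) {
  d <- cache$dims
  p <- d[1]; f <- d[2]; B <- d[3]; D <- d[4]
  Dl <- D %/% 2L; Dg <- D - Dl
  L <- p * f
  dh <- Dg %/% n_heads

  bw <- last_mm_bwd(dY, cache$O, pb$Wf)
  dO <- bw$dx
  g <- list(Wf = bw$dW, bf = bw$db)

  dOl <- dO[, , , seq_len(Dl), drop = FALSE]
  dOg4 <- dO[, , , (Dl + 1L):D, drop = FALSE]

  # local branch
  dAl <- dOl * cache$Vl
  dVl <- dOl * cache$Al
  dSl <- dAl * cache$Al * (1 - cache$Al)
  dQl <- dSl * cache$Kl / sqrt(Dl)
  dKl <- dSl * cache$Ql / sqrt(Dl)
  bq <- last_mm_bwd(dQl, cache$Xl, pb$Wq_l)
  ck <- dwconv_bwd(dKl, cache$Xl, pb$Kk)
  cv <- dwconv_bwd(dVl, cache$Xl, pb$Kv)
  g$Wq_l <- bq$dW; g$bq_l <- bq$db
  g$Kk <- ck$dK; g$bk <- ck$db
  g$Kv <- cv$dK; g$bv <- cv$db
  dXl <- bq$dx + ck$dx + cv$dx

  # global branch (attention matrices are recomputed in the kernel)
  dOg <- dOg4; dim(dOg) <- c(L, B, Dg)
  gb <- .mha_bwd_cpp(cache$Qg, cache$Kp, cache$Vp, dOg, n_heads)
  dQg <- gb$dQ
  if (cache$kv_pool > 1L) {
    dKg <- unpool_grad(gb$dK, cache$kv_pool, L)
    dVg <- unpool_grad(gb$dV, cache$kv_pool, L)
  } else {
    dKg <- gb$dK; dVg <- gb$dV
  }
  dim(dQg) <- c(p, f, B, Dg); dim(dKg) <- c(p, f, B, Dg)
  dim(dVg) <- c(p, f, B, Dg)
  bqg <- last_mm_bwd(dQg, cache$Xg, pb$Wq_g)
  bkg <- last_mm_bwd(dKg, cache$Xg, pb$Wk_g)
  bvg <- last_mm_bwd(dVg, cache$Xg, pb$Wv_g)
  g$Wq_g <- bqg$dW; g$Wk_g <- bkg$dW; g$Wv_g <- bvg$dW
  dXg <- bqg$dx + bkg$dx + bvg$dx

  dx4 <- array(c(dXl, dXg), d)
  list(dx = dx4, grads = g)
}

#' Dual-branch attention block forward pass
#'
#' Runs one dual-branch attention module on a period x frequency tensor (or
#' a batch of them): the local branch mixes tokens with a depthwise
#' convolution gated by learned per-position attention weights, the global
#' branch applies multi-head softmax attention over all grid positions;
#' branch outputs are concatenated on channels and linearly fused. Shape is
#' preserved.
#'
#' @param x Array `p x f x D` (one tensor) or `p x f x B x D` (a batch).
#' @param weights Block weights from [cloblock_init()].
#' @param n_heads Global-attention heads (default 2).
#' @param kv_pool Key/value pooling factor (default 1, i.e. none).
#' @param return_attn Also return the global-branch attention matrices
#'   (rows sum to 1).
#' @return Array shaped like `x`; with `return_attn = TRUE`, a list with
#'   elements `y` and `attn`.
#' @export
cloblock_forward <- function(x, weights, n_heads = 2, kv_pool = 1,
                             return_attn = FALSE) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  D <- dim(x)[4]
  if (D %% 2 != 0 || (D %/% 2L) %% n_heads != 0) {
    stop("channel count indivisible by branch split / head count",
         call. = FALSE)
  }
  res <- clo_fwd(x, weights, n_heads, kv_pool = as.integer(kv_pool),
                 train = FALSE, keep_attn = return_attn)
  y <- res$y
  if (single) dim(y) <- dim(y)[-3]
  if (return_attn) list(y = y, attn = res$cache$attn) else y
}

# ---- period block -----------------------------------------------------------

tb_fwd <- function(U, pb, cfg, train = FALSE) {
  d <- dim(U)
  T_len <- d[1]; B <- d[2]; D <- d[3]
  hmax <- T_len %/% 2L
  k <- min(cfg$k_periods, hmax)
  Xm <- U; dim(Xm) <- c(T_len, B * D)
  sp <- Mod(stats::mvfft(Xm))[2:(hmax + 1L), , drop = FALSE]
  mx <- .col_max_cpp(sp)
  sp <- sp * rep(ifelse(mx > 0, 1 / mx, 0), each = hmax)
  dim(sp) <- c(hmax * B, D)
  chanavg <- matrix(rowMeans(sp), hmax, B)
  batchA <- rowMeans(chanavg)
  if (all(batchA == 0)) stop("no periodicity: block input is constant",
                             call. = FALSE)
  ord <- order(-batchA, seq_len(hmax))
  fs <- ord[seq_len(k)]
  wA <- chanavg[fs, , drop = FALSE]
  wexp <- exp(sweep(wA, 2, apply(wA, 2, max)))
  w <- sweep(wexp, 2, colSums(wexp), "/")   # k x B aggregation weights

  V <- array(0, d)
  caches <- if (train) vector("list", k) else NULL
  ps <- integer(k)
  for (i in seq_len(k)) {
    f <- fs[i]
    p <- ceiling(T_len / f)
    ps[i] <- p
    pf <- p * f
    Up <- array(0, c(pf, B, D))
    Up[seq_len(T_len), , ] <- U
    dim(Up) <- c(p, f, B, D)
    res <- clo_fwd(Up, pb, cfg$n_heads, kv_pool = cfg$kv_pool, train = train)
    Z <- res$y
    dim(Z) <- c(pf, B, D)
    Z <- Z[seq_len(T_len), , , drop = FALSE]
    V <- V + Z * array(rep(w[i, ], each = T_len), d)
    if (train) caches[[i]] <- res$cache
  }
  list(y = U + V,
       cache = if (train) list(caches = caches, fs = fs, ps = ps, w = w,
                               dims = d) else NULL,
       periods = ps, frequencies = fs, weights = w)
}

tb_bwd <- function(dOut, cache, pb, cfg) {
  d <- cache$dims
  T_len <- d[1]; B <- d[2]; D <- d[3]
  dU <- dOut
  grads <- NULL
  for (i in seq_along(cache$fs)) {
    f <- cache$fs[i]; p <- cache$ps[i]
    pf <- p * f
    dZ <- dOut * array(rep(cache$w[i, ], each = T_len), d)
    dP <- array(0, c(pf, B, D))
    dP[seq_len(T_len), , ] <- dZ
    dim(dP) <- c(p, f, B, D)
    bb <- clo_bwd(dP, cache$caches[[i]], pb, cfg$n_heads)
    dx <- bb$dx
    dim(dx) <- c(pf, B, D)
    dU <- dU + dx[seq_len(T_len), , , drop = FALSE]
    grads <- if (is.null(grads)) bb$grads else {
      Map(`+`, grads, bb$grads)
    }
  }
  list(dx = dU, grads = grads)
}

#' Period-decomposition block forward pass
#'
#' For each of the top-k FFT periods of the (embedded) input series:
#' reshape to a period x frequency tensor, apply the dual-branch attention
#' module, reshape back; aggregate the k branch outputs with
#' softmax-of-amplitude weights and add the block input (residual).
#'
#' @param x Array `T x D` (one series) or `T x B x D` (a batch).
#' @param weights Block weights from [cloblock_init()].
#' @param cfg A [model_config()].
#' @return Array shaped like `x`.
#' @export
times_block_forward <- function(x, weights, cfg) {
  single <- length(dim(x)) == 2L
  if (single) dim(x) <- c(dim(x)[1], 1L, dim(x)[2])
  if (dim(x)[1] < 4) stop("series length must be at least 4", call. = FALSE)
  y <- tb_fwd(x, weights, cfg, train = FALSE)$y
  if (single) dim(y) <- dim(y)[-2]
  y
}

# ---- whole network ----------------------------------------------------------

posenc <- function(T_len, D) {
  pos <- seq_len(T_len) - 1
  P <- matrix(0, T_len, D)
  for (j in seq_len(D)) {
    i <- (j - 1) %/% 2
    ang <- pos / 10000^(2 * i / D)
    P[, j] <- if (j %% 2 == 1) sin(ang) else cos(ang)
  }
  P
}

net_fwd <- function(params, cfg, X, train = FALSE) {
  d <- dim(X)
  T_len <- d[1]; B <- d[2]
  D <- cfg$embed_dim
  E <- last_mm(X, params$W_emb, params$b_emb)
  P <- posenc(T_len, D)
  E <- E + aperm(array(P, c(T_len, D, B)), c(1, 3, 2))
  mask <- NULL
  if (train && cfg$dropout > 0) {
    mask <- array((stats::runif(length(E)) >= cfg$dropout) /
                    (1 - cfg$dropout), dim(E))
    E <- E * mask
  }
  U <- E
  bcaches <- if (train) vector("list", cfg$n_blocks) else NULL
  for (bidx in seq_len(cfg$n_blocks)) {
    res <- tb_fwd(U, params$blocks[[bidx]], cfg, train = train)
    U <- res$y
    if (train) bcaches[[bidx]] <- res$cache
  }
  Y <- last_mm(U, params$W_out, params$b_out)
  dim(Y) <- c(T_len, B)
  list(pred = Y,
       cache = if (train) list(X = X, mask = mask, bcaches = bcaches,
                               U_final = U) else NULL)
}

net_bwd <- function(params, cfg, cache, dY) {
  d <- dim(cache$X)
  T_len <- d[1]; B <- d[2]
  dY3 <- dY; dim(dY3) <- c(T_len, B, 1L)
  bw <- last_mm_bwd(dY3, cache$U_final, params$W_out)
  grads <- list(W_out = bw$dW, b_out = bw$db)
  dU <- bw$dx
  gblocks <- vector("list", cfg$n_blocks)
  for (bidx in rev(seq_len(cfg$n_blocks))) {
    bb <- tb_bwd(dU, cache$bcaches[[bidx]], params$blocks[[bidx]], cfg)
    dU <- bb$dx
    gblocks[[bidx]] <- bb$grads
  }
  grads$blocks <- gblocks
  if (!is.null(cache$mask)) dU <- dU * cache$mask
  be <- last_mm_bwd(dU, cache$X, params$W_emb)
  grads$W_emb <- be$dW
  grads$b_emb <- be$db
  grads
}

#' Count trainable parameters of a configuration
#'
#' Exact tally of trainable scalars, plus float32 storage.
#'
#' @param cfg A [model_config()].
#' @return List with `count`, `bytes` and `mb` (float32 storage).
#' @export
count_parameters <- function(cfg) {
  C <- length(cfg$channels)
  D <- cfg$embed_dim
  Dl <- D %/% 2L
  Dg <- D - Dl
  kl <- cfg$local_kernel
  embed <- C * D + D
  block <- (Dl * Dl + Dl) +            # local query projection
    2 * (kl * kl * Dl + Dl) +          # depthwise key/value convolutions
    3 * Dg * Dg +                      # global q/k/v projections
    (D * D + D)                        # fusion
  head <- D + 1
  count <- embed + cfg$n_blocks * block + head
  list(count = count, bytes = 4 * count, mb = 4 * count / 2^20)
}

# total scalars held in a (possibly nested) parameter list
n_params <- function(params) {
  if (is.list(params)) sum(vapply(params, n_params, numeric(1)))
  else length(params)
}

#' Forward a feature window through a trained model
#'
#' Normalizes the window with the checkpoint's training statistics, runs
#' the network in evaluation mode (deterministic; no dropout) and returns
#' one temperature estimate per time step, in degrees Celsius.
#'
#' @param model A trained `temporal_model` (see [train_temporal_model()]).
#' @param window Numeric matrix `window_length x channels`, raw feature
#'   values with named columns, or a [feature_series()] segment.
#' @return Numeric vector of per-time-step temperature estimates, degC.
#' @export
model_forward <- function(model, window) {
  stopifnot(inherits(model, "temporal_model"))
  if (inherits(window, "feature_series")) window <- window$channels
  cfg <- model$cfg
  if (nrow(window) != cfg$window_length) {
    stop("window length must equal cfg$window_length", call. = FALSE)
  }
  if (!all(cfg$channels %in% colnames(window))) {
    stop("window channels do not match the training configuration",
         call. = FALSE)
  }
  Xn <- normalize_channels(window[, cfg$channels, drop = FALSE], model$norm)
  X <- array(Xn, c(nrow(Xn), 1L, ncol(Xn)))
  pred <- net_fwd(model$params, cfg, X, train = FALSE)$pred
  as.numeric(pred) * model$norm$t_sd + model$norm$t_mean
}

normalize_channels <- function(mat, norm) {
  sweep(sweep(mat, 2, norm$ch_mean, "-"), 2, norm$ch_sd, "/")
}
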