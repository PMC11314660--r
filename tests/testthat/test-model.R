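test_that("dual-branch block preserves shape and zeroes with a zero fusion", {
  cfg <- tiny_model_cfg()
  w <- cloblock_init(cfg, seed = 2)
  for (shape in list(c(3, 2), c(24, 20), c(7, 5))) {
    x <- array(rnorm(prod(shape) * 4), c(shape, 4))
    y <- cloblock_forward(x, w, n_heads = 2)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  w0 <- w; w0$Wf[] <- 0; w0$bf[] <- 0
  x <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  expect_true(all(cloblock_forward(x, w0, n_heads = 2) == 0))
  expect_error(cloblock_forward(array(rnorm(36), c(3, 2, 6)), w, n_heads = 4),
               "indivisible")
})

test_that("global-branch attention rows sum to one", {
  cfg <- tiny_model_cfg()
  w <- cloblock_init(cfg, seed = 5)
  x <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  res <- cloblock_forward(x, w, n_heads = 2, return_attn = TRUE)
  expect_identical(dim(res$y), dim(x))
  for (A in res$attn) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  # pooled keys/values keep rows normalized too
  res2 <- cloblock_forward(x, w, n_heads = 2, kv_pool = 4, return_attn = TRUE)
  for (A in res2$attn) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    expect_equal(ncol(A), ceiling(48 / 4))
  }
})

test_that("period block applies reshape, block, aggregation and residual", {
  cfg <- tiny_model_cfg()
  w <- cloblock_init(cfg, seed = 3)
  t <- 0:31
  x <- cbind(sin(2 * pi * 4 * t / 32), cos(2 * pi * 8 * t / 32),
             rnorm(32, sd = 0.1), rnorm(32, sd = 0.1))
  y <- times_block_forward(x, w, cfg)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  # a zeroed fusion reduces the block to the identity (pure residual)
  w0 <- w; w0$Wf[] <- 0; w0$bf[] <- 0
  expect_equal(times_block_forward(x, w0, cfg), x, tolerance = 1e-12)
  expect_error(times_block_forward(x[1:3, ], w, cfg), "at least 4")
})

test_that("backpropagation matches finite differences through the blocks", {
  set.seed(42)
  cfg <- model_config(channels = letters[1:3], k_periods = 2, embed_dim = 4,
                      n_blocks = 2, n_heads = 2, window_length = 16,
                      dropout = 0, kv_pool = 3)
  params <- ustherm:::init_tin_params(cfg)
  X <- array(rnorm(16 * 2 * 3), c(16, 2, 3))
  Y <- matrix(rnorm(32), 16, 2)
  fw <- ustherm:::net_fwd(params, cfg, X, train = TRUE)
  g <- ustherm:::net_bwd(params, cfg, fw$cache,
                         2 * (fw$pred - Y) / length(fw$pred))
  loss <- function(p) {
    mean((ustherm:::net_fwd(p, cfg, X, train = TRUE)$pred - Y)^2)
  }
  eps <- 1e-6
  # block-2 parameters sit below every period selection, so their gradients
  # are exact; the output head likewise
  for (leaf in names(params$blocks[[2]])) {
    for (ix in seq_len(min(3, length(params$blocks[[2]][[leaf]])))) {
      pa <- params; pa$blocks[[2]][[leaf]][ix] <- pa$blocks[[2]][[leaf]][ix] + eps
      pb <- params; pb$blocks[[2]][[leaf]][ix] <- pb$blocks[[2]][[leaf]][ix] - eps
      num <- (loss(pa) - loss(pb)) / (2 * eps)
      expect_equal(g$blocks[[2]][[leaf]][ix], num, tolerance = 1e-4)
    }
  }
  pa <- params; pa$W_out[1] <- pa$W_out[1] + eps
  pb <- params; pb$W_out[1] <- pb$W_out[1] - eps
  expect_equal(g$W_out[1], (loss(pa) - loss(pb)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("parameter count equals an independent layer-by-layer tally", {
  cfg <- model_config(channels = default_model_channels())
  pc <- count_parameters(cfg)
  # independent tally: embedding, two blocks, head
  embed <- 5 * 16 + 16
  local <- 8 * 8 + 8 + 2 * (3 * 3 * 8 + 8)
  global <- 3 * 8 * 8
  fusion <- 16 * 16 + 16
  head <- 16 + 1
  expect_equal(pc$count, embed + 2 * (local + global + fusion) + head)
  expect_equal(pc$bytes, 4 * pc$count)
  # the initialized parameter tree holds exactly that many scalars
  expect_equal(ustherm:::n_params(ustherm:::init_tin_params(cfg)),
               pc$count)
  # a single 6 -> 16 linear layer with bias
  expect_equal(6 * 16 + 16, 112)
})

test_that("model forward is deterministic in evaluation mode and validates input", {
  cfg <- tiny_model_cfg()
  model <- structure(
    list(cfg = cfg, params = ustherm:::init_tin_params(cfg),
         norm = list(ch_mean = rep(0, 5), ch_sd = rep(1, 5),
                     t_mean = 45, t_sd = 10),
         channels = cfg$channels),
    class = "temporal_model"
  )
  set.seed(1)
  win <- matrix(rnorm(32 * 5), 32, 5,
                dimnames = list(NULL, cfg$channels))
  p1 <- model_forward(model, win)
  p2 <- model_forward(model, win)
  expect_identical(p1, p2)
  expect_length(p1, 32L)
  expect_true(all(is.finite(p1)))
  expect_error(model_forward(model, win[1:10, ]), "window length")
  bad <- win; colnames(bad) <- letters[1:5]
  expect_error(model_forward(model, bad), "channels")
})
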