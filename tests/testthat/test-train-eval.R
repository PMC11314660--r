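test_that("experiment splits honor the ratio, determinism and floor protection", {
  exps <- as.list(1:40)
  s <- split_experiments(exps, 0.7, seed = 1)
  expect_length(s$train, 28L)
  expect_length(s$test, 12L)
  expect_length(intersect(s$train_idx, s$test_idx), 0L)
  expect_setequal(c(s$train_idx, s$test_idx), 1:40)
  s2 <- split_experiments(exps, 0.7, seed = 1)
  expect_identical(s$train_idx, s2$train_idx)
  tiny <- split_experiments(as.list(1:2), 0.7, seed = 3)
  expect_length(tiny$train, 1L)
  expect_length(tiny$test, 1L)
  expect_error(split_experiments(as.list(1), 0.7, 0), "at least 2")
})

test_that("evaluation metrics match hand computations and keep their identities", {
  preds <- list(list(pred = c(26, 28), obs = c(25, 30), times = 1:2))
  rep <- ustherm:::eval_report(preds)
  expect_equal(rep$mse, 2.5)      # errors +1, -2
  expect_equal(rep$mae, 1.5)
  expect_equal(rep$rmse, sqrt(rep$mse), tolerance = 1e-9)
  expect_lte(rep$mae, rep$rmse)

  exact <- ustherm:::eval_report(list(list(pred = c(30, 40), obs = c(30, 40),
                                           times = 1:2)))
  expect_equal(c(exact$mse, exact$rmse, exact$mae), c(0, 0, 0))
  biased <- ustherm:::eval_report(list(list(pred = c(31, 41), obs = c(30, 40),
                                            times = 1:2)))
  expect_equal(c(biased$mse, biased$rmse, biased$mae), c(1, 1, 1))
  # band breakdown is partitioned on the observed temperatures
  wide <- ustherm:::eval_report(list(list(pred = c(26, 35, 50),
                                          obs = c(25, 35, 50), times = 1:3)))
  expect_equal(sum(wide$per_band$n), 3L)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  items <- quick_feature_items(n_exp = 3, n = 120, seed = 7)
  cfg <- tiny_model_cfg(seed = 1)
  tc <- train_config(epochs = 15, patience = 0, stride = 16, batch_size = 8,
                     seed = 5)
  m1 <- train_temporal_model(items, cfg, tc)
  expect_lte(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_temporal_model(items, cfg, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # prediction path: per-step estimates in degC with overlap averaging
  pred <- predict_temperature(m1, items[[1]]$features, stride = 4)
  expect_length(pred, 120L)
  expect_true(all(is.finite(pred)))
  rep <- evaluate(m1, items[2:3], stride = 8)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$per_experiment), 2L)
})

test_that("LSTM baseline respects the parameter budget and the shared protocol", {
  budget <- count_parameters(model_config(channels = default_model_channels()))$count
  C <- 5L
  H <- 2L
  while (ustherm:::lstm_param_count(C, H) < budget) H <- H + 1L
  expect_gte(ustherm:::lstm_param_count(C, H), budget)
  expect_lt(ustherm:::lstm_param_count(C, H - 1L), budget)

  items <- quick_feature_items(n_exp = 4, n = 120, seed = 9)
  tc <- train_config(epochs = 5, patience = 0, stride = 24, batch_size = 8,
                     seed = 2)
  out <- baseline_lstm(items[1:3], items[4], tc, window_length = 32)
  expect_s3_class(out$report, "eval_report")
  expect_identical(out$model$cfg$hidden, H)
  expect_identical(out$model$channels, default_model_channels())
})

test_that("LSTM backpropagation matches finite differences", {
  set.seed(11)
  params <- ustherm:::init_lstm_params(C = 3, H = 4, seed = 13)
  X <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  Y <- matrix(rnorm(20), 10, 2)
  fw <- ustherm:::lstm_fwd(params, X, train = TRUE)
  g <- ustherm:::lstm_bwd(params, fw$cache, 2 * (fw$pred - Y) / 20)
  loss <- function(p) mean((ustherm:::lstm_fwd(p, X)$pred - Y)^2)
  eps <- 1e-6
  for (leaf in c("W", "U", "b", "W_out", "b_out")) {
    for (ix in seq_len(min(3, length(params[[leaf]])))) {
      pa <- params; pa[[leaf]][ix] <- pa[[leaf]][ix] + eps
      pb <- params; pb[[leaf]][ix] <- pb[[leaf]][ix] - eps
      expect_equal(g[[leaf]][ix], (loss(pa) - loss(pb)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("divergent training aborts with a diagnostic", {
  items <- quick_feature_items(n_exp = 2, n = 80, seed = 3)
  cfg <- tiny_model_cfg(seed = 1)
  tc <- train_config(lr = 1e100, epochs = 30, patience = 0, stride = 16,
                     batch_size = 8, seed = 1)
  expect_error(train_temporal_model(items, cfg, tc), "diverged")
})
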