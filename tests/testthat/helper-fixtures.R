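# Shared fixtures. Heavy objects are memoized so the acceptance tests can
# reuse one synthetic study set.

.fixture_env <- new.env(parent = emptyenv())

# The default synthetic study set: 40 heating experiments at the study
# conditions (480 s, 30 fps, full speckle), reduced to feature series.
acceptance_dataset <- function() {
  if (is.null(.fixture_env$feats40)) {
    .fixture_env$feats40 <- synthesize_dataset(40, seed = 0)
  }
  .fixture_env$feats40
}

# A fast, frame-free stand-in for feature items: channels are noisy affine
# and periodic functions of the heating curve, good enough to exercise the
# training loop without simulating images.
quick_feature_items <- function(n_exp = 4, n = 200, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_exp), function(i) {
    t <- 0:(n - 1)
    temps <- 25 + 40 * (1 - exp(-t / 60)) + rnorm(n, 0, 0.05)
    ch <- cbind(
      average_gray_level = 4 + 0.05 * (temps - 25) + rnorm(n, 0, 0.02),
      gray_level_entropy = 1.5 + 0.01 * (temps - 25) + rnorm(n, 0, 0.02),
      gray_temperature_grad = rnorm(n, 2, 0.1),
      mixture_entropy = 2 + 0.02 * (temps - 25) + rnorm(n, 0, 0.02),
      inertia = 3 + 0.5 * sin(2 * pi * t / 20) + rnorm(n, 0, 0.05),
      inverse_difference_moment = 0.8 - 0.002 * (temps - 25) +
        rnorm(n, 0, 0.005)
    )
    list(features = feature_series(t, ch), temps = temps, times = t)
  })
}

# tiny model configuration for fast structural tests
tiny_model_cfg <- function(...) {
  model_config(channels = c("average_gray_level", "gray_level_entropy",
                            "mixture_entropy", "inertia",
                            "inverse_difference_moment"),
               k_periods = 2, embed_dim = 4, n_blocks = 1, n_heads = 2,
               window_length = 32, dropout = 0, ...)
}
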