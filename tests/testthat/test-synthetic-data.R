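test_that("heating law evaluates to its closed form", {
  h <- heating_model(T0 = 25, Tmax = 65, tau = 120, duration = 480)
  tr <- simulate_trace(h, noise_sd = 0)
  expect_length(tr$times, 481L)
  expect_equal(tr$temps[tr$times == 0], 25)
  expect_equal(tr$temps[tr$times == 120], 25 + 40 * (1 - exp(-1)),
               tolerance = 1e-12)
  # asymptote and monotonicity of the noise-free curve
  long <- simulate_trace(heating_model(duration = 12000), noise_sd = 0)
  expect_equal(tail(long$temps, 1), 65, tolerance = 1e-3)
  expect_true(all(diff(tr$temps) >= 0))
})

test_that("heating and texture parameter validation rejects bad inputs", {
  expect_error(heating_model(T0 = 70, Tmax = 65), "T0")
  expect_error(heating_model(tau = 0), "tau")
  expect_error(simulate_trace(heating_model(), noise_sd = -1), "noise_sd")
  expect_error(texture_model(roi_size = 4), "roi_size")
  expect_error(texture_model(sub_periods = list(c(1, 0.5))), "periods")
  expect_error(texture_model(sub_periods = list(c(6, -1))), "amplitudes")
  tr <- simulate_trace(heating_model(duration = 60), 0)
  expect_error(simulate_frames(tr, texture_model(sub_periods = list(c(48, 1)))),
               "half the heating duration")
})

test_that("degenerate texture model yields constant frames and exact coupling", {
  h <- heating_model(duration = 20)
  tr <- simulate_trace(h, noise_sd = 0)
  tex0 <- texture_model(base_mean = 100, avgl_slope = 0, sub_periods = list(),
                        speckle_scale = 0, frame_rate = 5, pattern_amp = 0)
  seq0 <- simulate_frames(tr, tex0, seed = 1)
  expect_length(seq0$frames, 100L)   # span * frame_rate
  expect_true(all(vapply(seq0$frames, function(f) all(f == 100), logical(1))))

  # linear coupling: slope 0.5 and dT = 40 -> 20 gray levels, no other terms
  h2 <- heating_model(T0 = 25, Tmax = 65, tau = 30, duration = 300)
  tr2 <- simulate_trace(h2, noise_sd = 0)
  tex2 <- texture_model(base_mean = 70, avgl_slope = 0.5, sub_periods = list(),
                        speckle_scale = 0, frame_rate = 1, pattern_amp = 0)
  seq2 <- simulate_frames(tr2, tex2, seed = 1)
  dT <- tr2$temps[length(tr2$temps) - 1] - tr2$temps[1]
  expect_equal(mean(seq2$frames[[300]]) - mean(seq2$frames[[1]]),
               round(0.5 * dT), tolerance = 0.5)
})

test_that("frame simulation is bit-identical under a fixed seed", {
  tr <- simulate_trace(heating_model(duration = 10), noise_sd = 0)
  tex <- texture_model(frame_rate = 5, sub_periods = list(c(3, 0.5)))
  a <- simulate_frames(tr, tex, seed = 99)
  b <- simulate_frames(tr, tex, seed = 99)
  expect_identical(a, b)
})

test_that("experiment sets are deterministic and mutually distinct", {
  h <- heating_model(duration = 30)
  tex <- texture_model(frame_rate = 2, roi_size = 16,
                       sub_periods = list(c(6, 1)))
  one <- make_experiment_set(1, h, tex, seed = 3)
  expect_length(one, 1L)
  s1 <- make_experiment_set(5, h, tex, seed = 7)
  s2 <- make_experiment_set(5, h, tex, seed = 7)
  expect_identical(s1, s2)
  # jitter separates the traces pairwise
  temps <- vapply(s1, function(e) e$trace$temps, numeric(31))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gt(max(abs(temps[, i] - temps[, j])), 0)
  }
  expect_equal(s1[[1]]$injected_periods, 6)
})

test_that("noiseless feature series carries the temperature signal and the injected spectra", {
  tex0 <- texture_model(frame_rate = 2, speckle_scale = 0)
  tr0 <- simulate_trace(heating_model(), noise_sd = 0)
  fr0 <- simulate_frames(tr0, tex0, seed = 5)
  prep <- preprocess_sequence(fr0, tr0)
  fs <- extract_feature_series(prep$patches,
                               temperature_trace(prep$times, prep$temps))
  avgl <- fs$channels[, "average_gray_level"]
  expect_gt(cor(avgl, prep$temps), 0.95)
  # spectral ground truth: after removing the heating ramp (whose leakage
  # spans all frequencies), the amplitude spectrum has local maxima exactly
  # at the injected frequency indices (oracle: direct DFT)
  res <- residuals(lm(avgl ~ seq_along(avgl)))
  sp <- Mod(fft(res))[2:(length(res) %/% 2 + 1)]
  T_len <- length(res)
  for (p in c(6, 20, 48)) {
    f <- round(T_len / p)
    expect_gt(sp[f], sp[f - 1])
    expect_gt(sp[f], sp[f + 1])
  }
})
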