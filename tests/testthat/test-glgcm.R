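test_that("Sobel gradient magnitude matches direct kernel convolution", {
  cst <- matrix(42, 5, 5)
  expect_true(all(gradient_image(cst) == 0))

  # vertical step edge: equal positive magnitude along the interior column
  step <- cbind(matrix(0, 6, 3), matrix(255, 6, 3))
  g <- gradient_image(step)
  expect_true(all(g[, c(1, 2, 5, 6)] == 0))
  expect_true(all(g[, 3] == g[2, 3]) && g[2, 3] > 0)

  # worked 3x3 array vs hand-applied kernels with replicate padding
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  pad <- rbind(m[1, ], m, m[3, ])
  pad <- cbind(pad[, 1], pad, pad[, 3])
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  expected <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    w <- pad[i:(i + 2), j:(j + 2)]
    expected[i, j] <- sqrt(sum(w * kx)^2 + sum(w * ky)^2)
  }
  expect_equal(gradient_image(m), expected, tolerance = 1e-12)
  expect_error(gradient_image(matrix(1, 2, 2)), "3x3")
})

test_that("quantization follows the floor rule with degenerate-range handling", {
  cst <- matrix(7, 4, 4)
  q <- quantize_pair(cst, cst * 0, N = 8, M = 8)
  expect_true(all(q$F == 0) && all(q$G == 0))

  two <- matrix(c(0, 255), 1, 2)
  expect_equal(as.vector(quantize_pair(two, two * 0, N = 2, M = 2)$F), c(0, 1))

  ramp <- matrix(0:255, 16, 16)
  qr <- quantize_pair(ramp, ramp * 0, N = 4, M = 4)
  expect_equal(as.vector(table(qr$F)), rep(64L, 4))
  expect_error(quantize_pair(ramp, matrix(0, 2, 2)), "shape")
  expect_equal(qr$f_min, 0); expect_equal(qr$f_max, 255)
})

test_that("GLGCM counts joint occurrences and normalizes to one", {
  q <- structure(list(F = matrix(c(0L, 1L, 0L, 1L), 2, 2),
                      G = matrix(c(0L, 0L, 1L, 1L), 2, 2),
                      N = 2L, M = 2L, f_min = 0, f_max = 1, g_max = 1),
                 class = "quantized_pair")
  g <- build_glgcm(q)
  expect_true(all(g$h == 1))
  expect_true(all(g$H == 0.25))

  cst <- matrix(5, 8, 8)
  g2 <- build_glgcm(quantize_pair(cst, cst * 0, 4, 4))
  expect_equal(g2$h[1, 1], 64L)
  expect_equal(g2$H[1, 1], 1)
  expect_equal(sum(g2$H), 1, tolerance = 1e-12)
})

test_that("descriptors are invariant to scaling the counts and cover all pixels", {
  set.seed(10)
  img <- matrix(sample(0:255, 144, TRUE), 12, 12)
  tiled <- rbind(cbind(img, img), cbind(img, img))
  g1 <- build_glgcm(quantize_pair(img, gradient_image(img), 8, 8))
  # tiling multiplies interior pair counts; compare via the same H directly
  g4 <- g1; g4$h <- g1$h * 4L; g4$H <- g4$h / sum(g4$h)
  expect_equal(compute_features(g1, all_features = TRUE),
               compute_features(g4, all_features = TRUE), tolerance = 1e-12)
  expect_equal(sum(g1$h), 144L)
  expect_identical(dim(tiled), c(24L, 24L))
})

test_that("gray-temperature gradient handles lags, carries and errors", {
  temps <- 25 + (0:29)            # 1 degC per second
  avgl <- 10 + 0.5 * (0:29)       # 0.5 gray per second
  g <- gray_temperature_grad(avgl, temps, lag = 5)
  expect_length(g, 30L)
  expect_true(all(abs(g - 2.0) < 1e-12))
  # constant gray level carries the previous value (0 at start)
  g0 <- gray_temperature_grad(rep(3, 30), temps, lag = 5)
  expect_true(all(g0 == 0))
  expect_error(gray_temperature_grad(avgl, temps, lag = 0), "lag")
  expect_error(gray_temperature_grad(avgl[1:4], temps[1:4], lag = 5),
               "shorter")
})

test_that("feature ranking sorts by |r| and flags degenerate channels", {
  t <- 1:50
  temps <- 25 + 0.5 * t
  ch <- cbind(a = 2 * temps + 1, b = -temps, c = rnorm(50), d = rep(1, 50))
  fs <- feature_series(t, ch)
  tr <- temperature_trace(t, temps)
  expect_warning(rk <- pearson_rank(fs, tr), "zero-variance")
  expect_equal(rk$feature[1:2], c("a", "b"))
  expect_equal(rk$r[rk$feature == "a"], 1.0, tolerance = 1e-12)
  expect_equal(rk$r[rk$feature == "b"], -1.0, tolerance = 1e-12)
  expect_equal(rk$r[rk$feature == "d"], 0)
  expect_true(rk$zero_variance[rk$feature == "d"])
})
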