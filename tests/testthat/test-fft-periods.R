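test_that("a pure integer-frequency sinusoid yields its spectral line", {
  t <- 0:479
  x <- sin(2 * pi * 20 * t / 480)
  pd <- fft_period_select(matrix(x), k = 1)
  expect_equal(pd$frequencies, 20L)
  expect_equal(pd$periods, 24)
  expect_equal(pd$series_length, 480L)
})

test_that("per-channel normalization makes selection amplitude-agnostic", {
  t <- 0:479
  x <- cbind(100 * sin(2 * pi * 10 * t / 480),   # huge amplitude, f = 10
             0.01 * sin(2 * pi * 48 * t / 480))  # tiny amplitude, f = 48
  pd <- fft_period_select(x, k = 2)
  expect_setequal(pd$frequencies, c(10L, 48L))
})

test_that("selection is stable for k beyond the line count and errors sensibly", {
  t <- 0:127
  x <- sin(2 * pi * 8 * t / 128)
  pd <- fft_period_select(matrix(x), k = 2)
  expect_equal(pd$frequencies[1], 8L)
  # second pick is the largest residual bin of the full spectrum
  sp <- Mod(fft(x))[2:65]
  sp <- sp / max(sp)
  expect_equal(pd$frequencies[2], order(-sp, seq_along(sp))[2])
  expect_error(fft_period_select(matrix(rep(1, 64)), 3), "no periodicity")
  expect_error(fft_period_select(matrix(rnorm(64)), 64), "k must")
  expect_error(fft_period_select(matrix(rnorm(3)), 1), "at least 4")
})

test_that("shuffling the time axis changes the selected periods", {
  t <- 0:239
  x <- matrix(sin(2 * pi * 12 * t / 240) + 0.3 * sin(2 * pi * 40 * t / 240))
  orig <- fft_period_select(x, k = 2)$frequencies
  set.seed(8)
  shuf <- fft_period_select(x[sample(240), , drop = FALSE], k = 2)$frequencies
  expect_false(setequal(orig, shuf))
})

test_that("period reshape fills column-major with zero padding", {
  t2 <- reshape_2d(1:6, f = 2, p = 3)
  expect_equal(dim(t2$values), c(3L, 2L))
  expect_equal(t2$values[, 1], c(1, 2, 3))
  expect_equal(t2$values[, 2], c(4, 5, 6))
  expect_equal(t2$pad_length, 0L)

  t3 <- reshape_2d(1:5, f = 2, p = 3)
  expect_equal(t3$pad_length, 1L)
  expect_equal(t3$values[3, 2], 0)
  expect_error(reshape_2d(1:7, f = 2, p = 3), "cover")
})

test_that("inverse reshape inverts exactly and validates capacity", {
  x <- rnorm(29)
  expect_identical(inverse_reshape(reshape_2d(x, f = 5, p = 6)), x)
  expect_error(inverse_reshape(reshape_2d(x, f = 5, p = 6), T_len = 31),
               "capacity")
  # plain-matrix input needs an explicit length
  expect_error(inverse_reshape(matrix(1:6, 3, 2)), "required")
  expect_equal(inverse_reshape(matrix(1:6, 3, 2), 5), 1:5)
})
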