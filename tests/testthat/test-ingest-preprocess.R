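test_that("temporal fusion averages blocks with half-up rounding and drops partial blocks", {
  same <- frame_sequence(rep(list(matrix(100, 4, 4)), 30), 30)
  fused <- temporal_fuse(same, 1)
  expect_length(fused$frames, 1L)
  expect_true(all(fused$frames[[1]] == 100))
  expect_equal(fused$frame_rate, 1)

  # 15 frames of 0 and 15 of 255 -> mean 127.5 -> rounds half-up to 128
  alt <- frame_sequence(rep(list(matrix(0, 2, 2), matrix(255, 2, 2)), 15), 30)
  expect_true(all(temporal_fuse(alt, 1)$frames[[1]] == 128))

  # 35 frames at 30 fps: one complete block, 5 frames dropped
  seq35 <- frame_sequence(rep(list(matrix(7, 2, 2)), 35), 30)
  expect_length(temporal_fuse(seq35, 1)$frames, 1L)

  expect_error(temporal_fuse(same, 60), "exceeds")
})

test_that("fusion preserves the mean of complete blocks to within rounding", {
  set.seed(4)
  frames <- lapply(1:60, function(i) matrix(sample(0:255, 64, TRUE), 8, 8))
  seqr <- frame_sequence(frames, 30)
  fused <- temporal_fuse(seqr, 1)
  for (b in 1:2) {
    idx <- ((b - 1) * 30 + 1):(b * 30)
    block_mean <- mean(Reduce(`+`, frames[idx]) / 30)
    expect_lt(abs(mean(fused$frames[[b]]) - block_mean), 0.5)
  }
})

test_that("mean filter follows the box definition with replicate padding", {
  img <- matrix(0, 3, 3); img[2, 2] <- 9
  expect_equal(mean_filter(img, 3)[2, 2], 1.0)
  # identity cases
  cst <- matrix(5.5, 6, 6)
  expect_equal(mean_filter(cst, 5), cst)
  rnd <- matrix(runif(36), 6, 6)
  expect_equal(mean_filter(rnd, 1), rnd)
  expect_error(mean_filter(rnd, 4), "odd")
  # commutes with adding a constant
  expect_equal(mean_filter(rnd + 3, 3), mean_filter(rnd, 3) + 3,
               tolerance = 1e-12)
  # replicate padding: corner of a constant image stays put
  expect_equal(mean_filter(cst, 3)[1, 1], 5.5)
})

test_that("ROI extraction uses the 0-based half-open convention and rejects overflow", {
  frame <- matrix(seq_len(64 * 64), 64, 64)
  whole <- extract_roi(frame, roi_spec(32, 32, 64))
  expect_identical(whole, frame)
  expect_error(extract_roi(frame, roi_spec(10, 10, 64)), "outside")
  sub <- extract_roi(frame, roi_spec(32, 32, 2))
  expect_identical(sub, frame[32:33, 32:33])   # 0-based rows 31..32
  # idempotence of the centered spec
  again <- extract_roi(whole, roi_spec(32, 32, 64))
  expect_identical(again, whole)
})

test_that("frame directories round-trip through PNG and empty directories error", {
  d <- withr::local_tempdir()
  set.seed(2)
  frames <- lapply(1:3, function(i) matrix(sample(0:255, 16 * 16, TRUE), 16, 16))
  write_frames(frame_sequence(frames, 30), d)
  back <- read_sequence(d, frame_rate = 30)
  expect_length(back$frames, 3L)
  expect_equal(back$frame_rate, 30)
  for (i in 1:3) expect_equal(back$frames[[i]], frames[[i]])
  expect_error(read_sequence(d), "frame_rate")
  empty <- withr::local_tempdir()
  expect_error(read_sequence(empty), "no frames")
})

test_that("uncompressed AVI container round-trips pixels and frame rate", {
  set.seed(3)
  # non-multiple-of-4 width exercises the row stride padding
  frames <- lapply(1:4, function(i) matrix(sample(0:255, 10 * 7, TRUE), 10, 7))
  seqa <- frame_sequence(frames, 25)
  path <- withr::local_tempfile(fileext = ".avi")
  write_avi(seqa, path)
  back <- read_sequence(path)
  expect_length(back$frames, 4L)
  expect_equal(back$frame_rate, 25)
  for (i in 1:4) expect_equal(back$frames[[i]], frames[[i]])
  expect_error(read_avi(withr::local_tempfile(fileext = ".avi")))
})

test_that("alignment pairs frames with nearest trace samples within tolerance", {
  tr <- temperature_trace(0:10, seq(25, 35, by = 1))
  seq1 <- frame_sequence(rep(list(matrix(1, 2, 2)), 8), 1)
  al <- align_with_trace(seq1, tr)
  expect_equal(nrow(al), 8L)
  expect_equal(al$temp_C, 25:32)
  # offset beyond 0.5 s errors (coarse trace makes the mismatch exceed 0.5)
  tr2 <- temperature_trace(seq(0, 10, by = 2), seq(25, 35, by = 2))
  seq_off <- frame_sequence(rep(list(matrix(1, 2, 2)), 3), 1, t0 = 0.9)
  expect_error(align_with_trace(seq_off, tr2), "mismatch")
  # non-1 Hz input rejected
  seq30 <- frame_sequence(rep(list(matrix(1, 2, 2)), 3), 30)
  expect_error(align_with_trace(seq30, tr), "1 Hz")
})
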