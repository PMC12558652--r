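test_that("block averaging produces the documented downsampled size", {
  m <- matrix(rnorm(60 * 90), 60, 90)
  d <- tonotopr:::block_mean(m, 10)
  expect_equal(dim(d), c(6, 9))
  expect_equal(d[1, 1], mean(m[1:10, 1:10]))
  expect_error(tonotopr:::block_mean(matrix(0, 7, 10), 2), "row dimension")
})

test_that("preprocessing preserves a constant movie", {
  mov <- array(5, c(40, 60, 30))
  tt <- data.frame(stimulus = "4", onset_frame = c(10, 20))
  pp <- preprocess_widefield(mov, tt, downsample_factor = 10,
                             pre_frames = 5, post_frames = 5)
  expect_true(all(abs(pp$stimuli[["4"]] - 5) < 1e-12))
})

test_that("the 5x5 box filter spreads a point and conserves intensity", {
  m <- matrix(0, 15, 15); m[8, 8] <- 25
  f <- tonotopr:::box_filter(m, 5)
  expect_true(all(abs(f[6:10, 6:10] - 1) < 1e-12))
  expect_equal(sum(f), 25, tolerance = 1e-9)
})

test_that("df/f arithmetic and errors behave as specified", {
  mov <- array(100, c(6, 8, 20))
  mov[, , 11:20] <- 110
  out <- dff_widefield(mov, onset_frame = 11, fs_hz = 10)
  expect_equal(max(abs(out$response_map - 0.10)), 0, tolerance = 1e-12)
  # response equal to baseline: zero everywhere
  flat <- array(100, c(6, 8, 20))
  out0 <- dff_widefield(flat, onset_frame = 11, fs_hz = 10)
  expect_true(all(out0$response_map == 0))
  bad <- flat; bad[2, 3, 1:10] <- 0
  expect_error(dff_widefield(bad, onset_frame = 11, fs_hz = 10), "1 pixels")
})

test_that("df/f is invariant under multiplicative gain", {
  set.seed(4)
  mov <- array(100 + rnorm(6 * 8 * 20, 0, 2), c(6, 8, 20))
  mov[, , 11:20] <- mov[, , 11:20] + 10
  a <- dff_widefield(mov, 11, fs_hz = 10)$response_map
  b <- dff_widefield(mov * 3.7, 11, fs_hz = 10)$response_map
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("downsampling commutes with addition (linearity)", {
  a <- matrix(rnorm(400), 20, 20)
  b <- matrix(rnorm(400), 20, 20)
  expect_equal(tonotopr:::block_mean(a + b, 5),
               tonotopr:::block_mean(a, 5) + tonotopr:::block_mean(b, 5),
               tolerance = 1e-12)
})

test_that("area localization finds blob centroids and the axis", {
  g <- function(cx, cy) outer(exp(-(seq_len(30) - cy)^2 / 8),
                              exp(-(seq_len(40) - cx)^2 / 8))
  m4 <- g(10, 15); m32 <- g(30, 15)
  ar <- locate_areas(m4, m32, um_per_px = 100)
  expect_lt(abs(ar$centroids_px$lf["x"] - 10), 1)
  expect_lt(abs(ar$centroids_px$hf["x"] - 30), 1)
  expect_equal(unname(ar$axis$direction), c(1, 0), tolerance = 0.05)
  expect_false(ar$degenerate)
  # swapping LF and HF flips the axis
  ar2 <- locate_areas(m32, m4, um_per_px = 100)
  expect_equal(unname(ar2$axis$direction), -unname(ar$axis$direction),
               tolerance = 0.05)
  # identical maps: degenerate flag
  expect_true(locate_areas(m4, m4)$degenerate)
})

test_that("thresholding keeps only the dominant connected component", {
  g <- function(cx, a) a * outer(exp(-(seq_len(30) - 15)^2 / 8),
                                 exp(-(seq_len(40) - cx)^2 / 8))
  m <- g(10, 1) + g(30, 0.4)   # weaker second blob at 40% of max
  ar <- locate_areas(m, g(35, 1), threshold_frac = 0.5)
  expect_true(all(which(ar$masks$lf, arr.ind = TRUE)[, 2] < 20))
})

test_that("empty masks and mismatched shapes are rejected", {
  z <- matrix(0, 10, 10)
  expect_error(locate_areas(z, z), "lower threshold")
  expect_error(locate_areas(matrix(1, 5, 5), matrix(1, 6, 6)), "share a shape")
})
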