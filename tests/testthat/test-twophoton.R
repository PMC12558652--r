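test_that("df/f uses the interpolated 25th percentile baseline", {
  d <- compute_dff(c(1, 1, 1, 3))
  expect_equal(d$f0, 1)          # type-7 quantile of {1,1,1,3} at 0.25
  expect_equal(max(d$values), 2)
  expect_equal(compute_dff(rep(5, 100))$values, rep(0, 100))
})

test_that("df/f is invariant under positive rescaling of the raw trace", {
  set.seed(3)
  raw <- 100 + cumsum(rnorm(500))
  raw <- raw - min(raw) + 10
  d1 <- compute_dff(raw)
  d2 <- compute_dff(raw * 7.3)
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("non-positive baselines are rejected with advice", {
  expect_error(compute_dff(c(-5, -4, -3, 10)), "offset")
  expect_error(compute_dff(numeric(0)), "empty")
})

test_that("motion correction recovers injected integer shifts exactly", {
  p <- make_protocol()
  pop <- sample_population(synth_preset("TR"), 6, p, seed = 2,
                           tuned_only = TRUE)
  tr <- render_traces(pop, p, seed = 2)
  mv <- render_movie_2p(pop, tr$f[1:200, ], motion_sd_px = 2, seed = 9)
  mc <- motion_correct(mv$movie, max_shift_px = 6)
  expect_identical(unname(mc$shifts), unname(-mv$shifts_true))

  # already aligned movie: all shifts zero, and correction is idempotent
  mv0 <- render_movie_2p(pop, tr$f[1:100, ], motion_sd_px = 0, seed = 9)
  mc0 <- motion_correct(mv0$movie, max_shift_px = 4)
  expect_true(all(mc0$shifts == 0L))
  mc1 <- motion_correct(mc$corrected, max_shift_px = 4)
  expect_true(all(mc1$shifts == 0L))
})

test_that("per-frame SSD against the template does not increase", {
  p <- make_protocol()
  pop <- sample_population(synth_preset("TR"), 4, p, seed = 3,
                           tuned_only = TRUE)
  tr <- render_traces(pop, p, seed = 3)
  mv <- render_movie_2p(pop, tr$f[1:120, ], motion_sd_px = 1.5, seed = 4)
  mc <- motion_correct(mv$movie, max_shift_px = 5)
  # the chosen shift's overlap SSD never exceeds the zero-shift SSD
  for (k in seq(1, 120, by = 13)) {
    best <- tonotopr:::.ssd_best_shift(mv$movie[, , k], mc$template, 5)
    ssd_zero <- mean((mv$movie[, , k] - mc$template)^2)
    expect_lte(best$ssd, ssd_zero + 1e-9)
  }
})

test_that("shift search wider than half the frame is rejected", {
  expect_error(motion_correct(array(0, c(16, 16, 3)), max_shift_px = 10),
               "half the frame")
})

test_that("ROI traces are per-frame means over ROI pixels", {
  mov <- array(0, c(8, 8, 4))
  for (k in 1:4) mov[, , k] <- k
  rois <- matrix(0L, 8, 8); rois[2:3, 2:3] <- 1L; rois[6, 6] <- 2L
  tr <- extract_traces(mov, rois)
  expect_equal(unname(tr[, 1]), 1:4)
  # one-pixel ROI equals that pixel's series
  mov[6, 6, ] <- c(9, 8, 7, 6)
  tr <- extract_traces(mov, rois)
  expect_equal(unname(tr[, 2]), c(9, 8, 7, 6))
  expect_error(extract_traces(mov, matrix(0L, 8, 8)), "no ROIs")
})

test_that("noiseless extracted soma traces track the generating trace", {
  p <- make_protocol()
  pop <- sample_population(synth_preset("TR"), 3, p, seed = 6,
                           tuned_only = TRUE)
  pop$noise_sd <- 0
  tr <- render_traces(pop, p, seed = 6)
  mv <- render_movie_2p(pop, tr$f[1:300, ], motion_sd_px = 0,
                        neuropil_gain = 0)
  ext <- extract_traces(mv$movie, mv$rois)
  for (j in 1:3) {
    r <- suppressWarnings(cor(ext[, j], tr$f[1:300, j]))
    if (!is.na(r)) expect_gte(r, 0.99)
  }
})
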