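test_that("noiseless FRA recovery matches the generating support exactly", {
  p <- std_protocol()
  for (shape in c("V", "I", "O")) {
    nr <- gt_neuron(bf_idx = 6, bw_steps = 4, shape = shape,
                    threshold_level = 3)
    amps <- gt_trial_amps(nr, p)
    fra <- build_fra(protocol = p, trial_amps = amps, sigma = 0)
    gt <- make_gt_fra(6, 4, shape, 3)
    expect_identical(fra$sig_mask, gt$region)
    expect_identical(fra$region_mask, gt$region)
    expect_equal(best_frequency(fra), nr$bf_khz)
    expect_equal(classify_shape(fra), shape)
    expect_equal(bandwidths(fra)$bwmax_oct, 4 * protocol_step_oct(p))
  }
})

test_that("a silent response yields an empty significance mask", {
  p <- std_protocol()
  fra <- build_fra(protocol = p, trial_amps = numeric(330), sigma = 0)
  expect_false(any(fra$sig_mask))
  expect_equal(classify_neuron(fra), "silent")
})

test_that("the largest contiguous significant component defines the FRA", {
  p <- std_protocol()
  M <- matrix(0, 11, 6)
  M[2:4, 3:4] <- 1        # 6-cell blob
  M[8:10, 6] <- 1         # 3-cell blob
  fra <- build_fra(protocol = p, trial_amps = amps_from_matrix(M, p),
                   sigma = 0)
  expect_equal(sum(fra$region_mask), 6)
  expect_true(all(which(fra$region_mask, arr.ind = TRUE)[, 1] %in% 2:4))
})

test_that("best frequency averages over levels and breaks ties low", {
  p <- std_protocol()
  M <- matrix(0, 11, 6); M[7, ] <- 1
  fra <- build_fra(protocol = p, trial_amps = amps_from_matrix(M, p), sigma = 0)
  expect_equal(best_frequency(fra), p$frequencies_khz[7])
  M2 <- matrix(0, 11, 6); M2[4, ] <- 1; M2[9, ] <- 1
  fra2 <- build_fra(protocol = p, trial_amps = amps_from_matrix(M2, p), sigma = 0)
  expect_equal(best_frequency(fra2), p$frequencies_khz[4])
  expect_error(best_frequency(build_fra(protocol = p,
                                        trial_amps = numeric(330), sigma = 0)),
               "tuned neurons only")
})

test_that("shape rules follow the region width profile", {
  p <- std_protocol()
  mk <- function(widths_by_level, levels, peak_level = max(levels)) {
    M <- matrix(0, 11, 6)
    for (i in seq_along(levels)) {
      lv <- levels[i]; w <- widths_by_level[i]
      idx <- 6 + (-floor(w / 2)):(ceiling(w / 2))
      M[idx, lv] <- if (lv == peak_level) 1 else 0.8
      M[6, lv] <- if (lv == peak_level) 1 else 0.9
    }
    build_fra(protocol = p, trial_amps = amps_from_matrix(M, p), sigma = 0)
  }
  # widths growing 0..5 steps from 30 to 80 dB: V
  expect_equal(classify_shape(mk(0:5, 1:6)), "V")
  # constant width reaching 80 dB: I
  expect_equal(classify_shape(mk(rep(2, 6), 1:6)), "I")
  # region confined to 40-60 dB, peak at 50 dB: O
  expect_equal(classify_shape(mk(rep(2, 3), 2:4, peak_level = 3)), "O")
})

test_that("bandwidth arithmetic follows the width convention", {
  p <- std_protocol()
  step <- protocol_step_oct(p)
  # region spanning 5 frequencies at one level: BW_max = 4 steps = 1.73 oct;
  # only the central 3 frequencies exceed half peak
  M <- matrix(0, 11, 6); M[4:8, 6] <- c(0.3, 0.8, 1, 0.8, 0.3)
  fra <- build_fra(protocol = p, trial_amps = amps_from_matrix(M, p), sigma = 0)
  bw <- bandwidths(fra)
  expect_equal(bw$bwmax_oct, 4 * step, tolerance = 1e-9)
  expect_equal(bw$halfpeak_bw_oct, 2 * step, tolerance = 1e-9)
  # printed-value check: BF 8.94 kHz, effective band 6.63-12.07 kHz
  expect_equal(bw$effective_range_khz, p$frequencies_khz[c(5, 7)])
  expect_equal(bw$q_value,
               p$frequencies_khz[6] /
                 (p$frequencies_khz[7] - p$frequencies_khz[5]))
  expect_equal(bw$q_value, 1.64, tolerance = 0.005)
  # single effective frequency: zero width, Q missing
  M1 <- matrix(0, 11, 6); M1[6, 6] <- 1
  bw1 <- bandwidths(build_fra(protocol = p, trial_amps = amps_from_matrix(M1, p),
                              sigma = 0))
  expect_equal(bw1$halfpeak_bw_oct, 0)
  expect_true(is.na(bw1$q_value))
})

test_that("monotonicity index follows the BF column and clamps to [0, 1]", {
  p <- std_protocol()
  M <- matrix(0, 11, 6)
  M[6, ] <- c(2, 4, 8, 6, 3, 1) / 8
  fra <- build_fra(protocol = p, trial_amps = amps_from_matrix(M, p), sigma = 0)
  m <- monotonicity(fra)
  expect_equal(m$mi, 1 / 8)
  expect_false(m$monotonic)
  # response at 80 dB equals the maximum: MI = 1
  M2 <- matrix(0, 11, 6); M2[6, ] <- seq(0.2, 1, length.out = 6)
  m2 <- monotonicity(build_fra(protocol = p,
                               trial_amps = amps_from_matrix(M2, p), sigma = 0))
  expect_equal(m2$mi, 1)
  expect_true(m2$monotonic)
})

test_that("MI stays within [0, 1] across random noisy FRAs", {
  p <- std_protocol()
  set.seed(12)
  for (k in 1:20) {
    M <- matrix(0, 11, 6)
    M[4:8, 2:6] <- runif(25)
    M[6, 4] <- 2
    amps <- amps_from_matrix(M, p) + rnorm(330, 0, 0.05)
    fra <- build_fra(protocol = p, trial_amps = amps, sigma = 0.02)
    if (any(fra$region_mask)) {
      mi <- monotonicity(fra)$mi
      if (!is.na(mi)) expect_true(mi >= 0 && mi <= 1)
    }
  }
})

test_that("end-to-end classes partition a mixed population and agree with ground truth", {
  p <- std_protocol()
  pr <- synth_preset("TR")
  pop <- sample_population(pr, 30, p, seed = 14)
  res <- classify_population(pop, p, seed = 14)
  expect_true(all(res$cls_measured %in% c("tuned", "irregular", "silent")))
  expect_gte(mean(res$cls_measured == res$cls), 0.9)
  # noiseless BF and BW recovery is exact for tuned neurons
  tuned <- pop[pop$cls == "tuned", ]
  resn <- classify_population(tuned, p, seed = 14, noiseless = TRUE)
  expect_true(all(resn$cls_measured == "tuned"))
  expect_equal(resn$bf_khz_measured, tuned$bf_khz)
  expect_equal(resn$bwmax_oct, tuned$bw_steps * protocol_step_oct(p))
})
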