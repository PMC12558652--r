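test_that("a zero trace yields no events", {
  det <- detect_transients(rep(0, 2000), fs_hz = 30)
  expect_equal(nrow(det), 0)
})

test_that("a single 5-sigma transient is detected once, near its onset", {
  x <- synth_dff(onsets_s = 20, amps = 0.3, noise_sd = 0.06, seed = 4)
  det <- detect_transients(x, fs_hz = 30)
  expect_equal(nrow(det), 1)
  expect_lte(abs(det$onset_s - 20), 2 / 30)
})

test_that("false-positive rate on pure noise stays below 0.05 events/s", {
  n_ev <- vapply(1:40, function(s) {
    x <- synth_dff(numeric(0), numeric(0), duration_s = 60, seed = s)
    nrow(detect_transients(x, fs_hz = 30))
  }, numeric(1))
  expect_lte(mean(n_ev) / 60, 0.05)
})

test_that("detection count is monotone non-increasing in the noise multiple", {
  x <- synth_dff(c(5, 15, 25, 35, 45), c(0.12, 0.18, 0.25, 0.3, 0.4),
                 noise_sd = 0.05, seed = 7)
  counts <- vapply(c(1.5, 2, 3, 4, 6, 10), function(k)
    nrow(detect_transients(x, detection_params(noise_k = k), fs_hz = 30)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peeling conserves the trace: components + residual = input", {
  x <- synth_dff(c(10, 10.5, 30), c(0.3, 0.3, 0.25), noise_sd = 0, seed = 1)
  pl <- peel(x, fs_hz = 30)
  recon <- rowSums(cbind(pl$components, pl$residual))
  expect_lt(sqrt(mean((recon - x)^2)), 1e-6)
})

test_that("peeling resolves overlapping transients single-pass detection merges", {
  # two equal transients 0.5 s apart overlap into one detection run
  x <- synth_dff(c(10, 10.5), c(0.3, 0.3), noise_sd = 0, seed = 1)
  det <- detect_transients(x, fs_hz = 30)
  expect_equal(nrow(det), 1)
  pl <- peel(x, fs_hz = 30)
  expect_equal(nrow(pl$events), 2)
  expect_equal(sort(pl$events$onset_s), c(10, 10.5), tolerance = 0.1)
  expect_equal(pl$events$amplitude, c(0.3, 0.3), tolerance = 0.15)
})

test_that("well-separated transients: peeling agrees with plain detection", {
  # separation > 5 decay constants
  x <- synth_dff(c(10, 20), c(0.3, 0.3), noise_sd = 0, seed = 1)
  det <- detect_transients(x, fs_hz = 30)
  pl <- peel(x, fs_hz = 30)
  expect_equal(nrow(det), 2)
  expect_equal(nrow(pl$events), 2)
  expect_equal(pl$events$onset_s, det$onset_s, tolerance = 0.05)
})

test_that("evoked amplitude matches flat, rectangular and template inputs", {
  fs <- 30
  flat <- rep(0, 300)
  expect_equal(evoked_amplitude(flat, onset_s = 3, fs_hz = fs), 0)
  # rectangular pulse of height h spanning the peak window
  h <- 0.5
  x <- rep(0, 300); x[95:125] <- h
  expect_equal(evoked_amplitude(x, onset_s = 3, fs_hz = fs), h)
  # known template: measured amplitude within 10% of the template peak
  y <- synth_dff(onsets_s = 5, amps = 0.4, duration_s = 20, noise_sd = 0)
  a <- evoked_amplitude(y, onset_s = 4.95, fs_hz = fs)
  expect_equal(a, 0.4, tolerance = 0.1)
  expect_error(evoked_amplitude(flat, onset_s = 9.8, fs_hz = fs),
               "too close to the end")
})

test_that("BBN reliability counts evoked stimuli and applies the 50% rule", {
  fs <- 30
  onsets <- seq(5, 50, by = 5)          # 10 stimuli
  # responses after 7 of 10 onsets
  x <- synth_dff(onsets[1:7] + 0.1, rep(0.3, 7), duration_s = 60,
                 noise_sd = 0.04, seed = 2)
  r <- bbn_reliability(x, onsets, fs_hz = fs)
  expect_equal(r$success_rate, 0.7)
  expect_true(r$reliable)
  # boundary: 5 of 10 is reliable (inclusive)
  x5 <- synth_dff(onsets[1:5] + 0.1, rep(0.3, 5), duration_s = 60,
                  noise_sd = 0.04, seed = 3)
  r5 <- bbn_reliability(x5, onsets, fs_hz = fs)
  expect_equal(r5$success_rate, 0.5)
  expect_true(r5$reliable)
  # no transients: inactive, rate 0
  r0 <- bbn_reliability(synth_dff(numeric(0), numeric(0), seed = 5,
                                  noise_sd = 0.04),
                        onsets, fs_hz = fs)
  expect_equal(r0$success_rate, 0)
  expect_false(r0$active)
  expect_false(r0$reliable)
})
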