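test_that("class counts follow the preset mixture over seeded replicates", {
  pr <- synth_preset("TR")
  p <- std_protocol()
  n <- 60; reps <- 200
  fracs <- vapply(seq_len(reps), function(s)
    mean(sample_population(pr, n, p, seed = s)$cls == "tuned"), numeric(1))
  se <- sqrt(0.46 * 0.54 / (n * reps))
  expect_lt(abs(mean(fracs) - 0.46), 3 * se)
})

test_that("degenerate mixtures produce a single class", {
  pr <- synth_preset("TR")
  p <- std_protocol()
  pop <- sample_population(pr, 30, p, seed = 5, tuned_only = TRUE)
  expect_true(all(pop$cls == "tuned"))
  expect_true(all(is.finite(pop$bf_khz)))
})

test_that("population sampling is bit-identical under a fixed seed", {
  pr <- synth_preset("CT")
  p <- std_protocol()
  a <- sample_population(pr, 40, p, seed = 123)
  b <- sample_population(pr, 40, p, seed = 123)
  expect_identical(a, b)
  tra <- render_traces(a[1:3, ], p, seed = 9)
  trb <- render_traces(b[1:3, ], p, seed = 9)
  expect_identical(tra$f, trb$f)
  expect_identical(tra$events, trb$events)
})

test_that("sampled best frequencies sit on the tone grid", {
  pr <- synth_preset("TR")
  p <- std_protocol()
  pop <- sample_population(pr, 200, p, seed = 2, tuned_only = TRUE)
  oct <- khz_to_oct(pop$bf_khz)
  expect_true(all(abs(oct / protocol_step_oct(p) -
                        round(oct / protocol_step_oct(p))) < 1e-9))
  expect_true(all(pop$bw_steps >= 1 & pop$bw_steps <= 9))
})

test_that("single-neuron gradient recovery matches the preset target", {
  pr <- synth_preset("TR")
  p <- std_protocol()
  sl <- vapply(1:30, function(s) {
    pop <- sample_population(pr, 481, p, seed = s, tuned_only = TRUE)
    fit_gradient(pop$axis_mm, pop$bf_khz)$slope_oct_per_mm
  }, numeric(1))
  expect_lt(abs(mean(sl) - 1.76), 3 * sd(sl) / sqrt(length(sl)))
})

test_that("generating FRA geometry matches the declared shape and width", {
  for (shape in c("V", "I", "O")) {
    g <- make_gt_fra(bf_idx = 6, bw_steps = 4, shape = shape,
                     threshold_level = 3)
    expect_equal(max(colSums(g$region)) - 1, 4)
    expect_true(all(g$amp[!g$region] == 0))
    expect_true(all(g$amp[g$region] > 0))
    if (shape == "O") expect_equal(sum(g$region[, 6]), 0)
    else expect_gt(sum(g$region[, 6]), 0)
  }
  # widths clipped at the grid edge keep their size by shifting the window
  g <- make_gt_fra(bf_idx = 1, bw_steps = 6, shape = "I", threshold_level = 2)
  expect_equal(max(colSums(g$region)) - 1, 6)
})

test_that("focal-plane sampling recovers the plane-level gradient", {
  pr <- synth_preset("TR")
  sl <- vapply(1:40, function(s) {
    sp <- sample_planes(pr, seed = s)
    fit_gradient(sp$planes$axis_mm, sp$planes$median_bf_khz)$slope_oct_per_mm
  }, numeric(1))
  expect_lt(abs(mean(sl) - 2.13), 3 * sd(sl) / sqrt(length(sl)))
})
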