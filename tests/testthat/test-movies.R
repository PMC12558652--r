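test_that("2P rendering honours motion and geometry contracts", {
  p <- std_protocol()
  pop <- sample_population(synth_preset("TR"), 4, p, seed = 2,
                           tuned_only = TRUE)
  tr <- render_traces(pop, p, seed = 2)
  mv <- render_movie_2p(pop, tr$f[1:50, ], motion_sd_px = 0)
  expect_true(all(mv$shifts_true == 0L))
  expect_equal(sort(unique(as.integer(mv$rois[mv$rois > 0]))),
               seq_len(nrow(pop)))
  bad <- pop; bad$x_um[1] <- 500
  expect_error(render_movie_2p(bad, tr$f[1:50, ]), "outside frame")
  expect_error(render_movie_2p(pop, tr$f[1:50, ], px = 16), "at least 32")
})

test_that("movies round-trip through 16-bit TIFF", {
  arr <- array(runif(16 * 16 * 4, 0, 500), c(16, 16, 4))
  f <- tempfile(fileext = ".tif")
  w <- write_movie_tiff(arr, f)
  back <- read_movie_tiff(f, max_value = attr(w, "max_value"))
  expect_equal(dim(back), dim(arr))
  expect_lt(max(abs(back - arr)) / max(arr), 1e-4)
  rois <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
  f2 <- tempfile(fileext = ".tif")
  write_roi_tiff(rois, f2)
  expect_identical(read_roi_tiff(f2), rois)
})

test_that("wide-field scenes place a pure neuropil response at the tone's map locus", {
  pr <- synth_preset("TR")
  scene <- make_widefield_scene(pr, frame_px = c(60, 100), um_per_px = 20)
  wf <- render_widefield(scene, n_trials = 4, noise_sd = 0, seed = 1)
  pp <- preprocess_widefield(wf$movie, wf$trial_table, downsample_factor = 10,
                             pre_frames = 8, post_frames = 10)
  m4 <- dff_widefield(pp$stimuli[["4"]], pp$onset_index, fs_hz = wf$fs_hz)
  # generating response map: strength envelope times the neuropil tuning,
  # passed through the same downsample + box smoothing as the pipeline
  gen <- scene$strength * exp(-(scene$pref_oct - khz_to_oct(4))^2 /
                                (2 * 0.8^2))
  gen_ds <- tonotopr:::box_filter(tonotopr:::block_mean(gen, 10), 5)
  target <- which(gen_ds == max(gen_ds), arr.ind = TRUE)
  peak <- which(m4$response_map == max(m4$response_map), arr.ind = TRUE)
  expect_lte(abs(peak[1, 2] - target[1, 2]), 1)
  expect_lte(abs(peak[1, 1] - target[1, 1]), 1)
  # zero-response scene gives an identically zero df/f map
  wf0 <- render_widefield(scene, n_trials = 2, amp = 0, noise_sd = 0)
  pp0 <- preprocess_widefield(wf0$movie, wf0$trial_table, downsample_factor = 10,
                              pre_frames = 8, post_frames = 10)
  m0 <- dff_widefield(pp0$stimuli[["4"]], pp0$onset_index, fs_hz = 10)
  expect_true(all(m0$response_map == 0))
  expect_error(render_widefield(scene, n_trials = 0), ">= 1")
})
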