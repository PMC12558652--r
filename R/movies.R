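# Synthetic movie rendering (2P and wide-field) and TIFF I/O.

#' Render a two-photon movie from ground-truth traces
#'
#' Somata are 2-D Gaussian disks placed at the neurons' field-of-view
#' positions and scaled frame-by-frame by their fluorescence traces; an
#' optional smooth neuropil field and optional global integer-pixel motion
#' jitter (recorded as ground truth) are added.
#'
#' @param neurons a [sample_population()] subset with `x_um`, `y_um`.
#' @param traces frames x neurons matrix of raw fluorescence
#'   ([render_traces()] `$f`).
#' @param fov_um field size (µm).
#' @param px frame size in pixels (square, >= 32).
#' @param soma_sigma_um Gaussian soma radius parameter (µm).
#' @param motion_sd_px SD of the per-frame integer jitter (0 = none).
#' @param neuropil_gain amplitude of the smooth neuropil field relative to
#'   the mean soma baseline (0 = none).
#' @param seed integer seed (jitter and neuropil phase).
#' @return list with `movie` (px x px x frames), `rois` (integer label
#'   matrix; label = neuron row index), `shifts_true` (frames x 2, the
#'   applied (dy, dx)).
#' @export
render_movie_2p <- function(neurons, traces, fov_um = 200, px = 64,
                            soma_sigma_um = 6, motion_sd_px = 0,
                            neuropil_gain = 0, seed = 1) {
  stop_if(px < 32, "pixel grid must be at least 32 x 32")
  stop_if(motion_sd_px < 0, "motion_sd_px must be >= 0")
  nn <- nrow(neurons)
  stopifnot(ncol(traces) == nn)
  nf <- nrow(traces)
  um_per_px <- fov_um / px
  set.seed(seed)

  cx <- neurons$x_um / fov_um * (px - 1) + 1
  cy <- neurons$y_um / fov_um * (px - 1) + 1
  stop_if(any(cx < 1 | cx > px | cy < 1 | cy > px), "ROI outside frame")
  sig_px <- soma_sigma_um / um_per_px
  xs <- seq_len(px)
  W <- matrix(0, px * px, nn)
  rois <- matrix(0L, px, px)
  for (j in seq_len(nn)) {
    g <- outer(exp(-(xs - cy[j])^2 / (2 * sig_px^2)),
               exp(-(xs - cx[j])^2 / (2 * sig_px^2)))
    W[, j] <- as.numeric(g)
    rois[g >= exp(-2)] <- j   # mask out to ~2 sigma
  }
  flat <- W %*% t(traces)     # pixels x frames
  if (neuropil_gain > 0) {
    ph <- stats::runif(4, 0, 2 * pi)
    field <- outer(1 + 0.5 * sin(2 * pi * xs / px + ph[1]) * cos(2 * pi * xs / (px / 2) + ph[2]),
                   1 + 0.5 * cos(2 * pi * xs / px + ph[3]) * sin(2 * pi * xs / (px / 3) + ph[4]))
    field <- field / max(field)
    base <- mean(traces)
    flat <- flat + as.numeric(field) * neuropil_gain * base
  }
  movie <- array(flat, c(px, px, nf))
  shifts <- matrix(0L, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  if (motion_sd_px > 0) {
    shifts[, 1] <- as.integer(round(stats::rnorm(nf, 0, motion_sd_px)))
    shifts[, 2] <- as.integer(round(stats::rnorm(nf, 0, motion_sd_px)))
    fill <- stats::median(movie[1, , 1])
    for (k in seq_len(nf))
      movie[, , k] <- .translate_int(movie[, , k], shifts[k, 1], shifts[k, 2], fill)
  }
  list(movie = movie, rois = rois, shifts_true = shifts,
       um_per_px = um_per_px)
}

#' Build a wide-field scene with a smooth tonotopic neuropil map
#'
#' The scene carries, per pixel, a preferred frequency (octaves) following a
#' smooth linear tonotopic gradient along the map's x axis, and a response
#' strength envelope (Gaussian window over the auditory field).  This is the
#' neuropil/dendrite compartment whose summed fluorescence dominates
#' wide-field signals even when the underlying somata are heterogeneous.
#'
#' @param preset a [synth_preset()] (supplies the map gradient slope and axis
#'   extent).
#' @param frame_px c(rows, cols) of the rendered frame.
#' @param um_per_px microns per rendered pixel.
#' @param center_px optional c(row, col) center of the field envelope.
#' @return list of class `wf_scene`: `pref_oct`, `strength`, `um_per_px`,
#'   `axis_extent_mm`, `lf_origin_px`.
#' @export
make_widefield_scene <- function(preset, frame_px = c(150, 240),
                                 um_per_px = 20, center_px = NULL) {
  nr <- frame_px[1]; nc <- frame_px[2]
  if (is.null(center_px)) center_px <- c(nr / 2, nc / 2)
  extent_px <- preset$axis_extent_mm * 1000 / um_per_px
  x0 <- center_px[2] - extent_px / 2
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  pos_mm <- (cols - x0) * um_per_px / 1000
  slope <- preset$widefield_map_slope_oct_per_mm
  grid_oct <- preset$grid_oct
  center_oct <- (min(grid_oct) + max(grid_oct)) / 2
  pref <- clamp(center_oct + slope * (pos_mm - preset$axis_extent_mm / 2),
                min(grid_oct), max(grid_oct))
  strength <- exp(-((rows - center_px[1])^2 / (2 * (nr / 6)^2))) *
    exp(-pmax(0, abs(cols - center_px[2]) - extent_px / 2)^2 / (2 * (extent_px / 8)^2))
  structure(list(pref_oct = pref, strength = strength, um_per_px = um_per_px,
                 axis_extent_mm = preset$axis_extent_mm,
                 lf_origin_px = c(row = center_px[1], col = x0)),
            class = "wf_scene")
}

#' Render a wide-field movie for a two-tone mapping session
#'
#' Repeats the low/high tone `n_trials` times each (interleaved), rendering
#' 800 ms of pre-stimulus frames followed by a stimulus-locked response whose
#' spatial profile follows the scene's tonotopic preference map (Gaussian
#' frequency tuning of the neuropil, width `tuning_sd_oct`).  Somata, when
#' supplied, add small Gaussian blobs with their own (possibly heterogeneous)
#' frequency preferences.
#'
#' @param scene a [make_widefield_scene()].
#' @param stim_khz the two tone frequencies.
#' @param n_trials trials per tone.
#' @param fs_hz frame rate.
#' @param pre_s pre-stimulus baseline per trial (s).
#' @param post_s post-onset duration per trial (s).
#' @param tuning_sd_oct width of the neuropil frequency tuning (octaves).
#' @param amp peak df/f of the neuropil response.
#' @param noise_sd frame noise SD (fraction of baseline).
#' @param neurons optional tuned-neuron data.frame with `axis_mm`, `y_um`,
#'   `bf_khz`, rendered as somatic blobs.
#' @param seed integer seed.
#' @return list with `movie` (rows x cols x frames), `trial_table`
#'   (`stimulus`, `onset_frame`), `fs_hz`.
#' @export
render_widefield <- function(scene, stim_khz = c(4, 32), n_trials = 20,
                             fs_hz = 10, pre_s = 0.8, post_s = 1.2,
                             tuning_sd_oct = 0.8, amp = 0.08,
                             noise_sd = 0.01, neurons = NULL, seed = 1) {
  stop_if(n_trials < 1, "n_trials must be >= 1")
  set.seed(seed)
  nr <- nrow(scene$pref_oct); nc <- ncol(scene$pref_oct)
  pre_f <- ceiling(pre_s * fs_hz); post_f <- ceiling(post_s * fs_hz)
  tl <- pre_f + post_f
  stims <- rep(stim_khz, times = n_trials)
  stims <- stims[sample.int(length(stims))]
  nf <- tl * length(stims)
  baseline <- 100

  resp_maps <- lapply(stim_khz, function(f) {
    m <- scene$strength * exp(-(scene$pref_oct - khz_to_oct(f))^2 /
                                (2 * tuning_sd_oct^2))
    if (!is.null(neurons) && nrow(neurons)) {
      xs_col <- scene$lf_origin_px["col"] + neurons$axis_mm * 1000 / scene$um_per_px
      ys_row <- clamp(nr / 2 + (neurons$y_um - 100) / scene$um_per_px, 1, nr)
      for (j in seq_len(nrow(neurons))) {
        w <- exp(-(khz_to_oct(neurons$bf_khz[j]) - khz_to_oct(f))^2 / (2 * 0.5^2))
        rr <- round(clamp(ys_row[j] + (-2:2), 1, nr))
        cc <- round(clamp(xs_col[j] + (-2:2), 1, nc))
        m[rr, cc] <- m[rr, cc] + 0.3 * w
      }
    }
    m
  })
  names(resp_maps) <- as.character(stim_khz)

  # stimulus-locked temporal profile (rise ~1 frame, slow decay)
  tk <- transient_kernel(fs_hz, tau_rise_s = 0.12, tau_decay_s = 0.8,
                         duration_s = (post_f - 1) / fs_hz)
  movie <- array(0, c(nr, nc, nf))
  onset_frames <- integer(length(stims))
  for (t in seq_along(stims)) {
    f0 <- (t - 1) * tl
    onset_frames[t] <- f0 + pre_f + 1L
    rm <- resp_maps[[as.character(stims[t])]]
    for (k in seq_len(tl)) {
      fr <- baseline * matrix(1, nr, nc)
      if (k > pre_f) fr <- fr * (1 + amp * tk[k - pre_f] * rm)
      if (noise_sd > 0)
        fr <- fr + baseline * matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      movie[, , f0 + k] <- fr
    }
  }
  list(movie = movie,
       trial_table = data.frame(stimulus = stims, onset_frame = onset_frames),
       fs_hz = fs_hz)
}

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' @param movie rows x cols x frames array.
#' @param path output file.
#' @param max_value intensity mapped to the top of the 16-bit range (default:
#'   the movie maximum).
#' @return `path`, invisibly; the scaling factor is returned as attribute
#'   `max_value`.
#' @export
write_movie_tiff <- function(movie, path, max_value = NULL) {
  stopifnot(length(dim(movie)) == 3)
  if (is.null(max_value)) max_value <- max(movie)
  stop_if(max_value <= 0, "movie must have positive intensities")
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(k) clamp(movie[, , k] / max_value, 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(structure(path, max_value = max_value))
}

#' Read a multi-page TIFF as a movie array
#'
#' @param path TIFF file.
#' @param max_value intensity scale applied to the unit-range samples.
#' @return rows x cols x frames array.
#' @export
read_movie_tiff <- function(path, max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * max_value
  arr
}

#' Write an ROI label mask as a 16-bit TIFF
#' @param rois integer label matrix
#' @param path output file
#' @return `path`, invisibly
#' @export
write_roi_tiff <- function(rois, path) {
  tiff::writeTIFF(rois / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an ROI label mask written by [write_roi_tiff()]
#' @param path TIFF file
#' @return integer label matrix
#' @export
read_roi_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
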