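# Wide-field epifluorescence processing: downsampling, trial averaging,
# smoothing, df/f maps, LF/HF area localization and the tonotopic axis.

#' Preprocess a wide-field movie
#'
#' Frames are block-averaged by `downsample_factor` (750x1200 -> 75x120 at
#' the default factor 10), averaged across the trials of each stimulus
#' aligned to onset, then smoothed with a `spatial_kernel` x `spatial_kernel`
#' box filter (reflect padding) and a `temporal_window`-frame moving average.
#'
#' @param movie 3-D array (rows x cols x frames).
#' @param trial_table data.frame with columns `stimulus` and `onset_frame`
#'   (1-based frame index of the stimulus onset).
#' @param downsample_factor integer block size; frame dimensions must be
#'   divisible by it.
#' @param spatial_kernel odd box-filter size in downsampled pixels.
#' @param temporal_window moving-average length in frames.
#' @param pre_frames,post_frames window extracted around each onset.
#' @return list of class `wf_preproc`: `stimuli` (named list of
#'   rows x cols x window arrays), `onset_index` (frame index of the onset
#'   within the window), `downsample_factor`.
#' @export
preprocess_widefield <- function(movie, trial_table, downsample_factor = 10,
                                 spatial_kernel = 5, temporal_window = 3,
                                 pre_frames = 8, post_frames = 12) {
  stopifnot(length(dim(movie)) == 3)
  nr <- dim(movie)[1]; nc <- dim(movie)[2]; nf <- dim(movie)[3]
  stop_if(nr %% downsample_factor != 0,
          "row dimension (", nr, ") not divisible by factor ", downsample_factor)
  stop_if(nc %% downsample_factor != 0,
          "column dimension (", nc, ") not divisible by factor ", downsample_factor)
  stop_if(!all(c("stimulus", "onset_frame") %in% names(trial_table)),
          "trial_table needs columns stimulus, onset_frame")
  stims <- unique(trial_table$stimulus)
  win <- (-pre_frames):(post_frames)
  out <- lapply(stims, function(s) {
    onsets <- trial_table$onset_frame[trial_table$stimulus == s]
    stop_if(length(onsets) < 1, "no trials for stimulus ", s)
    ok <- onsets + min(win) >= 1 & onsets + max(win) <= nf
    onsets <- onsets[ok]
    stop_if(length(onsets) < 1, "no complete trial window for stimulus ", s)
    acc <- array(0, c(nr / downsample_factor, nc / downsample_factor,
                      length(win)))
    for (on in onsets)
      for (k in seq_along(win))
        acc[, , k] <- acc[, , k] + block_mean(movie[, , on + win[k]],
                                              downsample_factor)
    acc <- acc / length(onsets)
    for (k in seq_along(win)) acc[, , k] <- box_filter(acc[, , k], spatial_kernel)
    # centered temporal moving average, edge-truncated
    half <- (temporal_window - 1) %/% 2
    sm <- acc
    for (k in seq_along(win)) {
      idx <- max(1, k - half):min(length(win), k + half)
      sm[, , k] <- apply(acc[, , idx, drop = FALSE], c(1, 2), mean)
    }
    sm
  })
  names(out) <- as.character(stims)
  structure(list(stimuli = out, onset_index = pre_frames + 1L,
                 downsample_factor = downsample_factor),
            class = "wf_preproc")
}

#' Wide-field df/f and response map
#'
#' Pixelwise `df/f = (f - f0)/f0` with `f0` the mean of the frames covering
#' `baseline_s` before the onset; the response map is the mean df/f over the
#' post-onset response window.
#'
#' @param avg_movie rows x cols x frames trial-averaged array.
#' @param onset_frame onset index within the array.
#' @param baseline_s baseline duration before onset (s).
#' @param fs_hz frame rate.
#' @param response_window_s two-element post-onset window (s).
#' @return list with `dff` (same shape as input) and `response_map`.
#' @export
dff_widefield <- function(avg_movie, onset_frame, baseline_s = 0.8,
                          fs_hz = 10, response_window_s = c(0, 1)) {
  stopifnot(length(dim(avg_movie)) == 3)
  nb <- ceiling(baseline_s * fs_hz)
  stop_if(onset_frame - nb < 1, "fewer than ", nb, " baseline frames before onset")
  f0 <- apply(avg_movie[, , (onset_frame - nb):(onset_frame - 1), drop = FALSE],
              c(1, 2), mean)
  bad <- sum(f0 <= 0)
  stop_if(bad > 0, bad, " pixels have baseline f0 <= 0; cannot form df/f")
  dff <- sweep(sweep(avg_movie, c(1, 2), f0, "-"), c(1, 2), f0, "/")
  r0 <- onset_frame + round(response_window_s[1] * fs_hz)
  r1 <- min(dim(avg_movie)[3], onset_frame + round(response_window_s[2] * fs_hz))
  resp <- apply(dff[, , r0:r1, drop = FALSE], c(1, 2), mean)
  list(dff = dff, response_map = resp)
}

#' Locate LF and HF areas and the tonotopic axis
#'
#' Each area mask is the largest 8-connected component of pixels at or above
#' `threshold_frac` of that map's maximum.  Centroids are response-weighted;
#' the tonotopic axis is the unit vector from the LF to the HF centroid with
#' origin at the LF centroid.
#'
#' @param map_lf,map_hf response maps (same shape) for the low- and
#'   high-frequency tone.
#' @param threshold_frac fraction of the map maximum.
#' @param um_per_px microns per (downsampled) pixel.
#' @return list of class `wf_areas`: `masks` (`lf`, `hf`), `centroids_px`,
#'   `centroids_um` (x = column, y = row), `axis` (`origin_um`, `direction`,
#'   `length_mm`), `degenerate` (TRUE when the centroids coincide).
#' @export
locate_areas <- function(map_lf, map_hf, threshold_frac = 0.5, um_per_px = 200) {
  stop_if(!all(dim(map_lf) == dim(map_hf)), "maps must share a shape")
  one <- function(m) {
    thr <- threshold_frac * max(m)
    mask <- m >= thr & max(m) > 0
    stop_if(!any(mask), "empty area mask; lower threshold_frac")
    lab <- label_components(mask, connectivity = 8)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
    w <- pmax(m, 0) * mask
    rows <- row(m); cols <- col(m)
    ctr_px <- c(x = sum(cols * w) / sum(w), y = sum(rows * w) / sum(w))
    list(mask = mask, centroid_px = ctr_px)
  }
  lf <- one(map_lf); hf <- one(map_hf)
  d_px <- hf$centroid_px - lf$centroid_px
  degenerate <- sqrt(sum(d_px^2)) < 1
  dir <- if (degenerate) c(NA_real_, NA_real_) else d_px / sqrt(sum(d_px^2))
  structure(list(
    masks = list(lf = lf$mask, hf = hf$mask),
    centroids_px = list(lf = lf$centroid_px, hf = hf$centroid_px),
    centroids_um = list(lf = lf$centroid_px * um_per_px,
                        hf = hf$centroid_px * um_per_px),
    axis = list(origin_um = lf$centroid_px * um_per_px,
                direction = unname(dir),
                length_mm = sqrt(sum((d_px * um_per_px)^2)) / 1000),
    um_per_px = um_per_px, degenerate = degenerate),
    class = "wf_areas")
}

#' Tonotopic gradient of the wide-field map
#'
#' Assigns every responsive pixel an amplitude-weighted preferred frequency
#' from the LF and HF response maps and fits the tonotopic gradient of those
#' preferences along the axis.
#'
#' @param map_lf,map_hf response maps.
#' @param areas a [locate_areas()] result (supplies axis and pixel scale).
#' @param lf_khz,hf_khz the two tone frequencies.
#' @param min_frac pixels with summed response below `min_frac` times the
#'   maximum are excluded.
#' @return a [fit_gradient()] result.
#' @export
widefield_gradient <- function(map_lf, map_hf, areas, lf_khz = 4, hf_khz = 32,
                               min_frac = 0.2) {
  a <- pmax(map_lf, 0); b <- pmax(map_hf, 0)
  tot <- a + b
  keep <- tot >= min_frac * max(tot) & tot > 0
  pref_oct <- (a * khz_to_oct(lf_khz) + b * khz_to_oct(hf_khz)) / pmax(tot, 1e-12)
  xy_um <- cbind(col(a)[keep], row(a)[keep]) * areas$um_per_px
  pos_mm <- project_to_axis(xy_um, areas$axis)
  fit_gradient(pos_mm, oct_to_khz(pref_oct[keep]))
}
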