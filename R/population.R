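# Ground-truth neuron populations.

#' Construct a ground-truth frequency-response area
#'
#' Builds the generating FRA of one tuned neuron as an amplitude-fraction
#' matrix (frequencies x levels; 1 at the best-frequency / peak-level cell)
#' plus the generating region mask.  Region geometry follows the shape class:
#' V widens by one grid step per level up to the top level, I keeps a constant
#' width reaching the top level, O keeps a constant width confined below the
#' top level.  Within the region, amplitude tapers to `freq_edge_frac` at the
#' frequency edges and to `level_floor_frac` at the threshold level; for a
#' neuron with monotonicity target `mi < 1` the response at the top level is
#' `mi` times the peak.
#'
#' @param bf_idx index of the best frequency on the tone grid (1-based).
#' @param bw_steps maximum region width in grid steps (a region n frequencies
#'   wide has width n-1 steps).
#' @param shape `"V"`, `"I"` or `"O"`.
#' @param threshold_level lowest responsive level index.
#' @param mi generating monotonicity target in `[0, 1]` (ignored for O, which
#'   has no response at the top level).
#' @param n_freq,n_level grid dimensions.
#' @param freq_edge_frac,level_floor_frac amplitude taper fractions.
#' @return list with `amp` (n_freq x n_level matrix of amplitude fractions)
#'   and `region` (logical matrix).
#' @export
make_gt_fra <- function(bf_idx, bw_steps, shape, threshold_level = NULL,
                        mi = 1, n_freq = 11, n_level = 6,
                        freq_edge_frac = 0.95, level_floor_frac = 0.9) {
  stopifnot(bw_steps >= 0, bw_steps <= n_freq - 1, shape %in% c("V", "I", "O"))
  amp <- matrix(0, n_freq, n_level)
  region <- matrix(FALSE, n_freq, n_level)

  # frequency window of a given width (steps) containing bf_idx, shifted to
  # stay on the grid
  fwin <- function(steps) {
    nfr <- steps + 1L
    lo <- bf_idx - floor(steps / 2)
    lo <- min(max(lo, 1L), n_freq - nfr + 1L)
    lo:(lo + nfr - 1L)
  }

  if (shape == "V") {
    top <- n_level
    thr <- max(1L, n_level - bw_steps)
    widths <- pmax(0L, bw_steps - (top - thr:top))
    levels_in <- thr:top
  } else if (shape == "I") {
    top <- n_level
    thr <- if (is.null(threshold_level)) 2L else threshold_level
    thr <- min(thr, top)
    levels_in <- thr:top
    widths <- rep(bw_steps, length(levels_in))
  } else { # O: confined below the top level
    peak_lv <- if (is.null(threshold_level)) 4L else min(threshold_level + 1L, n_level - 1L)
    thr <- max(1L, peak_lv - 1L)
    top <- min(n_level - 1L, peak_lv + 1L)
    levels_in <- thr:top
    widths <- rep(bw_steps, length(levels_in))
  }

  peak_level <- if (shape == "O") levels_in[ceiling(length(levels_in) / 2)]
  else if (mi < 1) n_level - 1L else n_level

  for (k in seq_along(levels_in)) {
    lv <- levels_in[k]
    idx <- fwin(widths[k])
    region[idx, lv] <- TRUE
    # frequency taper: 1 at BF, freq_edge_frac at the window edge
    half <- max(widths[k] / 2, 1e-9)
    d <- abs(idx - bf_idx) / half
    ftap <- 1 - (1 - freq_edge_frac) * pmin(d, 1)
    # level profile: level_floor_frac at threshold rising to 1 at peak level,
    # then mi at levels above the peak
    if (lv <= peak_level) {
      span <- max(peak_level - levels_in[1], 1L)
      ltap <- level_floor_frac + (1 - level_floor_frac) * (lv - levels_in[1]) / span
      if (length(levels_in) == 1L) ltap <- 1
    } else {
      ltap <- if (shape == "O") level_floor_frac else mi
    }
    amp[idx, lv] <- ftap * ltap
  }
  list(amp = amp, region = region)
}

#' Sample a ground-truth neuron population
#'
#' Draws neuron classes, positions, best frequencies and FRA parameters from a
#' preset.  Tuned best frequencies follow the calibrated latent gradient model
#' (see [calibrate_bf_scatter()]): a linear trend in octaves along the
#' caudal-to-rostral axis plus Gaussian scatter, clamped to the tone-grid
#' range and snapped to the nearest protocol tone.
#'
#' @param preset a [synth_preset()].
#' @param n number of neurons.
#' @param protocol a [make_protocol()] protocol (supplies the tone grid).
#' @param seed integer seed.
#' @param tuned_only if TRUE all neurons are tuned (used for FRA-width and
#'   single-neuron gradient studies).
#' @param axis_mm optional fixed axis position (recycled); default uniform
#'   over the preset's axis extent.
#' @return data.frame of class `gt_population`, one row per neuron: `id`,
#'   `x_um`, `y_um`, `axis_mm`, `cls`, `bf_khz`, `bf_idx`, `bw_steps`,
#'   `shape`, `threshold_level`, `mi_target`, `gain_dff`, `noise_sd`,
#'   `tau_rise_s`, `tau_decay_s`, `irregular_rate_hz`.
#' @export
sample_population <- function(preset, n, protocol = make_protocol(), seed = 1,
                              tuned_only = FALSE, axis_mm = NULL) {
  stop_if(n < 1, "n must be >= 1")
  set.seed(seed)
  cf <- unlist(preset$class_fractions)[c("tuned", "irregular", "silent")]
  cls <- if (tuned_only) rep("tuned", n) else
    sample(names(cf), n, replace = TRUE, prob = cf)
  x_um <- stats::runif(n, 0, preset$fov_um)
  y_um <- stats::runif(n, 0, preset$fov_um)
  if (is.null(axis_mm)) axis_mm <- stats::runif(n, 0, preset$axis_extent_mm)
  axis_mm <- rep_len(axis_mm, n)

  grid_oct <- preset$grid_oct
  lat <- preset$gradient$neuron$latent
  bf_oct <- rep(NA_real_, n)
  tuned <- cls == "tuned"
  nt <- sum(tuned)
  if (nt > 0) {
    y <- lat$latent_intercept + lat$slope_latent * axis_mm[tuned] +
      stats::rnorm(nt, 0, lat$sigma_latent)
    y <- clamp(y, min(grid_oct), max(grid_oct))
    bounds <- (grid_oct[-1] + grid_oct[-length(grid_oct)]) / 2
    idx <- findInterval(y, bounds) + 1L
    bf_oct[tuned] <- grid_oct[idx]
  }
  bf_idx <- ifelse(is.na(bf_oct), NA_integer_,
                   match(round(bf_oct, 9), round(grid_oct, 9)))

  bw <- rep(NA_integer_, n)
  shape <- rep(NA_character_, n)
  thr <- rep(NA_integer_, n)
  mi <- rep(NA_real_, n)
  if (nt > 0) {
    bw[tuned] <- sample(seq_along(preset$bwmax_step_probs), nt, replace = TRUE,
                        prob = unlist(preset$bwmax_step_probs))
    sf <- unlist(preset$shape_fractions)[c("V", "I", "O")]
    sh <- sample(names(sf), nt, replace = TRUE, prob = sf)
    # a V region must widen by >= 2 steps; too-narrow draws become I-shaped
    sh[sh == "V" & bw[tuned] < 2] <- "I"
    shape[tuned] <- sh
    thr[tuned] <- sample(2:4, nt, replace = TRUE)
    # monotonicity target: mass at 1 with a half-normal tail below
    m <- 1 - abs(stats::rnorm(nt, 0, preset$mi_sd))
    m[m > 0.97] <- 1
    mi[tuned] <- clamp(m, 0.2, 1)
  }

  out <- data.frame(
    id = seq_len(n), x_um = x_um, y_um = y_um, axis_mm = axis_mm,
    cls = cls, bf_khz = oct_to_khz(bf_oct), bf_idx = bf_idx,
    bw_steps = bw, shape = shape, threshold_level = thr, mi_target = mi,
    gain_dff = preset$peak_gain_dff, noise_sd = preset$noise_sd,
    freq_edge_frac = preset$freq_edge_frac,
    level_floor_frac = preset$level_floor_frac,
    tau_rise_s = preset$tau_rise_s, tau_decay_s = preset$tau_decay_s,
    irregular_rate_hz = ifelse(cls == "irregular", preset$irregular_rate_hz, 0),
    stringsAsFactors = FALSE)
  out$bf_khz[!tuned] <- NA_real_
  class(out) <- c("gt_population", "data.frame")
  attr(out, "preset") <- preset$name
  out
}

#' Sample synthetic focal planes with tuned neurons
#'
#' Emulates the focal-plane level of the study: plane centers are placed along
#' the tonotopic axis; each plane receives a latent median best frequency from
#' the calibrated plane-level gradient model, and its tuned neurons scatter
#' around that latent value with the preset's within-plane spread before
#' snapping to the tone grid.  The latent plane scatter is deflated by the
#' expected sampling noise of the within-plane median so the realized
#' median-BF statistics match the plane-level targets.
#'
#' @param preset a [synth_preset()].
#' @param n_planes number of focal planes (defaults to the preset's study n).
#' @param tuned_per_plane tuned neurons per plane.
#' @param protocol tone protocol supplying the grid.
#' @param seed integer seed.
#' @return list with `planes` (data.frame: `plane`, `axis_mm`,
#'   `median_bf_khz`, `n_tuned`) and `neurons` (data.frame: `plane`,
#'   `axis_mm`, `x_um`, `y_um`, `bf_khz`).
#' @export
sample_planes <- function(preset, n_planes = preset$gradient$plane$n,
                          tuned_per_plane = preset$tuned_per_plane,
                          protocol = make_protocol(), seed = 1) {
  stop_if(n_planes < 2, "need >= 2 planes")
  set.seed(seed)
  grid_oct <- preset$grid_oct
  lat <- preset$gradient$plane$latent
  w <- preset$within_plane_sd_oct
  sigma_adj <- lat$sigma_plane_adj
  slope_adj <- lat$slope_plane_adj
  center <- (min(grid_oct) + max(grid_oct)) / 2
  intercept <- center - slope_adj * preset$axis_extent_mm / 2

  axis <- stats::runif(n_planes, 0, preset$axis_extent_mm)
  latent_med <- intercept + slope_adj * axis +
    stats::rnorm(n_planes, 0, sigma_adj)
  latent_med <- clamp(latent_med, min(grid_oct), max(grid_oct))

  bounds <- (grid_oct[-1] + grid_oct[-length(grid_oct)]) / 2
  neurons <- do.call(rbind, lapply(seq_len(n_planes), function(p) {
    y <- latent_med[p] + stats::rnorm(tuned_per_plane, 0, w)
    y <- clamp(y, min(grid_oct), max(grid_oct))
    idx <- findInterval(y, bounds) + 1L
    data.frame(plane = p, axis_mm = axis[p],
               x_um = stats::runif(tuned_per_plane, 0, preset$fov_um),
               y_um = stats::runif(tuned_per_plane, 0, preset$fov_um),
               bf_khz = oct_to_khz(grid_oct[idx]))
  }))
  med <- vapply(split(neurons$bf_khz, neurons$plane),
                function(v) oct_to_khz(stats::median(khz_to_oct(v))), numeric(1))
  planes <- data.frame(plane = seq_len(n_planes), axis_mm = axis,
                       median_bf_khz = as.numeric(med[as.character(seq_len(n_planes))]),
                       n_tuned = tuned_per_plane)
  list(planes = planes, neurons = neurons)
}
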