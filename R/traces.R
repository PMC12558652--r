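# Fluorescence trace synthesis.

#' Calcium transient template
#'
#' Difference-of-exponentials transient, peak-normalized to 1 (GCaMP6s-like
#' kinetics by default).
#'
#' @param fs_hz sampling rate.
#' @param tau_rise_s,tau_decay_s rise / decay time constants (s).
#' @param duration_s kernel support (s).
#' @return numeric vector starting at the event onset sample.
#' @export
transient_kernel <- function(fs_hz = 30, tau_rise_s = 0.18, tau_decay_s = 1.5,
                             duration_s = 8) {
  stopifnot(tau_rise_s > 0, tau_decay_s > tau_rise_s)
  t <- seq(0, duration_s, by = 1 / fs_hz)
  h <- exp(-t / tau_decay_s) - exp(-t / tau_rise_s)
  h / max(h)
}

.add_events <- function(trace, onset_idx, amps, kernel) {
  n <- length(trace); kl <- length(kernel)
  for (k in seq_along(onset_idx)) {
    i0 <- onset_idx[k]
    if (i0 > n) next
    i1 <- min(n, i0 + kl - 1L)
    trace[i0:i1] <- trace[i0:i1] + amps[k] * kernel[seq_len(i1 - i0 + 1L)]
  }
  trace
}

#' Render raw fluorescence traces for a ground-truth population
#'
#' Tuned neurons emit one transient after every presentation of a
#' frequency-level combination inside their generating FRA region, with
#' amplitude given by the FRA entry times per-trial lognormal jitter.
#' Irregular neurons emit Poisson-timed transients uncorrelated with the
#' stimuli.  Silent neurons emit none.  Gaussian noise is added on the df/f
#' scale and the trace is expressed as raw fluorescence
#' `F = f0 * (1 + signal + noise)` with a positive baseline offset.
#'
#' @param neurons a [sample_population()] data.frame (any subset of rows).
#' @param protocol the [make_protocol()] used for stimulation.
#' @param fs_hz sampling rate (Hz).
#' @param duration_s trace duration; defaults to the protocol duration.
#' @param seed integer seed.
#' @param noise_sd override the per-neuron noise SD (df/f units).
#' @param baseline_f0 raw fluorescence baseline (> 0).
#' @param freq_edge_frac,level_floor_frac FRA taper fractions passed to
#'   [make_gt_fra()].
#' @param amp_jitter_sdlog SD of the lognormal per-trial amplitude jitter
#'   (0 disables jitter).
#' @param response_latency_s delay from stimulus onset to transient onset.
#' @return list with `f` (frames x neurons matrix of raw fluorescence),
#'   `events` (data.frame: `neuron`, `onset_s`, `amp_dff`, `trial` (NA for
#'   spontaneous events)), `fs_hz`, and `baseline_f0`.
#' @export
render_traces <- function(neurons, protocol, fs_hz = 30, duration_s = NULL,
                          seed = 1, noise_sd = NULL, baseline_f0 = 100,
                          freq_edge_frac = NULL, level_floor_frac = NULL,
                          amp_jitter_sdlog = 0.2, response_latency_s = 0.05) {
  stop_if(fs_hz <= 0, "fs_hz must be positive")
  if (is.null(duration_s)) duration_s <- protocol_duration_s(protocol)
  stop_if(duration_s < max(protocol$trials$onset_s) + 2,
          "duration_s must cover all trial onsets plus 2 s")
  set.seed(seed)
  n_frames <- round(duration_s * fs_hz)
  nn <- nrow(neurons)
  f <- matrix(0, n_frames, nn)
  events <- vector("list", nn)
  trials <- protocol$trials

  for (j in seq_len(nn)) {
    nr <- neurons[j, ]
    kern <- transient_kernel(fs_hz, nr$tau_rise_s, nr$tau_decay_s)
    sig <- numeric(n_frames)
    ev <- NULL
    if (nr$cls == "tuned") {
      fef <- if (!is.null(freq_edge_frac)) freq_edge_frac
             else if (!is.null(nr$freq_edge_frac)) nr$freq_edge_frac else 0.95
      lff <- if (!is.null(level_floor_frac)) level_floor_frac
             else if (!is.null(nr$level_floor_frac)) nr$level_floor_frac else 0.9
      fra <- make_gt_fra(nr$bf_idx, nr$bw_steps, nr$shape, nr$threshold_level,
                         mi = nr$mi_target,
                         n_freq = length(protocol$frequencies_khz),
                         n_level = length(protocol$levels_db),
                         freq_edge_frac = fef,
                         level_floor_frac = lff)
      frac <- fra$amp[cbind(trials$freq_idx, trials$level_idx)]
      hit <- which(frac > 0)
      if (length(hit)) {
        jit <- if (amp_jitter_sdlog > 0)
          stats::rlnorm(length(hit), -amp_jitter_sdlog^2 / 2, amp_jitter_sdlog)
        else rep(1, length(hit))
        amps <- nr$gain_dff * frac[hit] * jit
        onsets <- trials$onset_s[hit] + response_latency_s
        ev <- data.frame(neuron = nr$id, onset_s = onsets, amp_dff = amps,
                         trial = hit)
      }
    } else if (nr$cls == "irregular" && nr$irregular_rate_hz > 0) {
      n_ev <- stats::rpois(1, nr$irregular_rate_hz * duration_s)
      if (n_ev > 0) {
        onsets <- sort(stats::runif(n_ev, 0, duration_s - 2))
        jit <- if (amp_jitter_sdlog > 0)
          stats::rlnorm(n_ev, -amp_jitter_sdlog^2 / 2, amp_jitter_sdlog)
        else rep(1, n_ev)
        ev <- data.frame(neuron = nr$id, onset_s = onsets,
                         amp_dff = nr$gain_dff * jit, trial = NA_integer_)
      }
    }
    if (!is.null(ev)) {
      sig <- .add_events(sig, pmax(1L, round(ev$onset_s * fs_hz) + 1L),
                         ev$amp_dff, kern)
      events[[j]] <- ev
    }
    nsd <- if (is.null(noise_sd)) nr$noise_sd else noise_sd
    if (nsd > 0) sig <- sig + stats::rnorm(n_frames, 0, nsd)
    f[, j] <- baseline_f0 * (1 + sig)
  }
  events <- if (length(ev_all <- Filter(Negate(is.null), events)))
    do.call(rbind, ev_all)
  else data.frame(neuron = integer(), onset_s = numeric(),
                  amp_dff = numeric(), trial = integer())
  list(f = f, events = events, fs_hz = fs_hz, baseline_f0 = baseline_f0)
}
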