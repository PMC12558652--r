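# Calcium transient detection, iterative peeling, evoked amplitudes and
# broadband-noise reliability.

#' Detection parameters
#'
#' @param noise_window_s window for the rolling baseline SD (s).
#' @param noise_k threshold in baseline-SD multiples for the peak-amplitude
#'   criterion.
#' @param smooth_tau_s time constant of the exponential IIR smoothing (s).
#' @param min_rise_rate minimum rise rate (df/f per s); default
#'   `noise_k * sigma / 0.4` is filled in at detection time.
#' @param max_iterations peeling iteration cap.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(noise_window_s = 1, noise_k = 3,
                             smooth_tau_s = 0.2, min_rise_rate = NULL,
                             max_iterations = 500, tau_rise_s = 0.18,
                             tau_decay_s = 1.5) {
  stopifnot(noise_window_s > 0, noise_k > 0, smooth_tau_s > 0,
            max_iterations > 0, tau_rise_s > 0, tau_decay_s > tau_rise_s)
  structure(list(noise_window_s = noise_window_s, noise_k = noise_k,
                 smooth_tau_s = smooth_tau_s, min_rise_rate = min_rise_rate,
                 max_iterations = max_iterations, tau_rise_s = tau_rise_s,
                 tau_decay_s = tau_decay_s),
            class = "detection_params")
}

# Baseline noise SD of a df/f trace: SD in rolling windows (noise_window_s),
# summarized by the lower quartile across windows so that windows containing
# transients do not inflate the estimate.
baseline_sigma <- function(values, fs_hz, noise_window_s = 1) {
  w <- max(3L, round(noise_window_s * fs_hz))
  rs <- rolling_sd(values, w)
  max(pctl(rs, 0.25), 1e-12)
}

.detect_core <- function(values, fs_hz, params, sigma = NULL) {
  n <- length(values)
  w <- round(params$noise_window_s * fs_hz)
  stop_if(n <= w, "trace shorter than the noise window")
  # thresholds are relative to the resting df/f level, which is slightly
  # above zero when f0 is a low percentile of the recording
  values <- values - stats::median(values)
  if (is.null(sigma))
    sigma <- baseline_sigma(values, fs_hz, params$noise_window_s)
  ys <- ema_filter(values, fs_hz, params$smooth_tau_s)
  amp_thresh <- params$noise_k * sigma
  # candidate segmentation threshold; the scale-relative floor keeps long
  # exponential tails from merging well-separated events on noiseless traces
  entry <- max(amp_thresh / 2, 0.02 * max(abs(ys)))
  min_rise <- if (is.null(params$min_rise_rate)) amp_thresh / 0.4
              else params$min_rise_rate

  above <- ys > entry
  if (!any(above)) return(list(events = NULL, sigma = sigma, ys = ys))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  # split runs at pronounced interior minima: consecutive transients whose
  # tails keep the smoothed trace above the entry threshold would otherwise
  # merge into one candidate.  A dip must fall below half of the smaller
  # neighbouring peak, so noise ripples on a single transient never split it.
  split_run <- function(a, b) {
    seg <- ys[a:b]
    if (length(seg) < 5) return(matrix(c(a, b), 1))
    pk <- which(diff(sign(diff(seg))) < 0) + 1L
    pk <- pk[seg[pk] > entry]
    if (length(pk) < 2) return(matrix(c(a, b), 1))
    out <- NULL; start <- 1L
    for (i in seq_len(length(pk) - 1L)) {
      lo <- which.min(seg[pk[i]:pk[i + 1]]) + pk[i] - 1L
      if (seg[lo] < 0.5 * min(seg[pk[i]], seg[pk[i + 1]])) {
        out <- rbind(out, c(a + start - 1L, a + lo - 1L))
        start <- lo + 1L
      }
    }
    rbind(out, c(a + start - 1L, b))
  }
  runs <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i)
    split_run(runs[i, 1], runs[i, 2])))

  half_pk <- max(1L, round(0.1 * fs_hz))   # 200 ms peak-averaging window
  base_w <- max(1L, round(0.1 * fs_hz))    # local pre-onset baseline
  slope_w <- max(2L, round(0.1 * fs_hz))   # 100 ms rise-rate window
  # template for the matched-filter amplitude estimate
  kern <- transient_kernel(fs_hz, params$tau_rise_s, params$tau_decay_s,
                           duration_s = min(2, (n - 1) / fs_hz))

  ev <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    seg <- values[a:b]
    pk <- a - 1L + which.max(seg)
    # onset: walk back from the peak to where the smoothed trace last sat
    # near baseline
    on_lim <- max(1L, a - round(0.2 * fs_hz))
    onset <- a
    k <- a
    while (k > on_lim && ys[k - 1L] < entry && ys[k - 1L] > -entry) {
      k <- k - 1L
      if (ys[k] <= max(0.5 * sigma, 0.02 * ys[pk])) { onset <- k; break }
      onset <- k
    }
    # peak amplitude: raw-trace mean over 200 ms centered on the peak, minus
    # the local pre-onset baseline
    pk_lo <- max(1L, pk - half_pk); pk_hi <- min(n, pk + half_pk)
    b_lo <- max(1L, onset - base_w)
    base_val <- mean(values[b_lo:max(b_lo, onset - 1L)])
    amp_win <- mean(values[pk_lo:pk_hi]) - min(base_val, 0)
    # matched-filter amplitude: template least squares from the onset; the
    # long window averages down noise that the short peak window cannot
    i1 <- min(n, onset + length(kern) - 1L)
    kseg <- kern[seq_len(i1 - onset + 1L)]
    amp_fit <- sum(values[onset:i1] * kseg) / sum(kseg * kseg)
    amp <- max(amp_win, amp_fit)
    # rise rate: steepest 100 ms climb of the smoothed trace before the peak
    rr_idx <- onset:pk
    rise <- if (length(rr_idx) > slope_w)
      max(ys[rr_idx[-seq_len(slope_w)]] - ys[rr_idx[seq_len(length(rr_idx) - slope_w)]]) /
        (slope_w / fs_hz)
    else (ys[pk] - ys[onset]) / max((pk - onset) / fs_hz, 1 / fs_hz)
    if (amp >= amp_thresh && rise >= min_rise) {
      ev[[length(ev) + 1L]] <- data.frame(
        onset_s = (onset - 1) / fs_hz, peak_s = (pk - 1) / fs_hz,
        peak_amplitude = amp, rise_rate = rise)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  list(events = events, sigma = sigma, ys = ys)
}

#' Detect calcium transients by amplitude and rise-rate criteria
#'
#' Candidate events are contiguous excursions of the exponentially smoothed
#' df/f trace above half the noise level; the noise level is
#' `noise_k` times the baseline SD, estimated in rolling 1-s windows and
#' summarized over quiet windows.  A candidate is accepted when its peak
#' amplitude (raw-trace mean over 200 ms around the peak, corrected for the
#' 100-ms pre-onset baseline) reaches the noise level and its steepest
#' 100-ms rise is at least `min_rise_rate`.
#'
#' @param dff a [compute_dff()] trace, or a numeric df/f vector (then supply
#'   `fs_hz`).
#' @param params a [detection_params()] list.
#' @param fs_hz sampling rate when `dff` is a bare vector.
#' @return data.frame with `onset_s`, `peak_s`, `peak_amplitude`,
#'   `rise_rate`, sorted by onset (zero rows if nothing detected).
#' @export
detect_transients <- function(dff, params = detection_params(), fs_hz = NULL) {
  if (inherits(dff, "dff_trace")) { values <- dff$values; fs_hz <- dff$fs_hz }
  else { values <- as.numeric(dff); stop_if(is.null(fs_hz), "supply fs_hz") }
  res <- .detect_core(values, fs_hz, params)
  if (is.null(res$events))
    return(data.frame(onset_s = numeric(), peak_s = numeric(),
                      peak_amplitude = numeric(), rise_rate = numeric()))
  res$events[order(res$events$onset_s), , drop = FALSE]
}

#' Decompose a trace into transients by iterative peeling
#'
#' Repeatedly detects the strongest remaining transient, fits the
#' difference-of-exponentials template amplitude to the residual trace by
#' least squares over a short window after the onset (short enough that a
#' second transient half a second later does not contaminate the fit), and
#' subtracts the full-length scaled template.  Detection then runs on the
#' residual, so overlapping events are resolved one at a time.  The sum of
#' all component traces plus the final residual reproduces the input exactly.
#'
#' @inheritParams detect_transients
#' @param tau_rise_s,tau_decay_s template time constants.
#' @param fit_window_s least-squares fit window after the event onset (s).
#' @return list with `events` (as [detect_transients()] plus `amplitude`, the
#'   fitted template amplitude), `residual`, `components` (frames x events
#'   matrix), and `converged` (FALSE when `max_iterations` was hit).
#' @export
peel <- function(dff, params = detection_params(), fs_hz = NULL,
                 tau_rise_s = 0.18, tau_decay_s = 1.5, fit_window_s = 0.45) {
  if (inherits(dff, "dff_trace")) { values <- dff$values; fs_hz <- dff$fs_hz }
  else { values <- as.numeric(dff); stop_if(is.null(fs_hz), "supply fs_hz") }
  n <- length(values)
  kern <- transient_kernel(fs_hz, tau_rise_s, tau_decay_s,
                           duration_s = min(8, (n - 1) / fs_hz))
  sigma <- baseline_sigma(values, fs_hz, params$noise_window_s)
  residual <- values
  comps <- list(); evs <- list()
  used_onsets <- integer()
  converged <- TRUE
  wfit <- max(3L, round(fit_window_s * fs_hz))

  for (it in seq_len(params$max_iterations)) {
    det <- .detect_core(residual, fs_hz, params, sigma = sigma)
    if (is.null(det$events)) break
    cand <- det$events[order(-det$events$peak_amplitude), , drop = FALSE]
    cand_idx <- round(cand$onset_s * fs_hz) + 1L
    fresh <- which(!vapply(cand_idx, function(i)
      any(abs(i - used_onsets) <= 2L), logical(1)))
    if (length(fresh) == 0) break
    pick <- fresh[1]
    i0 <- cand_idx[pick]
    i1 <- min(n, i0 + wfit - 1L)
    kseg <- kern[seq_len(i1 - i0 + 1L)]
    A <- sum(residual[i0:i1] * kseg) / sum(kseg * kseg)
    if (!is.finite(A) || A <= 0) { used_onsets <- c(used_onsets, i0); next }
    comp <- numeric(n)
    j1 <- min(n, i0 + length(kern) - 1L)
    comp[i0:j1] <- A * kern[seq_len(j1 - i0 + 1L)]
    residual <- residual - comp
    comps[[length(comps) + 1L]] <- comp
    e <- cand[pick, , drop = FALSE]
    e$amplitude <- A
    evs[[length(evs) + 1L]] <- e
    used_onsets <- c(used_onsets, i0)
    if (it == params$max_iterations) converged <- FALSE
  }
  if (it == params$max_iterations && !is.null(det$events)) converged <- FALSE
  events <- if (length(evs)) {
    out <- do.call(rbind, evs)
    out[order(out$onset_s), , drop = FALSE]
  } else data.frame(onset_s = numeric(), peak_s = numeric(),
                    peak_amplitude = numeric(), rise_rate = numeric(),
                    amplitude = numeric())
  if (!converged)
    warning("peeling stopped at max_iterations; partial result returned")
  list(events = events, residual = residual,
       components = if (length(comps)) do.call(cbind, comps)
                    else matrix(0, n, 0),
       converged = converged)
}

#' Evoked response amplitude for one stimulus
#'
#' Mean df/f over 200 ms centered on the post-onset peak minus the mean over
#' 100 ms before the stimulus onset.  The peak is searched in
#' `(onset, onset + response_search_s]`.
#'
#' @inheritParams detect_transients
#' @param onset_s stimulus onset (s); may be a vector.
#' @param peak_window_s width of the peak-averaging window (s).
#' @param baseline_window_s width of the pre-onset baseline window (s).
#' @param response_search_s post-onset search window for the peak (s).
#' @return numeric vector of amplitudes (df/f units).
#' @export
evoked_amplitude <- function(dff, onset_s, peak_window_s = 0.2,
                             baseline_window_s = 0.1, response_search_s = 1,
                             fs_hz = NULL) {
  if (inherits(dff, "dff_trace")) { values <- dff$values; fs_hz <- dff$fs_hz }
  else { values <- as.numeric(dff); stop_if(is.null(fs_hz), "supply fs_hz") }
  n <- length(values)
  half_pk <- max(0L, round(peak_window_s * fs_hz / 2))
  bw <- max(1L, round(baseline_window_s * fs_hz))
  sw <- max(1L, round(response_search_s * fs_hz))
  vapply(onset_s, function(on) {
    o <- round(on * fs_hz) + 1L
    stop_if(o + sw > n, "stimulus onset too close to the end of the trace")
    win <- (o + 1L):(o + sw)
    mx <- max(values[win])
    at_max <- win[values[win] == mx]
    pk <- at_max[ceiling(length(at_max) / 2)]  # center of a plateau
    pk_lo <- max(1L, pk - half_pk); pk_hi <- min(n, pk + half_pk)
    b_lo <- max(1L, o - bw); b_hi <- max(1L, o - 1L)
    mean(values[pk_lo:pk_hi]) - mean(values[b_lo:b_hi])
  }, numeric(1))
}

#' Broadband-noise response reliability
#'
#' A stimulus counts as evoked when a detected transient onset falls within
#' 1 s after it.  `success_rate` is the evoked fraction over the stimuli;
#' a neuron is `active` when it shows any transient in the recording and
#' `reliable` when it is active with a success rate of at least 0.5
#' (boundary inclusive).
#'
#' @inheritParams detect_transients
#' @param bbn_onsets stimulus onsets (s).
#' @param evoked_window_s post-onset window defining an evoked response.
#' @return list with `success_rate`, `active`, `reliable`, `events`.
#' @export
bbn_reliability <- function(dff, bbn_onsets, params = detection_params(),
                            evoked_window_s = 1, fs_hz = NULL) {
  stop_if(length(bbn_onsets) < 1, "need at least one stimulus onset")
  ev <- detect_transients(dff, params, fs_hz = fs_hz)
  hit <- vapply(bbn_onsets, function(on)
    any(ev$onset_s > on & ev$onset_s <= on + evoked_window_s), logical(1))
  rate <- mean(hit)
  active <- nrow(ev) > 0
  list(success_rate = rate, active = active,
       reliable = active && rate >= 0.5, events = ev)
}
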