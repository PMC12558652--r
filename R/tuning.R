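# Frequency-response areas and per-neuron tuning metrics.

#' Build a frequency-response area
#'
#' Trial amplitudes are the evoked amplitudes of every presentation
#' ([evoked_amplitude()]); the FRA is their mean over repeats for each of the
#' frequency x level combinations.  A combination is significant when its
#' trial-mean amplitude exceeds `noise_k` times the baseline SD *and* it was
#' evoked (a detected transient onset within the 1-s post-onset window) in at
#' least 3 of 5 repeats.  When more than one contiguous (4-connected) area of
#' significant combinations remains, the largest is taken as the FRA region
#' (ties broken by larger summed response, then by lower frequency).
#'
#' @param dff a [compute_dff()] trace (trace mode), or NULL when supplying
#'   `trial_amps` directly.
#' @param protocol the [make_protocol()] protocol of the recording.
#' @param trial_amps optional vector of per-presentation response amplitudes
#'   aligned with `protocol$trials` (bypasses the trace).
#' @param evoked optional logical vector (per presentation); in trace mode it
#'   is derived from detected transients, in amplitude mode it defaults to
#'   `trial_amps > noise_k * sigma`.
#' @param params [detection_params()].
#' @param sigma baseline noise SD; estimated from the trace, or 0 in
#'   amplitude mode.
#' @param min_evoked_frac fraction of repeats that must be evoked (default
#'   0.6, i.e. 3 of 5).
#' @return object of class `fra`: list with `mean_resp` (n_freq x n_level),
#'   `trial_resp` (n_freq x n_level x n_repeats), `sig_mask`, `region_mask`,
#'   `sigma`, `events`, `n_evoked` (per combination), `protocol`.
#' @export
build_fra <- function(dff = NULL, protocol, trial_amps = NULL, evoked = NULL,
                      params = detection_params(), sigma = NULL,
                      min_evoked_frac = 0.6) {
  trials <- protocol$trials
  n_trial <- nrow(trials)
  nf <- length(protocol$frequencies_khz)
  nl <- length(protocol$levels_db)
  nr <- protocol$n_repeats
  events <- NULL

  if (is.null(trial_amps)) {
    stop_if(is.null(dff), "supply a dff trace or trial_amps")
    stop_if(length(dff$values) < round((max(trials$onset_s) + 1) * dff$fs_hz),
            "trace does not cover the protocol")
    if (is.null(sigma))
      sigma <- baseline_sigma(dff$values, dff$fs_hz, params$noise_window_s)
    events <- detect_transients(dff, params)
    trial_amps <- evoked_amplitude(dff, trials$onset_s)
    if (is.null(evoked))
      evoked <- vapply(trials$onset_s, function(on)
        any(events$onset_s > on & events$onset_s <= on + 1), logical(1))
  } else {
    stop_if(length(trial_amps) != n_trial,
            "trial_amps length must match the protocol (", n_trial, " trials)")
    if (is.null(sigma)) sigma <- 0
    if (is.null(evoked)) evoked <- trial_amps > params$noise_k * sigma
  }

  combo <- (trials$level_idx - 1L) * nf + trials$freq_idx
  mean_resp <- matrix(as.numeric(tapply(trial_amps, factor(combo, levels = seq_len(nf * nl)), mean)), nf, nl)
  n_evoked <- matrix(as.integer(tapply(evoked, factor(combo, levels = seq_len(nf * nl)), sum)), nf, nl)
  trial_resp <- array(NA_real_, c(nf, nl, nr))
  trial_resp[cbind(trials$freq_idx, trials$level_idx, trials$rep_idx)] <- trial_amps

  min_ev <- ceiling(min_evoked_frac * nr)
  sig <- mean_resp > params$noise_k * sigma & n_evoked >= min_ev

  region <- matrix(FALSE, nf, nl)
  if (any(sig)) {
    lab <- label_components(sig, connectivity = 4)
    sizes <- tabulate(lab[lab > 0])
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      sums <- vapply(best, function(b) sum(mean_resp[lab == b]), numeric(1))
      best <- best[sums == max(sums)]
      if (length(best) > 1) {
        lowf <- vapply(best, function(b)
          min((which(lab == b) - 1L) %% nf) + 1L, numeric(1))
        best <- best[which.min(lowf)]
      }
    }
    region <- lab == best[1]
  }

  structure(list(mean_resp = mean_resp, trial_resp = trial_resp,
                 sig_mask = sig, region_mask = region, n_evoked = n_evoked,
                 sigma = sigma, events = events, protocol = protocol),
            class = "fra")
}

#' @export
print.fra <- function(x, ...) {
  cat(sprintf("FRA: %d x %d grid, %d significant combinations, region size %d\n",
              nrow(x$mean_resp), ncol(x$mean_resp), sum(x$sig_mask),
              sum(x$region_mask)))
  invisible(x)
}

#' Classify a neuron as tuned, irregular or silent
#'
#' Silent: no detected transient anywhere in the recording.  Tuned: the FRA
#' has a nonempty significant region (consistent stimulus-locked responses).
#' Irregular: active but without a significant, repeatable frequency-level
#' response.  The classes partition any population.
#'
#' @param fra a [build_fra()] result.
#' @param events optional detection data.frame (defaults to the FRA's own);
#'   in amplitude mode pass the ground-truth or detected events if available.
#' @return one of `"tuned"`, `"irregular"`, `"silent"`.
#' @export
classify_neuron <- function(fra, events = NULL) {
  if (is.null(events)) events <- fra$events
  n_events <- if (is.null(events)) sum(fra$n_evoked) else nrow(events)
  if (n_events == 0) return("silent")
  if (any(fra$region_mask)) "tuned" else "irregular"
}

#' Best frequency of a tuned neuron
#'
#' The frequency with the highest response averaged across all sound levels;
#' ties break toward the lower frequency.
#'
#' @param fra a [build_fra()] result with a nonempty region.
#' @return best frequency in kHz.
#' @export
best_frequency <- function(fra) {
  stop_if(!any(fra$region_mask), "best frequency is defined for tuned neurons only")
  curve <- rowMeans(fra$mean_resp)
  fra$protocol$frequencies_khz[which.max(curve)]
}

#' Classify the FRA shape (V / I / O)
#'
#' Let w(L) be the region width in grid steps at level L over the levels the
#' region spans.  O when the region's peak response does not occur at the
#' highest tested level and the region excludes that level; otherwise V when
#' the region reaches the top level with non-decreasing widths and
#' `w(top) - w(threshold) >= 2` steps; otherwise I when the widths vary by at
#' most one step; otherwise unclassified.
#'
#' @param fra a [build_fra()] result.
#' @return `"V"`, `"I"`, `"O"` or `"unclassified"`.
#' @export
classify_shape <- function(fra) {
  stop_if(!any(fra$region_mask), "shape is defined for tuned neurons only")
  reg <- fra$region_mask
  nl <- ncol(reg)
  levels_in <- which(colSums(reg) > 0)
  w <- colSums(reg)[levels_in] - 1L   # width in grid steps at each level
  peak_cell <- which(fra$mean_resp == max(fra$mean_resp[reg]) & reg,
                     arr.ind = TRUE)
  peak_at_top <- any(peak_cell[, 2] == nl)
  reaches_top <- nl %in% levels_in
  if (!peak_at_top && !reaches_top) return("O")
  if (reaches_top && all(diff(w) >= 0) && (w[length(w)] - w[1]) >= 2)
    return("V")
  if (max(w) - min(w) <= 1) return("I")
  "unclassified"
}

#' Tuning bandwidths and Q value
#'
#' Effective frequencies are those whose level-averaged response exceeds half
#' the maximal response; the half-peak bandwidth is the contiguous run of
#' effective frequencies around the best frequency, `(n - 1)` grid steps in
#' octaves.  `BW_max` is the maximum FRA-region width at any single level (in
#' octaves, same width convention).  Q is the best frequency divided by the
#' half-peak width in kHz (edge-to-edge of the effective band); a
#' single-frequency band has zero width and Q is reported missing.
#'
#' @param fra a [build_fra()] result.
#' @return list with `halfpeak_bw_oct`, `q_value`, `bwmax_oct`,
#'   `effective_range_khz`.
#' @export
bandwidths <- function(fra) {
  stop_if(!any(fra$region_mask), "bandwidths are defined for tuned neurons only")
  step <- protocol_step_oct(fra$protocol)
  freqs <- fra$protocol$frequencies_khz
  curve <- pmax(rowMeans(fra$mean_resp), 0)
  bf_idx <- which.max(curve)
  eff <- curve > max(curve) / 2
  # contiguous run of effective frequencies containing the BF
  lo <- bf_idx; while (lo > 1 && eff[lo - 1]) lo <- lo - 1
  hi <- bf_idx; while (hi < length(eff) && eff[hi + 1]) hi <- hi + 1
  n_eff <- hi - lo + 1
  halfpeak <- (n_eff - 1) * step
  width_khz <- freqs[hi] - freqs[lo]
  q <- if (n_eff > 1) freqs[bf_idx] / width_khz else NA_real_
  bwmax <- (max(colSums(fra$region_mask)) - 1) * step
  list(halfpeak_bw_oct = halfpeak, q_value = q, bwmax_oct = bwmax,
       effective_range_khz = c(freqs[lo], freqs[hi]))
}

#' Monotonicity index
#'
#' The neuron's response at the highest tested intensity divided by its
#' maximum response across intensities, computed on the best-frequency
#' column with responses clamped at zero.  1 indicates a monotonically
#' increasing intensity response; values below 0.5 flag intensity-tuned
#' (non-monotonic) neurons.
#'
#' @param fra a [build_fra()] result.
#' @param column `"bf"` (default) computes MI on the BF column; `"global"`
#'   uses the matrix-wide maximum cell's column.
#' @return list with `mi` (in `[0, 1]`, or NA when the maximum response is 0)
#'   and `monotonic` (`mi >= 0.5`).
#' @export
monotonicity <- function(fra, column = c("bf", "global")) {
  column <- match.arg(column)
  stop_if(!any(fra$region_mask), "MI is defined for tuned neurons only")
  curve <- rowMeans(fra$mean_resp)
  idx <- if (column == "bf") which.max(curve)
  else which(fra$mean_resp == max(fra$mean_resp), arr.ind = TRUE)[1, 1]
  col <- pmax(fra$mean_resp[idx, ], 0)
  mx <- max(col)
  if (mx <= 0) return(list(mi = NA_real_, monotonic = NA))
  mi <- clamp(col[length(col)] / mx, 0, 1)
  list(mi = mi, monotonic = mi >= 0.5)
}

#' Full tuning analysis of one neuron
#'
#' Convenience wrapper: builds the FRA, classifies the neuron, and computes
#' BF, shape, bandwidths and MI for tuned neurons.
#'
#' @inheritParams build_fra
#' @return one-row data.frame: `cls`, `bf_khz`, `bf_oct`, `shape`,
#'   `halfpeak_bw_oct`, `q_value`, `bwmax_oct`, `mi`, `monotonic`,
#'   `n_events`.
#' @export
analyze_tuning <- function(dff = NULL, protocol, trial_amps = NULL,
                           evoked = NULL, params = detection_params(),
                           sigma = NULL) {
  fra <- build_fra(dff, protocol, trial_amps = trial_amps, evoked = evoked,
                   params = params, sigma = sigma)
  cls <- classify_neuron(fra)
  out <- data.frame(cls = cls, bf_khz = NA_real_, bf_oct = NA_real_,
                    shape = NA_character_, halfpeak_bw_oct = NA_real_,
                    q_value = NA_real_, bwmax_oct = NA_real_, mi = NA_real_,
                    monotonic = NA,
                    n_events = if (is.null(fra$events)) sum(fra$n_evoked)
                               else nrow(fra$events),
                    stringsAsFactors = FALSE)
  if (cls == "tuned") {
    out$bf_khz <- best_frequency(fra)
    out$bf_oct <- khz_to_oct(out$bf_khz)
    out$shape <- classify_shape(fra)
    bw <- bandwidths(fra)
    out$halfpeak_bw_oct <- bw$halfpeak_bw_oct
    out$q_value <- bw$q_value
    out$bwmax_oct <- bw$bwmax_oct
    m <- monotonicity(fra)
    out$mi <- m$mi
    out$monotonic <- m$monotonic
  }
  out
}
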