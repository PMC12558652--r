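#' Build a pure-tone stimulation protocol
#'
#' Constructs the frequency x level x repeat stimulus grid used for
#' frequency-response-area (FRA) mapping, with a seeded random presentation
#' order.  The standard protocol is 11 tones geometrically spaced from 2 to
#' 40 kHz at 6 levels (30-80 dB SPL), 5 repeats: 330 presentations over 66
#' unique combinations.
#'
#' @param f_min_khz,f_max_khz lowest / highest tone frequency (kHz).
#' @param n_freq number of tone frequencies (geometric spacing).
#' @param levels_db sound levels in dB SPL, ascending.
#' @param n_repeats presentations per frequency-level combination.
#' @param tone_duration_s stimulus duration in seconds.
#' @param iti_s silent interval between stimulus offsets and the next onset.
#' @param lead_in_s silence before the first onset.
#' @param seed integer seed for the presentation order.
#' @return An object of class `tone_protocol`: list with `frequencies_khz`,
#'   `levels_db`, `n_repeats`, `tone_duration_s`, `iti_s`, and `trials`, a
#'   data.frame with columns `freq_idx`, `level_idx`, `rep_idx`, `onset_s`.
#' @examples
#' p <- make_protocol()
#' nrow(p$trials)                       # 330
#' length(p$frequencies_khz) * length(p$levels_db)  # 66 combinations
#' @export
make_protocol <- function(f_min_khz = 2, f_max_khz = 40, n_freq = 11,
                          levels_db = seq(30, 80, by = 10), n_repeats = 5,
                          tone_duration_s = 0.1, iti_s = 2.9,
                          lead_in_s = 2, seed = 1) {
  stop_if(f_min_khz <= 0 || f_max_khz <= 0, "frequencies must be positive")
  stop_if(f_min_khz >= f_max_khz, "f_min_khz must be below f_max_khz")
  stop_if(n_freq < 2, "need at least 2 frequencies")
  stop_if(length(levels_db) == 0, "levels_db must be nonempty")
  stop_if(n_repeats < 1, "n_repeats must be >= 1")

  freqs <- f_min_khz * (f_max_khz / f_min_khz)^(seq(0, n_freq - 1) / (n_freq - 1))
  combos <- expand.grid(freq_idx = seq_len(n_freq),
                        level_idx = seq_along(levels_db),
                        rep_idx = seq_len(n_repeats))
  set.seed(seed)
  ord <- sample.int(nrow(combos))
  trials <- combos[ord, , drop = FALSE]
  rownames(trials) <- NULL
  period <- tone_duration_s + iti_s
  trials$onset_s <- lead_in_s + (seq_len(nrow(trials)) - 1) * period

  structure(list(frequencies_khz = freqs,
                 levels_db = sort(levels_db),
                 n_repeats = n_repeats,
                 tone_duration_s = tone_duration_s,
                 iti_s = iti_s,
                 lead_in_s = lead_in_s,
                 trials = trials),
            class = "tone_protocol")
}

#' @export
print.tone_protocol <- function(x, ...) {
  cat(sprintf("Tone protocol: %d frequencies (%.3g-%.3g kHz) x %d levels (%g-%g dB SPL) x %d repeats\n",
              length(x$frequencies_khz), min(x$frequencies_khz), max(x$frequencies_khz),
              length(x$levels_db), min(x$levels_db), max(x$levels_db), x$n_repeats))
  cat(sprintf("  %d presentations, grid step %.3f octaves, last onset %.1f s\n",
              nrow(x$trials), protocol_step_oct(x), max(x$trials$onset_s)))
  invisible(x)
}

#' Octave spacing between adjacent protocol frequencies
#' @param protocol a `tone_protocol`
#' @return step size in octaves (log2 ratio of adjacent frequencies)
#' @export
protocol_step_oct <- function(protocol) {
  f <- protocol$frequencies_khz
  log2(f[2] / f[1])
}

#' Total recording duration implied by a protocol
#' @param protocol a `tone_protocol`
#' @param tail_s silence appended after the last onset (seconds)
#' @return duration in seconds
#' @export
protocol_duration_s <- function(protocol, tail_s = 4) {
  max(protocol$trials$onset_s) + tail_s
}

#' Snap frequencies to the nearest protocol grid tone
#'
#' @param f_khz frequencies in kHz (or octaves if `oct = TRUE`, re 2 kHz)
#' @param protocol a `tone_protocol`
#' @param oct interpret and return octaves instead of kHz
#' @return snapped values on the protocol grid
#' @export
snap_to_grid <- function(f_khz, protocol, oct = FALSE) {
  grid_oct <- khz_to_oct(protocol$frequencies_khz)
  x <- if (oct) f_khz else khz_to_oct(f_khz)
  bounds <- (grid_oct[-1] + grid_oct[-length(grid_oct)]) / 2
  idx <- findInterval(x, bounds) + 1L
  if (oct) grid_oct[idx] else protocol$frequencies_khz[idx]
}
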