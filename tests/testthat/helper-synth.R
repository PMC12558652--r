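# Shared fixtures, built in code.

std_protocol <- function(seed = 1) make_protocol(seed = seed)

# One hand-built tuned neuron row, compatible with render_traces /
# gt_trial_amps without going through sample_population.
gt_neuron <- function(id = 1, cls = "tuned", bf_idx = 5, bw_steps = 3,
                      shape = "I", threshold_level = 2, mi_target = 1,
                      gain_dff = 0.3, noise_sd = 0.06,
                      irregular_rate_hz = 0) {
  data.frame(id = id, x_um = 100, y_um = 100, axis_mm = 0.6, cls = cls,
             bf_khz = 2 * 20^((bf_idx - 1) / 10), bf_idx = bf_idx,
             bw_steps = bw_steps, shape = shape,
             threshold_level = threshold_level, mi_target = mi_target,
             gain_dff = gain_dff, noise_sd = noise_sd,
             freq_edge_frac = 0.95, level_floor_frac = 0.9,
             tau_rise_s = 0.18, tau_decay_s = 1.5,
             irregular_rate_hz = irregular_rate_hz,
             stringsAsFactors = FALSE)
}

# A df/f vector containing transients of given amplitudes at given onsets
# (seconds), over Gaussian noise.
synth_dff <- function(onsets_s, amps, duration_s = 60, fs_hz = 30,
                      noise_sd = 0.06, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs_hz)
  x <- rnorm(n, 0, noise_sd)
  kern <- transient_kernel(fs_hz)
  for (k in seq_along(onsets_s)) {
    i0 <- round(onsets_s[k] * fs_hz) + 1L
    i1 <- min(n, i0 + length(kern) - 1L)
    x[i0:i1] <- x[i0:i1] + amps[k] * kern[seq_len(i1 - i0 + 1L)]
  }
  x
}

# Build per-trial amplitudes realizing a given freq x level response matrix.
amps_from_matrix <- function(M, protocol) {
  M[cbind(protocol$trials$freq_idx, protocol$trials$level_idx)]
}
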