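# Generating parameters for the two synthetic neuron populations.
#
# TR: thalamocortical-recipient-like - tonotopic gradient, narrow tuning.
# CT: corticothalamic-like - no somatic tonotopy, broad tuning, but a smooth
#     tonotopic neuropil field (wide-field maps remain tonotopic).
#
# Gradient entries give the *measured* population statistics the generator is
# calibrated to reproduce (OLS slope in octaves/mm and Pearson R of
# log2-best-frequency against caudal->rostral axis position), at the neuron
# and focal-plane level, together with the study sample sizes.
#
# bwmax_step_probs: probability of each maximum FRA width (1..9 grid steps of
# 0.432 octaves); medians 3 steps (TR, ~1.29 oct) and 7 steps (CT, ~3.01 oct).

common:
  axis_extent_mm: 1.2
  fov_um: 200
  fs_hz: 30
  tau_rise_s: 0.18
  tau_decay_s: 1.5
  response_latency_s: 0.05
  noise_sd: 0.06          # additive Gaussian noise on the df/f scale
  peak_gain_dff: 0.30     # max-gain transient peak = 5 x noise_sd
  amp_jitter_sdlog: 0.2   # per-trial multiplicative (lognormal) jitter
  irregular_rate_hz: 0.03 # Poisson rate of stimulus-unlocked transients
  baseline_f0: 100        # raw fluorescence offset (arbitrary units)
  freq_edge_frac: 0.95    # FRA amplitude at the frequency edges of the region
  level_floor_frac: 0.90  # FRA amplitude at the threshold level
  mi_sd: 0.2              # spread of the monotonicity-index mixture (V/I cells)
  widefield_map_slope_oct_per_mm: 2.13

TR:
  class_fractions: {tuned: 0.46, irregular: 0.41, silent: 0.13}
  gradient:
    neuron: {slope_oct_per_mm: 1.76, pearson_r: 0.52, "n": 481}
    plane:  {slope_oct_per_mm: 2.13, pearson_r: 0.77, "n": 23}
  tuned_per_plane: 21
  within_plane_sd_oct: 0.956   # field IQR median 1.29 oct / 1.349
  bwmax_step_probs: [0.10, 0.20, 0.30, 0.17, 0.09, 0.06, 0.04, 0.03, 0.01]
  shape_fractions: {V: 0.395, I: 0.362, O: 0.243}

CT:
  class_fractions: {tuned: 0.18, irregular: 0.57, silent: 0.25}
  gradient:
    neuron: {slope_oct_per_mm: 0.37, pearson_r: 0.079, "n": 491}
    plane:  {slope_oct_per_mm: 0.21, pearson_r: 0.20, "n": 40}
  tuned_per_plane: 12
  within_plane_sd_oct: 1.438   # field IQR median 1.94 oct / 1.349
  bwmax_step_probs: [0.02, 0.03, 0.05, 0.08, 0.10, 0.12, 0.25, 0.20, 0.15]
  shape_fractions: {V: 0.507, I: 0.228, O: 0.265}
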