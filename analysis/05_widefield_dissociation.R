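#!/usr/bin/env Rscript
# Stage 5: wide-field versus two-photon dissociation.
#
# Renders a wide-field mapping session for the CT preset - heterogeneous
# somata over a smooth tonotopic neuropil field - then runs the wide-field
# chain (downsample, trial average, smooth, df/f, LF/HF localization) and
# compares the map-level gradient with the soma-level gradient of the same
# neurons.  Writes results/widefield.json.

suppressMessages(library(tonotopr))
dir.create("results", showWarnings = FALSE)

pr <- synth_preset("CT")
p <- make_protocol()
scene <- make_widefield_scene(pr)
pop <- sample_population(pr, 300, p, seed = 6, tuned_only = TRUE)
wf <- render_widefield(scene, neurons = pop, seed = 6)
pp <- preprocess_widefield(wf$movie, wf$trial_table)
m4 <- dff_widefield(pp$stimuli[["4"]], pp$onset_index, fs_hz = wf$fs_hz)
m32 <- dff_widefield(pp$stimuli[["32"]], pp$onset_index, fs_hz = wf$fs_hz)
areas <- locate_areas(m4$response_map, m32$response_map,
                      um_per_px = 20 * pp$downsample_factor)
wf_fit <- widefield_gradient(m4$response_map, m32$response_map, areas)
soma_fit <- fit_gradient(pop$axis_mm, pop$bf_khz)

cat(sprintf("LF centroid (px): (%.1f, %.1f); HF centroid: (%.1f, %.1f); axis %.2f mm\n",
            areas$centroids_px$lf["x"], areas$centroids_px$lf["y"],
            areas$centroids_px$hf["x"], areas$centroids_px$hf["y"],
            areas$axis$length_mm))
cat(sprintf("wide-field gradient: R = %.2f (slope %.2f oct/mm)\n",
            wf_fit$pearson_r, wf_fit$slope_oct_per_mm))
cat(sprintf("soma-level gradient: R = %.2f, p = %.2f (slope %.2f oct/mm)\n",
            soma_fit$pearson_r, soma_fit$p_value, soma_fit$slope_oct_per_mm))

jsonlite::write_json(list(
  widefield = list(r = wf_fit$pearson_r, slope = wf_fit$slope_oct_per_mm),
  soma = list(r = soma_fit$pearson_r, p = soma_fit$p_value,
              slope = soma_fit$slope_oct_per_mm),
  axis_length_mm = areas$axis$length_mm),
  "results/widefield.json", auto_unbox = TRUE, digits = NA)

cat("\nThe summed neuropil signal shows clear tonotopy in the wide-field map\n",
    "even though the underlying somata carry no somatic gradient - the same\n",
    "dissociation seen between epifluorescence mapping and single-cell 2P\n",
    "imaging of corticothalamic neurons.\n")
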