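# tonotopr

Tools for asking a specific question of calcium-imaging data from mouse
primary auditory cortex (A1): **is a neuron population tonotopically
organized?**  Tonotopy — a spatial gradient of preferred sound frequency —
is the organizing principle of the ascending auditory system, but it is a
population-level property: answering the question requires a chain from raw
movies to per-neuron best frequencies (BFs) to spatial statistics, and every
link can fail silently.  `tonotopr` implements that chain and pairs it with
a synthetic-data generator with known ground truth, so the whole pipeline is
testable end to end.

The package was built around the contrast between two projection-defined
populations: thalamocortical-recipient-like neurons ("TR" preset — clear
gradient, ~46% tuned, narrow tuning) and corticothalamic-like neurons
("CT" preset — no somatic gradient, ~18% tuned, broad tuning), including
the instructive dissociation that wide-field imaging still shows a tonotopic
map over CT somata because the neuropil dominates the summed signal.

## What it computes

* **Wide-field branch** — downsample 10×, trial-average, 5×5 spatial +
  3-frame temporal smoothing, pixelwise Δf/f against an 800-ms pre-stimulus
  baseline; localize the 4-kHz (LF) and 32-kHz (HF) response areas and
  define the tonotopic axis from their centroids
  (`preprocess_widefield()`, `dff_widefield()`, `locate_areas()`).
* **Two-photon branch** — rigid SSD motion correction with exact
  integer-shift recovery, ROI mean traces, Δf/f with the 25th-percentile
  baseline (`motion_correct()`, `extract_traces()`, `compute_dff()`).
* **Transients** — detection by peak-amplitude (3× baseline SD, 1-s
  windows) and rise-rate criteria on an IIR-smoothed trace; iterative
  peeling that resolves overlapping events and conserves the trace exactly
  (`detect_transients()`, `peel()`, `evoked_amplitude()`,
  `bbn_reliability()`).
* **Tuning** — 11×6 frequency-response areas from the 66 stimulus
  combinations; tuned/irregular/silent classes; BF, V/I/O shape, half-peak
  bandwidth, Q, maximum bandwidth BW_max, monotonicity index
  (`build_fra()`, `analyze_tuning()`).
* **Topography** — OLS gradient of log2(BF) along the caudal→rostral axis
  (octaves/mm with Pearson R), field IQR (100 µm / 5-neuron rule), local
  IQR (25 µm radius), nearest-neighbour Δfrequency
  (`fit_gradient()`, `field_iqr()`, `local_iqr()`, `nn_delta_frequency()`).
* **Group statistics** — median\25–75% summaries and two-sided Wilcoxon
  tests, as the field reports them (`summarize_group()`,
  `compare_groups()`).
* **Synthetic data** — presets, populations, traces, 2P movies and
  wide-field scenes with ground truth (`synth_preset()`,
  `sample_population()`, `sample_planes()`, `render_traces()`,
  `render_movie_2p()`, `render_widefield()`).

The core statistic is the gradient fit: for tuned neurons at axis positions
`x` (mm), fit `log2(BF / 2 kHz) = a + b·x`; `b` is the slope in octaves/mm
and Pearson's R with its two-sided p-value decides "tonotopic or not".
Under the TR presets the generator is calibrated so the measured slope and R
equal 2.13 oct/mm, R = 0.77 (plane level) and 1.76 oct/mm, R = 0.52 (neuron
level); under CT, 0.21 / 0.37 oct/mm with R = 0.20 / 0.079.

## Worked example

```r
library(tonotopr)

protocol <- make_protocol()           # 11 x 6 x 5 = 330 pure tones
protocol
#> Tone protocol: 11 frequencies (2-40 kHz) x 6 levels (30-80 dB SPL) x 5 repeats
#>   330 presentations, grid step 0.432 octaves, last onset 989.0 s

preset <- synth_preset("TR")
pop <- sample_population(preset, 120, protocol, seed = 5)
res <- classify_population(pop, protocol, seed = 5)
table(res$cls_measured)
#> irregular    silent     tuned
#>        43        20        57

tuned <- subset(res, cls_measured == "tuned")
fit_gradient(tuned$axis_mm, tuned$bf_khz_measured)
#> Tonotopic gradient: 1.23 oct/mm, R = 0.388, p = 0.00287, n = 57
```

The classified fractions track the preset mixture (46/41/13%), and the fit
detects the tonotopic gradient (significantly positive slope; at n = 57 the
slope estimate is noisy — the study-sized runs in `analysis/` recover
1.76 oct/mm, R = 0.52).  Running the same lines with `synth_preset("CT")`
yields a flat, non-significant fit.

The `analysis/` directory holds the numbered stage drivers
(`01_protocol_and_gradients.R` … `05_widefield_dissociation.R`); each is a
thin narrative script over the package functions that prints what it finds
and writes its tables under `results/`.

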