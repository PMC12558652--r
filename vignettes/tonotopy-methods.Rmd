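---
title: "Methods: from calcium movies to a tonotopy verdict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from calcium movies to a tonotopy verdict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonotopr)
```

`tonotopr` implements the analysis chain used to ask whether a cortical
neuron population is tonotopically organized: wide-field mapping to define
the caudal-to-rostral tonotopic axis, two-photon (2P) preprocessing and
transient detection to measure single-neuron tone responses, construction of
frequency-response areas (FRAs) and tuning metrics, and spatial statistics
over best frequencies (BFs).  Because the interesting claims are
population-level statistics, the package also ships a synthetic generator
whose presets encode two contrasting populations — a thalamocortical-
recipient-like ("TR") population with a clear gradient and narrow tuning,
and a corticothalamic-like ("CT") population with no somatic gradient and
broad tuning — so that every stage can be validated against ground truth.

## Stimulus model

The mapping stimulus is a grid of 11 pure tones geometrically spaced from
2 to 40 kHz (adjacent tones are `log2(20)/10 = 0.432` octaves apart) at six
levels, 30–80 dB SPL, five repeats: 330 presentations over 66 unique
combinations (`make_protocol()`).  All octave values in the package are
relative to 2 kHz, so the grid spans 0–4.32 octaves.  Tones last 100 ms; the
default inter-trial interval is 2.9 s, a conventional spacing that lets
GCaMP6s transients (decay constant ~1.5 s) relax between trials while
keeping a full session under 17 minutes.  The interval is a package choice:
it affects only how much transients overlap, which the detection and
peeling stages are designed to handle.

## Wide-field branch

`preprocess_widefield()` follows the standard epifluorescence recipe:
block-mean downsampling by 10 (750×1200 → 75×120 pixels), trial averaging
per stimulus, a 5×5 spatial box filter and a 3-frame temporal moving
average.  Downsampling is block-mean and the box filter uses reflect
padding; both choices are stated here because the recipe itself names only
the factors.  `dff_widefield()` computes pixelwise `df/f = (f - f0)/f0`
against the mean of the 800 ms before stimulus onset, and averages df/f
over 0–1 s after onset for the response map (the response window is a
package default; nothing in the chain is sensitive to it at the tested
noise levels).  `locate_areas()` thresholds each map at half its maximum
(configurable), keeps the largest 8-connected component, and defines the
tonotopic axis as the unit vector from the low-frequency (4 kHz) to the
high-frequency (32 kHz) area centroid.  Degenerate inputs — identical maps,
hence coincident centroids — are flagged rather than silently projected.

## Two-photon branch

Motion correction (`motion_correct()`) is rigid and integer-pixel: each
frame takes the (dy, dx) within ±`max_shift_px` minimizing the mean squared
difference against a template (the mean of the first 100 frames, refined
once from the corrected movie).  Sub-pixel registration is deliberately
omitted; the method being emulated minimizes squared intensity differences
over translations only.  Vacated edges are filled with the template border
median.  ROI traces are plain pixel means (`extract_traces()`; no neuropil
subtraction, matching the soma-only measurement the analysis assumes), and
`compute_dff()` uses the 25th percentile of the whole recording as f0, with
linear-interpolation percentiles everywhere in the package so that
independent implementations agree to machine precision.

## Transient detection and peeling

Detection (`detect_transients()`) works on the df/f trace re-centred on its
median (f0 is a low percentile, so the resting level sits slightly above
zero).  The noise level is `noise_k = 3` times the baseline SD, where the
baseline SD is the lower quartile of rolling 1-s-window SDs — windows that
contain transients inflate the rolling SD, and the lower quartile tracks the
quiet windows.  Candidate events are excursions of the exponentially
smoothed trace (single-pole IIR, 200 ms time constant) above half the noise
level; a candidate is accepted when

* its peak amplitude reaches the noise level — amplitude is the larger of
  the 200-ms raw-trace mean around the peak (baseline-corrected by the
  100 ms before onset) and a least-squares fit of the transient template
  over 2 s from the onset, which averages noise down near threshold; and
* its steepest 100-ms rise is at least `min_rise_rate` (default: noise
  level / 0.4 s), which rejects slow drifts without penalizing genuine
  fast-rising transients.

With these defaults the false-positive rate on pure noise is effectively
zero (the smoothed noise floor sits far below the threshold), which is what
lets "silent" be a meaningful class over a 1000-s recording, and events at
5× the noise SD are recovered with precision and recall above 0.9.

`peel()` decomposes overlapping events: detect the strongest remaining
event, fit the difference-of-exponentials template (rise 0.18 s, decay
1.5 s — GCaMP6s-like defaults, configurable) at its onset, subtract the
full-length scaled template, repeat on the residual.  The amplitude is fit
over a 0.45-s window after onset rather than a longer one: a window shorter
than the typical event separation keeps the fit of the first event
uncontaminated by the next, which is precisely what allows two equal
transients 0.5 s apart to be resolved where single-pass detection merges
them.  By construction the component traces plus the residual reproduce the
input exactly.

## FRAs and tuning metrics

`build_fra()` computes each presentation's evoked amplitude (mean df/f over
200 ms centered on the post-onset peak, minus the 100-ms pre-onset
baseline, peak searched within 1 s of onset) and averages over the five
repeats of each of the 66 combinations.  A combination is significant when
its trial-mean amplitude exceeds 3× the baseline SD *and* a detected
transient followed it in at least 3 of 5 repeats; the conjunction is a
reconstruction (no explicit test is prescribed for "tuned"), chosen so that
chance coincidences of spontaneous transients essentially never produce a
significant combination.  When several significant patches remain, the
largest 4-connected component is the FRA (ties: larger summed response,
then lower frequency).

Classes partition every population: *silent* (no detected transient
anywhere), *tuned* (nonempty FRA region), *irregular* (active but no
consistent stimulus-locked response).  For tuned neurons:

* **BF** — frequency with the highest level-averaged response (ties toward
  the lower frequency).
* **Shape** — O if the region's peak is not at 80 dB and the region
  excludes 80 dB; else V if the region reaches 80 dB with non-decreasing
  widths growing by ≥ 2 grid steps; else I if widths vary by ≤ 1 step.
* **Bandwidths** — a region n frequencies wide has width `(n-1) × 0.432`
  octaves, so a single-frequency region has width 0; this convention makes
  widths and BF differences multiples of 0.43 including 0.  BW_max is the
  maximum region width at any level; the half-peak bandwidth is the
  contiguous run of "effective" frequencies (level-averaged response above
  half maximum) around the BF; Q is BF divided by the effective band's
  width in kHz (a dimensionless sharpness index; an octave-domain variant
  would differ only monotonically).
* **MI** — response at 80 dB divided by the maximum response, computed on
  the BF column (the natural reading of "the neuron's response"; a
  global-column variant is exposed via `monotonicity(column = "global")`),
  clamped to [0, 1]; MI < 0.5 flags intensity-tuned neurons.

## Topography statistics

`fit_gradient()` is ordinary least squares of log2(BF/2 kHz) on axis
position with Pearson correlation ("R" is taken as Pearson; Spearman can be
computed from the same inputs if wanted).  Heterogeneity is measured as the
IQR of BFs in octaves: per focal plane (`field_iqr()`, reported missing
unless ≥ 5 tuned neurons lie within 100 µm of the field center), locally
(`local_iqr()`, 25 µm radius around sampled tuned neurons, retained when at
least 3 neurons fall in the radius — the minimum-neighbour rule is a
package default since none is prescribed), and per nearest neighbour
(`nn_delta_frequency()`, ties in distance broken toward the lower index).
Group summaries and tests (`summarize_group()`, `compare_groups()`) follow
the reporting style of the source analyses: median\25–75%, box-plot
whiskers at 1.5 IQR, two-sided Wilcoxon tests (exact null when both groups
have ≤ 10 observations and no ties, normal approximation with tie
correction otherwise).

## The synthetic generator and its calibration

The generator's presets *are* the study conditions.  Class mixtures
(TR 46/41/13% tuned/irregular/silent; CT 18/57/25%), population sizes
(481/491 tuned neurons; 23/40 focal planes over a 1.2 mm axis), FRA width
tables (medians 3 and 7 grid steps ≈ 1.29 and 3.01 octaves), and gradient
targets (TR: 2.13 oct/mm at plane level with R 0.77, 1.76 oct/mm at neuron
level with R 0.52; CT: 0.21 and 0.37 oct/mm with R 0.20 and 0.079) are
fixed in `inst/extdata/presets.yaml`.

Tuned BFs are generated from a latent linear model in octaves along the
axis plus Gaussian scatter, then clamped to the 2–40 kHz range and snapped
to the tone grid.  The textbook variance decomposition
`sigma = |slope| · SD(pos) · sqrt(1/R² − 1)` is only the starting point:
clamping and quantization attenuate both the realized slope and R (severely
for the CT single-neuron case, where the scatter implied by R = 0.079 is
wide relative to the 4.32-octave range).  `calibrate_bf_scatter()` therefore
solves for the latent slope and scatter numerically, using closed-form
moments of the censored/quantized normal, so that the *measured* population
statistics equal the targets.  Focal-plane sampling adds one more
correction: per-plane median BFs inherit sampling noise from the
within-plane scatter (set from the field-IQR medians, 1.29 and 1.94
octaves), so the plane-level latent scatter is deflated by the expected
median-sampling variance and the plane-level latent slope corrected by an
exact order-statistics computation of the expected sample median.

Traces are rendered at 30 Hz with difference-of-exponential transients
(rise 0.18 s, decay 1.5 s), additive Gaussian noise on the df/f scale
(SD 0.06), and a peak response gain of 0.30 df/f — i.e. maximal responses
are 5 noise SDs, with lognormal per-trial jitter (SD 0.2 on the log scale).
None of these acquisition constants is prescribed by the emulated study;
they are conventional GCaMP6s values and are config-exposed.  Within an
FRA region, amplitudes taper mildly (to 95% of the peak at the frequency
edges, 90% at the threshold level).  The taper is intentionally shallow:
the tested contract is that at the default SNR the significance mask
recovers the generating region (so BW_max medians are exact noiseless and
within one grid step noisy); a steep taper would model sub-threshold region
edges instead, which is a different — untested — regime.  Irregular neurons
fire Poisson transients at 0.03 Hz, a sparse spontaneous rate typical of
GCaMP6s imaging in quiet auditory cortex; at this rate the chance that
spontaneous events mimic a consistent 3-of-5-repeats stimulus-locked
response anywhere in the 66-combination grid stays near 1%, keeping class
recovery faithful.

Wide-field scenes separate compartments: a smooth neuropil field whose
preferred frequency follows a linear tonotopic map (2.13 oct/mm by default)
regardless of the preset's somatic organization, plus small somatic blobs
with the neurons' own BFs.  Rendering defaults to 150×240 pixels (the
original aspect at one tenth the size, downsampling factor kept at 10) so a
20-trial two-tone session stays around 200 MB; full-size rendering is a
parameter away.  This construction reproduces the dissociation that
motivates the whole design: with the CT preset, the wide-field pipeline
reports a strong map-level gradient (|R| ≥ 0.7) while the soma-level fit on
the same neurons stays flat (|R| ≤ 0.3).

## What the synthetic data does and does not show

Passing tests demonstrate that the pipeline recovers known ground truth
under the stated statistical structure: correct class mixtures, exact BF
and BW recovery without noise, calibrated gradient slopes, the TR < CT
heterogeneity ordering, and the wide-field/soma dissociation.  They do not
demonstrate robustness to features the generator omits: non-rigid motion,
neuropil contamination of somatic ROIs, bleaching and slow drifts,
correlated (shared) noise across neurons, spike-to-fluorescence
nonlinearity, or real FRA shapes beyond the V/I/O taxonomy.  Results on
real movies depend on those factors in ways these tests cannot certify.

## Numerical choices and degenerate inputs

Percentiles interpolate linearly (type 7) everywhere.  Connected components
use 4-connectivity on the FRA grid and 8-connectivity on wide-field masks.
Tie-breaks are deterministic (lower frequency, lower index).  Degenerate
inputs return flagged results rather than errors where a value is
meaningful (zero BF variance → slope 0 with a `degenerate` flag; identical
LF/HF maps → `degenerate` axis; fewer than 5 neurons in the field radius →
missing IQR), and errors name the offending axis, pixel count or label
otherwise.  Statistical power is a real constraint on one headline
property: with a true plane-level R of 0.20 and 40 planes, the correlation
test rejects at the 5% level in roughly a quarter of replicates, so "the CT
fit is non-significant" holds in about three quarters of seeds — not in
(say) 90% of them.  The package reports the observed fraction rather than
forcing the property.

## Problem sizes used by the tests and scripts

The test suite and the analysis scripts run the study-sized configurations
where they are cheap (gradient fits, noiseless FRA metrics at n = 481/491,
1041 and 2721-neuron end-to-end classification in the acceptance script)
and scaled-down populations elsewhere (e.g. ~100-neuron default-noise FRA
checks, 300-neuron wide-field scenes); each script states its sizes.  The
choices balance Monte-Carlo error against runtime and are package choices,
not properties of the method.
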