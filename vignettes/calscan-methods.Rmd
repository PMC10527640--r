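---
title: "Quantifying cardiac Ca2+ handling from confocal line scans: methods and design"
author: "calscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac Ca2+ handling from confocal line scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calscan)
```

## The measurement problem

Confocal line scanning acquires a single spatial line across cardiac tissue
(or a myocyte) repeatedly, producing a space-by-time (x-t) fluorescence
image of a Ca2+-sensitive dye. Four quantities summarize Ca2+ handling in
such recordings:

* **Transient kinetics.** Each heartbeat (sinus or paced) produces a
  spatially synchronous Ca2+ transient. After normalization to the resting
  fluorescence, its **amplitude** is the peak dF/F0 above the local
  diastolic background and its **decay constant tau** is the e-fold time of
  the relaxation: one tau after the peak, a mono-exponential decay has lost
  63.2% of its peak-above-baseline (36.8% remains). Slowed decay reflects
  impaired SR Ca2+ reuptake and elevated diastolic Ca2+.
* **Ca2+ waves.** Spontaneous diastolic SR Ca2+ release propagates along
  the cell at a few mm/s, drawing oblique (chevron-shaped) bands in x-t —
  unlike stimulus-evoked transients, which activate the whole line
  essentially simultaneously. Waves are pro-arrhythmic triggers; their
  frequency is reported per scanned length and time, in waves/(mm x s).
* **SR Ca2+ leak.** With Na+/Ca2+ exchange blocked (0 Na+/0 Ca2+ solution),
  tetracaine closes RyR2 and the diastolic fluorescence steps down; the
  drop between a pre- and post-tetracaine recording, normalized to baseline
  fluorescence, measures the diastolic SR leak.
* **SR Ca2+ load.** Caffeine opens RyR2 completely; the peak dF/F0 of the
  evoked transient against the pre-caffeine diastolic background measures
  the releasable SR content.

`calscan` implements this pipeline end to end, together with a synthetic
line-scan generator whose ground truth is fully logged, so every stage is
validated by parameter recovery rather than by eye.

## Normalization: estimating F0

F0 is the resting (diastolic) fluorescence of each spatial pixel. Two
estimators are provided (`estimate_f0()`):

* **`prestim`** (default whenever at least two beat times are annotated):
  the per-pixel *median* over the 20 ms windows immediately preceding each
  beat. A time-criterion estimator is unbiased under symmetric noise, and
  the median makes it robust to a wave that happens to cross a window.
* **`quantile`**: the per-pixel mean of the lowest 20% of time samples.
  This needs no beat annotation (it is the fallback for quiescent leak/load
  recordings), but selecting low order statistics from noisy samples biases
  the estimate low by roughly 1.2-1.4 noise SDs. The estimator therefore
  adds back the Gaussian truncation bias, scaled by a robust noise SD
  (median absolute first difference / (sqrt(2) * 0.6745), immune to slow
  structure) and by the estimated diastolic fraction of the trace. An
  uncorrected low quantile would inflate every dF/F0 amplitude by several
  percent; with the correction both estimators agree to well under 1%.

Slow drift and photobleaching can be removed (`detrend = "linear"` or
`"exp"`) by fitting a global multiplicative trend through the per-beat
diastolic levels; F0 is then `profile(x) * trend(t)`, with the trend
anchored to 1 at t = 0. Normalization itself is exact arithmetic:
`dF/F0 = F / F0 - 1`, so every downstream measure is invariant to rescaling
the raw intensities.

## Transients: segmentation, amplitude, tau

Segmentation windows run from each stimulus to the next (or the trace end).
The peak is the maximum sample in the window; the **diastolic background is
local** — the mean dF/F0 over the 20 ms before the onset — so incomplete
decay between fast-paced beats and residual drift subtract out. A segment
is accepted only if its peak-above-background exceeds
`max(5 x MAD noise SD, 0.02)`; a flat trace with annotated stimuli yields
flagged, not accepted, segments.

Tau is estimated two ways (`estimate_tau()`):

* **`exp_fit`** (default): least-squares fit of
  `a * exp(-(t - t_peak)/tau) + c` (via `nls` with the `SSasymp`
  self-start) over the decay span from one sample after the observed peak
  to 90% of the window. The free offset `c` absorbs diastolic elevation and
  any F0 scale error, which is why tau is insensitive to the F0 estimator.
  The fit starts one sample late so that, under noise, no rising sample can
  leak into the decay span.
* **`crossing`**: the linearly interpolated first time the trace falls to
  `diastole + (peak - diastole) * exp(-1)`; tau is that time minus the peak
  time. "Decay by 63.2%" and "e-fold time" coincide for a mono-exponential,
  which is the reading adopted here; the two methods agree exactly on
  noiseless mono-exponential decays and to within 2% on realistic noise.

If the decay span has fewer than 5 samples (short windows at 20 Hz pacing
with slow decay and coarse sampling), tau is flagged undefined rather than
extrapolated; if the fit fails, the crossing value is returned with a flag.

## Wave detection

The detector exploits the one structural difference the physiology
guarantees: paced transients are spatially synchronous, waves are not.

1. **Two thresholded views.** The dF/F0 image carries the full-width
   transients; a **residual** image — dF/F0 minus the per-line spatial
   median (the synchronous component) — carries only local events. Both are
   thresholded at `3.5` robust noise SDs above the per-pixel diastolic
   level, never below an absolute floor of 0.05 dF/F0 (so noiseless images
   do not threshold at zero).
2. **Components.** Supra-threshold pixels are grouped into 8-connected x-t
   components (`EBImage::bwlabel` plus a diagonal-merge pass); components
   narrower than 50 um or shorter than 20 ms are discarded — this excludes
   Ca2+ sparks, which are not counted. Raw-image components that merely
   duplicate a residual component are dropped; raw components spanning more
   than 60% of the line are the stimulus-evoked transients.
3. **Origin splitting.** Within a residual component the per-position
   activation time t_first(x) is a chevron with its vertex at the wave
   origin. Local minima of this profile with prominence >= 4 ms (two scan
   lines — comfortably above the sub-millisecond threshold-crossing jitter
   at realistic noise) are separate origins; basins are cut at the ridge
   between adjacent minima. Front velocity is the inverse slope of
   t_first(x) regressed along the longer chevron side (a synchronous front
   gives ~0 slope, i.e. infinite velocity).
4. **Classification.** An event is a wave iff its onset is more than 30 ms
   from every stimulus, **or** its front velocity is below 5 mm/s (slow
   waves that happen to start near a stimulus are still waves). Paced
   fronts appear faster than 20 mm/s; the decade between the bounds makes
   the call insensitive to their exact values, and all of them live in
   `wave_config()`. Without stimulus annotations classification degrades to
   the velocity criterion with a warning.

`wave_frequency()` counts onsets in a half-open analysis window and divides
by scanned length times window duration. The default window is the full
scan, matching the generator's protocol (a short pacing burst followed by
an overdrive-suppressed spontaneous period, with waves eligible anywhere
outside the 60 ms post-stimulus refractory windows); the "first stimulus to
2 s after the last" post-pacing window remains available via
`analysis_window_ms`.

### Censoring at high event rates and the planted-probe correction

At the highest observed rates (~24 waves/(mm x s)) roughly one origin in
five is unresolvable *in principle*: it falls inside another event's
supra-threshold band, in its immediate shadow, or so close that the
activation-time minimum loses its prominence. No detector can count those;
left uncorrected they bias the frequency down by 5-20% exactly in the
conditions of greatest interest.

`estimate_wave_recovery()` measures this censoring empirically on the scan
itself: clones of detected single-event waves (their supra-threshold
residual patches) are planted at uniform positions over the eligible
space-time, the detector is re-run, and the fraction of planted origins
that reappear as *new* events (detection is deterministic, so a set
difference isolates them) is the per-origin recovery probability p. Probes
are spaced so they cannot interact with each other, and the reciprocal-use
bias of a finite-probe estimate (E[n/p-hat] > n/p) is removed with the
standard delta-method factor. `frequency_corrected = n /(mm x s x p)`;
the uncorrected `frequency` is always reported alongside and equals
`n_waves / (scan_length_mm x duration_s)` exactly. At low rates p ~ 1 and
the two coincide. A cheaper geometric fallback (the occupied fraction of
eligible space-time, `occupancy`) is used when no donor wave exists.

## SR flux measurements

**Leak** (`measure_leak()`): F0 is the mean over the first 2 s of the
quiescent pre-tetracaine recording; the leak is the difference between the
means over the final 2 s of the pre and post recordings, divided by F0.
Settling of the post signal is verified by requiring the fitted slope over
its final window to stay below 0.5% of F0 per second. Negative values are
reported but flagged (`negative_leak`), signalling protocol failure rather
than being silently clipped.

**Load** (`measure_load()`): F0 comes from the start of the baseline
recording and the diastolic background from its mean level. The caffeine
transient peak is read from a mono-exponential-plus-offset fit of the decay
phase evaluated at the observed peak time: a plain max-of-samples estimator
carries an upward noise bias proportional to the noise SD (max-selection
over near-tied samples around a slow peak), which a decay-fit intercept
does not; on noiseless input the two coincide exactly. A caffeine recording
with no excursion above `max(5 sigma, 0.05)` dF/F0 yields an undefined-load
flag. Both flux values are dimensionless dF/F0 (the protocols provide no
dye calibration to absolute concentration).

## Group statistics

`summarize_groups()` reports mean and SEM (sample SD / sqrt(n), n >= 2
required). `compare_groups()` applies the test-selection rule standard for
such data: Student's t-test (pooled variance) for two groups or one-way
ANOVA with post-hoc Tukey HSD for more, switching to the Mann-Whitney U
test or Kruskal-Wallis rank ANOVA when Levene's test (centre = median,
alpha = 0.05) detects variance heterogeneity — the usual operationalization
of "when heterogeneity of variance was observed", with Kruskal-Wallis as
the standard reading of "nonparametric one-way ANOVA". The two-group path
holds its nominal 5% type-I error under both homoscedastic and
heteroscedastic nulls (the latter exercising the switch), verified by
simulation in the test suite.

## The synthetic generator: what it emulates, and what it does not

`simulate_paced_scan()` builds scans from explicit ground truth:

* **Transients** use a saturating-exponential upstroke (time constant
  2 ms, peak 10 ms after the stimulus) joined *piecewise* to a
  mono-exponential decay at the peak. A product of rise and decay terms —
  the other common choice — would make the post-peak decay only
  asymptotically exponential and miss the 36.8%-at-tau construction
  invariant by several percent for realistic rise times; the piecewise form
  satisfies it exactly, which is what lets tau recovery be tested at the
  0.1% level.
* **Waves** are chevron bands: origins uniform in space and uniform over
  eligible time (outside 60 ms post-stimulus refractory windows; diastolic
  events are what matters for arrhythmia), propagating bidirectionally at
  2 mm/s over 120 um, releasing locally for 20 ms with 0.5 dF/F0 amplitude.
  The injected count is exactly Poisson with mean
  `rate x scan_length_mm x duration_s`.
* **Protocol.** Paced scans carry a 2 s burst at the requested frequency
  followed by an overdrive-suppressed quiescent period (after burst pacing
  the sinus node is transiently suppressed, so the immediate post-pacing
  window is modelled as beat-free); `pacing_hz = 0` gives a sinus surrogate
  at 2.5 Hz — a realistic rate for an isolated perfused mouse heart at room
  temperature — for the full duration.
* **Noise and variability.** Photon shot noise is Gaussian with variance
  `shot_scale x mean` (shot_scale 1, i.e. Poisson-like, at a 500-count
  baseline); optional linear drift and exponential photobleaching; integer
  quantization like a detector ADC. Biological variability is lognormal and
  mean-preserving: 3% beat-to-beat amplitude CV, 2% beat-to-beat tau CV,
  and a 5% recording-level (heart- or cell-to-cell) CV applied to kinetics
  and to leak/load magnitudes. Wave counts carry *no* extra-Poisson
  dispersion so that the count distribution stays exactly Poisson.
  `noise_off()` disables everything, making the generator deterministic.
* **Presets** `wt_sham`, `wt_alc` and `jnk2dn_alc` carry the published
  group means as ground truth: decay constants 30.03 / 55.9 / 30.03 ms (the
  JNK2dn value is not printed and is taken as the sham value it was
  reported to normalize to) and wave rates 1.99/4.84/7.59,
  10.20/15.38/24.05 and 2.71/3.11/7.34 waves/(mm x s) at 8/10/20 Hz.
  Leak/load preset magnitudes (0.10/1.5 sham-like, 0.25/2.0 alcohol-like
  dF/F0) are representative values — the source figures print no numbers —
  and are documented as such in the preset file.

What the generator does **not** emulate: reaction-diffusion or stochastic
RyR2-cluster spark physics, Ca2+ alternans, motion artefacts, spatially
heterogeneous dye loading, or electrophysiological coupling. Passing
recovery tests therefore demonstrates that the *measurement pipeline* is
unbiased under controlled optics and kinetics — not that it is robust to
every pathology of real tissue recordings.

## Problem sizes and numerical choices

Recovery studies use 40 seeded scans per condition: sinus scans of 6 s
(256 pixels x 1 mm line, 2 ms line period; ~15 beats each, ~600 transients
per condition) for tau, and paced scans of 10 s for waves. These sizes put
the Monte-Carlo SEM of each recovered mean near or below 2% of its target,
which is tight enough to expose estimator bias while running the whole
suite on a single CPU in minutes. Tolerances asserted in the tests are:
tau recovery within 2 SEM of truth; noiseless tau to 0.1%, with the two tau
methods within 2%; noiseless leak exact to 1e-5 and load to 1e-3 (the
settling exponential and the fit's numerical tolerance); Poisson moments
within 3 standard errors over 150-200 seeds; type-I error within 0.05 +/-
0.01 over 5000 null replicates. Degenerate inputs are flagged, not guessed
at: too few decay samples, non-settling post-tetracaine signals, flat
caffeine recordings and missing pair members all return explicit flags or
typed errors.

## Known limitations

* Raising the detection threshold `k_sd` reduces the wave count
  monotonically over the operating range (~3-6 SDs), but at extreme
  thresholds a merged multi-wave component can fragment back into its
  constituent events and the count can locally increase; the
  origin-splitting that makes dense scenes countable necessarily trades
  away strict global monotonicity.
* Beat inference is deliberately absent: stimulus (or sinus beat) times are
  metadata. Traces without annotations segment to nothing, with a warning.
* The wave classifier's velocity and asynchrony bounds are tuned to the
  regime gap the generator makes explicit (2 mm/s waves vs synchronous
  transients); tissue with genuinely slow conduction would need
  `wave_config()` adjusted.
* The planted-probe correction assumes event origins are well modelled as
  homogeneous Poisson in the eligible region — the same assumption the
  frequency statistic itself makes. Strongly clustered (e.g. focal) wave
  sources would violate it and the corrected frequency would then be
  approximate.
* Leak and load are reported in dF/F0 units only; converting to absolute
  Ca2+ would require a dye calibration the protocols do not include.
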