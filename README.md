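# calscan

Quantification of cardiac Ca²⁺ handling from confocal **line-scan** (x–t)
fluorescence recordings, for researchers studying atrial/ventricular
arrhythmia mechanisms: Ca²⁺ transient kinetics, propagating diastolic Ca²⁺
waves, and sarcoplasmic-reticulum (SR) leak and load — plus a synthetic
line-scan generator with a complete ground-truth log, so that every stage
of the pipeline is validated by parameter recovery.

## What it computes

For a space×time image `F(x, t)` of a Ca²⁺-sensitive dye:

* **ΔF/F₀ normalization** — `ΔF/F₀ = (F − F₀)/F₀`, with `F₀` the resting
  diastolic fluorescence (pre-beat-window median, or a bias-corrected
  low-quantile estimator for quiescent recordings; optional drift /
  photobleaching detrend).
* **Transient kinetics** — per beat, amplitude (peak ΔF/F₀ above the local
  diastolic background) and decay constant **τ**: the e-fold time of the
  decay, i.e. the time for the transient to decay by 63.2% of its
  systolic peak (36.8% remaining), from a mono-exponential fit with a
  crossing-time cross-check.
* **Ca²⁺ wave frequency** — propagating diastolic release events are
  detected as oblique bands in x–t (threshold → 8-connected components →
  activation-time chevron splitting), separated from spatially synchronous
  paced transients by asynchrony (>30 ms from every stimulus) or slow front
  velocity (<5 mm/s), and reported in **waves/(mm × s)**. At high event
  rates a planted-probe correction removes the censoring bias from
  overlapping events.
* **SR flux** — tetracaine-sensitive diastolic **leak**
  `(F_pre − F_post)/F₀` and caffeine-releasable **load** (peak ΔF/F₀ of the
  caffeine transient) from paired recordings.
* **Group statistics** — mean ± SEM and the heterogeneity-aware comparison
  rule (Student's t / ANOVA + Tukey, switching to Mann–Whitney U /
  Kruskal–Wallis when Levene's test detects unequal variances).

On-disk format: single-page grayscale TIFF plus a YAML sidecar
(`pixel_pitch_um`, `line_period_ms`, `protocol`, `stimulus_times_ms`, …);
see `read_linescan()` / `write_linescan()`.

## Worked example

Simulate a paced atrial scan in the 2-month-alcohol condition (ground-truth
τ = 55.9 ms, wave rate 10.20 waves/(mm × s) at 8 Hz) and recover both:

```r
library(calscan)

p   <- group_preset("wt_alc", pacing_hz = 8)
sim <- simulate_paced_scan(p$kinetics, p$waves, noise_model(),
                           pacing_hz = 8, duration_s = 10, seed = 4)
sim$image
#> <linescan_image> 256 px x 5000 lines | 1.000 mm x 10.00 s | paced | 16 stimuli

aw <- analyze_waves(sim$image)
nrow(sim$truth$waves); nrow(aw$waves)
#> [1] 110
#> [1] 102
aw$frequency[, c("n_waves", "frequency", "frequency_corrected")]
#>   n_waves frequency frequency_corrected
#> 1     102      10.2            11.65541
```

This seed drew 110 waves (Poisson around the nominal 102); 102 of them are
resolved — the rest start inside another event's footprint — and the
probe-based recovery correction moves the frequency from the raw 10.2 back
toward the realized 11.0 waves/(mm × s). Averaged over 40 seeded scans the
corrected frequency recovers the injected 10.20 within 2 SEM. Transient
kinetics from a sinus-rhythm scan:

```r
sin_sim <- simulate_paced_scan(p$kinetics, wave_model(0), noise_model(),
                               pacing_hz = 0, duration_s = 6, seed = 2)
tt <- analyze_transients(sin_sim$image)
round(mean(tt$tau_ms), 1); round(mean(tt$peak_dff0), 2)
#> [1] 56.8
#> [1] 0.73
```

(56.8 ms against a 55.9 ms ground truth for this single simulated heart;
the per-recording spread reflects the generator's 5% heart-to-heart
variability, and the grand mean over 40 hearts recovers 55.9 within
2 SEM.) Leak, load and group comparison:

```r
leak <- measure_leak(simulate_leak_pair(500, 0.25, noise_model(), seed = 5)$set)
leak$value_dff0
#> [1] 0.2394398

set.seed(10)
compare_groups(values = c(rnorm(10, 30, 6), rnorm(10, 56, 6)),
               groups = rep(c("sham", "alc"), each = 10))
#> <group_comparison> alc vs sham | t_test: statistic = 16.94, p = 1.653e-12
```

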