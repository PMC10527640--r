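#' Transient kinetics parameters
#'
#' Ground-truth kinetics of a stimulus-locked Ca2+ transient as produced by
#' the synthetic generator. The waveform is a saturating-exponential upstroke
#' that reaches its peak `5 * rise_ms` after the stimulus and then decays
#' mono-exponentially with constant `tau_decay_ms`, so a noiseless transient
#' is at exactly 36.8% (`exp(-1)`) of its peak-above-baseline one
#' `tau_decay_ms` after its peak.
#'
#' @param amplitude_dff0 peak dF/F0 above the diastolic level (> 0).
#' @param rise_ms upstroke time constant in ms (> 0); time to peak is
#'   `5 * rise_ms`.
#' @param tau_decay_ms mono-exponential decay constant in ms (> 0).
#' @param f0_counts resting (diastolic) fluorescence in detector counts (> 0).
#' @param diastolic_dff0 residual diastolic elevation in dF/F0 units (>= 0).
#' @return An object of class `transient_kinetics`.
#' @export
transient_kinetics <- function(amplitude_dff0 = 0.8, rise_ms = 2,
                               tau_decay_ms = 30, f0_counts = 500,
                               diastolic_dff0 = 0) {
  for (nm in c("amplitude_dff0", "rise_ms", "tau_decay_ms", "f0_counts")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort_validation(sprintf("'%s' must be a single positive number", nm))
  }
  if (diastolic_dff0 < 0) abort_validation("'diastolic_dff0' must be >= 0")
  structure(list(amplitude_dff0 = amplitude_dff0, rise_ms = rise_ms,
                 tau_decay_ms = tau_decay_ms, f0_counts = f0_counts,
                 diastolic_dff0 = diastolic_dff0),
            class = "transient_kinetics")
}

#' Propagating-wave model parameters
#'
#' Diastolic Ca2+ waves are injected as chevron-shaped x-t bands: an origin
#' point from which activation propagates bidirectionally at
#' `velocity_mm_s`, each reached position releasing for `duration_ms` with a
#' fast saturating upstroke (`rise_ms`) and an exponential offset
#' (`decay_ms`). The number of waves injected into a scan is Poisson with
#' mean `rate_per_mm_s * scan_length_mm * duration_s`.
#'
#' @param rate_per_mm_s expected wave initiations per mm per s (>= 0).
#' @param velocity_mm_s propagation speed (> 0); must be well below the
#'   apparent (infinite) speed of paced transients for detection to work.
#' @param amplitude_dff0 local wave peak in dF/F0 units (> 0).
#' @param extent_um total spatial propagation span of one wave (> 0).
#' @param duration_ms local release duration at each position (> 0).
#' @param rise_ms,decay_ms local upstroke / offset time constants (> 0).
#' @return An object of class `wave_model`.
#' @export
wave_model <- function(rate_per_mm_s = 0, velocity_mm_s = 2,
                       amplitude_dff0 = 0.5, extent_um = 120,
                       duration_ms = 20, rise_ms = 3, decay_ms = 12) {
  if (!is.numeric(rate_per_mm_s) || rate_per_mm_s < 0 || !is.finite(rate_per_mm_s))
    abort_validation("'rate_per_mm_s' must be >= 0")
  for (nm in c("velocity_mm_s", "amplitude_dff0", "extent_um", "duration_ms",
               "rise_ms", "decay_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort_validation(sprintf("'%s' must be a single positive number", nm))
  }
  structure(list(rate_per_mm_s = rate_per_mm_s, velocity_mm_s = velocity_mm_s,
                 amplitude_dff0 = amplitude_dff0, extent_um = extent_um,
                 duration_ms = duration_ms, rise_ms = rise_ms,
                 decay_ms = decay_ms),
            class = "wave_model")
}

#' Acquisition noise and variability model
#'
#' Photon shot noise is approximated as Gaussian with variance
#' `shot_scale * mean` (counts); `drift_per_s` adds a linear baseline drift
#' and `bleach_tau_s` a mono-exponential photobleaching envelope. Beyond the
#' optics, the model carries the biological variability the generator
#' emulates: beat-to-beat lognormal jitter of transient amplitude and tau
#' (`beat_amp_cv`, `beat_tau_cv`) and recording-level (heart- or
#' cell-to-cell) lognormal scaling of kinetics and flux magnitudes
#' (`sample_cv`), all mean-preserving. `quantize` rounds the final counts to
#' integers like a detector ADC. With every parameter at zero (or `Inf` for
#' `bleach_tau_s`, `FALSE` for `quantize`) the generator is fully
#' deterministic given the kinetics.
#'
#' @param shot_scale variance-to-mean factor for photon noise (>= 0).
#' @param drift_per_s linear baseline drift fraction per second.
#' @param bleach_tau_s mono-exponential bleaching constant in s (`Inf` = none).
#' @param beat_amp_cv,beat_tau_cv beat-to-beat coefficients of variation.
#' @param sample_cv recording-level coefficient of variation.
#' @param quantize round counts to integers.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot_scale = 1, drift_per_s = 0, bleach_tau_s = Inf,
                        beat_amp_cv = 0.03, beat_tau_cv = 0.02,
                        sample_cv = 0.05, quantize = TRUE) {
  if (shot_scale < 0) abort_validation("'shot_scale' must be >= 0")
  if (bleach_tau_s <= 0) abort_validation("'bleach_tau_s' must be > 0 (Inf = none)")
  for (nm in c("beat_amp_cv", "beat_tau_cv", "sample_cv")) {
    if (get(nm) < 0) abort_validation(sprintf("'%s' must be >= 0", nm))
  }
  structure(list(shot_scale = shot_scale, drift_per_s = drift_per_s,
                 bleach_tau_s = bleach_tau_s, beat_amp_cv = beat_amp_cv,
                 beat_tau_cv = beat_tau_cv, sample_cv = sample_cv,
                 quantize = isTRUE(quantize)),
            class = "noise_model")
}

#' Fully deterministic noise model (all noise and variability off)
#' @return A `noise_model` with every stochastic component disabled.
#' @export
noise_off <- function() {
  noise_model(shot_scale = 0, drift_per_s = 0, bleach_tau_s = Inf,
              beat_amp_cv = 0, beat_tau_cv = 0, sample_cv = 0,
              quantize = FALSE)
}

#' Scan geometry
#'
#' @param n_pixels spatial pixels along the line.
#' @param pixel_pitch_um micrometres per pixel; the default gives a 1 mm line.
#' @param line_period_ms milliseconds per scan line.
#' @return A list with the three fields, class `scan_geometry`.
#' @export
scan_geometry <- function(n_pixels = 256, pixel_pitch_um = 1000 / 256,
                          line_period_ms = 2) {
  if (n_pixels < 8) abort_validation("'n_pixels' must be >= 8")
  if (pixel_pitch_um <= 0 || line_period_ms <= 0)
    abort_validation("calibration values must be positive")
  structure(list(n_pixels = as.integer(n_pixels),
                 pixel_pitch_um = pixel_pitch_um,
                 line_period_ms = line_period_ms),
            class = "scan_geometry")
}

# Mean-preserving lognormal multiplier(s): E[draw] = 1 for any cv >= 0.
lognormal_scale <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

#' Experimental-group presets
#'
#' Returns the ground-truth parameter bundle for one of the emulated
#' experimental groups. Decay constants and wave rates are the group means
#' reported for WT sham, 2-month-alcohol WT and 2-month-alcohol JNK2dn
#' atria; all other parameters (amplitude, rise time, baseline counts, wave
#' shape, leak/load magnitudes) are representative defaults recorded in the
#' preset file, not measured values. Presets live in
#' `system.file("extdata", "presets.yaml", package = "calscan")` and can be
#' overridden with a user file of the same structure.
#'
#' @param name preset name, see [preset_names()].
#' @param pacing_hz optional pacing frequency (8, 10 or 20); selects the
#'   matching wave rate for the returned `wave_model`. With `NULL` the wave
#'   rate is 0.
#' @param file optional path to an alternative preset YAML file.
#' @return A list with elements `name`, `kinetics` (`transient_kinetics`),
#'   `waves` (`wave_model`), `wave_rates` (named per-frequency vector),
#'   `leak_dff0` and `load_dff0`.
#' @export
group_preset <- function(name, pacing_hz = NULL, file = NULL) {
  presets <- load_presets(file)
  if (!name %in% names(presets))
    abort_validation(sprintf("unknown preset '%s' (available: %s)",
                             name, paste(names(presets), collapse = ", ")))
  p <- presets[[name]]
  rates <- unlist(p$wave_rates)
  rate <- 0
  if (!is.null(pacing_hz)) {
    key <- paste0("hz", format(pacing_hz))
    if (!key %in% names(rates))
      abort_validation(sprintf("preset '%s' has no wave rate for %s Hz",
                               name, format(pacing_hz)))
    rate <- unname(rates[key])
  }
  list(name = name,
       kinetics = do.call(transient_kinetics, p$kinetics),
       waves = do.call(wave_model, c(list(rate_per_mm_s = rate), p$wave_shape)),
       wave_rates = rates,
       leak_dff0 = p$leak_dff0,
       load_dff0 = p$load_dff0)
}

#' @rdname group_preset
#' @export
preset_names <- function(file = NULL) names(load_presets(file))

load_presets <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "presets.yaml", package = "calscan")
  if (!nzchar(file) || !file.exists(file))
    abort_input("preset file not found")
  yaml::read_yaml(file)
}
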