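# Synthetic line-scan generator. Every recording is produced from explicit
# ground truth (kinetics, wave model, noise model) and returned together with
# a complete event log, so each analysis stage can be validated by parameter
# recovery.

#' Canonical transient waveform
#'
#' Unit-peak waveform of a Ca2+ transient: a saturating-exponential upstroke
#' reaching its peak at `peak_factor * rise_ms`, joined continuously to a
#' mono-exponential decay. By construction the waveform equals `exp(-1)`
#' (36.8% of peak) exactly `tau_ms` after the peak.
#'
#' @param s_ms time since onset, ms (vector; values < 0 give 0).
#' @param rise_ms upstroke time constant.
#' @param tau_ms decay constant.
#' @param peak_factor time-to-peak in units of `rise_ms`.
#' @return Numeric vector of the same length as `s_ms`, peak value 1.
#' @export
transient_waveform <- function(s_ms, rise_ms, tau_ms, peak_factor = 5) {
  tp <- peak_factor * rise_ms
  w <- numeric(length(s_ms))
  up <- s_ms > 0 & s_ms < tp
  dn <- s_ms >= tp
  w[up] <- (1 - exp(-s_ms[up] / rise_ms)) / (1 - exp(-peak_factor))
  w[dn] <- exp(-(s_ms[dn] - tp) / tau_ms)
  w
}

# Local release profile of a wave at one position: saturating upstroke for
# duration_ms (unit peak at s = duration_ms), then exponential offset.
wave_profile <- function(s_ms, duration_ms, rise_ms, decay_ms) {
  w <- numeric(length(s_ms))
  up <- s_ms > 0 & s_ms < duration_ms
  dn <- s_ms >= duration_ms
  norm <- 1 - exp(-duration_ms / rise_ms)
  w[up] <- (1 - exp(-s_ms[up] / rise_ms)) / norm
  w[dn] <- exp(-(s_ms[dn] - duration_ms) / decay_ms)
  w
}

# Complement of the post-stimulus refractory windows within [0, t_end):
# matrix with columns start, end (ms). Waves may only start here.
eligible_intervals <- function(stimulus_times_ms, refractory_ms, t_end_ms) {
  if (!length(stimulus_times_ms))
    return(matrix(c(0, t_end_ms), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  blocked <- cbind(stimulus_times_ms, pmin(stimulus_times_ms + refractory_ms, t_end_ms))
  out <- NULL
  cursor <- 0
  for (i in seq_len(nrow(blocked))) {
    if (blocked[i, 1] > cursor) out <- rbind(out, c(cursor, blocked[i, 1]))
    cursor <- max(cursor, blocked[i, 2])
  }
  if (cursor < t_end_ms) out <- rbind(out, c(cursor, t_end_ms))
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

# Uniform draw over a union of intervals.
sample_in_intervals <- function(n, intervals) {
  len <- intervals[, "end"] - intervals[, "start"]
  pick <- sample.int(nrow(intervals), n, replace = TRUE, prob = len)
  intervals[pick, "start"] + stats::runif(n) * len[pick]
}

apply_noise_surface <- function(counts, noise, line_times_ms) {
  t_s <- line_times_ms / 1000
  trend <- (1 + noise$drift_per_s * t_s) * exp(-t_s / noise$bleach_tau_s)
  counts <- sweep(counts, 2, trend, `*`)
  if (noise$shot_scale > 0) {
    counts <- counts + stats::rnorm(length(counts)) *
      sqrt(noise$shot_scale * pmax(counts, 0))
  }
  counts <- pmax(counts, 0)
  if (noise$quantize) counts <- round(counts)
  list(counts = counts, trend = trend)
}

#' Simulate a paced or sinus-rhythm line-scan recording
#'
#' Produces one x-t image containing a spatially synchronous Ca2+ transient
#' per beat plus Poisson-injected propagating diastolic waves, degraded by
#' the chosen noise model, together with the full ground-truth event log.
#'
#' Protocol: with `pacing_hz > 0`, a pacing burst of `pacing_train_s`
#' seconds starts at t = 0 and the remainder of the scan is an
#' overdrive-suppressed quiescent period (no beats); with `pacing_hz = 0`
#' the recording is a sinus surrogate with beats at `sinus_hz` throughout.
#' Wave origins are uniform in space and uniform over all eligible time,
#' i.e. outside a `refractory_ms` window after every beat; the injected wave
#' count is Poisson with mean
#' `rate_per_mm_s * scan_length_mm * duration_s`. Identical arguments and
#' seed give byte-identical output.
#'
#' @param kinetics a [transient_kinetics()].
#' @param waves a [wave_model()].
#' @param noise a [noise_model()].
#' @param pacing_hz pacing frequency in Hz (0 = sinus surrogate).
#' @param duration_s recording length in seconds.
#' @param geometry a [scan_geometry()].
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param pacing_train_s length of the pacing burst (paced protocols).
#' @param sinus_hz intrinsic rate of the sinus surrogate.
#' @param refractory_ms post-beat window in which no wave may start.
#' @param group_tag free-form group label stored in the image.
#' @return A list of class `calscan_simulation`: `image` (a
#'   [linescan_image()]) and `truth` with `stimuli`, `beats` (per-beat
#'   amplitude and tau actually used), `waves` (one row per injected wave),
#'   `baseline_counts` (noiseless baseline track per line) and
#'   `eligible_ms` (wave-start intervals).
#' @export
simulate_paced_scan <- function(kinetics, waves = wave_model(),
                                noise = noise_model(), pacing_hz = 8,
                                duration_s = 10, geometry = scan_geometry(),
                                seed = NULL, pacing_train_s = 2,
                                sinus_hz = 2.5, refractory_ms = 60,
                                group_tag = "") {
  stopifnot(inherits(kinetics, "transient_kinetics"),
            inherits(waves, "wave_model"), inherits(noise, "noise_model"),
            inherits(geometry, "scan_geometry"))
  if (!is.numeric(pacing_hz) || pacing_hz < 0)
    abort_validation("'pacing_hz' must be >= 0")
  if (duration_s <= 0) abort_validation("'duration_s' must be > 0")
  if (!is.null(seed)) set.seed(seed)

  period <- geometry$line_period_ms
  n_lines <- round(duration_s * 1000 / period)
  n_px <- geometry$n_pixels
  tline <- (seq_len(n_lines) - 1) * period
  t_end <- n_lines * period
  x_um <- (seq_len(n_px) - 0.5) * geometry$pixel_pitch_um
  length_mm <- n_px * geometry$pixel_pitch_um / 1000

  beat_grid <- function(interval_ms, until_ms) {
    n <- floor((until_ms - 1e-6) / interval_ms) + 1
    seq(0, by = interval_ms, length.out = max(n, 0))
  }
  if (pacing_hz > 0) {
    stim <- beat_grid(1000 / pacing_hz, min(pacing_train_s, duration_s) * 1000)
    protocol <- "paced"
  } else {
    stim <- beat_grid(1000 / sinus_hz, t_end)
    protocol <- "sinus"
  }

  # recording-level (heart-to-heart) scaling, then beat-to-beat jitter
  samp_amp <- lognormal_scale(1, noise$sample_cv)
  samp_tau <- lognormal_scale(1, noise$sample_cv)
  n_beats <- length(stim)
  beat_amp <- kinetics$amplitude_dff0 * samp_amp *
    lognormal_scale(n_beats, noise$beat_amp_cv)
  beat_tau <- kinetics$tau_decay_ms * samp_tau *
    lognormal_scale(n_beats, noise$beat_tau_cv)

  trace <- rep(kinetics$diastolic_dff0, n_lines)
  for (b in seq_len(n_beats)) {
    first <- floor(stim[b] / period) + 1
    last <- min(n_lines,
                ceiling((stim[b] + 5 * kinetics$rise_ms + 9 * beat_tau[b]) / period) + 1)
    idx <- first:last
    trace[idx] <- trace[idx] +
      beat_amp[b] * transient_waveform(tline[idx] - stim[b],
                                       kinetics$rise_ms, beat_tau[b])
  }
  dff0 <- matrix(trace, nrow = n_px, ncol = n_lines, byrow = TRUE)

  eligible <- eligible_intervals(stim, refractory_ms, t_end)
  n_waves <- stats::rpois(1, waves$rate_per_mm_s * length_mm * duration_s)
  if (n_waves > 0 && (nrow(eligible) == 0 ||
                      sum(eligible[, "end"] - eligible[, "start"]) <= 0))
    abort_validation("no eligible diastolic time for wave placement")
  wave_log <- data.frame(x0_um = numeric(0), t0_ms = numeric(0),
                         extent_um = numeric(0), duration_ms = numeric(0),
                         velocity_mm_s = numeric(0), amplitude_dff0 = numeric(0))
  if (n_waves > 0) {
    x0 <- stats::runif(n_waves, 0, n_px * geometry$pixel_pitch_um)
    t0 <- sample_in_intervals(n_waves, eligible)
    v_um_ms <- waves$velocity_mm_s  # mm/s == um/ms
    for (m in seq_len(n_waves)) {
      rows <- which(abs(x_um - x0[m]) <= waves$extent_um / 2)
      if (!length(rows)) next
      ta <- t0[m] + abs(x_um[rows] - x0[m]) / v_um_ms
      c0 <- max(1L, floor(min(ta) / period))
      c1 <- min(n_lines, ceiling((max(ta) + waves$duration_ms +
                                    8 * waves$decay_ms) / period) + 1)
      if (c0 > c1) next
      cols <- c0:c1
      s <- outer(-ta, tline[cols], `+`)
      dff0[rows, cols] <- dff0[rows, cols] + waves$amplitude_dff0 *
        wave_profile(s, waves$duration_ms, waves$rise_ms, waves$decay_ms)
    }
    wave_log <- data.frame(x0_um = x0, t0_ms = t0,
                           extent_um = waves$extent_um,
                           duration_ms = waves$duration_ms,
                           velocity_mm_s = waves$velocity_mm_s,
                           amplitude_dff0 = waves$amplitude_dff0)
  }

  surf <- apply_noise_surface(kinetics$f0_counts * (1 + dff0), noise, tline)
  image <- linescan_image(surf$counts, geometry$pixel_pitch_um, period,
                          stimulus_times_ms = stim, protocol_tag = protocol,
                          group_tag = group_tag)
  structure(list(
    image = image,
    truth = list(stimuli = stim,
                 beats = data.frame(onset_ms = stim, amplitude_dff0 = beat_amp,
                                    tau_ms = beat_tau),
                 waves = wave_log,
                 baseline_counts = kinetics$f0_counts * surf$trend,
                 eligible_ms = eligible)),
    class = "calscan_simulation")
}

#' Simulate a tetracaine leak protocol pair
#'
#' The pre-tetracaine recording is quiescent at the diastolic level; after
#' tetracaine the fluorescence settles mono-exponentially (constant
#' `settle_tau_s`) onto a level lower by `leak_dff0` in dF/F0 units, the
#' tetracaine-sensitive diastolic SR Ca2+ leak. Recording-level variability
#' (`noise$sample_cv`) scales the realized leak around its nominal value,
#' mean-preservingly.
#'
#' @param f0_counts baseline fluorescence in counts.
#' @param leak_dff0 nominal leak magnitude, dF/F0 units (>= 0).
#' @param noise a [noise_model()].
#' @param duration_s length of each recording.
#' @param seed integer seed or `NULL`.
#' @param geometry a [scan_geometry()].
#' @param settle_tau_s settling time constant of the post recording.
#' @return List of class `calscan_simulation`: `set` (a [recording_set()]
#'   with `pre_tetracaine` and `post_tetracaine`) and `truth` (realized leak).
#' @export
simulate_leak_pair <- function(f0_counts = 500, leak_dff0 = 0.1,
                               noise = noise_model(), duration_s = 6,
                               seed = NULL,
                               geometry = scan_geometry(n_pixels = 64),
                               settle_tau_s = 0.3) {
  stopifnot(inherits(noise, "noise_model"), inherits(geometry, "scan_geometry"))
  if (!is.numeric(leak_dff0) || leak_dff0 < 0)
    abort_validation("'leak_dff0' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  period <- geometry$line_period_ms
  n_lines <- round(duration_s * 1000 / period)
  tline <- (seq_len(n_lines) - 1) * period
  leak_eff <- leak_dff0 * lognormal_scale(1, noise$sample_cv)

  pre_level <- rep(f0_counts, n_lines)
  post_level <- f0_counts * (1 - leak_eff * (1 - exp(-tline / 1000 / settle_tau_s)))
  mk <- function(levels, tag) {
    m <- matrix(levels, nrow = geometry$n_pixels, ncol = n_lines, byrow = TRUE)
    surf <- apply_noise_surface(m, noise, tline)
    linescan_image(surf$counts, geometry$pixel_pitch_um, period,
                   protocol_tag = tag)
  }
  set <- recording_set(list(mk(pre_level, "pre_tetracaine"),
                            mk(post_level, "post_tetracaine")))
  structure(list(set = set, truth = list(leak_dff0 = leak_eff,
                                         f0_counts = f0_counts)),
            class = "calscan_simulation")
}

#' Simulate a caffeine SR-load protocol pair
#'
#' The baseline recording is quiescent; the caffeine recording contains a
#' single large, slow Ca2+ transient whose peak dF/F0 equals `load_dff0`
#' (scaled by recording-level variability), the caffeine-releasable SR Ca2+
#' load. The caffeine transient uses the canonical waveform with slow
#' constants (`rise_ms`, time-to-peak `3 * rise_ms`, decay `decay_ms`).
#'
#' @param kinetics a [transient_kinetics()] (supplies `f0_counts` and
#'   `diastolic_dff0`).
#' @param load_dff0 nominal caffeine-transient peak, dF/F0 units (> 0).
#' @param noise a [noise_model()].
#' @param seed integer seed or `NULL`.
#' @param geometry a [scan_geometry()].
#' @param baseline_s,caffeine_s recording lengths.
#' @param onset_s caffeine-transient onset within the caffeine recording.
#' @param rise_ms,decay_ms caffeine-transient time constants.
#' @return List of class `calscan_simulation`: `set` (a [recording_set()]
#'   with `baseline` and `caffeine`) and `truth` (realized load and peak time).
#' @export
simulate_load_pair <- function(kinetics = transient_kinetics(),
                               load_dff0 = 1.5, noise = noise_model(),
                               seed = NULL,
                               geometry = scan_geometry(n_pixels = 64),
                               baseline_s = 4, caffeine_s = 8, onset_s = 1,
                               rise_ms = 60, decay_ms = 800) {
  stopifnot(inherits(kinetics, "transient_kinetics"),
            inherits(noise, "noise_model"), inherits(geometry, "scan_geometry"))
  if (!is.numeric(load_dff0) || load_dff0 <= 0)
    abort_validation("'load_dff0' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  period <- geometry$line_period_ms
  load_eff <- load_dff0 * lognormal_scale(1, noise$sample_cv)
  f0 <- kinetics$f0_counts
  dia <- kinetics$diastolic_dff0

  mk <- function(dff0_trace, tag) {
    n <- length(dff0_trace)
    tl <- (seq_len(n) - 1) * period
    m <- matrix(f0 * (1 + dff0_trace), nrow = geometry$n_pixels,
                ncol = n, byrow = TRUE)
    surf <- apply_noise_surface(m, noise, tl)
    linescan_image(surf$counts, geometry$pixel_pitch_um, period,
                   protocol_tag = tag)
  }
  nb <- round(baseline_s * 1000 / period)
  nc <- round(caffeine_s * 1000 / period)
  tc <- (seq_len(nc) - 1) * period
  caf <- dia + load_eff * transient_waveform(tc - onset_s * 1000,
                                             rise_ms, decay_ms,
                                             peak_factor = 3)
  set <- recording_set(list(mk(rep(dia, nb), "baseline"), mk(caf, "caffeine")))
  structure(list(set = set,
                 truth = list(load_dff0 = load_eff,
                              peak_ms = onset_s * 1000 + 3 * rise_ms)),
            class = "calscan_simulation")
}
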