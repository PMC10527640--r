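test_that("F0 of a constant image is the constant", {
  f0 <- estimate_f0(quiet_image(100))
  expect_equal(unname(f0$profile), rep(100, 32))
  norm <- normalize_scan(quiet_image(100), f0)
  expect_true(all(abs(norm$dff0) < 1e-12))
})

test_that("F0 recovers the generator baseline on clean and noisy scans", {
  sim <- simulate_paced_scan(transient_kinetics(f0_counts = 500),
                             wave_model(0), noise_off(), pacing_hz = 0,
                             duration_s = 4,
                             geometry = scan_geometry(n_pixels = 32), seed = 1)
  f0 <- estimate_f0(sim$image)
  expect_equal(unname(f0$profile), rep(500, 32), tolerance = 1e-3)

  nsim <- simulate_paced_scan(transient_kinetics(f0_counts = 500),
                              wave_model(0),
                              noise_model(sample_cv = 0, beat_amp_cv = 0,
                                          beat_tau_cv = 0),
                              pacing_hz = 0, duration_s = 4,
                              geometry = scan_geometry(n_pixels = 32), seed = 2)
  nf0 <- estimate_f0(nsim$image)
  expect_lt(abs(mean(nf0$profile) - 500) / 500, 0.01)
})

test_that("detrended F0 tracks a bleaching baseline within 2% at every decile", {
  noise <- noise_model(shot_scale = 0, bleach_tau_s = 20, beat_amp_cv = 0,
                       beat_tau_cv = 0, sample_cv = 0, quantize = FALSE)
  sim <- simulate_paced_scan(transient_kinetics(f0_counts = 500),
                             wave_model(0), noise, pacing_hz = 0,
                             duration_s = 8,
                             geometry = scan_geometry(n_pixels = 32), seed = 3)
  f0 <- estimate_f0(sim$image, detrend = "exp")
  est <- mean(f0$profile) * f0$trend
  truth <- sim$truth$baseline_counts
  deciles <- round(seq(1, length(truth), length.out = 10))
  expect_true(all(abs(est[deciles] - truth[deciles]) / truth[deciles] < 0.02))
})

test_that("normalization is (F - F0)/F0 elementwise", {
  img <- quiet_image(200)
  img$pixels[3, 7] <- 400
  f0 <- structure(list(profile = rep(200, 32), trend = rep(1, 400),
                       method = "given", detrend = "none", noise_sd = 0),
                  class = "f0_estimate")
  norm <- normalize_scan(img, f0)
  expect_equal(norm$dff0[3, 7], 1)
  expect_equal(sum(norm$dff0 != 0), 1L)
  bad <- structure(list(profile = rep(200, 10), trend = rep(1, 400)),
                   class = "f0_estimate")
  expect_error(normalize_scan(img, bad), class = "calscan_validation_error")
})

test_that("a noiseless transient normalizes to its construction amplitude", {
  sim <- simulate_paced_scan(transient_kinetics(amplitude_dff0 = 0.8),
                             wave_model(0), noise_off(), pacing_hz = 0,
                             duration_s = 4,
                             geometry = scan_geometry(n_pixels = 32), seed = 1)
  norm <- normalize_scan(sim$image)
  expect_equal(max(norm$dff0), 0.8, tolerance = 1e-3)
})

test_that("trace extraction averages bands linearly", {
  img <- quiet_image(100, n_px = 32)
  img$pixels[1:16, ] <- 150
  norm <- normalize_scan(img, structure(
    list(profile = rep(100, 32), trend = rep(1, 400), method = "given",
         detrend = "none", noise_sd = 0), class = "f0_estimate"))
  full <- extract_trace(norm, "all")
  lo <- extract_trace(norm, c(1, 16))
  hi <- extract_trace(norm, c(17, 32))
  expect_equal(full$dff0, (lo$dff0 + hi$dff0) / 2)
  one <- extract_trace(norm, 5)
  expect_equal(one$dff0, norm$dff0[5, ])
  expect_error(extract_trace(norm, c(0, 5)), class = "calscan_validation_error")
})

test_that("segment count equals stimulus count on wave-free scans at 8/10/20 Hz", {
  for (hz in c(8, 10, 20)) {
    sim <- simulate_paced_scan(transient_kinetics(tau_decay_ms = 55.9),
                               wave_model(0), noise_model(), pacing_hz = hz,
                               duration_s = 4,
                               geometry = scan_geometry(n_pixels = 64),
                               seed = hz)
    tt <- analyze_transients(sim$image)
    expect_identical(nrow(tt), length(sim$image$stimulus_times_ms))
    expect_true(all(tt$accepted))
  }
})

test_that("a flat trace with stimuli yields flagged, not accepted, segments", {
  img <- quiet_image(100, n_lines = 1000,
                     stimulus_times_ms = seq(0, 1600, by = 400))
  tt <- analyze_transients(img)
  expect_identical(nrow(tt), 5L)
  expect_false(any(tt$accepted))
})

test_that("a trace without stimuli returns no segments with a warning", {
  norm <- normalize_scan(quiet_image(100))
  tr <- extract_trace(norm)
  expect_warning(seg <- segment_transients(tr), "no stimulus")
  expect_identical(nrow(seg), 0L)
})

test_that("tau is recovered to <0.5% across tau and sampling-rate grids, both methods agreeing", {
  for (period in c(0.5, 2, 4)) {
    for (tau in c(10, 50, 120, 200)) {
      # isolated decays (beats far apart relative to tau) with the peak on
      # the sample grid: the regime both estimators are defined for
      cycle_ms <- max(800, 8 * tau)
      g <- scan_geometry(n_pixels = 16, line_period_ms = period)
      sim <- simulate_paced_scan(
        transient_kinetics(tau_decay_ms = tau, rise_ms = period),
        wave_model(0), noise_off(), pacing_hz = 0,
        duration_s = 3 * cycle_ms / 1000, geometry = g,
        sinus_hz = 1000 / cycle_ms, seed = 1)
      norm <- normalize_scan(sim$image)
      tr <- extract_trace(norm)
      seg <- segment_transients(tr)
      fit <- estimate_tau(seg[2, ], tr, "exp_fit")
      crs <- estimate_tau(seg[2, ], tr, "crossing")
      expect_lt(abs(fit$tau_ms - tau) / tau, 0.005)
      expect_lt(abs(fit$tau_ms - crs$tau_ms) / tau, 0.02)
    }
  }
})

test_that("a noiseless 50 ms decay is measured as 50 ms by both methods", {
  sim <- simulate_paced_scan(transient_kinetics(tau_decay_ms = 50),
                             wave_model(0), noise_off(), pacing_hz = 0,
                             duration_s = 4,
                             geometry = scan_geometry(n_pixels = 16), seed = 1)
  tt_fit <- analyze_transients(sim$image, tau_method = "exp_fit")
  tt_crs <- analyze_transients(sim$image, tau_method = "crossing")
  expect_true(all(abs(tt_fit$tau_ms - 50) < 0.1))
  expect_true(all(abs(tt_crs$tau_ms - 50) < 0.1))
})

test_that("tau is flagged undefined when the decay has too few samples", {
  # 20 Hz pacing leaves ~40 ms windows; with 10 ms lines that is < 5 samples
  sim <- simulate_paced_scan(transient_kinetics(tau_decay_ms = 55.9),
                             wave_model(0), noise_off(), pacing_hz = 20,
                             duration_s = 2,
                             geometry = scan_geometry(n_pixels = 16,
                                                      line_period_ms = 10),
                             seed = 1)
  tt <- analyze_transients(sim$image)
  expect_true(all(is.na(tt$tau_ms[tt$accepted])))
  expect_true(all(tt$tau_flag[tt$accepted] == "too_few_samples"))
})

test_that("amplitude subtracts the local diastolic background", {
  sim <- simulate_paced_scan(transient_kinetics(amplitude_dff0 = 0.8),
                             wave_model(0), noise_off(), pacing_hz = 0,
                             duration_s = 4,
                             geometry = scan_geometry(n_pixels = 32), seed = 1)
  norm <- normalize_scan(sim$image)
  tr <- extract_trace(norm)
  seg <- segment_transients(tr)
  amp0 <- measure_amplitude(seg[3, ], tr)
  expect_equal(amp0, 0.8, tolerance = 5e-3)
  # a constant offset on the trace (elevated diastole) leaves amplitude unchanged
  tr2 <- tr
  tr2$dff0 <- tr$dff0 + 0.1
  seg2 <- segment_transients(tr2)
  expect_equal(measure_amplitude(seg2[3, ], tr2), amp0, tolerance = 1e-9)
})

test_that("amplitude recovery is unbiased over 100 noisy beats", {
  per_scan <- lapply(1:10, function(s) {
    sim <- simulate_paced_scan(transient_kinetics(amplitude_dff0 = 0.8),
                               wave_model(0), noise_model(), pacing_hz = 0,
                               duration_s = 4,
                               geometry = scan_geometry(n_pixels = 64),
                               seed = 300 + s)
    tt <- analyze_transients(sim$image)
    tt$peak_dff0[tt$accepted]
  })
  expect_gte(length(unlist(per_scan)), 100L)
  # beats within a recording share its biological scale factor, so the
  # grand mean's SEM comes from the recording-level means
  means <- vapply(per_scan, mean, numeric(1))
  sem <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(unlist(per_scan)) - 0.8), 2 * sem)
})

test_that("dF/F0 measures are invariant to raw-intensity scaling", {
  sim <- simulate_paced_scan(transient_kinetics(), wave_model(0),
                             noise_model(quantize = FALSE), pacing_hz = 0,
                             duration_s = 4,
                             geometry = scan_geometry(n_pixels = 32),
                             seed = 9)
  ref <- analyze_transients(sim$image)
  for (c_scale in c(0.5, 3)) {
    scaled <- sim$image
    scaled$pixels <- scaled$pixels * c_scale
    got <- analyze_transients(scaled)
    expect_equal(got$tau_ms, ref$tau_ms, tolerance = 1e-8)
    expect_equal(got$peak_dff0, ref$peak_dff0, tolerance = 1e-8)
  }
})
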