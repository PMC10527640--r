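test_that("identical parameters and seed give byte-identical output", {
  p <- group_preset("wt_alc", pacing_hz = 8)
  g <- scan_geometry(n_pixels = 48)
  a <- simulate_paced_scan(p$kinetics, p$waves, noise_model(), 8, 2, g, seed = 11)
  b <- simulate_paced_scan(p$kinetics, p$waves, noise_model(), 8, 2, g, seed = 11)
  c <- simulate_paced_scan(p$kinetics, p$waves, noise_model(), 8, 2, g, seed = 12)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$waves, b$truth$waves)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("a 2 s scan paced at 8 Hz with zero wave rate has 16 stimuli and an empty log", {
  sim <- simulate_paced_scan(transient_kinetics(), wave_model(0), noise_off(),
                             pacing_hz = 8, duration_s = 2,
                             geometry = scan_geometry(n_pixels = 48), seed = 1)
  expect_length(sim$image$stimulus_times_ms, 16L)
  expect_identical(nrow(sim$truth$waves), 0L)
})

test_that("the noiseless waveform reaches 36.8% of peak exactly tau after the peak", {
  for (tau in c(12, 30.03, 55.9, 180)) {
    for (rise in c(1, 2, 5)) {
      tp <- 5 * rise
      expect_equal(transient_waveform(tp, rise, tau), 1)
      expect_equal(transient_waveform(tp + tau, rise, tau), exp(-1))
    }
  }
})

test_that("injected wave counts are Poisson with mean rate x mm x s", {
  g <- scan_geometry(n_pixels = 64)   # 0.25 mm line
  rate <- 10; dur <- 10
  mu <- rate * 64 * g$pixel_pitch_um / 1000 * dur
  k <- transient_kinetics()
  w <- wave_model(rate_per_mm_s = rate)
  counts <- vapply(1:200, function(s) {
    sim <- simulate_paced_scan(k, w, noise_off(), pacing_hz = 8,
                               duration_s = dur, geometry = g, seed = 1000 + s)
    nrow(sim$truth$waves)
  }, numeric(1))
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 200))
  expect_lt(abs(var(counts) - mu), 3 * mu * sqrt(2 / 199))
})

test_that("waves never start inside the post-stimulus refractory window", {
  p <- group_preset("wt_alc", pacing_hz = 10)
  sim <- simulate_paced_scan(p$kinetics, p$waves, noise_off(), pacing_hz = 10,
                             duration_s = 10,
                             geometry = scan_geometry(n_pixels = 64), seed = 5)
  stim <- sim$truth$stimuli
  for (t0 in sim$truth$waves$t0_ms) {
    d <- t0 - stim
    expect_false(any(d >= 0 & d < 60))
  }
})

test_that("doubling the amplitude doubles the noiseless peak-above-baseline everywhere", {
  g <- scan_geometry(n_pixels = 32)
  mk <- function(a) simulate_paced_scan(
    transient_kinetics(amplitude_dff0 = a, f0_counts = 400),
    wave_model(0), noise_off(), pacing_hz = 0, duration_s = 2,
    geometry = g, seed = 3)$image$pixels
  d1 <- mk(0.4) / 400 - 1
  d2 <- mk(0.8) / 400 - 1
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("non-physical generator parameters are rejected", {
  expect_error(wave_model(rate_per_mm_s = -1), class = "calscan_validation_error")
  expect_error(wave_model(velocity_mm_s = 0), class = "calscan_validation_error")
  expect_error(transient_kinetics(tau_decay_ms = -5),
               class = "calscan_validation_error")
  expect_error(simulate_leak_pair(leak_dff0 = -0.1),
               class = "calscan_validation_error")
  expect_error(simulate_load_pair(load_dff0 = 0),
               class = "calscan_validation_error")
})

test_that("leak and load pairs are built to their nominal magnitudes", {
  lp <- simulate_leak_pair(500, 0.25, noise_off(), duration_s = 6, seed = 2)
  pre <- lp$set$recordings$pre_tetracaine$pixels
  post <- lp$set$recordings$post_tetracaine$pixels
  expect_equal(mean(pre), 500)
  expect_equal(mean(post[, ncol(post)]), 500 * 0.75, tolerance = 1e-6)

  ld <- simulate_load_pair(transient_kinetics(), 1.5, noise_off(), seed = 2)
  caf <- ld$set$recordings$caffeine
  trace <- colMeans(caf$pixels) / 500 - 1
  expect_equal(max(trace), 1.5, tolerance = 1e-9)
  pk_idx <- round(ld$truth$peak_ms / caf$line_period_ms) + 1
  expect_equal(which.max(trace), pk_idx)
})

test_that("group presets carry the per-frequency wave rates and kinetics", {
  p <- group_preset("wt_alc", pacing_hz = 10)
  expect_equal(p$kinetics$tau_decay_ms, 55.9)
  expect_equal(p$waves$rate_per_mm_s, 15.38)
  expect_equal(unname(group_preset("wt_sham", 8)$waves$rate_per_mm_s), 1.99)
  expect_setequal(preset_names(), c("wt_sham", "wt_alc", "jnk2dn_alc"))
  expect_error(group_preset("nope"), class = "calscan_validation_error")
})
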