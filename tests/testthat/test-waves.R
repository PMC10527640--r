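test_that("an all-zero (flat) scan yields no candidates and zero frequency", {
  img <- quiet_image(100, n_px = 64, n_lines = 1000)
  norm <- normalize_scan(img)
  cands <- detect_candidate_events(norm)
  expect_identical(nrow(cands$events), 0L)
  cls <- suppressWarnings(classify_events(cands))
  fq <- wave_frequency(cls, img)
  expect_identical(fq$n_waves, 0L)
  expect_identical(fq$frequency, 0)
})

test_that("a single injected wave is one candidate whose geometry matches truth", {
  img <- quiet_image(500, n_px = 256, n_lines = 2000)
  img <- inject_chevron(img, x0_um = 480, t0_ms = 1500, f0_counts = 500)
  norm <- normalize_scan(img)
  cands <- detect_candidate_events(norm)
  ev <- cands$events[cands$events$channel == "residual", ]
  expect_identical(nrow(ev), 1L)
  pitch <- img$pixel_pitch_um
  expect_lt(abs(ev$extent_um - 120), 1.5 * pitch)
  cls <- suppressWarnings(classify_events(cands))
  expect_identical(nrow(cls$waves), 1L)
  expect_lt(abs(cls$waves$origin_um - 480), 1.5 * pitch)
  expect_lt(abs(cls$waves$origin_ms - 1500), 2 * img$line_period_ms + 1)
  expect_lt(abs(cls$waves$velocity_mm_s - 2), 0.4)
  expect_equal(cls$waves$peak_dff0, 0.5, tolerance = 0.05)
})

test_that("paced transients alone give one full-width candidate per beat", {
  sim <- simulate_paced_scan(transient_kinetics(tau_decay_ms = 30),
                             wave_model(0), noise_off(), pacing_hz = 0,
                             duration_s = 4,
                             geometry = scan_geometry(n_pixels = 64), seed = 2)
  norm <- normalize_scan(sim$image)
  cands <- detect_candidate_events(norm)
  raw <- cands$events[cands$events$channel == "raw", ]
  expect_identical(nrow(raw), length(sim$image$stimulus_times_ms))
  expect_true(all(raw$width_frac > 0.9))
  expect_identical(sum(cands$events$channel == "residual"), 0L)
  cls <- classify_events(cands)
  expect_identical(nrow(cls$waves), 0L)
  expect_identical(nrow(cls$paced), nrow(raw))
})

test_that("noiseless detection matches the truth log with precision = recall = 1", {
  # sparse enough that no two events overlap (fixture seed chosen for that)
  k <- transient_kinetics()
  w <- wave_model(rate_per_mm_s = 2)
  sim <- simulate_paced_scan(k, w, noise_off(), pacing_hz = 8,
                             duration_s = 10, seed = 44)
  aw <- analyze_waves(sim$image, probe_correction = FALSE)
  m <- match_waves(aw$waves, sim$truth$waves)
  expect_identical(nrow(aw$waves), nrow(sim$truth$waves))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
})

test_that("at moderate density noiseless precision stays 1 and recall high", {
  p <- group_preset("wt_alc", pacing_hz = 8)
  sim <- simulate_paced_scan(p$kinetics, p$waves, noise_off(), pacing_hz = 8,
                             duration_s = 10, seed = 21)
  aw <- analyze_waves(sim$image, probe_correction = FALSE)
  m <- match_waves(aw$waves, sim$truth$waves)
  expect_equal(m$precision, 1)
  expect_gt(m$recall, 0.9)
})

test_that("a slow wave right after a stimulus is still classified as a wave", {
  sim <- simulate_paced_scan(transient_kinetics(tau_decay_ms = 30),
                             wave_model(0), noise_off(), pacing_hz = 8,
                             duration_s = 4, seed = 3)
  stim <- sim$image$stimulus_times_ms
  img <- inject_chevron(sim$image, x0_um = 500, t0_ms = stim[5] + 5,
                        f0_counts = 500)
  aw <- analyze_waves(img, probe_correction = FALSE)
  expect_identical(nrow(aw$waves), 1L)
  expect_lte(abs(aw$waves$synchrony_offset_ms), 30)
  expect_lt(aw$waves$velocity_mm_s, 5)
})

test_that("false-positive rate on wave-free noisy scans is below 0.5 waves/(mm s)", {
  n_fp <- 0; area <- 0
  for (s in 1:50) {
    sim <- simulate_paced_scan(transient_kinetics(), wave_model(0),
                               noise_model(), pacing_hz = 0, duration_s = 5,
                               geometry = scan_geometry(n_pixels = 64),
                               seed = 700 + s)
    aw <- analyze_waves(sim$image, probe_correction = FALSE)
    n_fp <- n_fp + nrow(aw$waves)
    area <- area + scan_length_mm(sim$image) * scan_duration_s(sim$image)
  }
  expect_lt(n_fp / area, 0.5)
})

test_that("raising the detection threshold never increases the wave count", {
  # over the detector's operating range of k; at extreme thresholds merged
  # clusters can fragment back into their constituent events (see vignette)
  p <- group_preset("wt_alc", pacing_hz = 8)
  sim <- simulate_paced_scan(p$kinetics, p$waves, noise_model(), pacing_hz = 8,
                             duration_s = 6, seed = 31)
  counts <- vapply(c(3, 3.5, 4.5, 6), function(k) {
    aw <- analyze_waves(sim$image, wave_config(k_sd = k),
                        probe_correction = FALSE)
    nrow(aw$waves)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("frequency is count over length times duration, half-open window", {
  scan <- quiet_image(100, n_px = 256, n_lines = 1000)  # 1 mm x 2 s
  waves <- data.frame(origin_um = c(100, 500, 900),
                      origin_ms = c(100, 500, 1500))
  fq <- wave_frequency(waves, scan)
  expect_equal(fq$frequency, 1.5)
  expect_equal(wave_frequency(waves, scan, c(0, 500))$n_waves, 1L)
  expect_equal(wave_frequency(waves[0, ], scan)$frequency, 0)
  expect_error(wave_frequency(waves, scan, c(500, 500)),
               class = "calscan_validation_error")
})

test_that("wave counts and frequency are invariant to intensity scaling", {
  p <- group_preset("wt_alc", pacing_hz = 8)
  sim <- simulate_paced_scan(p$kinetics, p$waves,
                             noise_model(quantize = FALSE), pacing_hz = 8,
                             duration_s = 6, seed = 13)
  ref <- analyze_waves(sim$image, probe_correction = FALSE)
  scaled <- sim$image
  scaled$pixels <- scaled$pixels * 3
  got <- analyze_waves(scaled, probe_correction = FALSE)
  expect_identical(nrow(got$waves), nrow(ref$waves))
  expect_equal(got$frequency$frequency, ref$frequency$frequency)
})

test_that("wave frequency is invariant to pixel pitch at fixed physical length", {
  k <- transient_kinetics()
  w <- wave_model(rate_per_mm_s = 4)
  for (s in 61:63) {
    a <- simulate_paced_scan(k, w, noise_off(), pacing_hz = 8, duration_s = 6,
                             geometry = scan_geometry(n_pixels = 128,
                                                      pixel_pitch_um = 1000 / 128),
                             seed = s)
    b <- simulate_paced_scan(k, w, noise_off(), pacing_hz = 8, duration_s = 6,
                             geometry = scan_geometry(n_pixels = 256,
                                                      pixel_pitch_um = 1000 / 256),
                             seed = s)
    expect_identical(nrow(a$truth$waves), nrow(b$truth$waves))
    fa <- analyze_waves(a$image, probe_correction = FALSE)$frequency$frequency
    fb <- analyze_waves(b$image, probe_correction = FALSE)$frequency$frequency
    expect_equal(fa, fb, tolerance = 0.15)
  }
})

test_that("doubling the injected rate doubles the detected frequency", {
  k <- transient_kinetics()
  freq_at <- function(rate, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_paced_scan(k, wave_model(rate_per_mm_s = rate),
                                 noise_model(), pacing_hz = 8, duration_s = 6,
                                 geometry = scan_geometry(n_pixels = 128),
                                 seed = 800 + s)
      analyze_waves(sim$image, probe_correction = FALSE)$frequency$frequency
    }, numeric(1)))
  }
  f1 <- freq_at(4, 1:20)
  f2 <- freq_at(8, 21:40)
  expect_lt(abs(f2 / f1 - 2), 0.25)
})
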