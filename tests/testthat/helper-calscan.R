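# Shared fixtures, all built in code at test time.

# A quiescent constant-intensity recording.
quiet_image <- function(value = 100, n_px = 32, n_lines = 400,
                        pitch = 1000 / 256, period = 2, protocol = "sinus",
                        stimulus_times_ms = numeric(0)) {
  linescan_image(matrix(value, n_px, n_lines), pitch, period,
                 stimulus_times_ms = stimulus_times_ms,
                 protocol_tag = protocol)
}

# Add one chevron-shaped propagating wave directly into an image's pixel
# matrix (origin x0 um / t0 ms, bidirectional at v mm/s), mirroring the
# generator's wave geometry so detector tests can place events precisely.
inject_chevron <- function(image, x0_um, t0_ms, amplitude_dff0 = 0.5,
                           extent_um = 120, duration_ms = 20, v_mm_s = 2,
                           rise_ms = 3, decay_ms = 12, f0_counts = NULL) {
  px <- image$pixels
  if (is.null(f0_counts)) f0_counts <- stats::median(px)
  x_um <- (seq_len(nrow(px)) - 0.5) * image$pixel_pitch_um
  tline <- (seq_len(ncol(px)) - 1) * image$line_period_ms
  rows <- which(abs(x_um - x0_um) <= extent_um / 2)
  for (i in rows) {
    s <- tline - (t0_ms + abs(x_um[i] - x0_um) / v_mm_s)
    norm <- 1 - exp(-duration_ms / rise_ms)
    prof <- ifelse(s <= 0, 0,
                   ifelse(s < duration_ms,
                          (1 - exp(-s / rise_ms)) / norm,
                          exp(-(s - duration_ms) / decay_ms)))
    px[i, ] <- px[i, ] + f0_counts * amplitude_dff0 * prof
  }
  linescan_image(px, image$pixel_pitch_um, image$line_period_ms,
                 image$stimulus_times_ms, image$protocol_tag,
                 image$group_tag)
}

# Greedy one-to-one matching of detected wave origins against a truth log.
match_waves <- function(detected, truth, tol_um = 60, tol_ms = 20) {
  used <- rep(FALSE, nrow(detected))
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    d <- which(!used &
                 abs(detected$origin_um - truth$x0_um[i]) < tol_um &
                 abs(detected$origin_ms - truth$t0_ms[i]) < tol_ms)
    if (length(d)) {
      used[d[1L]] <<- TRUE
      TRUE
    } else FALSE
  }, logical(1))
  list(recall = if (nrow(truth)) mean(matched) else NA_real_,
       precision = if (nrow(detected)) sum(matched) / nrow(detected) else NA_real_,
       n_matched = sum(matched))
}
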