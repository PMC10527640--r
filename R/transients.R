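# Stimulus-locked transient segmentation and kinetics. tau follows the
# e-fold convention: one decay constant after the peak a mono-exponential
# has decayed BY 63.2% of its peak-above-baseline (36.8% remaining).

#' Segment stimulus-locked Ca2+ transients in a trace
#'
#' One segment per stimulus, windowed from the stimulus to the next stimulus
#' (or trace end). The peak is the maximum sample in the window; the
#' diastolic background of a segment is the mean dF/F0 over the
#' `prestim_window_ms` preceding its onset (local, so slow drift and
#' incomplete decay between fast beats are subtracted out). Segments whose
#' peak-above-background falls below the detection floor are flagged, not
#' accepted.
#'
#' @param trace an `ls_trace` from [extract_trace()].
#' @param stimulus_times_ms stimulus times; defaults to the trace annotation.
#' @param detection_floor minimum accepted amplitude in dF/F0 units;
#'   `NULL` (default) uses `max(5 * MAD-based noise SD of the pooled
#'   diastolic samples, 0.02)`.
#' @param prestim_window_ms diastolic window length before each onset.
#' @return A data.frame with one row per stimulus: `onset_ms`, `peak_ms`,
#'   `end_ms`, `peak_dff0` (amplitude above local diastole),
#'   `diastolic_dff0`, `accepted`, `peak_idx`, `window_start_idx`,
#'   `window_end_idx`. Attribute `noise_sd` carries the diastolic noise SD.
#' @export
segment_transients <- function(trace, stimulus_times_ms = NULL,
                               detection_floor = NULL,
                               prestim_window_ms = 20) {
  stopifnot(inherits(trace, "ls_trace"))
  stim <- stimulus_times_ms %||% trace$stimulus_times_ms
  empty <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      end_ms = numeric(0), peak_dff0 = numeric(0),
                      diastolic_dff0 = numeric(0), accepted = logical(0),
                      peak_idx = integer(0), window_start_idx = integer(0),
                      window_end_idx = integer(0))
  if (!length(stim)) {
    warning("no stimulus times annotated and beat inference is not attempted; returning no segments")
    return(empty)
  }
  y <- trace$dff0
  period <- trace$line_period_ms
  n <- length(y)
  t_end <- n * period

  dia_cols <- function(s) {
    c0 <- max(1L, floor((s - prestim_window_ms) / period) + 1)
    c1 <- min(n, floor(s / period))
    if (c1 >= c0 && c1 >= 1L) c0:c1 else integer(0)
  }
  # temporal-difference robust SD: immune to the systematic beat-to-beat
  # variation that inflates a plain MAD of diastolic samples at fast pacing
  noise_sd <- robust_noise_sd(y)
  if (is.null(detection_floor)) detection_floor <- max(5 * noise_sd, 0.02)

  ends <- c(stim[-1L], t_end)
  dia_all <- vapply(stim, function(s) {
    cols <- dia_cols(s)
    if (length(cols)) return(mean(y[cols]))
    # no pre-onset window (first beat at t = 0): the sample at the window
    # start precedes the upstroke and carries the local diastolic level
    y[floor(s / period) + 1L]
  }, numeric(1))

  seg <- lapply(seq_along(stim), function(i) {
    w0 <- floor(stim[i] / period) + 1
    w1 <- max(w0, ceiling(ends[i] / period))
    w1 <- min(w1, n)
    win <- w0:w1
    pk <- win[which.max(y[win])]
    amp <- y[pk] - dia_all[i]
    data.frame(onset_ms = stim[i], peak_ms = (pk - 1) * period,
               end_ms = ends[i], peak_dff0 = amp,
               diastolic_dff0 = dia_all[i],
               accepted = amp >= detection_floor,
               peak_idx = pk, window_start_idx = w0, window_end_idx = w1)
  })
  out <- do.call(rbind, seg)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "detection_floor") <- detection_floor
  out
}

#' Decay constant tau of one transient
#'
#' `"exp_fit"` (default): least-squares mono-exponential-plus-offset fit
#' (`stats::nls` with `SSasymp`) over the decay span from one sample after
#' the observed peak to 90% of the segment window; tau is the fitted e-fold
#' constant. `"crossing"`: the first time after the peak at which the trace
#' falls to `diastole + (peak - diastole) * exp(-1)`, linearly interpolated
#' between the bracketing samples; tau is that time minus the peak time.
#' Both agree exactly on noiseless mono-exponential decays. If the fit fails
#' the crossing value is returned with a flag; if the decay has fewer than 5
#' samples or never reaches the crossing level, tau is `NA` with a flag.
#'
#' @param segment one row of the data.frame from [segment_transients()].
#' @param trace the `ls_trace` the segment was cut from.
#' @param method `"exp_fit"` or `"crossing"`.
#' @return A list: `tau_ms`, `tau_method` (method actually used), `flag`
#'   (`"ok"`, `"too_few_samples"`, `"no_crossing"`, `"fit_failed"`),
#'   `fit_quality` (RMS residual / amplitude; `NA` for crossing).
#' @export
estimate_tau <- function(segment, trace, method = c("exp_fit", "crossing")) {
  stopifnot(inherits(trace, "ls_trace"))
  method <- match.arg(method)
  if (!isTRUE(segment$accepted))
    abort_validation("tau is only defined for accepted segments")
  y <- trace$dff0
  period <- trace$line_period_ms
  pk <- segment$peak_idx
  fit_end_ms <- segment$onset_ms + 0.9 * (segment$end_ms - segment$onset_ms)
  i0 <- pk + 1L
  i1 <- min(length(y), floor(fit_end_ms / period) + 1L, segment$window_end_idx)
  if (i1 - i0 + 1L < 5L)
    return(list(tau_ms = NA_real_, tau_method = method,
                flag = "too_few_samples", fit_quality = NA_real_))

  crossing <- function() {
    level <- segment$diastolic_dff0 +
      (y[pk] - segment$diastolic_dff0) * exp(-1)
    span <- pk:segment$window_end_idx
    below <- which(y[span] <= level)
    if (!length(below))
      return(list(tau_ms = NA_real_, tau_method = "crossing",
                  flag = "no_crossing", fit_quality = NA_real_))
    k <- span[below[1L]]
    if (k == pk)
      return(list(tau_ms = 0, tau_method = "crossing", flag = "ok",
                  fit_quality = NA_real_))
    frac <- (y[k - 1L] - level) / (y[k - 1L] - y[k])
    t_cross <- ((k - 1L - 1L) + frac) * period
    list(tau_ms = t_cross - segment$peak_ms, tau_method = "crossing",
         flag = "ok", fit_quality = NA_real_)
  }
  if (method == "crossing") return(crossing())

  # stop the fit span shortly after the decay has effectively completed:
  # long all-baseline tails add nothing and can defeat the self-starter
  amp0 <- y[pk] - segment$diastolic_dff0
  done <- which(y[i0:i1] < segment$diastolic_dff0 + 0.02 * amp0)
  if (length(done)) i1 <- min(i1, i0 + done[1L] + 4L)
  if (i1 - i0 + 1L < 5L)
    return(list(tau_ms = NA_real_, tau_method = method,
                flag = "too_few_samples", fit_quality = NA_real_))
  s <- (seq(i0, i1) - pk) * period
  yy <- y[i0:i1]
  fit <- tryCatch(
    stats::nls(yy ~ SSasymp(s, Asym, R0, lrc),
               control = stats::nls.control(scaleOffset = 1, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # explicit-start retry: seed tau from the crossing estimate if it exists
    cr0 <- crossing()
    tau0 <- if (is.finite(cr0$tau_ms) && cr0$tau_ms > 0) cr0$tau_ms
    else (i1 - i0 + 1L) * period / 3
    fit <- tryCatch(
      stats::nls(yy ~ Asym + (R0 - Asym) * exp(-exp(lrc) * s),
                 start = list(Asym = segment$diastolic_dff0, R0 = y[pk],
                              lrc = log(1 / tau0)),
                 control = stats::nls.control(scaleOffset = 1,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
  }
  tau <- if (!is.null(fit)) unname(1 / exp(stats::coef(fit)["lrc"])) else NA_real_
  if (is.null(fit) || !is.finite(tau) || tau <= 0) {
    out <- crossing()
    out$tau_method <- "crossing_fallback"
    if (out$flag == "ok") out$flag <- "fit_failed"
    return(out)
  }
  amp <- y[pk] - segment$diastolic_dff0
  fq <- sqrt(mean(stats::resid(fit)^2)) / max(amp, .Machine$double.eps)
  list(tau_ms = tau, tau_method = "exp_fit", flag = "ok", fit_quality = fq)
}

#' Amplitude of one transient
#'
#' Peak dF/F0 of the segment window minus the segment's local diastolic
#' background (mean dF/F0 over the window preceding the onset).
#'
#' @param segment one row from [segment_transients()].
#' @param trace the `ls_trace` the segment was cut from.
#' @return Amplitude in dF/F0 units.
#' @export
measure_amplitude <- function(segment, trace) {
  stopifnot(inherits(trace, "ls_trace"))
  if (!isTRUE(segment$accepted))
    abort_validation("amplitude is only defined for accepted segments")
  win <- segment$window_start_idx:segment$window_end_idx
  max(trace$dff0[win]) - segment$diastolic_dff0
}

#' One-stop transient analysis of a line-scan image
#'
#' Runs F0 estimation, dF/F0 normalization, spatial averaging, segmentation
#' and per-beat kinetics, returning one row per stimulus.
#'
#' @param image a [linescan_image()].
#' @param band spatial band passed to [extract_trace()].
#' @param tau_method passed to [estimate_tau()].
#' @param f0 optional precomputed `f0_estimate`.
#' @param ... further arguments to [segment_transients()].
#' @return Data.frame with the segment fields plus `tau_ms`, `tau_method`,
#'   `tau_flag`, `fit_quality`.
#' @export
analyze_transients <- function(image, band = "all",
                               tau_method = c("exp_fit", "crossing"),
                               f0 = NULL, ...) {
  tau_method <- match.arg(tau_method)
  norm <- normalize_scan(image, f0)
  trace <- extract_trace(norm, band)
  seg <- segment_transients(trace, ...)
  if (!nrow(seg)) {
    seg$tau_ms <- numeric(0); seg$tau_method <- character(0)
    seg$tau_flag <- character(0); seg$fit_quality <- numeric(0)
    return(seg)
  }
  res <- lapply(seq_len(nrow(seg)), function(i) {
    if (!seg$accepted[i])
      return(list(tau_ms = NA_real_, tau_method = NA_character_,
                  flag = "not_accepted", fit_quality = NA_real_))
    estimate_tau(seg[i, ], trace, method = tau_method)
  })
  seg$tau_ms <- vapply(res, `[[`, numeric(1), "tau_ms")
  seg$tau_method <- vapply(res, function(r) as.character(r$tau_method), character(1))
  seg$tau_flag <- vapply(res, `[[`, character(1), "flag")
  seg$fit_quality <- vapply(res, `[[`, numeric(1), "fit_quality")
  seg
}
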