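# Paired-protocol SR Ca2+ flux measurements, reported in dF/F0 units
# (dimensionless; no dye calibration to absolute concentration is applied).

flux_result <- function(kind, value_dff0, f0_counts, pre_window_ms,
                        post_window_ms, settled, flag = "ok") {
  structure(list(kind = kind, value_dff0 = value_dff0, f0_counts = f0_counts,
                 pre_window_ms = pre_window_ms, post_window_ms = post_window_ms,
                 settled = settled, flag = flag),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> %s = %s dF/F0 (F0 = %.1f counts, settled = %s, flag = %s)\n",
              x$kind,
              if (is.na(x$value_dff0)) "NA" else sprintf("%.4f", x$value_dff0),
              x$f0_counts, format(x$settled), x$flag))
  invisible(x)
}

band_trace_counts <- function(image) colMeans(image$pixels)

#' Tetracaine-sensitive diastolic SR Ca2+ leak
#'
#' The leak is the drop in quiescent diastolic fluorescence caused by
#' tetracaine (with NCX blocked), normalized to the resting fluorescence:
#' `(mean F over the pre window - mean F over the post steady-state window)
#' / F0`, with `F0` the steady-state mean at the beginning of the
#' pre-tetracaine recording. Both recordings must be quiescent. A negative
#' value is reported but flagged (protocol failure), and `settled` records
#' whether the post-tetracaine signal reached steady state
#' (|slope| < `settle_slope_frac * F0` per second over the post window).
#'
#' @param pair a [recording_set()] containing `pre_tetracaine` and
#'   `post_tetracaine`.
#' @param f0_window_s window at the start of the pre recording defining F0.
#' @param steady_window_s averaging window at the end of each recording.
#' @param settle_slope_frac settling criterion, fraction of F0 per second.
#' @return A `flux_result` with `kind = "leak"`.
#' @export
measure_leak <- function(pair, f0_window_s = 2, steady_window_s = 2,
                         settle_slope_frac = 0.005) {
  pre <- set_member(pair, "leak", "pre_tetracaine")
  post <- set_member(pair, "leak", "post_tetracaine")
  if (length(pre$stimulus_times_ms) || length(post$stimulus_times_ms))
    abort_validation("leak measurement requires quiescent (unstimulated) recordings")
  tr_pre <- band_trace_counts(pre)
  tr_post <- band_trace_counts(post)
  per_pre <- pre$line_period_ms
  per_post <- post$line_period_ms

  head_n <- max(2L, min(length(tr_pre), round(f0_window_s * 1000 / per_pre)))
  tail_n_pre <- max(2L, min(length(tr_pre), round(steady_window_s * 1000 / per_pre)))
  tail_n_post <- max(2L, min(length(tr_post), round(steady_window_s * 1000 / per_post)))

  f0 <- mean(tr_pre[seq_len(head_n)])
  if (f0 <= 0) abort_validation("F0 from the pre recording is not positive")
  pre_win <- tr_pre[(length(tr_pre) - tail_n_pre + 1L):length(tr_pre)]
  post_win <- tr_post[(length(tr_post) - tail_n_post + 1L):length(tr_post)]
  leak <- (mean(pre_win) - mean(post_win)) / f0

  t_post <- (seq_along(post_win) - 1) * per_post / 1000
  slope <- unname(stats::coef(stats::lm(post_win ~ t_post))[2L])
  settled <- abs(slope) < settle_slope_frac * f0
  flux_result("leak", leak, f0,
              pre_window_ms = steady_window_s * 1000,
              post_window_ms = steady_window_s * 1000,
              settled = settled,
              flag = if (leak < 0) "negative_leak" else "ok")
}

#' Caffeine-releasable SR Ca2+ load
#'
#' The load is the peak dF/F0 of the caffeine-evoked transient against the
#' diastolic background of the baseline recording, with F0 taken from the
#' start of the baseline recording. The peak is read from a
#' mono-exponential-plus-offset fit of the decay phase evaluated at the
#' observed peak time (robust to the noise-induced bias of a plain maximum);
#' if the fit fails the raw maximum is used. If the caffeine recording
#' contains no transient above the detection floor the result is flagged
#' undefined (`value_dff0 = NA`).
#'
#' @param pair a [recording_set()] containing `baseline` and `caffeine`.
#' @param f0_window_s window at the start of the baseline recording for F0.
#' @param floor_dff0 absolute minimum detectable peak.
#' @return A `flux_result` with `kind = "load"`.
#' @export
measure_load <- function(pair, f0_window_s = 2, floor_dff0 = 0.05) {
  base <- set_member(pair, "load", "baseline")
  caf <- set_member(pair, "load", "caffeine")
  tr_base <- band_trace_counts(base)
  tr_caf <- band_trace_counts(caf)
  per <- caf$line_period_ms

  head_n <- max(2L, min(length(tr_base), round(f0_window_s * 1000 / base$line_period_ms)))
  f0 <- mean(tr_base[seq_len(head_n)])
  if (f0 <= 0) abort_validation("F0 from the baseline recording is not positive")
  dia <- mean(tr_base) / f0 - 1
  y <- tr_caf / f0 - 1

  sigma <- robust_noise_sd(y)
  floor_eff <- max(5 * sigma, floor_dff0)
  pk <- which.max(y)
  if (y[pk] - dia < floor_eff)
    return(flux_result("load", NA_real_, f0, NA_real_, NA_real_,
                       settled = NA, flag = "no_transient"))

  i0 <- min(length(y), pk + 2L)
  load <- y[pk] - dia
  if (length(y) - i0 + 1L >= 10L) {
    s <- (seq(i0, length(y)) - pk) * per
    yy <- y[i0:length(y)]
    fit <- tryCatch(
      stats::nls(yy ~ SSasymp(s, Asym, R0, lrc),
                 control = stats::nls.control(scaleOffset = 1)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      # fitted decay extrapolated back to the observed peak time (s = 0),
      # minus the shift of the fit start: R0 is the fitted value at s = 0
      # only if the predictor starts there, so predict explicitly
      at_peak <- cf[["Asym"]] + (cf[["R0"]] - cf[["Asym"]]) * exp(-exp(cf[["lrc"]]) * 0)
      if (is.finite(at_peak)) load <- at_peak - dia
    }
  }
  flux_result("load", load, f0,
              pre_window_ms = f0_window_s * 1000,
              post_window_ms = (length(y) - 1) * per,
              settled = NA, flag = "ok")
}
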