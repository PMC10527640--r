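# dF/F0 normalization. F0 is the resting (diastolic) fluorescence; the
# default estimator uses a time criterion (the windows immediately preceding
# each stimulus), which is unbiased under symmetric noise, and falls back to
# an order-statistic estimator (lowest-quantile mean with a parametric bias
# correction) on quiescent recordings without beat annotations.

# Robust per-scan noise SD from first temporal differences: slow structure
# (transients, waves, drift) cancels in the median of |diff|.
robust_noise_sd <- function(m) {
  d <- if (is.matrix(m)) m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  else diff(m)
  stats::median(abs(d)) / (sqrt(2) * stats::qnorm(0.75))
}

#' Estimate the resting fluorescence F0
#'
#' @param image a [linescan_image()] with at least 200 time lines.
#' @param method `"auto"` (default): `"prestim"` when >= 2 stimulus times are
#'   annotated, else `"quantile"`. `"prestim"`: per-pixel median over the
#'   `prestim_window_ms` preceding each beat. `"quantile"`: per-pixel mean of
#'   the lowest `quantile` fraction of time samples, plus a Gaussian
#'   order-statistic bias correction scaled by the robust noise SD.
#' @param detrend `"none"`, `"linear"` or `"exp"`: optionally fit a global
#'   multiplicative baseline trend (drift / photobleaching) over the per-beat
#'   diastolic levels; the returned trend is 1 at t = 0.
#' @param quantile lower-tail fraction for the quantile estimator.
#' @param prestim_window_ms length of the pre-beat diastolic window.
#' @return An object of class `f0_estimate`: `profile` (strictly positive
#'   per-pixel F0 at t = 0), `trend` (per-line multiplicative factor),
#'   `method`, `detrend`, `noise_sd`.
#' @export
estimate_f0 <- function(image, method = c("auto", "prestim", "quantile"),
                        detrend = c("none", "linear", "exp"),
                        quantile = 0.2, prestim_window_ms = 20) {
  stopifnot(inherits(image, "linescan_image"))
  method <- match.arg(method)
  detrend <- match.arg(detrend)
  px <- image$pixels
  if (ncol(px) < 200)
    abort_validation("F0 estimation requires at least 200 time lines")
  stim <- image$stimulus_times_ms
  if (method == "auto")
    method <- if (length(stim) >= 2L) "prestim" else "quantile"

  tline <- line_times_ms(image)
  period <- image$line_period_ms
  n_lines <- ncol(px)

  prestim_cols <- function() {
    cols <- integer(0)
    for (s in stim) {
      c0 <- floor((s - prestim_window_ms) / period) + 1
      c1 <- floor(s / period)
      if (c1 >= c0 && c1 >= 1) cols <- c(cols, max(1L, c0):min(n_lines, c1))
    }
    sort(unique(cols))
  }

  trend <- rep(1, n_lines)
  if (detrend != "none") {
    # beat-wise (or chunk-wise) diastolic levels carry the bleaching/drift
    # envelope; fit a global multiplicative trend through them.
    if (length(stim) >= 3L) {
      anchors <- lapply(stim[-1L], function(s) {
        c0 <- max(1L, floor((s - prestim_window_ms) / period) + 1)
        c1 <- min(n_lines, floor(s / period))
        if (c1 < c0) return(NULL)
        c(t = mean(tline[c0:c1]), y = mean(px[, c0:c1]))
      })
      anchors <- do.call(rbind, anchors)
    } else {
      # quiescent: chunk the recording and use lower-quantile chunk levels
      breaks <- split(seq_len(n_lines), cut(seq_len(n_lines), 10))
      anchors <- t(vapply(breaks, function(ix)
        c(t = mean(tline[ix]),
          y = mean(apply(px[, ix, drop = FALSE], 1, stats::quantile,
                         probs = quantile))),
        numeric(2)))
    }
    tt <- anchors[, "t"]; yy <- anchors[, "y"]
    if (detrend == "linear") {
      fit <- stats::lm(yy ~ tt)
      g <- stats::predict(fit, newdata = data.frame(tt = tline))
    } else {
      fit <- stats::lm(log(pmax(yy, .Machine$double.eps)) ~ tt)
      g <- exp(stats::predict(fit, newdata = data.frame(tt = tline)))
    }
    g0 <- g[1L]
    if (g0 <= 0 || any(g <= 0))
      abort_validation("trend fit produced non-positive baseline")
    trend <- g / g0
  }
  pxd <- sweep(px, 2, trend, `/`)

  sigma <- robust_noise_sd(pxd)
  if (method == "prestim") {
    cols <- prestim_cols()
    if (length(cols) < 10L) {
      method <- "quantile"
    } else {
      profile <- apply(pxd[, cols, drop = FALSE], 1, stats::median)
    }
  }
  if (method == "quantile") {
    k <- max(2L, floor(quantile * n_lines))
    m_low <- apply(pxd, 1, function(r) mean(sort(r, partial = k)[seq_len(k)]))
    # fraction of samples that are baseline-like, to locate which quantile of
    # the baseline pool the lowest-k mean represents, then undo the Gaussian
    # truncation bias
    corr <- 0
    if (sigma > 0) {
      f_dia <- rowMeans(pxd < m_low + 4 * sigma)
      q <- pmin(1, quantile / pmax(f_dia, quantile))
      corr <- ifelse(q < 1, sigma * stats::dnorm(stats::qnorm(q)) / q, 0)
    }
    profile <- m_low + corr
  }
  if (any(profile <= 0))
    abort_validation("estimated F0 is not strictly positive (zero-intensity pixels?)")
  structure(list(profile = profile, trend = trend, method = method,
                 detrend = detrend, noise_sd = sigma),
            class = "f0_estimate")
}

#' Normalize a line-scan image to dF/F0
#'
#' @param image a [linescan_image()].
#' @param f0 an `f0_estimate` from [estimate_f0()] (computed from `image` if
#'   omitted).
#' @return An object of class `normalized_scan`: `dff0` matrix
#'   `(F - F0) / F0`, the `f0` estimate, calibration fields and provenance
#'   tags copied from the source image.
#' @export
normalize_scan <- function(image, f0 = NULL) {
  stopifnot(inherits(image, "linescan_image"))
  if (is.null(f0)) f0 <- estimate_f0(image)
  stopifnot(inherits(f0, "f0_estimate"))
  if (length(f0$profile) != nrow(image$pixels) ||
      length(f0$trend) != ncol(image$pixels))
    abort_validation("F0 estimate does not match the image dimensions")
  f0mat <- tcrossprod(f0$profile, f0$trend)
  structure(list(dff0 = image$pixels / f0mat - 1,
                 f0 = f0,
                 pixel_pitch_um = image$pixel_pitch_um,
                 line_period_ms = image$line_period_ms,
                 stimulus_times_ms = image$stimulus_times_ms,
                 protocol_tag = image$protocol_tag,
                 group_tag = image$group_tag),
            class = "normalized_scan")
}

#' Spatially averaged dF/F0 time trace
#'
#' @param norm a `normalized_scan`.
#' @param band `"all"` or an integer vector / `c(from, to)` range of spatial
#'   pixel rows to average over.
#' @return An object of class `ls_trace`: `dff0` (one value per line),
#'   `time_ms`, `line_period_ms`, `stimulus_times_ms`, `band`.
#' @export
extract_trace <- function(norm, band = "all") {
  stopifnot(inherits(norm, "normalized_scan"))
  n_px <- nrow(norm$dff0)
  rows <- if (identical(band, "all")) seq_len(n_px)
  else if (is.numeric(band) && length(band) == 2L) seq(band[1L], band[2L])
  else as.integer(band)
  if (!length(rows) || any(rows < 1L | rows > n_px))
    abort_validation("'band' must select at least one pixel inside the image")
  v <- if (length(rows) == 1L) norm$dff0[rows, ] else colMeans(norm$dff0[rows, , drop = FALSE])
  structure(list(dff0 = as.numeric(v),
                 time_ms = (seq_len(ncol(norm$dff0)) - 1) * norm$line_period_ms,
                 line_period_ms = norm$line_period_ms,
                 stimulus_times_ms = norm$stimulus_times_ms,
                 band = rows),
            class = "ls_trace")
}
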