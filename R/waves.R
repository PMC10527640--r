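# Propagating diastolic Ca2+ wave detection in normalized x-t images.
#
# Paced/sinus transients are spatially synchronous (apparent infinite
# velocity); waves propagate at finite velocity from a point origin, drawing
# chevron-shaped bands in x-t. The detector thresholds two views of the
# scan: the raw dF/F0 image (which carries the full-width transients) and a
# residual image with the spatially synchronous component (per-line spatial
# median) subtracted, on which only local events survive. Residual
# components are split into individual events at the local minima of their
# per-position activation-time profile (each chevron vertex is one origin),
# and classified as waves by asynchrony with the stimuli or by slow front
# velocity.

#' Wave-detector configuration
#'
#' @param k_sd detection threshold in robust noise SDs above the local
#'   diastolic level.
#' @param floor_dff0 absolute lower bound on the detection threshold in
#'   dF/F0 units (keeps noiseless images from thresholding at zero).
#' @param min_extent_um,min_span_ms minimum spatial extent and temporal span
#'   of a candidate component; smaller events (sparks) are discarded.
#' @param async_tol_ms an event onset farther than this from every stimulus
#'   is asynchronous (wave criterion a).
#' @param v_max_wave_mm_s maximum front velocity of a wave (criterion b).
#' @param v_min_paced_mm_s minimum apparent velocity of a synchronous paced
#'   front.
#' @param split_tol_ms prominence (ms) an activation-time minimum needs to
#'   count as a separate wave origin inside one component.
#' @param global_width_frac fraction of the line width above which a raw
#'   component is treated as a stimulus-evoked (full-width) transient.
#' @param refractory_ms post-stimulus window excluded from the eligible
#'   diastolic time used for the occupancy (occlusion) estimate.
#' @return A list of class `wave_config`.
#' @export
wave_config <- function(k_sd = 3.5, floor_dff0 = 0.05, min_extent_um = 50,
                        min_span_ms = 20, async_tol_ms = 30,
                        v_max_wave_mm_s = 5, v_min_paced_mm_s = 20,
                        split_tol_ms = 4, global_width_frac = 0.6,
                        refractory_ms = 60) {
  structure(list(k_sd = k_sd, floor_dff0 = floor_dff0,
                 min_extent_um = min_extent_um, min_span_ms = min_span_ms,
                 async_tol_ms = async_tol_ms,
                 v_max_wave_mm_s = v_max_wave_mm_s,
                 v_min_paced_mm_s = v_min_paced_mm_s,
                 split_tol_ms = split_tol_ms,
                 global_width_frac = global_width_frac,
                 refractory_ms = refractory_ms),
            class = "wave_config")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find pass over the label ids.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nmax <- max(lab)
  if (nmax < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

# Local minima of an activation-time profile, merged until every remaining
# minimum has prominence >= tol; returns minima positions and the basin
# boundaries between them (indices into tf).
split_profile_minima <- function(tf, tol) {
  r <- rle(tf)
  nv <- length(r$values)
  run_start <- cumsum(c(1L, r$lengths[-nv]))
  run_mid <- run_start + (r$lengths - 1L) %/% 2L
  is_min <- vapply(seq_len(nv), function(i) {
    left_ok <- i == 1L || r$values[i] < r$values[i - 1L]
    right_ok <- i == nv || r$values[i] < r$values[i + 1L]
    left_ok && right_ok
  }, logical(1))
  mins <- which(is_min)
  if (!length(mins)) mins <- which.min(r$values)
  while (length(mins) > 1L) {
    prom <- vapply(seq_len(length(mins) - 1L), function(j) {
      saddle <- max(r$values[mins[j]:mins[j + 1L]])
      saddle - max(r$values[mins[j]], r$values[mins[j + 1L]])
    }, numeric(1))
    j <- which.min(prom)
    if (prom[j] >= tol) break
    drop <- if (r$values[mins[j]] > r$values[mins[j + 1L]]) j else j + 1L
    mins <- mins[-drop]
  }
  bound_idx <- integer(0)
  if (length(mins) > 1L) {
    bound_idx <- run_mid[vapply(seq_len(length(mins) - 1L), function(j) {
      seg <- mins[j]:mins[j + 1L]
      seg[which.max(r$values[seg])]
    }, integer(1))]
  }
  list(minima_idx = run_mid[mins], bounds_idx = bound_idx)
}

#' Detect candidate Ca2+ release events in a normalized scan
#'
#' Thresholds the dF/F0 image and its synchronous-component-subtracted
#' residual at `k_sd` robust noise SDs above the per-pixel diastolic level
#' (never below `floor_dff0`), labels 8-connected x-t components and
#' discards components smaller than the minimum extent/span. Raw-image
#' components that merely duplicate a residual component (local events are
#' visible in both views) are dropped; full-width raw components are the
#' stimulus-evoked transients.
#'
#' @param norm a `normalized_scan`.
#' @param config a [wave_config()].
#' @return An object of class `wave_candidates`: `events` (one row per
#'   candidate with `channel` = `"residual"` or `"raw"`, onset, bounding box,
#'   extent, span, width fraction, peak), plus the label matrices, residual
#'   image and noise scales needed by [classify_events()].
#' @export
detect_candidate_events <- function(norm, config = wave_config()) {
  stopifnot(inherits(norm, "normalized_scan"), inherits(config, "wave_config"))
  dff0 <- norm$dff0
  n_px <- nrow(dff0); n_lines <- ncol(dff0)
  pitch <- norm$pixel_pitch_um; period <- norm$line_period_ms

  m_t <- apply(dff0, 2, stats::median)
  resid <- sweep(dff0, 2, m_t)

  thr_of <- function(mat) {
    sd_r <- robust_noise_sd(mat)
    dia <- apply(mat, 1, stats::quantile, probs = 0.2)
    list(thr = dia + max(config$k_sd * sd_r, config$floor_dff0), sd = sd_r)
  }
  th_raw <- thr_of(dff0)
  th_res <- thr_of(resid)
  mask_raw <- dff0 >= matrix(th_raw$thr, n_px, n_lines)
  mask_res <- resid >= matrix(th_res$thr, n_px, n_lines)

  lab_raw <- label8(mask_raw)
  lab_res <- label8(mask_res)

  # grouped component statistics without per-component data.frames (hot path)
  comp_table <- function(lab, values, channel) {
    idx <- which(lab > 0L)
    if (!length(idx))
      return(list(events = NULL, pix = list(), rows = list(), cols = list()))
    labs <- lab[idx]
    rc <- arrayInd(idx, dim(lab))
    ord <- order(labs)
    idx_s <- idx[ord]; rows_s <- rc[ord, 1L]; cols_s <- rc[ord, 2L]
    r <- rle(labs[ord])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- length(r$values)
    pix <- rows <- cols <- vector("list", k)
    row0 <- row1 <- col0 <- col1 <- integer(k)
    pk <- numeric(k)
    for (i in seq_len(k)) {
      s <- starts[i]:ends[i]
      pix[[i]] <- idx_s[s]; rows[[i]] <- rows_s[s]; cols[[i]] <- cols_s[s]
      row0[i] <- min(rows[[i]]); row1[i] <- max(rows[[i]])
      col0[i] <- min(cols[[i]]); col1[i] <- max(cols[[i]])
      pk[i] <- max(values[pix[[i]]])
    }
    events <- data.frame(
      channel = channel, comp_id = r$values,
      onset_ms = (col0 - 1) * period,
      row0 = row0, row1 = row1, col0 = col0, col1 = col1,
      n_px = r$lengths,
      extent_um = (row1 - row0 + 1) * pitch,
      span_ms = (col1 - col0 + 1) * period,
      width_frac = (row1 - row0 + 1) / n_px,
      peak_dff0 = pk, overlap_residual = NA_real_)
    names(pix) <- names(rows) <- names(cols) <- as.character(r$values)
    list(events = events, pix = pix, rows = rows, cols = cols)
  }
  ct_raw <- comp_table(lab_raw, dff0, "raw")
  ct_res <- comp_table(lab_res, resid, "residual")
  filt <- function(e) if (is.null(e)) NULL else
    e[e$extent_um >= config$min_extent_um & e$span_ms >= config$min_span_ms, ,
      drop = FALSE]
  ev_raw <- filt(ct_raw$events); ev_res <- filt(ct_res$events)

  if (!is.null(ev_raw) && nrow(ev_raw)) {
    ev_raw$overlap_residual <- vapply(as.character(ev_raw$comp_id), function(id)
      mean(mask_res[ct_raw$pix[[id]]]), numeric(1))
    dup <- ev_raw$overlap_residual > 0.5 &
      ev_raw$width_frac < config$global_width_frac
    ev_raw <- ev_raw[!dup, , drop = FALSE]
  }
  events <- rbind(ev_res, ev_raw)
  if (is.null(events)) {
    events <- data.frame(channel = character(0), comp_id = integer(0),
                         onset_ms = numeric(0), row0 = integer(0),
                         row1 = integer(0), col0 = integer(0),
                         col1 = integer(0), n_px = integer(0),
                         extent_um = numeric(0), span_ms = numeric(0),
                         width_frac = numeric(0), peak_dff0 = numeric(0),
                         overlap_residual = numeric(0))
  }
  rownames(events) <- NULL
  structure(list(events = events,
                 comp_raw = ct_raw[c("pix", "rows", "cols")],
                 comp_res = ct_res[c("pix", "rows", "cols")],
                 resid = resid, sd_raw = th_raw$sd, sd_res = th_res$sd,
                 config = config, pixel_pitch_um = pitch,
                 line_period_ms = period, n_space = n_px, n_lines = n_lines,
                 stimulus_times_ms = norm$stimulus_times_ms),
            class = "wave_candidates")
}

# Split one labeled component into events at the minima of its
# activation-time profile and measure each one. `vals` are the component's
# pixel values, aligned with `rows`/`cols`. Returns a list of numeric
# vectors (origin_um, origin_ms, extent_um, span_ms, velocity, peak, n_px).
component_events <- function(rows, cols, vals, pitch, period, tol) {
  r0 <- min(rows); r1 <- max(rows)
  prof_rows <- r0:r1
  np <- length(prof_rows)
  ord <- order(rows, cols)
  rr <- rows[ord]; cc <- cols[ord]
  firsts <- !duplicated(rr)
  lasts <- !duplicated(rr, fromLast = TRUE)
  tf <- rep(NA_real_, np)
  tmax <- rep(NA_real_, np)
  at <- rr[firsts] - r0 + 1L
  tf[at] <- (cc[firsts] - 1) * period
  tmax[at] <- (cc[lasts] - 1) * period
  if (anyNA(tf)) {    # rows missing from an 8-connected component: bridge them
    ok <- which(!is.na(tf))
    tf <- stats::approx(ok, tf[ok], xout = seq_len(np), rule = 2)$y
    tmax[is.na(tmax)] <- tf[is.na(tmax)]
  }
  sp <- split_profile_minima(tf, tol)
  cuts <- c(0L, sp$bounds_idx, np)
  lapply(seq_along(sp$minima_idx), function(j) {
    lo <- cuts[j] + 1L; hi <- cuts[j + 1L]
    mi <- sp$minima_idx[j]
    if (mi < lo || mi > hi) mi <- lo + which.min(tf[lo:hi]) - 1L
    origin_ms <- tf[mi]
    # front velocity: regress activation time on position along the longer
    # side of the chevron; a synchronous front has slope ~0 -> velocity Inf
    side <- if (mi - lo >= hi - mi) lo:mi else mi:hi
    v <- Inf
    if (length(side) >= 3L && stats::sd(tf[side]) > 0) {
      x_side <- (prof_rows[side] - 0.5) * pitch
      slope <- unname(stats::coef(stats::lm(tf[side] ~ x_side))[2L])
      if (is.finite(slope) && abs(slope) > 1e-9) v <- abs(1 / slope)  # um/ms == mm/s
    }
    in_seg <- rows >= prof_rows[lo] & rows <= prof_rows[hi]
    c(origin_um = (prof_rows[mi] - 0.5) * pitch,
      origin_ms = origin_ms,
      extent_um = (hi - lo + 1) * pitch,
      span_ms = max(tmax[lo:hi]) - origin_ms + period,
      velocity_mm_s = v,
      peak_dff0 = max(vals[in_seg]),
      n_px = sum(in_seg))
  })
}

#' Classify candidate events into waves and paced transients
#'
#' Residual-channel components are split into individual events at the
#' prominent minima of their activation-time profiles; each event is a WAVE
#' iff its onset is farther than `async_tol_ms` from every stimulus, or its
#' measured front velocity is below `v_max_wave_mm_s`. Full-width raw
#' components are stimulus-evoked transients; remaining raw components (not
#' duplicating a residual event) run through the same event logic. Without a
#' stimulus annotation classification degrades to the velocity criterion
#' with a warning.
#'
#' @param cands a `wave_candidates` from [detect_candidate_events()].
#' @param stimulus_times_ms stimulus times (defaults to the scan annotation).
#' @param config a [wave_config()] (defaults to the one used for detection).
#' @return A list of class `wave_events`: `waves` (one row per wave:
#'   `origin_um`, `origin_ms`, `extent_um`, `span_ms`, `velocity_mm_s`,
#'   `peak_dff0`, `synchrony_offset_ms`), `paced` (one row per synchronous
#'   event), and `occupancy` — the fraction of eligible (non-refractory)
#'   space-time covered by supra-threshold wave pixels, used by
#'   [wave_frequency()] for the occlusion (coincidence) correction.
#' @export
classify_events <- function(cands, stimulus_times_ms = NULL, config = NULL) {
  stopifnot(inherits(cands, "wave_candidates"))
  config <- config %||% cands$config
  stim <- stimulus_times_ms %||% cands$stimulus_times_ms
  if (!length(stim) && nrow(cands$events))
    warning("no stimulus times available; classifying by velocity only")
  pitch <- cands$pixel_pitch_um; period <- cands$line_period_ms

  offset_to_stim <- function(t) {
    if (!length(stim)) return(NA_real_)
    d <- t - stim
    d[which.min(abs(d))]
  }

  split_comps <- function(comp, vals_mat, ids) {
    out <- list(); src <- list()
    for (id in as.character(ids)) {
      ev <- component_events(comp$rows[[id]], comp$cols[[id]],
                             vals_mat[comp$pix[[id]]], pitch, period,
                             config$split_tol_ms)
      out <- c(out, ev)
      src <- c(src, rep(list(id), length(ev)))
    }
    list(events = out, src = src)
  }

  ev <- cands$events
  res_ids <- ev$comp_id[ev$channel == "residual"]
  raw_local_ids <- ev$comp_id[ev$channel == "raw" &
                                ev$width_frac < config$global_width_frac]
  raw_global <- ev[ev$channel == "raw" &
                     ev$width_frac >= config$global_width_frac, , drop = FALSE]

  sc <- split_comps(cands$comp_res, cands$resid, res_ids)
  sub_events <- sc$events
  sub_src <- lapply(sc$src, function(id) list(channel = "residual", id = id))
  # raw-channel local components (rare: events too wide for the median
  # residual to preserve); measured on the residual surface like the rest
  if (length(raw_local_ids)) {
    sc2 <- split_comps(cands$comp_raw, cands$resid, raw_local_ids)
    sub_events <- c(sub_events, sc2$events)
    sub_src <- c(sub_src, lapply(sc2$src, function(id)
      list(channel = "raw", id = id)))
  }

  wave_rows <- list(); paced_rows <- list(); wave_comp_ids <- character(0)
  wave_src_channel <- character(0); wave_src_comp <- character(0)
  for (i in seq_along(sub_events)) {
    e <- sub_events[[i]]
    off <- offset_to_stim(e[["origin_ms"]])
    async <- if (is.na(off)) FALSE else abs(off) > config$async_tol_ms
    slow <- is.finite(e[["velocity_mm_s"]]) &&
      e[["velocity_mm_s"]] < config$v_max_wave_mm_s
    e <- c(e, synchrony_offset_ms = off)
    if (async || slow) {
      wave_rows[[length(wave_rows) + 1L]] <- e
      wave_src_channel <- c(wave_src_channel, sub_src[[i]]$channel)
      wave_src_comp <- c(wave_src_comp, sub_src[[i]]$id)
      if (identical(sub_src[[i]]$channel, "residual"))
        wave_comp_ids <- c(wave_comp_ids, sub_src[[i]]$id)
    } else {
      paced_rows[[length(paced_rows) + 1L]] <- e
    }
  }
  # full-width raw components are the stimulus-evoked transient bands
  if (nrow(raw_global)) {
    for (i in seq_len(nrow(raw_global))) {
      paced_rows[[length(paced_rows) + 1L]] <-
        c(origin_um = (raw_global$row0[i] - 0.5) * pitch,
          origin_ms = raw_global$onset_ms[i],
          extent_um = raw_global$extent_um[i],
          span_ms = raw_global$span_ms[i],
          velocity_mm_s = Inf,
          peak_dff0 = raw_global$peak_dff0[i],
          n_px = raw_global$n_px[i],
          synchrony_offset_ms = offset_to_stim(raw_global$onset_ms[i]))
    }
  }
  as_event_df <- function(rows) {
    cols <- c("origin_um", "origin_ms", "extent_um", "span_ms",
              "velocity_mm_s", "peak_dff0", "n_px", "synchrony_offset_ms")
    if (!length(rows)) {
      out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                           cols))
      return(out)
    }
    as.data.frame(do.call(rbind, rows))
  }
  waves <- as_event_df(wave_rows)
  paced <- as_event_df(paced_rows)
  waves$src_channel <- if (nrow(waves)) wave_src_channel else character(0)
  waves$src_comp <- if (nrow(waves)) wave_src_comp else character(0)

  # Detectability censoring for the coincidence correction: a wave origin is
  # unresolvable if it falls inside the supra-threshold band of another wave
  # (occlusion) or within the prominence dead zone around it (the split
  # tolerance, ~a couple of scan lines), or too close to the end of the scan
  # to build the minimum temporal span. The blocked fraction of eligible
  # (non-refractory) space-time estimates that censoring probability.
  occupancy <- 0
  n_lines <- cands$n_lines
  line_t <- (seq_len(n_lines) - 1) * period
  eligible_line <- rep(TRUE, n_lines)
  for (s in stim)
    eligible_line[line_t >= s & line_t < s + config$refractory_ms] <- FALSE
  n_elig <- sum(eligible_line)
  if (n_elig > 0) {
    blocked <- matrix(FALSE, cands$n_space, n_lines)
    for (id in unique(wave_comp_ids)) blocked[cands$comp_res$pix[[id]]] <- TRUE
    shift_lines <- max(1L, ceiling(config$split_tol_ms / period))
    if (any(blocked)) {
      b <- blocked
      for (k in seq_len(shift_lines)) {
        b[, seq_len(n_lines - k)] <-
          b[, seq_len(n_lines - k)] | blocked[, (k + 1L):n_lines]
        b[, (k + 1L):n_lines] <-
          b[, (k + 1L):n_lines] | blocked[, seq_len(n_lines - k)]
      }
      blocked <- b
    }
    tail_lines <- min(n_lines, ceiling(config$min_span_ms / period))
    blocked[, (n_lines - tail_lines + 1L):n_lines] <- TRUE
    occupancy <- sum(blocked[, eligible_line]) / (cands$n_space * n_elig)
    occupancy <- min(occupancy, 0.9)
  }

  structure(list(waves = waves, paced = paced, occupancy = occupancy,
                 config = config,
                 scan_length_mm = cands$n_space * pitch / 1000,
                 duration_s = cands$n_lines * period / 1000,
                 stimulus_times_ms = stim),
            class = "wave_events")
}

#' Planted-probe estimate of the wave-detection recovery fraction
#'
#' At high event rates a fraction of wave origins is unresolvable in
#' principle: an origin inside (or in the shadow of) another event's
#' supra-threshold band produces no distinct activation-time minimum. This
#' estimates the per-origin recovery probability empirically: clones of
#' detected waves (their supra-threshold residual patches) are planted at
#' uniform positions over the eligible (non-refractory) space-time, the
#' detector is re-run on the augmented image, and the fraction of planted
#' origins recovered as distinct new events is returned. Probes planted too
#' close to another probe are excluded so that the probes measure the real
#' scene's censoring, not their own.
#'
#' @param norm the `normalized_scan` the detection ran on.
#' @param cands the `wave_candidates` from [detect_candidate_events()].
#' @param cls the `wave_events` from [classify_events()].
#' @param n_probes number of planted probes.
#' @param match_um,match_ms matching window between a planted origin and a
#'   recovered event.
#' @return The recovery fraction in (0, 1], or `NA` if no detected wave is
#'   available as a donor (nothing to correct: an empty scene has recovery
#'   ~1 anyway).
#' @export
estimate_wave_recovery <- function(norm, cands, cls, n_probes = 40,
                                   match_um = 60, match_ms = 20) {
  stopifnot(inherits(norm, "normalized_scan"),
            inherits(cands, "wave_candidates"), inherits(cls, "wave_events"))
  waves <- cls$waves
  donors <- which(waves$src_channel == "residual")
  if (!length(donors)) return(NA_real_)
  # prefer donors whose source component holds exactly one event, so a
  # planted patch is a single wave, not a clone of a merged cluster
  cnt <- table(waves$src_comp[donors])
  singles <- donors[cnt[waves$src_comp[donors]] == 1L]
  if (length(singles)) donors <- singles
  config <- cls$config
  pitch <- cands$pixel_pitch_um; period <- cands$line_period_ms
  n_space <- cands$n_space; n_lines <- cands$n_lines
  stim <- cls$stimulus_times_ms
  elig <- eligible_intervals(stim, config$refractory_ms, n_lines * period)
  if (!nrow(elig)) return(NA_real_)

  x_p <- stats::runif(n_probes, 0, n_space * pitch)
  t_p <- sample_in_intervals(n_probes, elig)
  # exclude probes interacting with an earlier probe
  span_x <- stats::median(waves$extent_um[donors]) * 1.5 + 2 * match_um
  span_t <- stats::median(waves$span_ms[donors]) * 1.5 + 2 * match_ms
  clean <- rep(TRUE, n_probes)
  for (j in seq_len(n_probes)[-1]) {
    prev <- seq_len(j - 1L)
    if (any(abs(x_p[j] - x_p[prev]) < span_x & abs(t_p[j] - t_p[prev]) < span_t))
      clean[j] <- FALSE
  }
  aug <- norm
  planted_rows <- integer(0)
  for (j in which(clean)) {
    d <- donors[[sample.int(length(donors), 1L)]]
    id <- waves$src_comp[d]
    rows <- cands$comp_res$rows[[id]]
    cols <- cands$comp_res$cols[[id]]
    vals <- cands$resid[cands$comp_res$pix[[id]]]
    drow <- round((x_p[j] - waves$origin_um[d]) / pitch)
    dcol <- round((t_p[j] - waves$origin_ms[d]) / period)
    nr <- rows + drow; ncv <- cols + dcol
    ok <- nr >= 1L & nr <= n_space & ncv >= 1L & ncv <= n_lines
    if (!any(ok)) { clean[j] <- FALSE; next }
    aug$dff0[cbind(nr[ok], ncv[ok])] <-
      aug$dff0[cbind(nr[ok], ncv[ok])] + vals[ok]
    planted_rows <- c(planted_rows, j)
  }
  if (!length(planted_rows)) return(NA_real_)
  cands2 <- detect_candidate_events(aug, config)
  cls2 <- suppressWarnings(classify_events(cands2, stim, config))
  w2 <- cls2$waves
  # detection is deterministic, so events untouched by a probe keep exactly
  # the same origin: the set difference isolates probe-caused origins
  key <- function(w) paste(round(w$origin_um, 6), round(w$origin_ms, 6))
  fresh <- w2[!key(w2) %in% key(waves), , drop = FALSE]
  recovered <- vapply(planted_rows, function(j)
    any(abs(fresh$origin_um - x_p[j]) < match_um &
          abs(fresh$origin_ms - t_p[j]) < match_ms),
    logical(1))
  p_hat <- mean(recovered)
  m <- length(recovered)
  # delta-method debias of the downstream 1/p correction:
  # E[n/p_hat] ~ (n/p) (1 + (1-p)/(m p)), so pre-inflate p_hat accordingly
  p_hat <- p_hat * (1 + (1 - p_hat) / (m * max(p_hat, 0.1)))
  min(max(p_hat, 1e-3), 1)
}

#' Ca2+ wave frequency in waves per millimetre per second
#'
#' Counts wave onsets inside the analysis window (half-open: an event counts
#' iff its onset is inside) and divides by scanned line length times window
#' duration. `frequency` is the raw count-based value
#' `n_waves / (scan_length_mm * duration_s)` exactly; `frequency_corrected`
#' additionally divides by `(1 - occupancy)`, the probability that a wave
#' origin falls outside the space-time already occupied by another detected
#' wave — a coincidence correction that removes the censoring bias at high
#' event rates. At low rates the two coincide.
#'
#' @param waves a `wave_events` object from [classify_events()] (or a plain
#'   data.frame of wave rows, in which case no occupancy is available).
#' @param scan the source [linescan_image()] (provides geometry and pacing).
#' @param analysis_window_ms `c(start, end)` in ms; default is the full scan.
#' @param recovery optional per-origin recovery probability from
#'   [estimate_wave_recovery()]; when supplied, `frequency_corrected`
#'   divides by it instead of the geometric `(1 - occupancy)` factor.
#' @return A data.frame of class `wave_frequency_result`: `n_waves`,
#'   `scan_length_mm`, `duration_s`, `frequency`, `frequency_corrected`,
#'   `occupancy`, `recovery`, `pacing_hz`.
#' @export
wave_frequency <- function(waves, scan, analysis_window_ms = NULL,
                           recovery = NULL) {
  stopifnot(inherits(scan, "linescan_image"))
  occ <- 0
  wdf <- waves
  if (inherits(waves, "wave_events")) {
    occ <- waves$occupancy
    wdf <- waves$waves
  }
  t_end <- ncol(scan$pixels) * scan$line_period_ms
  win <- analysis_window_ms %||% c(0, t_end)
  if (length(win) != 2L || !is.numeric(win) || diff(win) <= 0)
    abort_validation("'analysis_window_ms' must be c(start, end) with end > start")
  n <- if (nrow(wdf)) sum(wdf$origin_ms >= win[1L] & wdf$origin_ms < win[2L]) else 0L
  len_mm <- scan_length_mm(scan)
  dur_s <- diff(win) / 1000
  stim <- scan$stimulus_times_ms
  pacing_hz <- if (length(stim) >= 2L) 1000 / stats::median(diff(stim)) else 0
  p_rec <- if (!is.null(recovery) && is.finite(recovery) && recovery > 0)
    recovery else 1 - occ
  out <- data.frame(n_waves = n, scan_length_mm = len_mm, duration_s = dur_s,
                    frequency = n / (len_mm * dur_s),
                    frequency_corrected = n / (len_mm * dur_s * p_rec),
                    occupancy = occ,
                    recovery = if (is.null(recovery)) NA_real_ else recovery,
                    pacing_hz = pacing_hz)
  class(out) <- c("wave_frequency_result", "data.frame")
  out
}

#' One-stop wave analysis of a line-scan image
#'
#' @param image a [linescan_image()].
#' @param config a [wave_config()].
#' @param f0 optional precomputed `f0_estimate`.
#' @param analysis_window_ms counting window passed to [wave_frequency()].
#' @param probe_correction estimate the detection recovery fraction with
#'   [estimate_wave_recovery()] and use it for `frequency_corrected`
#'   (default); with `FALSE` the cheaper geometric occupancy factor is used.
#' @param n_probes probes for the recovery estimate.
#' @return List with `waves`, `paced` (data.frames), `frequency` (a
#'   `wave_frequency_result`) and `recovery`.
#' @export
analyze_waves <- function(image, config = wave_config(), f0 = NULL,
                          analysis_window_ms = NULL, probe_correction = TRUE,
                          n_probes = 40) {
  norm <- normalize_scan(image, f0)
  cands <- detect_candidate_events(norm, config)
  cls <- classify_events(cands)
  recovery <- NULL
  if (isTRUE(probe_correction) && nrow(cls$waves))
    recovery <- estimate_wave_recovery(norm, cands, cls, n_probes = n_probes)
  list(waves = cls$waves, paced = cls$paced,
       frequency = wave_frequency(cls, image, analysis_window_ms, recovery),
       recovery = recovery)
}
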