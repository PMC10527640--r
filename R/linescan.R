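#' Line-scan image container
#'
#' A `linescan_image` holds one single-channel confocal line-scan recording as
#' a space-by-time intensity matrix together with its physical calibration and
#' protocol annotations. Rows are spatial pixels along the scanned line
#' (pixel centres at `(i - 0.5) * pixel_pitch_um` for 1-based row `i`),
#' columns are successive scan lines (line `j` starts at
#' `(j - 1) * line_period_ms`).
#'
#' @param pixels numeric matrix `[space x time]` of non-negative, finite
#'   fluorescence intensities (arbitrary units).
#' @param pixel_pitch_um micrometres per spatial pixel (> 0).
#' @param line_period_ms milliseconds per scan line (> 0).
#' @param stimulus_times_ms strictly increasing vector of pacing-stimulus or
#'   sinus-beat times in ms, all within `[0, n_lines * line_period_ms)`. May
#'   be empty (quiescent protocols).
#' @param protocol_tag one of `"sinus"`, `"paced"`, `"pre_tetracaine"`,
#'   `"post_tetracaine"`, `"baseline"`, `"caffeine"`.
#' @param group_tag free-form experimental group label (e.g. `"wt_sham"`).
#' @return An object of class `linescan_image`.
#' @export
linescan_image <- function(pixels, pixel_pitch_um, line_period_ms,
                           stimulus_times_ms = numeric(0),
                           protocol_tag = "sinus", group_tag = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_validation("'pixels' must be a numeric matrix [space x time]")
  if (any(!is.finite(pixels)))
    abort_validation("all intensities must be finite")
  if (any(pixels < 0))
    abort_validation("all intensities must be >= 0")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    abort_validation("'pixel_pitch_um' must be a single positive number")
  if (!is.numeric(line_period_ms) || length(line_period_ms) != 1L ||
      !is.finite(line_period_ms) || line_period_ms <= 0)
    abort_validation("'line_period_ms' must be a single positive number")
  stimulus_times_ms <- as.numeric(stimulus_times_ms)
  if (length(stimulus_times_ms)) {
    if (any(diff(stimulus_times_ms) <= 0))
      abort_validation("'stimulus_times_ms' must be strictly increasing")
    t_end <- ncol(pixels) * line_period_ms
    if (stimulus_times_ms[1L] < 0 ||
        stimulus_times_ms[length(stimulus_times_ms)] >= t_end)
      abort_validation("stimulus times must lie within [0, n_lines * line_period_ms)")
  }
  protocol_tag <- match.arg(protocol_tag, protocol_tags())
  structure(
    list(pixels = pixels,
         pixel_pitch_um = pixel_pitch_um,
         line_period_ms = line_period_ms,
         stimulus_times_ms = stimulus_times_ms,
         protocol_tag = protocol_tag,
         group_tag = as.character(group_tag)[1L]),
    class = "linescan_image")
}

protocol_tags <- function() {
  c("sinus", "paced", "pre_tetracaine", "post_tetracaine",
    "baseline", "caffeine")
}

#' Physical length of the scanned line in millimetres
#' @param image a `linescan_image`.
#' @return Scan length in mm (`n_space_pixels * pixel_pitch_um / 1000`).
#' @export
scan_length_mm <- function(image) {
  stopifnot(inherits(image, "linescan_image"))
  nrow(image$pixels) * image$pixel_pitch_um / 1000
}

#' Duration of a recording in seconds
#' @param image a `linescan_image`.
#' @return `n_lines * line_period_ms / 1000`.
#' @export
scan_duration_s <- function(image) {
  stopifnot(inherits(image, "linescan_image"))
  ncol(image$pixels) * image$line_period_ms / 1000
}

#' Start times of the scan lines in milliseconds
#' @param image a `linescan_image`.
#' @return Numeric vector of line start times.
#' @export
line_times_ms <- function(image) {
  stopifnot(inherits(image, "linescan_image"))
  (seq_len(ncol(image$pixels)) - 1) * image$line_period_ms
}

#' @export
print.linescan_image <- function(x, ...) {
  cat(sprintf(
    "<linescan_image> %d px x %d lines | %.3f mm x %.2f s | %s%s | %d stimuli\n",
    nrow(x$pixels), ncol(x$pixels), scan_length_mm(x), scan_duration_s(x),
    x$protocol_tag,
    if (nzchar(x$group_tag)) paste0(" (", x$group_tag, ")") else "",
    length(x$stimulus_times_ms)))
  invisible(x)
}

#' Bundle recordings from one imaging session into a recording set
#'
#' Groups recordings by protocol tag and resolves the paired protocols used by
#' the flux measurements: `pre_tetracaine`/`post_tetracaine` for the
#' tetracaine-sensitive SR leak and `baseline`/`caffeine` for the
#' caffeine-releasable SR load. Each protocol tag may appear at most once, and
#' both members of a pair must share their spatial and temporal calibration.
#'
#' @param recordings list of `linescan_image` objects.
#' @return An object of class `recording_set` with elements `recordings`
#'   (named by protocol tag) and `pairing` (named list of resolved pairs).
#' @export
recording_set <- function(recordings) {
  if (!is.list(recordings) || length(recordings) < 1L)
    abort_validation("'recordings' must be a non-empty list of linescan_image")
  if (!all(vapply(recordings, inherits, logical(1), "linescan_image")))
    abort_validation("every element of 'recordings' must be a linescan_image")
  tags <- vapply(recordings, `[[`, character(1), "protocol_tag")
  if (anyDuplicated(tags))
    abort_validation(sprintf("duplicate protocol tag within set: %s",
                             paste(unique(tags[duplicated(tags)]), collapse = ", ")))
  names(recordings) <- tags
  pairing <- list()
  pairs <- list(leak = c("pre_tetracaine", "post_tetracaine"),
                load = c("baseline", "caffeine"))
  for (kind in names(pairs)) {
    members <- pairs[[kind]]
    if (all(members %in% tags)) {
      a <- recordings[[members[1L]]]
      b <- recordings[[members[2L]]]
      if (a$pixel_pitch_um != b$pixel_pitch_um ||
          a$line_period_ms != b$line_period_ms)
        abort_validation(sprintf(
          "calibration mismatch within the %s pair (%s vs %s)",
          kind, members[1L], members[2L]))
      pairing[[kind]] <- members
    }
  }
  structure(list(recordings = recordings, pairing = pairing),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> %d recording(s): %s | pairs: %s\n",
              length(x$recordings),
              paste(names(x$recordings), collapse = ", "),
              if (length(x$pairing)) paste(names(x$pairing), collapse = ", ")
              else "none"))
  invisible(x)
}

# Fetch one member of a resolved pair, with a pairing error if absent.
set_member <- function(set, kind, tag) {
  stopifnot(inherits(set, "recording_set"))
  if (is.null(set$pairing[[kind]]))
    abort_pairing(sprintf(
      "recording set has no resolved %s pair (needs both %s recordings)",
      kind, paste(if (kind == "leak") c("pre_tetracaine", "post_tetracaine")
                  else c("baseline", "caffeine"), collapse = " and ")))
  set$recordings[[tag]]
}
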