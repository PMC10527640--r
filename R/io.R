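# On-disk contract: single-page grayscale TIFF (x-t raster) plus a YAML
# sidecar carrying the physical calibration and protocol annotations.
# Integer-valued images are stored as 16-bit TIFF and round-trip exactly;
# anything else falls back to 32-bit float with an intensity_scale key
# (float32 precision, documented).

required_meta_keys <- c("pixel_pitch_um", "line_period_ms", "protocol")

#' Read a line-scan image and its sidecar metadata
#'
#' @param image_path path to a single-channel grayscale TIFF (x-t raster).
#' @param meta_path path to the YAML sidecar declaring at least
#'   `pixel_pitch_um`, `line_period_ms` and `protocol`. Optional keys:
#'   `group`, `stimulus_times_ms`, `layout` (`"space_time"`, the default, or
#'   `"time_space"` for transposed rasters) and `intensity_scale` (written by
#'   [write_linescan()] for float images).
#' @return A validated [linescan_image()]; the in-memory orientation is always
#'   `[space x time]` regardless of the on-disk layout flag.
#' @export
read_linescan <- function(image_path, meta_path) {
  if (!file.exists(image_path))
    abort_input(sprintf("image file not found: %s", image_path))
  if (!file.exists(meta_path))
    abort_input(sprintf("metadata file not found: %s", meta_path))
  px <- tryCatch(tiff::readTIFF(image_path, as.is = TRUE, all = FALSE),
                 error = function(e)
                   abort_input(sprintf("cannot read TIFF '%s': %s",
                                       image_path, conditionMessage(e))))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] != 1L)
      abort_input("multi-channel TIFF: a single-channel grayscale image is required")
    px <- px[, , 1L]
  }
  meta <- tryCatch(yaml::read_yaml(meta_path),
                   error = function(e)
                     abort_schema(sprintf("cannot parse metadata '%s': %s",
                                          meta_path, conditionMessage(e))))
  missing <- setdiff(required_meta_keys, names(meta))
  if (length(missing))
    abort_schema(sprintf("metadata missing required key(s): %s",
                         paste(missing, collapse = ", ")))
  for (k in c("pixel_pitch_um", "line_period_ms")) {
    v <- meta[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort_validation(sprintf("metadata key '%s' must be a positive number", k))
  }
  layout <- meta$layout %||% "space_time"
  if (!layout %in% c("space_time", "time_space"))
    abort_schema("metadata 'layout' must be 'space_time' or 'time_space'")
  px <- storage_to_matrix(px)
  if (identical(layout, "time_space")) px <- t(px)
  if (!is.null(meta$intensity_scale)) px <- px * meta$intensity_scale
  linescan_image(
    pixels = px,
    pixel_pitch_um = meta$pixel_pitch_um,
    line_period_ms = meta$line_period_ms,
    stimulus_times_ms = as.numeric(meta$stimulus_times_ms %||% numeric(0)),
    protocol_tag = meta$protocol,
    group_tag = meta$group %||% "")
}

# readTIFF returns [rows = image height, cols = width]; we write rasters so
# that TIFF rows are spatial pixels, so no flip is needed, only a plain cast.
storage_to_matrix <- function(px) {
  storage.mode(px) <- "double"
  px
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a line-scan image plus sidecar metadata
#'
#' Inverse of [read_linescan()]: `read_linescan(write_linescan(x))` preserves
#' pixel values exactly for integer-valued images (16-bit storage) and to
#' 32-bit float precision otherwise, and preserves metadata to full precision.
#'
#' @param image a [linescan_image()].
#' @param image_path,meta_path output paths for the TIFF and the YAML sidecar.
#' @return Invisibly, a list with the two paths.
#' @export
write_linescan <- function(image, image_path, meta_path) {
  stopifnot(inherits(image, "linescan_image"))
  px <- image$pixels
  meta <- list(
    pixel_pitch_um = image$pixel_pitch_um,
    line_period_ms = image$line_period_ms,
    protocol = image$protocol_tag,
    group = image$group_tag,
    stimulus_times_ms = as.numeric(image$stimulus_times_ms),
    layout = "space_time")
  integral <- all(px == round(px)) && max(px) <= 65535
  ok <- tryCatch({
    if (integral) {
      tiff::writeTIFF(px / 65535, image_path, bits.per.sample = 16L,
                      compression = "none")
    } else {
      scale <- max(px, 1)
      meta$intensity_scale <- scale
      tiff::writeTIFF(px / scale, image_path, bits.per.sample = 32L,
                      compression = "none")
    }
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok))
    abort_input(sprintf("cannot write TIFF '%s': %s", image_path, ok))
  yaml::write_yaml(meta, meta_path, precision = 15L)
  invisible(list(image_path = image_path, meta_path = meta_path))
}

#' Read several recordings and assemble them into a recording set
#'
#' @param entries list of `c(image_path, meta_path)` pairs (or a two-column
#'   character matrix / data.frame).
#' @return A [recording_set()] with pairing invariants validated.
#' @export
assemble_recording_set <- function(entries) {
  if (is.data.frame(entries) || is.matrix(entries))
    entries <- lapply(seq_len(nrow(entries)), function(i) unlist(entries[i, ]))
  if (!length(entries))
    abort_validation("'entries' must contain at least one (image, metadata) pair")
  recs <- lapply(entries, function(e) {
    if (length(e) != 2L)
      abort_validation("each entry must be a (image_path, meta_path) pair")
    read_linescan(e[[1L]], e[[2L]])
  })
  recording_set(recs)
}
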