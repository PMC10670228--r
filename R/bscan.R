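#' Construct a B-scan object
#'
#' A B-scan is a depth x width log-intensity image (dB, 0 dB at the frame
#' maximum) with physical pixel pitches and provenance.
#'
#' @param image Numeric matrix, rows = depth, columns = lateral position.
#' @param depth_pitch Depth sampling pitch in micrometres per pixel (in air).
#' @param lateral_pitch Lateral pitch in micrometres per pixel.
#' @param volume_id Identifier of the parent volume (or `NA`).
#' @param frame_index Frame index within the volume (or `NA`).
#' @return An object of class `oct_bscan`.
#' @export
new_bscan <- function(image, depth_pitch, lateral_pitch,
                      volume_id = NA_character_, frame_index = NA_integer_) {
  check_matrix(image, "image")
  if (!all(is.finite(image))) oct_abort("B-scan image must be finite")
  check_number(depth_pitch, "depth_pitch")
  check_number(lateral_pitch, "lateral_pitch")
  structure(
    list(image = image,
         depth_pitch = depth_pitch,
         lateral_pitch = lateral_pitch,
         volume_id = volume_id,
         frame_index = frame_index),
    class = "oct_bscan"
  )
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf(
    "<oct_bscan> %d x %d px (%.2f um depth, %.2f um lateral pitch), volume %s frame %s\n",
    nrow(x$image), ncol(x$image), x$depth_pitch, x$lateral_pitch,
    as.character(x$volume_id), as.character(x$frame_index)))
  invisible(x)
}

# Coerce an oct_bscan or plain matrix to a matrix.
bscan_matrix <- function(x) {
  if (inherits(x, "oct_bscan")) x$image else check_matrix(x, "image")
}
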