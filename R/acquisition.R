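#' Acquisition metadata for a synthetic imaging experiment
#'
#' Bundles the camera timing and geometry that every simulated or analysed
#' dataset carries: the frame interval, the exposure time within each frame,
#' the pixel size, the field of view and the number of frames. The two
#' regimes used for kinetic imaging of bilayer-tethered ligands are short
#' exposures (tens of milliseconds), where fast and slow molecules are both
#' resolved, and long exposures (hundreds of milliseconds), where fast
#' diffusers blur into background and only receptor-bound molecules remain
#' point-like.
#'
#' @param frame_interval Time between frame starts, seconds.
#' @param exposure_time Integration time per frame, seconds; must not exceed
#'   `frame_interval`. Defaults to the full frame interval.
#' @param pixel_size Pixel edge length in micrometers (default 0.105).
#' @param field_size Integer vector `c(nx, ny)` in pixels, at least 16 x 16.
#' @param n_frames Number of frames in the acquisition.
#'
#' @return An object of class `acquisition_meta` (a named list).
#' @examples
#' meta <- acquisition_meta(frame_interval = 0.0175, n_frames = 200)
#' meta$pixel_size
#' @export
acquisition_meta <- function(frame_interval,
                             exposure_time = frame_interval,
                             pixel_size = 0.105,
                             field_size = c(64L, 64L),
                             n_frames = 100L) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop_smkin("frame_interval must be a single positive number (seconds)",
               "smkin_invalid_metadata")
  }
  if (!is.numeric(exposure_time) || exposure_time <= 0 ||
      exposure_time > frame_interval + 1e-12) {
    stop_smkin("exposure_time must satisfy 0 < exposure_time <= frame_interval",
               "smkin_invalid_metadata")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop_smkin("pixel_size must be positive (micrometers)",
               "smkin_invalid_metadata")
  }
  field_size <- as.integer(field_size)
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  if (any(field_size < 16L)) {
    stop_smkin("field_size must be at least 16 x 16 pixels",
               "smkin_invalid_metadata")
  }
  if (!is_count(n_frames)) {
    stop_smkin("n_frames must be a positive integer", "smkin_invalid_metadata")
  }
  structure(
    list(frame_interval = frame_interval,
         exposure_time = exposure_time,
         pixel_size = pixel_size,
         field_size = field_size,
         n_frames = as.integer(n_frames)),
    class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf(
    "<acquisition_meta> %d frames @ %.4g s (exposure %.4g s), %dx%d px, %.3f um/px\n",
    x$n_frames, x$frame_interval, x$exposure_time,
    x$field_size[1], x$field_size[2], x$pixel_size))
  invisible(x)
}

# Field extent in micrometers; pixel origin at the center of the top-left
# pixel, so world coordinate = pixel index (0-based) * pixel_size.
field_extent_um <- function(meta) meta$field_size * meta$pixel_size
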