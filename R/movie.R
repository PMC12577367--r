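#' Multi-channel time-lapse movie container
#'
#' A `division_movie` holds a role-tagged multi-channel raster time series with
#' its physical calibration. Pixel data live in a 4-D numeric array indexed
#' `[y, x, channel, frame]` (1-based, row = y); channel roles (e.g. `histone`,
#' `actin`, `membrane`, `tubulin`, `focus_marker`) name the third dimension.
#'
#' @param data Numeric 4-D array `[y, x, channel, frame]`.
#' @param channels Character vector of channel roles, one per channel slice;
#'   roles must be unique.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @param frame_interval_min Time between frames in minutes. Frame `f` is
#'   acquired at `(f - 1) * frame_interval_min` minutes.
#'
#' @return An object of class `division_movie`.
#' @export
new_movie <- function(data, channels, pixel_size_um, frame_interval_min) {
  if (length(dim(data)) != 4) {
    abort("`data` must be a 4-D array [y, x, channel, frame].")
  }
  if (length(channels) != dim(data)[3]) {
    abort("`channels` must name every channel slice of `data`.")
  }
  if (anyDuplicated(channels)) {
    abort("channel roles must be unique.")
  }
  stopifnot(pixel_size_um > 0, frame_interval_min > 0)
  dimnames(data) <- list(NULL, NULL, channels, NULL)
  structure(
    list(
      data = data,
      channels = as.character(channels),
      pixel_size_um = pixel_size_um,
      frame_interval_min = frame_interval_min
    ),
    class = "division_movie"
  )
}

#' @export
print.division_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(
    sprintf(
      "<division_movie> %d x %d px, %d channel(s) [%s], %d frame(s)\n",
      d[1], d[2], d[3], paste(x$channels, collapse = ", "), d[4]
    ),
    sprintf(
      "  calibration: %.4g um/px, %.4g min/frame\n",
      x$pixel_size_um, x$frame_interval_min
    )
  )
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A `division_movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[4]

#' Extract one channel of one frame
#'
#' @param movie A `division_movie`.
#' @param role Channel role name (e.g. `"histone"`).
#' @param frame 1-based frame index.
#' @return A numeric matrix `[y, x]`.
#' @export
movie_channel <- function(movie, role, frame) {
  if (!role %in% movie$channels) {
    abort(sprintf("channel role '%s' not present (have: %s).",
                  role, paste(movie$channels, collapse = ", ")))
  }
  if (frame < 1 || frame > n_frames(movie)) {
    abort(sprintf("frame %d out of range [1, %d].", frame, n_frames(movie)))
  }
  movie$data[, , role, frame]
}

#' Time of a frame, and first frame at or after a time
#'
#' Frame `f` (1-based) is acquired at `(f - 1) * frame_interval_min` minutes.
#' `frame_at_time()` returns the first frame whose acquisition time is at or
#' after `t_min`; events are considered visible from that frame onwards.
#'
#' @param frame 1-based frame index (vectorised).
#' @param t_min Time in minutes (vectorised).
#' @param frame_interval_min Minutes per frame.
#' @return Minutes (`frame_time`) or 1-based frame indices (`frame_at_time`).
#' @export
frame_time <- function(frame, frame_interval_min) {
  (frame - 1) * frame_interval_min
}

#' @rdname frame_time
#' @export
frame_at_time <- function(t_min, frame_interval_min) {
  as.integer(ceiling(t_min / frame_interval_min - 1e-9)) + 1L
}
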