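# Movie I/O: multi-page 32-bit float TIFF (frame-major, channel-interleaved
# pages) plus a JSON sidecar carrying channel roles, calibration and the
# intensity scale used to map values into the [0, 1] range TIFF stores.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a movie to a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major (all channels of frame 1, then frame 2,
#' ...). Intensities are divided by their global maximum and stored as
#' 32-bit float; the sidecar records the scale, channel roles and physical
#' calibration so that [read_movie()] restores the movie exactly at float32
#' precision.
#'
#' @param movie A `division_movie`.
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  scale <- max(movie$data, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 0L
  for (f in seq_len(d[4])) {
    for (ci in seq_len(d[3])) {
      k <- k + 1L
      pages[[k]] <- movie$data[, , ci, f] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(
      channels = movie$channels,
      pixel_size_um = movie$pixel_size_um,
      frame_interval_min = movie$frame_interval_min,
      intensity_scale = scale,
      n_frames = d[4],
      shape_px = d[1:2]
    ),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a movie from a multi-page TIFF
#'
#' Metadata come from the JSON sidecar written by [write_movie()]; for
#' plain TIFFs without a sidecar, the channel layout and calibration must be
#' supplied, and a missing calibration is an error naming the field.
#'
#' @param path TIFF path.
#' @param channels Channel roles in page order (overrides the sidecar).
#' @param pixel_size_um,frame_interval_min Calibration overrides.
#' @param intensity_scale Multiplier restoring stored values to intensities.
#' @return A `division_movie`.
#' @export
read_movie <- function(path, channels = NULL, pixel_size_um = NULL,
                       frame_interval_min = NULL, intensity_scale = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'.", path))
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list()
  }
  channels <- channels %||% meta$channels
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  frame_interval_min <- frame_interval_min %||% meta$frame_interval_min
  intensity_scale <- intensity_scale %||% meta$intensity_scale %||% 1
  for (field in c("channels", "pixel_size_um", "frame_interval_min")) {
    if (is.null(get(field))) {
      abort(sprintf("missing metadata field '%s': no sidecar and no override.",
                    field))
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  n_ch <- length(channels)
  if (length(pages) %% n_ch != 0) {
    abort("page count is not a multiple of the channel count.")
  }
  nf <- length(pages) %/% n_ch
  d1 <- dim(pages[[1]])
  data <- array(0, c(d1[1], d1[2], n_ch, nf))
  k <- 0L
  for (f in seq_len(nf)) {
    for (ci in seq_len(n_ch)) {
      k <- k + 1L
      data[, , ci, f] <- pages[[k]] * intensity_scale
    }
  }
  new_movie(data, channels, pixel_size_um, frame_interval_min)
}
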