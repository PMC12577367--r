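# Midzone region of interest: the rectangle between the two nucleus
# centroids where the cleavage furrow and post-anaphase actin patches sit.

#' Build the midzone ROI between two nuclei
#'
#' The rectangle is centred on the midpoint of the two nucleus centroids,
#' with its height dimension (half the internuclear centroid distance) along
#' the internuclear axis and its width (twice the mean nuclear major axis)
#' perpendicular to it.
#'
#' @param region_a,region_b One-row tibbles (or lists) with `centroid_y`,
#'   `centroid_x` and `major_axis_px`, e.g. rows of [label_nuclei()].
#' @return A `midzone_roi` object: `center` (y, x), `axis` unit vector
#'   (y, x) from A to B, `height_px`, `width_px`.
#' @export
build_midzone_roi <- function(region_a, region_b) {
  ay <- region_a$centroid_y; ax <- region_a$centroid_x
  by <- region_b$centroid_y; bx <- region_b$centroid_x
  d <- sqrt((by - ay)^2 + (bx - ax)^2)
  if (d <= 0) {
    abort("nucleus centroids coincide: midzone axis is undefined.",
          class = "nocutr_degenerate_roi")
  }
  structure(
    list(
      center = c(y = (ay + by) / 2, x = (ax + bx) / 2),
      axis = c(y = (by - ay) / d, x = (bx - ax) / d),
      height_px = d / 2,
      width_px = 2 * mean(c(region_a$major_axis_px, region_b$major_axis_px))
    ),
    class = "midzone_roi"
  )
}

#' @export
print.midzone_roi <- function(x, ...) {
  cat(sprintf(
    "<midzone_roi> center (%.2f, %.2f), axis (%.3f, %.3f), height %.2f px, width %.2f px\n",
    x$center["y"], x$center["x"], x$axis["y"], x$axis["x"],
    x$height_px, x$width_px
  ))
  invisible(x)
}

#' Rasterize a midzone ROI to a pixel mask
#'
#' A pixel belongs to the rectangle when its center lies inside the oriented
#' rectangle, boundary inclusive.
#'
#' @param roi A [build_midzone_roi()] object.
#' @param dim Image dimensions `c(height, width)`.
#' @return Logical matrix.
#' @export
roi_mask <- function(roi, dim) {
  g <- coord_grids(dim[1], dim[2])
  dy <- g$y - roi$center["y"]
  dx <- g$x - roi$center["x"]
  u <- dy * roi$axis["y"] + dx * roi$axis["x"]        # along internuclear axis
  v <- -dy * roi$axis["x"] + dx * roi$axis["y"]       # perpendicular
  abs(u) <= roi$height_px / 2 + 1e-12 & abs(v) <= roi$width_px / 2 + 1e-12
}
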