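# Midbody quantification from tubulin Z-stacks: best-focus slice, five-slice
# maximum projection, moments-matched "tight" ellipse, total intensity.

check_rect <- function(rect, dim) {
  if (is.null(rect$y) || is.null(rect$x) ||
      length(rect$y) != 2 || length(rect$x) != 2) {
    abort("`seed_roi` must be list(y = c(ymin, ymax), x = c(xmin, xmax)).")
  }
  y <- sort(as.integer(rect$y)); x <- sort(as.integer(rect$x))
  if (y[1] < 1 || y[2] > dim[1] || x[1] < 1 || x[2] > dim[2]) {
    abort("`seed_roi` must lie inside the image.")
  }
  list(y = y, x = x)
}

#' Select the best-focused slice of a tubulin stack
#'
#' The best-focused slice maximises the intensity variance of the tubulin
#' signal within the seed ROI (sharp structures have high local contrast;
#' defocus blurs it away). `method = "integrated"` instead maximises total
#' intensity. Ties resolve to the lowest slice index.
#'
#' @param tubulin_stack 3-D array `[y, x, z]`.
#' @param seed_roi `list(y = c(ymin, ymax), x = c(xmin, xmax))`.
#' @param method `"variance"` (default) or `"integrated"`.
#' @return 1-based slice index.
#' @export
select_best_focus <- function(tubulin_stack, seed_roi,
                              method = c("variance", "integrated")) {
  method <- match.arg(method)
  d <- dim(tubulin_stack)
  r <- check_rect(seed_roi, d)
  crop <- tubulin_stack[r$y[1]:r$y[2], r$x[1]:r$x[2], , drop = FALSE]
  if (length(crop) == 0) abort("empty seed ROI.")
  score <- apply(crop, 3, function(m) {
    if (method == "variance") var(as.vector(m)) else sum(m)
  })
  which.max(score)  # which.max returns the first (lowest) index on ties
}

#' Maximum projection of the five slices around a center slice
#'
#' Per-pixel maximum over slices `z_center - 2` to `z_center + 2`, clipped
#' to the stack bounds (edge slices use the available slices).
#'
#' @param stack 3-D array `[y, x, z]`.
#' @param z_center Center slice (1-based).
#' @return Numeric matrix.
#' @export
project_five <- function(stack, z_center) {
  nz <- dim(stack)[3]
  zs <- max(1L, z_center - 2L):min(nz, z_center + 2L)
  apply(stack[, , zs, drop = FALSE], c(1, 2), max)
}

#' Fit a tight ellipse to the midbody tubulin signal
#'
#' Otsu-thresholds the tubulin projection inside the seed ROI, keeps the
#' largest 8-connected component, and returns its moments-matched ellipse:
#' centroid from first moments, semi-axes `2 sqrt(eigenvalues)` of the pixel
#' covariance (which recovers the semi-axes of a filled ellipse exactly),
#' orientation from the principal eigenvector. By default the moments are
#' weighted by the background-subtracted tubulin intensity (background =
#' median outside the mask), which down-weights the dim defocus halo that a
#' maximum projection attaches to the component and makes the fit robust to
#' read noise; `weighted = FALSE` gives plain binary-mask moments.
#'
#' @param tubulin_projection Numeric matrix (e.g. [project_five()] output).
#' @param seed_roi `list(y = c(ymin, ymax), x = c(xmin, xmax))`.
#' @param weighted Weight moments by background-subtracted intensity.
#' @return List of class `midbody_ellipse`: `center` (y, x),
#'   `semi_major_px`, `semi_minor_px`, `angle_rad` (major axis from +x
#'   towards +y), `component_area_px`, `background`.
#' @export
fit_midbody_ellipse <- function(tubulin_projection, seed_roi,
                                weighted = TRUE) {
  d <- dim(tubulin_projection)
  r <- check_rect(seed_roi, d)
  crop <- tubulin_projection[r$y[1]:r$y[2], r$x[1]:r$x[2], drop = FALSE]
  mask <- tryCatch(
    threshold_positive(crop, method = "otsu"),
    nocutr_ambiguous_threshold = function(e) NULL
  )
  if (is.null(mask) || !any(mask)) {
    abort("no midbody signal in the seed ROI.", class = "NO_MIDBODY_SIGNAL")
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big)
  h <- nrow(crop)
  ys <- ((idx - 1) %% h) + 1 + r$y[1] - 1
  xs <- ((idx - 1) %/% h) + 1 + r$x[1] - 1
  bg <- if (all(mask)) 0 else median(crop[lab == 0])
  w <- if (weighted) pmax(crop[idx] - bg, 0) else rep(1, length(idx))
  if (sum(w) <= 0) w <- rep(1, length(idx))
  cy <- sum(w * ys) / sum(w)
  cx <- sum(w * xs) / sum(w)
  cyy <- sum(w * (ys - cy)^2) / sum(w)
  cxx <- sum(w * (xs - cx)^2) / sum(w)
  cxy <- sum(w * (ys - cy) * (xs - cx)) / sum(w)
  ev <- eigen(matrix(c(cyy, cxy, cxy, cxx), 2), symmetric = TRUE)
  vec <- ev$vectors[, 1]  # (y, x) direction of the major axis
  structure(
    list(
      center = c(y = cy, x = cx),
      semi_major_px = 2 * sqrt(max(ev$values[1], 0)),
      semi_minor_px = 2 * sqrt(max(ev$values[2], 0)),
      angle_rad = atan2(vec[1], vec[2]) %% pi,
      component_area_px = length(idx),
      background = bg
    ),
    class = "midbody_ellipse"
  )
}

#' Measure total intensity inside a midbody ellipse
#'
#' Mean intensity over pixels whose centers fall inside the ellipse, area as
#' that pixel count (and in um^2 via the calibration), and total intensity
#' as the exact product area (px^2) x mean. A constant `background` offset
#' may be subtracted from the mean before the product (the only background
#' correction in scope).
#'
#' @param channel_projection Numeric matrix: channel of interest, projected
#'   the same way as the tubulin used for the fit.
#' @param ellipse A [fit_midbody_ellipse()] result.
#' @param pixel_size_um Optional calibration for `area_um2`.
#' @param background Constant offset subtracted from the mean intensity.
#' @param cell_id,z_best Optional metadata carried into the result.
#' @return One-row tibble: `cell_id`, `z_best`, ellipse geometry, `area_px`,
#'   `area_um2`, `mean_intensity`, `total_intensity`.
#' @export
measure_total_intensity <- function(channel_projection, ellipse,
                                    pixel_size_um = NULL, background = 0,
                                    cell_id = NA, z_best = NA_integer_) {
  d <- dim(channel_projection)
  g <- coord_grids(d[1], d[2])
  inside <- ellipse_mask(g, ellipse$center["y"], ellipse$center["x"],
                         ellipse$semi_major_px, ellipse$semi_minor_px,
                         ellipse$angle_rad)
  if (!any(inside)) {
    abort("ellipse covers no pixel centers inside the image.")
  }
  area_px <- sum(inside)
  mean_int <- mean(channel_projection[inside]) - background
  tibble(
    cell_id = cell_id, z_best = z_best,
    center_y = unname(ellipse$center["y"]),
    center_x = unname(ellipse$center["x"]),
    semi_major_px = ellipse$semi_major_px,
    semi_minor_px = ellipse$semi_minor_px,
    angle_rad = ellipse$angle_rad,
    area_px = area_px,
    area_um2 = if (is.null(pixel_size_um)) NA_real_ else area_px * pixel_size_um^2,
    mean_intensity = mean_int,
    total_intensity = area_px * mean_int
  )
}
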