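# Membrane-channel intensity profiles along the mother-daughter axis at the
# bud neck: single- vs double-peak classification and abscission timing.

bilinear <- function(img, y, x) {
  h <- nrow(img); w <- ncol(img)
  y <- pmin(pmax(y, 1), h)
  x <- pmin(pmax(x, 1), w)
  y0 <- pmin(floor(y), h - 1); x0 <- pmin(floor(x), w - 1)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

#' Extract a membrane intensity profile across the neck
#'
#' Samples the membrane channel along the mother-daughter axis segment at
#' ~1 px spacing, averaging over a perpendicular band of `+/- half_width_px`.
#' A Z-stack input is first aggregated by maximum (or mean) projection.
#'
#' @param x A `division_movie` (uses its `membrane` channel and
#'   calibration), a numeric matrix, or a 3-D array `[y, x, z]`.
#' @param axis_endpoints List with elements `from` and `to`, each `c(y, x)`
#'   in pixels (e.g. `ground_truth$neck_axis`).
#' @param half_width_px Half width of the perpendicular averaging band.
#' @param frame Frame index (movie input).
#' @param pixel_size_um Calibration (required for matrix/array input).
#' @param z_reduce `"max"` or `"mean"` projection for stack input.
#' @return Tibble of class `neck_profile`: `position_um`, `intensity`;
#'   attributes `frame` and `pixel_size_um`.
#' @export
extract_neck_profile <- function(x, axis_endpoints, half_width_px = 2,
                                 frame = NULL, pixel_size_um = NULL,
                                 z_reduce = c("max", "mean")) {
  z_reduce <- match.arg(z_reduce)
  if (inherits(x, "division_movie")) {
    if (is.null(frame)) abort("`frame` is required for movie input.")
    img <- movie_channel(x, "membrane", frame)
    pixel_size_um <- pixel_size_um %||% x$pixel_size_um
  } else if (length(dim(x)) == 3) {
    img <- apply(x, c(1, 2), if (z_reduce == "max") max else mean)
  } else {
    img <- x
  }
  if (is.null(pixel_size_um)) abort("`pixel_size_um` is required.")
  from <- axis_endpoints$from; to <- axis_endpoints$to
  h <- nrow(img); w <- ncol(img)
  pts <- rbind(from, to)
  if (any(pts[, 1] < 1 | pts[, 1] > h | pts[, 2] < 1 | pts[, 2] > w)) {
    abort("axis endpoints must lie inside the image.")
  }
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) abort("axis segment has zero length.")
  u <- (to - from) / len
  v <- c(-u[2], u[1])  # perpendicular
  ts <- seq(0, len, length.out = ceiling(len) + 1)
  offs <- seq(-half_width_px, half_width_px)
  ints <- vapply(ts, function(t) {
    py <- from[1] + t * u[1] + offs * v[1]
    px <- from[2] + t * u[2] + offs * v[2]
    mean(bilinear(img, py, px))
  }, numeric(1))
  out <- tibble(position_um = ts * pixel_size_um, intensity = ints)
  attr(out, "frame") <- frame
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("neck_profile", class(out))
  out
}

# candidate local maxima (plateaus collapse to their first index) and their
# topographic prominences
profile_peaks <- function(ints) {
  n <- length(ints)
  cand <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ints[j + 1] == ints[i]) j <- j + 1L
    left_ok <- i == 1L || ints[i - 1] < ints[i]
    right_ok <- j == n || ints[j + 1] < ints[i]
    strict <- !(i == 1L && j == n)  # a fully flat profile has no peak
    if (left_ok && right_ok && strict && !(i == 1L || j == n)) {
      cand <- c(cand, i)
    }
    i <- j + 1L
  }
  prom <- vapply(cand, function(p) {
    hgt <- ints[p]
    lmin <- hgt; k <- p
    while (k > 1 && ints[k - 1] <= hgt) {
      k <- k - 1
      lmin <- min(lmin, ints[k])
    }
    left_base <- if (k == 1) min(ints[1:p]) else lmin
    rmin <- hgt; k <- p
    while (k < length(ints) && ints[k + 1] <= hgt) {
      k <- k + 1
      rmin <- min(rmin, ints[k])
    }
    right_base <- if (k == length(ints)) min(ints[p:length(ints)]) else rmin
    hgt - max(left_base, right_base)
  }, numeric(1))
  list(index = cand, prominence = prom)
}

#' Classify a neck profile as single- or double-peaked
#'
#' Local maxima with topographic prominence of at least `prominence_rel`
#' times the profile maximum are accepted peaks. One accepted peak means the
#' membranes have not separated (`SINGLE`); two or more peaks whose maximal
#' pairwise separation reaches `min_separation_um` mark membrane separation
#' (`DOUBLE`); anything else — including an all-zero profile — is
#' `AMBIGUOUS`. The call is invariant under multiplicative intensity
#' scaling.
#'
#' @param profile A [extract_neck_profile()] tibble.
#' @param prominence_rel Relative prominence cutoff.
#' @param min_separation_um Minimum peak separation for a `DOUBLE` call.
#' @return One-row tibble: `frame`, `n_peaks`, `classification`,
#'   `peak_positions_um` (list column), `peak_separation_um`.
#' @export
classify_profile <- function(profile, prominence_rel = 0.25,
                             min_separation_um = 0.4) {
  if (nrow(profile) < 5) abort("profile needs at least 5 samples.")
  ints <- profile$intensity
  frame <- attr(profile, "frame") %||% NA_integer_
  res <- function(n, cls, pos, sep) {
    tibble(frame = frame, n_peaks = n, classification = cls,
           peak_positions_um = list(pos), peak_separation_um = sep)
  }
  if (max(ints) <= 0) return(res(0L, "AMBIGUOUS", numeric(), NA_real_))
  pk <- profile_peaks(ints)
  acc <- pk$index[pk$prominence >= prominence_rel * max(ints)]
  if (length(acc) == 0) return(res(0L, "AMBIGUOUS", numeric(), NA_real_))
  pos <- profile$position_um[acc]
  if (length(acc) == 1) return(res(1L, "SINGLE", pos, NA_real_))
  sep <- max(pos) - min(pos)
  if (sep >= min_separation_um) {
    res(length(acc), "DOUBLE", pos, sep)
  } else {
    res(length(acc), "AMBIGUOUS", pos, NA_real_)
  }
}

#' Time from membrane ingression to abscission
#'
#' Abscission is the first frame at/after ingression whose `DOUBLE` call is
#' sustained for `persistence_frames` consecutive frames; a transient double
#' peak does not count. Returns elapsed minutes from ingression, or `NA`
#' when membrane separation is never sustained within the recording
#' (censored); completion horizons (e.g. 60 min) are applied downstream.
#'
#' @param calls Tibble of [classify_profile()] rows for consecutive frames.
#' @param t_ingression_min Ingression time in minutes.
#' @param persistence_frames Consecutive `DOUBLE` frames required.
#' @param frame_interval_min Minutes per frame.
#' @return Minutes from ingression, or `NA` (censored).
#' @export
time_to_abscission <- function(calls, t_ingression_min, persistence_frames = 2L,
                               frame_interval_min) {
  if (is.null(calls) || nrow(calls) == 0) abort("`calls` must be nonempty.")
  calls <- calls[order(calls$frame), ]
  sub <- calls[frame_time(calls$frame, frame_interval_min) >=
                 t_ingression_min - 1e-9, ]
  if (nrow(sub) == 0) return(NA_real_)
  dbl <- sub$classification == "DOUBLE"
  run <- 0L
  for (i in seq_along(dbl)) {
    run <- if (dbl[i]) run + 1L else 0L
    if (run >= persistence_frames) {
      f <- sub$frame[i - persistence_frames + 1L]
      return(frame_time(f, frame_interval_min) - t_ingression_min)
    }
  }
  NA_real_
}

profile_fwhm <- function(profile) {
  ints <- profile$intensity
  pos <- profile$position_um
  if (max(ints) <= 0) return(NA_real_)
  p <- which.max(ints)
  half <- ints[p] / 2
  # walk left
  l <- p
  while (l > 1 && ints[l - 1] >= half) l <- l - 1
  left <- if (l == 1) pos[1] else {
    pos[l - 1] + (pos[l] - pos[l - 1]) * (half - ints[l - 1]) / (ints[l] - ints[l - 1])
  }
  r <- p
  n <- length(ints)
  while (r < n && ints[r + 1] >= half) r <- r + 1
  right <- if (r == n) pos[n] else {
    pos[r] + (pos[r + 1] - pos[r]) * (ints[r] - half) / (ints[r] - ints[r + 1])
  }
  right - left
}

#' Detect membrane ingression from profile narrowing
#'
#' Ingression is the first frame whose full width at half maximum of the
#' neck profile falls below `ingression_fraction` times its baseline (median
#' FWHM of the first `baseline_frames` frames), sustained for `persistence`
#' frames. Returns the frame index, or `NA` when no narrowing occurs.
#'
#' @param profiles List of [extract_neck_profile()] tibbles for consecutive
#'   frames.
#' @param ingression_fraction Required FWHM reduction.
#' @param baseline_frames,persistence Baseline window and persistence.
#' @return 1-based frame index or `NA` (censored).
#' @export
detect_ingression <- function(profiles, ingression_fraction = 0.6,
                              baseline_frames = 5L, persistence = 2L) {
  if (length(profiles) < 3) abort("need at least 3 frames of profiles.")
  widths <- map_dbl(profiles, profile_fwhm)
  frames <- map_dbl(profiles, function(p) attr(p, "frame") %||% NA_real_)
  if (any(is.na(frames))) frames <- seq_along(profiles)
  baseline <- median(widths[seq_len(min(baseline_frames, length(widths)))],
                     na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) return(NA_integer_)
  cond <- !is.na(widths) & widths < ingression_fraction * baseline
  for (i in seq_len(length(cond) - persistence + 1L)) {
    if (all(cond[i:(i + persistence - 1L)])) return(as.integer(frames[i]))
  }
  NA_integer_
}
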