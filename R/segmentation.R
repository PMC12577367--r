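# Histone-channel segmentation: thresholding, 8-connected components,
# nucleus geometry, chromatin-bridge status and RPA focus calls.

#' Threshold an image into a positive-signal mask
#'
#' Pixels strictly above the threshold are positive. With `method = "otsu"`
#' the threshold is computed per image by Otsu's criterion; a constant image
#' has no meaningful Otsu threshold and raises an error of class
#' `nocutr_ambiguous_threshold` (callers may fall back to `method = "fixed"`).
#'
#' @param image Numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold for `method = "fixed"`.
#' @param levels Histogram bins for Otsu.
#' @return Logical mask with attribute `threshold`.
#' @export
threshold_positive <- function(image, method = c("otsu", "fixed"),
                               value = NULL, levels = 256L) {
  method <- match.arg(method)
  if (length(image) == 0) abort("`image` must be nonempty.")
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0) {
      abort("constant image: Otsu threshold is ambiguous.",
            class = "nocutr_ambiguous_threshold")
    }
    thr <- EBImage::otsu(image, range = rng, levels = levels)
  } else {
    if (is.null(value)) abort("`value` is required for method = 'fixed'.")
    thr <- value
  }
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Zero out sub-threshold pixels
#'
#' The actin-channel variant of thresholding: background pixels are set to
#' zero so that only positive signal contributes to downstream intensity
#' statistics.
#'
#' @param image Numeric matrix.
#' @param mask Logical mask from [threshold_positive()].
#' @return Numeric matrix with sub-threshold pixels set to 0.
#' @export
zero_below <- function(image, mask) {
  image * mask
}

shift_matrix <- function(M, dy, dx, fill = NA) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h
  okx <- xs >= 1 & xs <= w
  out[oky, okx] <- M[ys[oky], xs[okx], drop = FALSE]
  out
}

eight_shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                     c(0, 1), c(1, -1), c(1, 0), c(1, 1))

# 8-connected component labelling by iterated minimum-label propagation.
# Returns an integer matrix, background 0, components labelled 1..n in
# raster (column-major first-pixel) order.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  L <- matrix(as.numeric(seq_len(h * w)), h, w)
  L[!mask] <- NA
  repeat {
    Ln <- L
    for (d in eight_shifts) {
      Ln <- pmin(Ln, shift_matrix(L, d[1], d[2]), na.rm = TRUE)
    }
    Ln[!mask] <- NA
    if (identical(Ln, L)) break
    L <- Ln
  }
  ids <- sort(unique(L[mask]))
  lab[mask] <- match(L[mask], ids)
  lab
}

# dilate a logical mask by one pixel, 8-connectivity
dilate1 <- function(mask) {
  out <- mask
  for (d in eight_shifts) {
    out <- out | shift_matrix(mask, d[1], d[2], fill = FALSE)
  }
  out
}

region_moments <- function(ys, xs) {
  n <- length(ys)
  cy <- mean(ys); cx <- mean(xs)
  syy <- mean((ys - cy)^2)
  sxx <- mean((xs - cx)^2)
  sxy <- mean((ys - cy) * (xs - cx))
  ev <- eigen(matrix(c(syy, sxy, sxy, sxx), 2), symmetric = TRUE)
  list(cy = cy, cx = cx, major = 4 * sqrt(max(ev$values, 0)),
       minor = 4 * sqrt(max(min(ev$values), 0)))
}

#' Segment nuclei from a thresholded histone mask
#'
#' Labels 8-connected components, discards those smaller than `min_area_px`,
#' and measures each region: unweighted mask centroid, area, major axis
#' length from second-order moments (4 sqrt of the largest eigenvalue of the
#' pixel covariance, which recovers the diameter of a disk), and whether the
#' region touches the image border (border-touching regions are excluded
#' from downstream geometry).
#'
#' @param mask Logical matrix from [threshold_positive()].
#' @param min_area_px Minimum region area in pixels.
#' @param frame Optional frame index recorded in the output.
#' @return A tibble (class `nucleus_set`) with columns `frame`, `label`,
#'   `centroid_y`, `centroid_x`, `area_px`, `major_axis_px`,
#'   `touches_border`, and attribute `labels` holding the label matrix of
#'   the retained regions.
#' @export
label_nuclei <- function(mask, min_area_px = 20L, frame = NA_integer_) {
  lab <- label_components(mask)
  h <- nrow(mask); w <- ncol(mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  keep_lab <- matrix(0L, h, w)
  rows <- list()
  new_id <- 0L
  for (id in sort(ids)) {
    idx <- which(lab == id)
    if (length(idx) < min_area_px) next
    ys <- ((idx - 1) %% h) + 1
    xs <- ((idx - 1) %/% h) + 1
    m <- region_moments(ys, xs)
    new_id <- new_id + 1L
    keep_lab[idx] <- new_id
    rows[[new_id]] <- tibble(
      frame = frame, label = new_id,
      centroid_y = m$cy, centroid_x = m$cx,
      area_px = length(idx), major_axis_px = m$major,
      touches_border = any(ys == 1 | ys == h | xs == 1 | xs == w)
    )
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    frame = integer(), label = integer(), centroid_y = numeric(),
    centroid_x = numeric(), area_px = integer(), major_axis_px = numeric(),
    touches_border = logical()
  )
  attr(out, "labels") <- keep_lab
  class(out) <- c("nucleus_set", class(out))
  out
}

#' Keep only frames with exactly two interior nuclei
#'
#' Frames whose count of non-border-touching regions differs from two are
#' dropped; border-touching regions do not count against a frame.
#'
#' @param sets A list of [label_nuclei()] tibbles (one per frame).
#' @return The filtered list, named by frame index where available.
#' @export
select_two_nuclei_frames <- function(sets) {
  keep <- map_lgl(sets, function(s) sum(!s$touches_border) == 2L)
  out <- sets[keep]
  frames <- map_dbl(out, function(s) {
    if (nrow(s)) s$frame[1] else NA_real_
  })
  if (!any(is.na(frames))) names(out) <- frames
  out
}

#' Classify the chromatin-bridge status of one frame
#'
#' A frame is `CONNECTED` when one positive component of the histone mask
#' touches both nucleus masks; `FRAGMENTED` when positive objects of at
#' least `min_object_px` pixels lie in the midzone corridor outside the
#' nuclei without connecting them; `RESOLVED` otherwise. Both `CONNECTED`
#' and `FRAGMENTED` count as unresolved for bridge timing, because stretched
#' bridge DNA can drop below the detection limit in places while the bridge
#' persists.
#'
#' @param histone_mask Logical matrix: positive histone signal (typically a
#'   lower threshold than the one used to segment nuclei, so that the dim
#'   bridge is included).
#' @param nuclei A [label_nuclei()] result with exactly two interior regions.
#' @param corridor A [build_midzone_roi()] region.
#' @param min_object_px Minimum size for a bridge fragment.
#' @param frame Optional frame index recorded in the output.
#' @return One-row tibble: `frame`, `status`, `corridor_positive_px` (size of
#'   the largest bridge object in the corridor).
#' @export
detect_bridge <- function(histone_mask, nuclei, corridor, min_object_px = 4L,
                          frame = NA_integer_) {
  interior <- nuclei[!nuclei$touches_border, ]
  if (nrow(interior) != 2) {
    abort("`nuclei` must contain exactly two interior regions.",
          class = "nocutr_precondition_error")
  }
  lab_n <- attr(nuclei, "labels")
  if (is.null(lab_n)) abort("`nuclei` is missing its label matrix.")
  mask_a <- lab_n == interior$label[1]
  mask_b <- lab_n == interior$label[2]
  comp <- label_components(histone_mask)
  ids_a <- setdiff(unique(comp[dilate1(mask_a)]), 0L)
  ids_b <- setdiff(unique(comp[dilate1(mask_b)]), 0L)
  connected <- length(intersect(ids_a, ids_b)) > 0

  cmask <- roi_mask(corridor, dim(histone_mask))
  bridge_px <- histone_mask & cmask & !(lab_n > 0)
  biggest <- 0L
  if (any(bridge_px)) {
    sizes <- table(comp[bridge_px])
    sizes <- sizes[names(sizes) != "0"]
    if (length(sizes)) biggest <- as.integer(max(sizes))
  }
  status <- if (connected) {
    "CONNECTED"
  } else if (biggest >= min_object_px) {
    "FRAGMENTED"
  } else {
    "RESOLVED"
  }
  tibble(frame = frame, status = status, corridor_positive_px = biggest)
}

#' Time of chromatin-bridge resolution
#'
#' The resolution frame is the first frame at/after anaphase onset whose
#' status is `RESOLVED` and that is never followed by a non-`RESOLVED`
#' frame (transient disappearances do not count as resolution). Returns the
#' elapsed time from anaphase onset in minutes, or `NA` when the bridge
#' never resolves within the recording (censored).
#'
#' @param statuses Tibble of [detect_bridge()] rows, ordered by `frame`.
#' @param t_anaphase_min Anaphase-onset time in minutes.
#' @param frame_interval_min Minutes per frame.
#' @return Minutes from anaphase onset, or `NA` (censored).
#' @export
bridge_resolution_time <- function(statuses, t_anaphase_min,
                                   frame_interval_min) {
  if (is.null(statuses) || nrow(statuses) == 0) {
    abort("`statuses` must be nonempty.")
  }
  statuses <- statuses[order(statuses$frame), ]
  sub <- statuses[frame_time(statuses$frame, frame_interval_min) >=
                    t_anaphase_min - 1e-9, ]
  if (nrow(sub) == 0) return(NA_real_)
  resolved <- sub$status == "RESOLVED"
  if (!any(resolved)) return(NA_real_)
  bad <- which(!resolved)
  if (length(bad) == 0) {
    f <- sub$frame[1]
  } else if (max(bad) == nrow(sub)) {
    return(NA_real_)
  } else {
    f <- sub$frame[max(bad) + 1]
  }
  frame_time(f, frame_interval_min) - t_anaphase_min
}

#' Detect anaphase onset from a chromatin major-axis trace
#'
#' Anaphase onset is defined by the rapid elongation of the chromatin mass:
#' the first frame whose major axis is at least `elongation_factor` times
#' the pre-division baseline (median of the first `baseline_frames` frames),
#' sustained for `persistence` consecutive frames.
#'
#' @param trace Numeric vector of per-frame major-axis lengths (px), or a
#'   tibble with a `major_axis_px` column such as [chromatin_axis_trace()].
#' @param baseline_frames Frames used for the baseline median.
#' @param elongation_factor Required fold increase over baseline.
#' @param persistence Consecutive frames the increase must be sustained.
#' @return 1-based frame index of onset, or `NA` if elongation is never
#'   sustained (censored).
#' @export
detect_anaphase_onset <- function(trace, baseline_frames = 5L,
                                  elongation_factor = 1.5, persistence = 2L) {
  if (is.data.frame(trace)) trace <- trace$major_axis_px
  n <- length(trace)
  if (n < baseline_frames + 2L) {
    abort("trace too short for baseline + detection.")
  }
  baseline <- median(trace[seq_len(baseline_frames)])
  cond <- trace >= elongation_factor * baseline
  for (f in seq_len(n - persistence + 1L)) {
    if (all(cond[f:(f + persistence - 1L)])) return(f)
  }
  NA_integer_
}

#' Per-frame major axis of the whole chromatin mass
#'
#' Thresholds the histone channel of every frame and measures the major axis
#' of all foreground pixels treated as one object; feeds
#' [detect_anaphase_onset()].
#'
#' @param movie A `division_movie`.
#' @param method,value Passed to [threshold_positive()].
#' @return Tibble with `frame` and `major_axis_px`.
#' @export
chromatin_axis_trace <- function(movie, method = "otsu", value = NULL) {
  rows <- map(seq_len(n_frames(movie)), function(f) {
    img <- movie_channel(movie, "histone", f)
    mask <- threshold_positive(img, method = method, value = value)
    idx <- which(mask)
    if (length(idx) < 3) {
      return(tibble(frame = f, major_axis_px = 0))
    }
    h <- nrow(mask)
    m <- region_moments(((idx - 1) %% h) + 1, ((idx - 1) %/% h) + 1)
    tibble(frame = f, major_axis_px = m$major)
  })
  bind_rows(rows)
}

#' Detect RPA-like foci inside nucleus masks
#'
#' The nucleoplasmic background is the median intensity over the nucleus
#' masks; foci are 8-neighbourhood local maxima inside the masks whose
#' intensity exceeds `background + k * MAD`, merged greedily (brightest
#' first) within `min_separation_px`. Focus counts are non-increasing in
#' `k`.
#'
#' @param focus_channel Numeric matrix (focus-marker channel).
#' @param nucleus_masks Logical matrix or [label_nuclei()] label matrix.
#' @param k Robust z-score cutoff above the nucleoplasmic background.
#' @param min_separation_px Minimum distance between reported foci.
#' @return Tibble of foci (`y`, `x`, `peak_intensity`, `nucleus_label`) with
#'   attributes `background_level` and `cutoff`.
#' @export
detect_rpa_foci <- function(focus_channel, nucleus_masks, k = 3,
                            min_separation_px = 2) {
  lab <- if (is.logical(nucleus_masks)) {
    matrix(as.integer(nucleus_masks), nrow(nucleus_masks))
  } else {
    nucleus_masks
  }
  inside <- lab > 0
  if (!any(inside)) abort("nucleus masks are empty.")
  vals <- focus_channel[inside]
  bg <- median(vals)
  cutoff <- bg + k * mad(vals)

  is_max <- matrix(TRUE, nrow(focus_channel), ncol(focus_channel))
  for (d in eight_shifts) {
    nb <- shift_matrix(focus_channel, d[1], d[2], fill = -Inf)
    is_max <- is_max & (focus_channel >= nb)
  }
  cand <- which(is_max & inside & focus_channel > cutoff)
  h <- nrow(focus_channel)
  out <- tibble(
    y = ((cand - 1) %% h) + 1,
    x = ((cand - 1) %/% h) + 1,
    peak_intensity = focus_channel[cand],
    nucleus_label = lab[cand]
  )
  out <- out[order(-out$peak_intensity, out$y, out$x), ]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    d2 <- (out$y[keep] - out$y[i])^2 + (out$x[keep] - out$x[i])^2
    keep[i] <- all(d2 > min_separation_px^2)
  }
  out <- out[keep, ]
  attr(out, "background_level") <- bg
  attr(out, "cutoff") <- cutoff
  out
}
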