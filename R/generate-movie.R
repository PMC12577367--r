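# Synthetic cytokinesis movies with ground truth.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# event active on frame f (time t) iff t_start <= t < t_end; NA start = never,
# NA end = until movie end
event_active <- function(t, t_start, t_end = NA) {
  if (is.na(t_start)) return(FALSE)
  t >= t_start && (is.na(t_end) || t < t_end)
}

#' Generate a synthetic division movie with ground truth
#'
#' Renders the analytic scene described by [scene_params()] frame by frame
#' (histone, actin, membrane and tubulin channels), then applies the camera
#' model: Poisson shot noise on the clean signal (optional), additive Gaussian
#' read noise, a constant background offset, and clipping at zero. All
#' randomness derives from `params$seed` through per-purpose sub-streams, so
#' identical parameters give bit-identical movies.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `movie` (a [new_movie()] object) and
#'   `ground_truth`: the parameters, an event table (`event`, `t_min`,
#'   `frame`, `observed`), per-frame true nucleus centroids and major axes,
#'   actin-cluster positions, the noise-free scene array (`clean`), and the
#'   neck axis endpoints used by the membrane profiler.
#' @export
generate_division_movie <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  validate_scene_params(params)
  p <- params
  h <- p$image_shape_px[1]; w <- p$image_shape_px[2]
  g <- coord_grids(h, w)
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  channels <- c("histone", "actin", "membrane", "tubulin")
  clean <- array(0, c(h, w, length(channels), p$n_frames),
                 dimnames = list(NULL, NULL, channels, NULL))

  # one draw per movie: cluster geometry
  cl <- with_seed(sub_seed(p$seed, 10L), {
    if (p$n_clusters > 0) {
      tibble(
        y = cy0 + runif(p$n_clusters, -8, 8),
        x = cx0 + runif(p$n_clusters, -4, 4),
        peak = p$cluster_peak * runif(p$n_clusters, 0.85, 1.15)
      )
    } else {
      tibble(y = numeric(), x = numeric(), peak = numeric())
    }
  })

  sep_max_px <- max(4, w - 5 * p$nucleus_sigma_px)
  half_max <- sqrt(2 * log(2))  # mask radius of a Gaussian at half maximum
  centroids <- vector("list", p$n_frames)

  for (f in seq_len(p$n_frames)) {
    t <- frame_time(f, p$frame_interval_min)

    # --- nuclei ------------------------------------------------------------
    d <- 0
    if (!is.na(p$t_anaphase_min) && t >= p$t_anaphase_min) {
      d <- min(p$separation_speed_um_per_min * (t - p$t_anaphase_min) /
                 p$pixel_size_um, sep_max_px)
    }
    xa <- cx0 - d / 2; xb <- cx0 + d / 2
    hist_f <- pmax(gauss_blob(g, cy0, xa, p$nucleus_sigma_px, p$nucleus_peak),
                   gauss_blob(g, cy0, xb, p$nucleus_sigma_px, p$nucleus_peak))
    centroids[[f]] <- tibble(
      frame = f, y_a = cy0, x_a = xa, y_b = cy0, x_b = xb,
      separation_px = d,
      major_axis_px = 2 * half_max * p$nucleus_sigma_px
    )

    # --- chromatin bridge ---------------------------------------------------
    if (event_active(t, p$t_anaphase_min, p$t_bridge_resolve_min) &&
        d > 2.4 * p$nucleus_sigma_px && p$bridge_peak > 0) {
      x1 <- xa + 1.2 * p$nucleus_sigma_px
      x2 <- xb - 1.2 * p$nucleus_sigma_px
      line <- p$bridge_peak * exp(-(g$y - cy0)^2 / (2 * p$bridge_width_px^2))
      if (p$bridge_fragmented) {
        len <- x2 - x1
        in_frag <- (g$x >= x1 + 0.10 * len & g$x <= x1 + 0.40 * len) |
                   (g$x >= x1 + 0.60 * len & g$x <= x1 + 0.90 * len)
      } else {
        in_frag <- g$x >= xa & g$x <= xb  # reaches into both nuclei: connected
      }
      hist_f <- pmax(hist_f, line * in_frag)
    }
    clean[, , "histone", f] <- hist_f

    # --- actin: furrow band, then clusters ---------------------------------
    act_f <- matrix(0, h, w)
    yband <- abs(g$y - cy0) <= 2.5 * p$nucleus_sigma_px
    if (event_active(t, p$t_anaphase_min, p$t_cluster_start_min)) {
      act_f <- p$furrow_peak *
        exp(-(g$x - cx0)^2 / (2 * p$furrow_sigma_px^2)) * yband
    } else if (event_active(t, p$t_cluster_start_min, p$t_clear_min) &&
               nrow(cl) > 0) {
      for (i in seq_len(nrow(cl))) {
        act_f <- pmax(act_f, gauss_blob(g, cl$y[i], cl$x[i],
                                        p$cluster_sigma_px, cl$peak[i]))
      }
    }
    clean[, , "actin", f] <- act_f

    # --- membrane: neck ridge, narrowing then splitting ---------------------
    sigma_m <- p$membrane_ridge_sigma_px
    if (event_active(t, p$t_ingression_min)) sigma_m <- sigma_m / 2
    neck <- abs(g$y - cy0) <= 0.3 * h
    if (event_active(t, p$t_abscission_min)) {
      gap_px <- p$post_abscission_gap_um / p$pixel_size_um
      mem_f <- pmax(
        exp(-(g$x - (cx0 - gap_px / 2))^2 / (2 * sigma_m^2)),
        exp(-(g$x - (cx0 + gap_px / 2))^2 / (2 * sigma_m^2))
      )
    } else {
      mem_f <- exp(-(g$x - cx0)^2 / (2 * sigma_m^2))
    }
    clean[, , "membrane", f] <- p$membrane_peak * mem_f * neck

    # --- tubulin: midbody ellipse -------------------------------------------
    if (event_active(t, p$t_midbody_form_min, p$t_midbody_sever_min)) {
      mb <- ellipse_mask(g, cy0, cx0, p$midbody_semi_major_px,
                         p$midbody_semi_minor_px, pi / 2)
      clean[, , "tubulin", f] <- p$midbody_peak * mb
    }
  }

  # --- camera model ----------------------------------------------------------
  noisy <- clean
  for (ci in seq_along(channels)) {
    noisy[, , ci, ] <- with_seed(sub_seed(p$seed, ci), {
      x <- clean[, , ci, ]
      if (p$poisson_noise) x[] <- rpois(length(x), lambda = x)
      if (p$read_noise_sd > 0) x <- x + rnorm(length(x), 0, p$read_noise_sd)
      pmax(x + p$background_offset, 0)
    })
  }

  horizon <- frame_time(p$n_frames, p$frame_interval_min)
  ev <- tibble(
    event = c("anaphase", "ingression", "abscission", "midbody_form",
              "midbody_sever", "bridge_resolve", "cluster_start", "clear"),
    t_min = c(p$t_anaphase_min, p$t_ingression_min, p$t_abscission_min,
              p$t_midbody_form_min, p$t_midbody_sever_min,
              p$t_bridge_resolve_min, p$t_cluster_start_min, p$t_clear_min)
  )
  ev$observed <- !is.na(ev$t_min) & ev$t_min <= horizon
  ev$frame <- ifelse(ev$observed,
                     frame_at_time(ev$t_min, p$frame_interval_min), NA_integer_)

  gt <- structure(
    list(
      params = p,
      events = ev,
      centroids = bind_rows(centroids),
      clusters = cl,
      clean = clean,
      neck_axis = list(
        from = c(y = cy0, x = max(1, cx0 - 0.25 * w)),
        to = c(y = cy0, x = min(w, cx0 + 0.25 * w))
      )
    ),
    class = "ground_truth"
  )

  list(
    movie = new_movie(noisy, channels, p$pixel_size_um, p$frame_interval_min),
    ground_truth = gt
  )
}

#' Ground-truth event time
#'
#' @param ground_truth A `ground_truth` object from [generate_division_movie()].
#' @param event Event name (e.g. `"abscission"`, `"clear"`).
#' @return Time in minutes, or `NA` if the event never happens.
#' @export
true_event_time <- function(ground_truth, event) {
  ev <- ground_truth$events
  if (!event %in% ev$event) {
    abort(sprintf("unknown event '%s'.", event))
  }
  ev$t_min[ev$event == event]
}
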