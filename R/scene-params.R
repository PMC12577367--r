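#' Parameters for a synthetic cytokinesis movie
#'
#' Defines the analytic scene rendered by [generate_division_movie()]: two
#' Gaussian nuclei that separate after anaphase onset, an optional chromatin
#' bridge (contiguous or fragmented) persisting until resolution, a midzone
#' actin furrow followed by bright long-lived actin clusters, a membrane
#' ridge across the neck that narrows at ingression and splits into two
#' ridges at abscission, and a midbody-like tubulin ellipse. Event times are
#' in minutes from the start of the recording; an `NA` time means the event
#' never happens (downstream scoring sees it as censored at movie end).
#'
#' Defaults emulate a HeLa-style recording: 0.2 um/px, one frame every 5 min,
#' 60 frames (295 min), anaphase at 20 min, actin clusters from 35 to 80 min
#' (clearance ~60 min after anaphase onset, the behaviour of unperturbed
#' cells), midbody lifetime 130 min. For a yeast-style membrane recording use
#' `frame_interval_min = 2` and a shorter horizon.
#'
#' @param image_shape_px Integer `(height, width)` in pixels.
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @param frame_interval_min Minutes between frames.
#' @param n_frames Number of frames.
#' @param t_anaphase_min,t_ingression_min,t_abscission_min Times of anaphase
#'   onset, membrane ingression and abscission (minutes, or `NA`).
#' @param t_midbody_form_min,t_midbody_sever_min Midbody formation/severing
#'   times (minutes, or `NA`); their difference is the midbody lifetime.
#' @param t_bridge_resolve_min Time at which the chromatin bridge disappears
#'   (`NA`: never resolves within the recording).
#' @param t_cluster_start_min,t_clear_min Actin clusters replace the furrow at
#'   `t_cluster_start_min` and disappear at `t_clear_min` (`NA`: never clear).
#' @param nucleus_sigma_px,nucleus_peak Gaussian sigma (px) and peak amplitude
#'   of each nucleus in the histone channel.
#' @param separation_speed_um_per_min Speed at which the two nucleus centroids
#'   separate from anaphase onset.
#' @param bridge_width_px,bridge_peak Gaussian cross-section sigma and peak of
#'   the chromatin bridge (histone channel).
#' @param bridge_fragmented If `TRUE` the bridge is rendered as two disjoint
#'   fragments that touch neither nucleus.
#' @param n_clusters,cluster_sigma_px,cluster_peak Number, sigma and peak of
#'   post-furrow actin clusters.
#' @param furrow_peak,furrow_sigma_px Peak and cross-section sigma of the
#'   actin furrow band.
#' @param membrane_ridge_sigma_px,membrane_peak Sigma (along the division
#'   axis) and peak of the membrane neck ridge.
#' @param post_abscission_gap_um Separation of the two membrane ridges after
#'   abscission (must exceed the classifier's minimum peak separation for the
#'   double-peak call to be reachable).
#' @param midbody_peak,midbody_semi_major_px,midbody_semi_minor_px Tubulin
#'   ellipse intensity and semi-axes.
#' @param background_offset Constant camera offset added last.
#' @param read_noise_sd Gaussian read-noise standard deviation (0 = none).
#' @param poisson_noise Apply Poisson shot noise to the clean signal first.
#' @param seed Integer seed; same `(params, seed)` gives bit-identical movies.
#'
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(image_shape_px = c(96L, 128L),
                         pixel_size_um = 0.2,
                         frame_interval_min = 5,
                         n_frames = 60L,
                         t_anaphase_min = 20,
                         t_ingression_min = 30,
                         t_abscission_min = 50,
                         t_midbody_form_min = 40,
                         t_midbody_sever_min = 170,
                         t_bridge_resolve_min = 40,
                         t_cluster_start_min = 35,
                         t_clear_min = 80,
                         nucleus_sigma_px = 6,
                         nucleus_peak = 200,
                         separation_speed_um_per_min = 0.6,
                         bridge_width_px = 1.5,
                         bridge_peak = 60,
                         bridge_fragmented = FALSE,
                         n_clusters = 3L,
                         cluster_sigma_px = 2.5,
                         cluster_peak = 150,
                         furrow_peak = 150,
                         furrow_sigma_px = 2,
                         membrane_ridge_sigma_px = 2,
                         membrane_peak = 180,
                         post_abscission_gap_um = 0.8,
                         midbody_peak = 180,
                         midbody_semi_major_px = 8,
                         midbody_semi_minor_px = 3,
                         background_offset = 10,
                         read_noise_sd = 3,
                         poisson_noise = TRUE,
                         seed = 1L) {
  p <- as.list(environment())
  p$image_shape_px <- as.integer(image_shape_px)
  p$n_frames <- as.integer(n_frames)
  p$seed <- as.integer(seed)
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  stopifnot(
    length(p$image_shape_px) == 2, all(p$image_shape_px >= 8),
    p$pixel_size_um > 0, p$frame_interval_min > 0, p$n_frames >= 2,
    p$nucleus_sigma_px > 0, p$nucleus_peak > 0,
    p$separation_speed_um_per_min > 0,
    p$bridge_width_px > 0, p$bridge_peak >= 0,
    p$n_clusters >= 0, p$cluster_sigma_px > 0, p$cluster_peak >= 0,
    p$membrane_ridge_sigma_px > 0, p$membrane_peak > 0,
    p$post_abscission_gap_um > 0,
    p$background_offset >= 0, p$read_noise_sd >= 0
  )
  check_order <- function(a, b, na_ok = TRUE) {
    ta <- p[[a]]; tb <- p[[b]]
    if (!is.na(ta) && !is.na(tb) && ta > tb) {
      abort(
        sprintf("event ordering violated: %s (%.3g) > %s (%.3g).", a, ta, b, tb),
        class = "nocutr_event_order_error"
      )
    }
  }
  check_order("t_anaphase_min", "t_ingression_min")
  check_order("t_ingression_min", "t_abscission_min")
  check_order("t_midbody_form_min", "t_midbody_sever_min")
  times <- c("t_anaphase_min", "t_ingression_min", "t_abscission_min",
             "t_midbody_form_min", "t_midbody_sever_min",
             "t_bridge_resolve_min", "t_cluster_start_min", "t_clear_min")
  for (nm in times) {
    if (!is.na(p[[nm]]) && p[[nm]] < 0) {
      abort(sprintf("%s must be nonnegative or NA.", nm))
    }
  }
  invisible(p)
}
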