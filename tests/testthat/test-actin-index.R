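# Midzone ROI geometry and the actin-cluster index (enrichment x
# clustering), including the independent per-pixel oracle and the clearance
# rule.

test_that("midzone ROI follows the stated geometry", {
  a <- list(centroid_y = 5, centroid_x = 5, major_axis_px = 6)
  b <- list(centroid_y = 5, centroid_x = 15, major_axis_px = 8)
  roi <- build_midzone_roi(a, b)
  expect_equal(unname(roi$center), c(5, 10))
  expect_equal(unname(roi$axis), c(0, 1))       # along +x
  expect_equal(roi$height_px, 5)                # half the internuclear distance
  expect_equal(roi$width_px, 14)                # twice the mean major axis

  expect_error(build_midzone_roi(a, a), class = "nocutr_degenerate_roi")
})

test_that("rotating the scene rotates the rasterized ROI identically", {
  # nuclei along +x, then the same pair rotated 90 degrees about the image
  # center of a square frame: masks must agree under coordinate transposition
  n <- 41; c0 <- (n + 1) / 2
  a1 <- list(centroid_y = c0, centroid_x = c0 - 8, major_axis_px = 6)
  b1 <- list(centroid_y = c0, centroid_x = c0 + 8, major_axis_px = 6)
  a2 <- list(centroid_y = c0 - 8, centroid_x = c0, major_axis_px = 6)
  b2 <- list(centroid_y = c0 + 8, centroid_x = c0, major_axis_px = 6)
  m1 <- roi_mask(build_midzone_roi(a1, b1), c(n, n))
  m2 <- roi_mask(build_midzone_roi(a2, b2), c(n, n))
  expect_identical(unname(t(m1)), unname(m2))
})

test_that("a uniform ROI has zero enrichment and zero index", {
  img <- matrix(2, 20, 20)
  roi <- build_midzone_roi(list(centroid_y = 10, centroid_x = 4, major_axis_px = 8),
                           list(centroid_y = 10, centroid_x = 16, major_axis_px = 8))
  sc <- score_actin_frame(img, roi, img > 0)
  expect_equal(sc$enrichment, 0)
  expect_equal(sc$index, 0)
  expect_true(sc$valid)
})

test_that("the worked two-level example gives the stated component values", {
  # 100 positive pixels: 95 at 1.0 spread out, 5 at 3.0 co-located
  img <- matrix(0, 10, 10)
  img[] <- 1
  blob <- cbind(y = c(5, 5, 5, 6, 6), x = c(5, 6, 7, 5, 6))
  img[blob] <- 3
  roi <- build_midzone_roi(list(centroid_y = 5.5, centroid_x = -6, major_axis_px = 12.5),
                           list(centroid_y = 5.5, centroid_x = 17, major_axis_px = 12.5))
  stopifnot(sum(roi_mask(roi, c(10, 10))) == 100)  # ROI covers the frame
  sc <- score_actin_frame(img, roi, img > 0, min_positive_px = 20)
  expect_equal(sc$n_positive, 100L)
  expect_equal(sc$int_all, 1.10)
  expect_equal(sc$int_top, 3.0)
  expect_equal(sc$enrichment, (3 - 1.1) / 1.1)
  o <- oracle_actin_index(img, roi, img > 0)
  expect_equal(sc$clustering, o$clustering, tolerance = 1e-12)
  expect_equal(sc$index, o$index, tolerance = 1e-12)
})

test_that("all index components match the naive per-pixel oracle on random ROIs", {
  for (seed in 1:100) {
    sc_in <- random_roi_scene(seed)
    got <- score_actin_frame(sc_in$img, sc_in$roi, sc_in$mask,
                             min_positive_px = 1)
    want <- oracle_actin_index(sc_in$img, sc_in$roi, sc_in$mask)
    if (is.null(want)) {
      expect_equal(got$n_positive, 0L)
      next
    }
    for (f in c("n_positive", "int_all", "int_top", "enrichment", "com_y",
                "com_x", "d_all", "d_top", "clustering", "index")) {
      expect_lt(abs(got[[f]] - want[[f]]), 1e-9)
    }
  }
})

test_that("the index is invariant under intensity scaling with a fixed positive set", {
  sc_in <- random_roi_scene(7)
  base <- score_actin_frame(sc_in$img, sc_in$roi, sc_in$mask, min_positive_px = 1)
  scaled <- score_actin_frame(sc_in$img * 37.5, sc_in$roi, sc_in$mask,
                              min_positive_px = 1)
  expect_lt(abs(base$enrichment - scaled$enrichment), 1e-9)
  expect_lt(abs(base$clustering - scaled$clustering), 1e-9)
  expect_lt(abs(base$index - scaled$index), 1e-9)
})

test_that("translating the scene translates the COM and preserves the index", {
  h <- 50; w <- 50
  g <- nocutr:::coord_grids(h, w)
  mk <- function(dy, dx) {
    img <- matrix(1, h, w)
    img <- img + nocutr:::gauss_blob(g, 20 + dy, 20 + dx, 2, 5)
    roi <- build_midzone_roi(
      list(centroid_y = 20 + dy, centroid_x = 8 + dx, major_axis_px = 10),
      list(centroid_y = 20 + dy, centroid_x = 32 + dx, major_axis_px = 10)
    )
    score_actin_frame(img, roi, img > 0.5, min_positive_px = 1)
  }
  a <- mk(0, 0)
  b <- mk(5, 7)
  expect_equal(b$com_y - a$com_y, 5, tolerance = 1e-9)
  expect_equal(b$com_x - a$com_x, 7, tolerance = 1e-9)
  expect_equal(a$index, b$index, tolerance = 1e-9)
})

test_that("a brighter, more compact blob never decreases the index", {
  h <- 40; w <- 40
  g <- nocutr:::coord_grids(h, w)
  roi <- build_midzone_roi(list(centroid_y = 20, centroid_x = 5, major_axis_px = 9),
                           list(centroid_y = 20, centroid_x = 35, major_axis_px = 9))
  idx_at_peak <- vapply(seq(2, 20, by = 2), function(peak) {
    img <- matrix(1, h, w) + nocutr:::gauss_blob(g, 20, 20, 2, peak)
    score_actin_frame(img, roi, matrix(TRUE, h, w), min_positive_px = 1)$index
  }, numeric(1))
  expect_true(all(diff(idx_at_peak) >= -1e-9))
})

test_that("degenerate frames are invalid rather than infinite", {
  img <- matrix(0, 20, 20)
  img[10, 10] <- 5  # a single positive pixel: top set of one point
  roi <- build_midzone_roi(list(centroid_y = 10, centroid_x = 4, major_axis_px = 8),
                           list(centroid_y = 10, centroid_x = 16, major_axis_px = 8))
  sc <- score_actin_frame(img, roi, img > 0, min_positive_px = 20)
  expect_false(sc$valid)
  expect_true(is.na(sc$index))
  expect_equal(sc$reason, "too_few_positive")

  expect_error(
    score_actin_frame(img, build_midzone_roi(
      list(centroid_y = 500, centroid_x = 500, major_axis_px = 4),
      list(centroid_y = 500, centroid_x = 510, major_axis_px = 4)
    ), img > 0),
    class = "nocutr_roi_outside"
  )
})

test_that("clearance scoring follows the step-trace arithmetic", {
  mk_trace <- function(idx, frames = seq_along(idx)) {
    tb <- tibble::tibble(frame = frames, index = idx,
                         valid = !is.na(idx),
                         reason = ifelse(is.na(idx), "degenerate_top", ""))
    tb
  }
  # steps from 5.0 to 0.1 at frame 12; anaphase at frame 2 of a 5-min movie
  tr <- mk_trace(c(rep(5, 11), rep(0.1, 6)))
  expect_equal(
    score_clearance(tr, tau_rel = 0.5, k_frames = 2,
                    t_anaphase_min = 5, frame_interval_min = 5),
    50
  )
  # a trace that stays high is censored (long-lived clusters)
  high <- mk_trace(rep(4, 15))
  expect_true(is.na(score_clearance(high, tau_rel = 0.5, k_frames = 2,
                                    t_anaphase_min = 5,
                                    frame_interval_min = 5)))
  # clearance time is non-decreasing in k_frames on a decreasing trace
  dec <- mk_trace(seq(6, 0.1, length.out = 20))
  cl <- vapply(1:4, function(k) {
    score_clearance(dec, tau_rel = 0.5, k_frames = k, t_anaphase_min = 5,
                    frame_interval_min = 5)
  }, numeric(1))
  expect_true(all(diff(cl) >= 0))
  # no pre-anaphase frames and no fallback: error; with tau_abs: notice
  post <- mk_trace(rep(2, 8))
  expect_error(score_clearance(post, t_anaphase_min = 0,
                               frame_interval_min = 5))
  expect_message(
    score_clearance(post, t_anaphase_min = 0, frame_interval_min = 5,
                    tau_abs = 0.5),
    "tau_abs"
  )
})

test_that("the index trace is elevated during the cluster interval and the loop closes", {
  sp <- scene_params(n_frames = 40L, frame_interval_min = 5,
                     t_anaphase_min = 20, t_cluster_start_min = 35,
                     t_clear_min = 140, t_bridge_resolve_min = 40,
                     read_noise_sd = 0, poisson_noise = FALSE,
                     background_offset = 0)
  sim <- generate_division_movie(sp)
  mv <- sim$movie
  sets <- lapply(seq_len(n_frames(mv)), function(f) {
    mask <- threshold_positive(movie_channel(mv, "histone", f), "fixed",
                               value = 100)
    label_nuclei(mask, frame = f)
  })
  kept <- select_two_nuclei_frames(sets)
  tr <- actin_trace(mv, kept, t_anaphase_min = 20,
                    threshold_method = "fixed", threshold_value = 30)
  active <- tr$frame >= frame_at_time(35, 5) & tr$frame < frame_at_time(140, 5)
  expect_true(all(tr$index[active & tr$valid] > 0.5))
  after <- tr$frame >= frame_at_time(140, 5)
  expect_true(all(tr$reason[after] == "too_few_positive"))
  clr <- score_clearance(tr, tau_abs = 0.3)
  expect_equal(clr, 140 - 20)

  # dropped frames (one nucleus) are absent from the trace
  expect_true(min(tr$frame) > 1)
})

test_that("an all-background actin channel yields no valid signal", {
  sp <- scene_params(n_frames = 10L, t_anaphase_min = NA, t_ingression_min = NA,
                     t_abscission_min = NA, t_cluster_start_min = NA,
                     t_clear_min = NA, t_bridge_resolve_min = NA,
                     t_midbody_form_min = NA, t_midbody_sever_min = NA,
                     read_noise_sd = 0, poisson_noise = FALSE,
                     background_offset = 0)
  sim <- generate_division_movie(sp)
  actin <- movie_channel(sim$movie, "actin", 5)
  expect_true(all(actin == 0))
})
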