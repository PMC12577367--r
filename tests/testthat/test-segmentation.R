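# Thresholding, nucleus labelling and geometry, bridge status and timing,
# anaphase-onset detection and RPA focus calls.

test_that("Otsu threshold matches the exhaustive sweep oracle on a two-level image", {
  set.seed(1)
  img <- matrix(10, 20, 20)
  bright <- sample(400, 40)
  img[bright] <- 100
  mask <- threshold_positive(img, "otsu")
  expect_identical(as.vector(mask), as.vector(oracle_otsu_mask(img)))
  expect_identical(which(as.vector(mask)), sort(bright))
})

test_that("Otsu segmentation of a two-level image is invariant under constant offset", {
  set.seed(2)
  img <- matrix(5, 15, 15)
  img[sample(225, 30)] <- 80
  m1 <- threshold_positive(img, "otsu")
  m2 <- threshold_positive(img + 57.3, "otsu")
  expect_identical(as.vector(m1), as.vector(m2))
})

test_that("fixed thresholding and the degenerate Otsu case behave as specified", {
  img <- matrix(runif(100, 1, 2), 10, 10)
  expect_true(all(threshold_positive(img, "fixed", value = 0)))
  expect_error(threshold_positive(matrix(3, 5, 5), "otsu"),
               class = "nocutr_ambiguous_threshold")
  expect_equal(zero_below(img, img > 1.5), img * (img > 1.5))
})

test_that("connected components use 8-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE  # diagonal chain
  m[6, 6] <- TRUE                                    # separate
  lab <- nocutr:::label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[4, 4])
})

test_that("label_nuclei measures squares, disks and border contact correctly", {
  mask <- matrix(FALSE, 30, 40)
  mask[5:9, 5:9] <- TRUE      # 5x5 square centred at (7, 7)
  mask[20:24, 30:34] <- TRUE  # 5x5 square centred at (22, 32)
  ns <- label_nuclei(mask, min_area_px = 10)
  expect_equal(nrow(ns), 2)
  expect_equal(ns$area_px, c(25L, 25L))
  expect_equal(ns$centroid_y, c(7, 22))
  expect_equal(ns$centroid_x, c(7, 32))
  expect_false(any(ns$touches_border))

  # a disk of radius r has major axis ~ 2r from second moments
  g <- nocutr:::coord_grids(40, 40)
  r <- 9
  disk <- (g$y - 20)^2 + (g$x - 20)^2 <= r^2
  nd <- label_nuclei(disk)
  expect_lt(abs(nd$major_axis_px - 2 * r) / (2 * r), 0.05)

  # border contact flag
  mb <- matrix(FALSE, 20, 20)
  mb[1:5, 8:12] <- TRUE
  expect_true(label_nuclei(mb)$touches_border)

  # small components are dropped; empty mask gives an empty set
  expect_equal(nrow(label_nuclei(matrix(FALSE, 5, 5))), 0)
})

test_that("frames are retained only with exactly two interior nuclei", {
  mk <- function(n_interior, n_border = 0, frame = 1) {
    mask <- matrix(FALSE, 50, 50)
    at <- list(c(10, 10), c(10, 35), c(35, 10))
    for (i in seq_len(n_interior)) {
      mask[at[[i]][1] + 0:4, at[[i]][2] + 0:4] <- TRUE
    }
    if (n_border > 0) mask[1:5, 20:24] <- TRUE
    label_nuclei(mask, min_area_px = 10, frame = frame)
  }
  sets <- list(mk(1, frame = 1), mk(2, frame = 2), mk(2, 1, frame = 3),
               mk(3, frame = 4))
  kept <- select_two_nuclei_frames(sets)
  expect_equal(as.integer(names(kept)), c(2L, 3L))
})

test_that("bridge status distinguishes connected, fragmented and resolved", {
  mask <- matrix(FALSE, 40, 60)
  mask[18:22, 8:12] <- TRUE    # nucleus A
  mask[18:22, 48:52] <- TRUE   # nucleus B
  nuc <- label_nuclei(mask, min_area_px = 10)
  roi <- build_midzone_roi(nuc[1, ], nuc[2, ])

  # 1-px line joining the two masks
  conn <- mask
  conn[20, 13:47] <- TRUE
  expect_equal(detect_bridge(conn, nuc, roi)$status, "CONNECTED")

  # isolated blob mid-corridor: fragmented, i.e. unresolved
  frag <- mask
  frag[19:21, 28:32] <- TRUE
  out <- detect_bridge(frag, nuc, roi)
  expect_equal(out$status, "FRAGMENTED")
  expect_gte(out$corridor_positive_px, 4)

  # clean corridor
  expect_equal(detect_bridge(mask, nuc, roi)$status, "RESOLVED")

  # sub-cutoff specks do not count
  speck <- mask
  speck[20, 30] <- TRUE
  expect_equal(detect_bridge(speck, nuc, roi, min_object_px = 4)$status,
               "RESOLVED")

  # precondition: exactly two interior nuclei
  one <- label_nuclei(matrix(FALSE, 40, 60))
  expect_error(detect_bridge(mask, one, roi),
               class = "nocutr_precondition_error")
})

test_that("bridge resolution time follows its definition and matches a scan oracle", {
  st <- function(frames, status) tibble::tibble(frame = frames, status = status)

  # RESOLVED from frame 5, anaphase at frame 2 (2 min/frame) -> 6 min
  s <- st(1:10, c(rep("CONNECTED", 4), rep("RESOLVED", 6)))
  expect_equal(bridge_resolution_time(s, t_anaphase_min = 2,
                                      frame_interval_min = 2), 6)

  # a relapse postpones resolution to the next stable frame
  s2 <- st(1:9, c("CONNECTED", "CONNECTED", "CONNECTED", "CONNECTED",
                  "RESOLVED", "CONNECTED", rep("RESOLVED", 3)))
  expect_equal(bridge_resolution_time(s2, 2, 2), (7 - 2) * 2)

  # never resolved -> censored
  s3 <- st(1:6, rep("FRAGMENTED", 6))
  expect_true(is.na(bridge_resolution_time(s3, 0, 2)))

  expect_error(bridge_resolution_time(st(integer(), character()), 0, 2))

  # property: equality with the literal-definition oracle
  set.seed(123)
  for (i in 1:400) {
    n <- sample(3:12, 1)
    status <- sample(c("CONNECTED", "FRAGMENTED", "RESOLVED"), n,
                     replace = TRUE)
    t_ana <- sample(0:4, 1)
    got <- bridge_resolution_time(st(1:n, status), t_ana, 1)
    f <- oracle_resolution_frame(1:n, status, t_ana + 1)
    want <- if (is.na(f)) NA_real_ else (f - 1) - t_ana
    expect_identical(got, want)
  }
})

test_that("anaphase onset is the first sustained 1.5x elongation", {
  tr <- c(rep(10, 7), rep(20, 5))
  expect_equal(detect_anaphase_onset(tr), 8)
  # fluctuation within 5% of baseline never triggers
  set.seed(4)
  flat <- 10 * (1 + runif(20, -0.05, 0.05))
  expect_true(is.na(detect_anaphase_onset(flat)))
  # one-frame spikes are not sustained
  spike <- c(rep(10, 6), 20, 10, rep(10, 4))
  expect_true(is.na(detect_anaphase_onset(spike)))
  expect_error(detect_anaphase_onset(c(1, 2, 3)), "too short")
})

test_that("anaphase onset is recovered from a noise-free movie within one frame", {
  sp <- scene_params(n_frames = 20L, frame_interval_min = 2,
                     t_anaphase_min = 14, t_ingression_min = 20,
                     t_abscission_min = 30, t_bridge_resolve_min = 20,
                     t_cluster_start_min = 20, t_clear_min = 30,
                     t_midbody_form_min = 20, t_midbody_sever_min = 36,
                     separation_speed_um_per_min = 1.5,
                     read_noise_sd = 0, poisson_noise = FALSE,
                     background_offset = 0)
  sim <- generate_division_movie(sp)
  tr <- chromatin_axis_trace(sim$movie, method = "fixed", value = 100)
  onset <- detect_anaphase_onset(tr)
  true_frame <- frame_at_time(14, 2)
  expect_lte(abs(onset - true_frame), 1)
})

test_that("RPA focus calls respect the background rule and the nucleus gate", {
  g <- nocutr:::coord_grids(40, 40)
  nuc <- matrix(FALSE, 40, 40)
  nuc[g$y >= 10 & g$y <= 30 & g$x >= 10 & g$x <= 30] <- TRUE

  # uniform nuclear intensity: zero foci
  img <- matrix(1, 40, 40)
  expect_equal(nrow(detect_rpa_foci(img, nuc, k = 3)), 0)

  # one bright Gaussian spot at 5x the nucleoplasmic median
  spot <- 1 + nocutr:::gauss_blob(g, 20, 20, 1.5, 4)
  foci <- detect_rpa_foci(spot, nuc, k = 3)
  expect_equal(nrow(foci), 1)
  expect_lte(max(abs(c(foci$y - 20, foci$x - 20))), 1)

  # the same spot outside any nucleus mask is ignored
  outside <- 1 + nocutr:::gauss_blob(g, 35, 35, 1.5, 4)
  nuc_small <- matrix(FALSE, 40, 40)
  nuc_small[10:25, 10:25] <- TRUE
  expect_equal(nrow(detect_rpa_foci(outside, nuc_small, k = 3)), 0)

  expect_error(detect_rpa_foci(img, matrix(FALSE, 40, 40)), "empty")
})

test_that("focus counts are non-increasing in k", {
  set.seed(9)
  g <- nocutr:::coord_grids(50, 50)
  img <- matrix(rnorm(2500, 10, 0.5), 50, 50)
  for (i in 1:6) {
    img <- img + nocutr:::gauss_blob(g, runif(1, 10, 40), runif(1, 10, 40),
                                     1.2, runif(1, 2, 8))
  }
  nuc <- matrix(TRUE, 50, 50)
  counts <- vapply(c(1, 2, 3, 5, 8),
                   function(k) nrow(detect_rpa_foci(img, nuc, k = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fragmented-bridge scenes score unresolved until resolution, then resolved", {
  sp <- scene_params(n_frames = 24L, frame_interval_min = 5,
                     t_anaphase_min = 10, t_ingression_min = 30,
                     t_abscission_min = 60, t_bridge_resolve_min = 70,
                     t_cluster_start_min = 30, t_clear_min = 90,
                     t_midbody_form_min = 30, t_midbody_sever_min = 100,
                     bridge_fragmented = TRUE,
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
  statuses <- dplyr::bind_rows(lapply(kept, function(set) {
    f <- set$frame[1]
    low <- threshold_positive(movie_channel(mv, "histone", f), "fixed",
                              value = 25)
    interior <- set[!set$touches_border, ]
    roi <- build_midzone_roi(interior[1, ], interior[2, ])
    detect_bridge(low, set, roi, frame = f)
  }))
  resolve_frame <- frame_at_time(70, 5)
  # skip the first post-anaphase frame, where the internuclear corridor is
  # still too narrow for bridge fragments to exist at all
  pre <- statuses[statuses$frame < resolve_frame & statuses$frame >= 5, ]
  post <- statuses[statuses$frame >= resolve_frame, ]
  expect_true(all(pre$status == "FRAGMENTED"))
  expect_true(all(post$status == "RESOLVED"))
})
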