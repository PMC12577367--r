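# Synthetic per-cell event tables and qPCR Ct tables with known truth.

draw_times <- function(spec, n) {
  if (is.null(spec$dist)) abort("each event distribution needs a `dist` field.")
  switch(spec$dist,
    point = rep(spec$value, n),
    normal = rnorm(n, spec$mean, spec$sd),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    uniform = runif(n, spec$min, spec$max),
    exponential = spec$offset %||% 0 + rexp(n, rate = spec$rate),
    never = rep(NA_real_, n),
    abort(sprintf("unknown distribution '%s'.", spec$dist))
  )
}

#' Generate a synthetic per-cell event table
#'
#' Draws per-cell event times for one or more experimental conditions from
#' fully specified distributions, flagging events past the movie horizon as
#' censored (`NA` time with `horizon_min` recorded). Distributions are given
#' declaratively, e.g. `list(dist = "normal", mean = 130, sd = 25)`,
#' `list(dist = "point", value = 16)`, `list(dist = "lognormal", meanlog =
#' 3, sdlog = 0.4)`, or `list(dist = "never")` for events that do not occur.
#'
#' @param n_cells Cells per condition.
#' @param condition_specs Named list: one element per condition label, each a
#'   list of `event name -> distribution spec`. Recognised event names are
#'   free-form; downstream helpers use `t_anaphase`, `t_ingression`,
#'   `t_abscission`, `t_midbody_form`, `t_midbody_sever`, `t_bridge_resolve`,
#'   `t_clear`. Optional logical fields `has_bridge` and `binucleate_prob`
#'   may be supplied per condition.
#' @param seed Integer seed.
#' @param horizon_min Movie horizon: later event times are censored.
#' @return A tibble (one row per cell) with `cell_id`, `condition`, one
#'   numeric column per event (`NA` = censored) and `horizon_min`.
#' @export
generate_event_table <- function(n_cells, condition_specs, seed,
                                 horizon_min = Inf) {
  if (length(condition_specs) == 0) abort("`condition_specs` must be nonempty.")
  if (is.null(names(condition_specs)) || any(names(condition_specs) == "")) {
    abort("`condition_specs` must be a named list of conditions.")
  }
  stopifnot(n_cells >= 0)
  with_seed(seed, {
    out <- imap(condition_specs, function(spec, label) {
      events <- spec[!names(spec) %in% c("has_bridge", "binucleate_prob")]
      cols <- map(events, draw_times, n = n_cells)
      tb <- tibble(
        cell_id = if (n_cells > 0) paste0(label, "_", seq_len(n_cells)) else character(),
        condition = rep(label, n_cells)
      )
      for (nm in names(cols)) tb[[nm]] <- cols[[nm]]
      tb$has_bridge <- rep(isTRUE(spec$has_bridge), n_cells)
      if (!is.null(spec$binucleate_prob)) {
        tb$binucleate <- runif(n_cells) < spec$binucleate_prob
      } else {
        tb$binucleate <- rep(FALSE, n_cells)
      }
      tb
    })
    tb <- bind_rows(out)
    num <- vapply(tb, is.numeric, logical(1))
    for (nm in names(tb)[num]) {
      tb[[nm]][!is.na(tb[[nm]]) & tb[[nm]] > horizon_min] <- NA_real_
    }
    tb$horizon_min <- rep(horizon_min, nrow(tb))
    tb
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Builds replicate Ct measurements whose implied normalised relative
#' expression equals the requested fold changes exactly at zero noise:
#' `Ct(target) = ct_reference + dct_control - log2(fold)`, plus independent
#' Gaussian replicate noise on every Ct.
#'
#' @param true_fold_changes Named numeric vector of per-sample fold changes
#'   relative to the control (all > 0). The control sample itself has fold 1.
#' @param ct_reference Reference-gene Ct (cycle number).
#' @param noise_sd Gaussian SD added independently to each replicate Ct.
#' @param n_replicates Technical replicates per sample.
#' @param seed Integer seed.
#' @param control Name of the control sample (added with fold 1 if absent).
#' @param dct_control Baseline delta-Ct of the control sample.
#' @return A tibble with columns `sample`, `replicate`, `target_gene`,
#'   `reference_gene`, `ct_target`, `ct_reference`, `is_control`.
#' @export
generate_qpcr_table <- function(true_fold_changes, ct_reference = 20,
                                noise_sd = 0, n_replicates = 3L, seed = 1L,
                                control = "control", dct_control = 2) {
  if (any(true_fold_changes <= 0)) {
    abort("fold changes must be strictly positive.")
  }
  if (is.null(names(true_fold_changes))) abort("fold changes must be named.")
  stopifnot(n_replicates >= 1)
  if (!control %in% names(true_fold_changes)) {
    true_fold_changes <- c(setNames(1, control), true_fold_changes)
  }
  with_seed(seed, {
    rows <- imap(as.list(true_fold_changes), function(fold, nm) {
      dct <- dct_control - log2(fold)
      tibble(
        sample = nm,
        replicate = seq_len(n_replicates),
        target_gene = "target",
        reference_gene = "reference",
        ct_target = ct_reference + dct + rnorm(n_replicates, 0, noise_sd),
        ct_reference = ct_reference + rnorm(n_replicates, 0, noise_sd),
        is_control = nm == control
      )
    })
    bind_rows(rows)
  })
}

#' Generate a synthetic midbody Z-stack
#'
#' Renders a filled tubulin ellipse together with a channel of interest that
#' is uniform inside the same ellipse, then applies the camera model
#' (Gaussian read noise and background offset). The structure has physical
#' thickness: it stays nearly in focus over the five slices centred on
#' `z_best` (mild `inner_blur` per slice of defocus, so the best-focus slice
#' is still unique) and defocuses steeply (`blur_per_slice`) beyond them,
#' the geometry the five-slice maximum projection is designed for. Used to
#' exercise best-focus selection, five-slice projection, tight-ellipse
#' fitting and total-intensity measurement against known truth.
#'
#' @param shape `(height, width)` in pixels.
#' @param n_slices Number of Z slices.
#' @param z_best Index of the sharpest slice.
#' @param semi_major_px,semi_minor_px,angle_rad Ellipse geometry.
#' @param tubulin_peak,channel_level Tubulin intensity inside the ellipse and
#'   the uniform level of the channel of interest.
#' @param inner_blur Blur sigma per slice of defocus within the in-focus
#'   five-slice core.
#' @param blur_per_slice Additional blur sigma per slice of defocus beyond
#'   the core.
#' @param background_offset,read_noise_sd Camera model.
#' @param seed Integer seed.
#' @return List with `tubulin` and `channel` 3-D arrays `[y, x, z]` and a
#'   `truth` list (center, axes, angle, area_px, total_intensity).
#' @export
generate_midbody_stack <- function(shape = c(64L, 64L), n_slices = 9L,
                                   z_best = 5L, semi_major_px = 10,
                                   semi_minor_px = 4, angle_rad = pi / 6,
                                   tubulin_peak = 200, channel_level = 120,
                                   inner_blur = 0.3, blur_per_slice = 1.2,
                                   background_offset = 10, read_noise_sd = 0,
                                   seed = 1L) {
  h <- shape[1]; w <- shape[2]
  g <- coord_grids(h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  mask <- ellipse_mask(g, cy, cx, semi_major_px, semi_minor_px, angle_rad)
  sharp_tub <- tubulin_peak * mask
  sharp_ch <- channel_level * mask
  tub <- array(0, c(h, w, n_slices))
  ch <- array(0, c(h, w, n_slices))
  for (z in seq_len(n_slices)) {
    dz <- abs(z - z_best)
    s <- inner_blur * min(dz, 2) + blur_per_slice * max(dz - 2, 0)
    tub[, , z] <- gaussian_blur(sharp_tub, s)
    ch[, , z] <- gaussian_blur(sharp_ch, s)
  }
  with_seed(sub_seed(seed, 1L), {
    if (read_noise_sd > 0) {
      tub <- tub + rnorm(length(tub), 0, read_noise_sd)
      ch <- ch + rnorm(length(ch), 0, read_noise_sd)
    }
    tub <- pmax(tub + background_offset, 0)
    ch <- pmax(ch + background_offset, 0)
  })
  list(
    tubulin = tub,
    channel = ch,
    truth = list(
      center = c(y = cy, x = cx),
      semi_major_px = semi_major_px,
      semi_minor_px = semi_minor_px,
      angle_rad = angle_rad,
      z_best = z_best,
      area_px = sum(mask),
      channel_level = channel_level,
      total_intensity = sum(mask) * (channel_level + background_offset)
    )
  )
}
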