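# Workflow driver binding the modules into the three imaging workflows
# (yeast abscission, actin index, midbody quantification) plus simulation
# and event-table statistics. Configuration is a named list or a YAML file;
# outputs are CSV/JSON files stamped with the package version and the hash
# of the effective configuration.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    scene = list(),
    movie = NULL,
    events = NULL,
    histone_threshold = NULL,   # fixed nucleus-segmentation threshold
    actin_threshold = NULL,     # fixed actin threshold
    min_area_px = 20L,
    min_object_px = 4L,
    top_fraction = 0.05,
    min_positive_px = 20L,
    epsilon = 1e-6,
    tau_rel = 0.5,
    tau_abs = 0.3,
    k_frames = 2L,
    prominence_rel = 0.25,
    min_separation_um = 0.4,
    persistence_frames = 2L,
    half_width_px = 2,
    horizon_min = 60,
    midbody = list()
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")),
          class = "nocutr_config_error")
  }
  base[names(config)] <- config
  base
}

# hash of the analysis-relevant configuration (where outputs land is not
# part of the analysis identity)
config_hash <- function(cfg) {
  rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
}

stamp <- function(df, cfg) {
  df$package_version <- as.character(utils::packageVersion("nocutr"))
  df$config_hash <- config_hash(cfg)
  df
}

write_table <- function(df, cfg, dir, name) {
  path <- file.path(dir, name)
  df <- stamp(df, cfg)
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(x, collapse = ";"), "") else col
  }))
  write.csv(df, path, row.names = FALSE)
  path
}

pipeline_movie <- function(cfg) {
  if (!is.null(cfg$movie)) {
    list(movie = read_movie(cfg$movie), ground_truth = NULL)
  } else {
    sp <- do.call(scene_params, c(cfg$scene, list(seed = cfg$seed)))
    generate_division_movie(sp)
  }
}

segment_movie_nuclei <- function(movie, cfg) {
  sets <- map(seq_len(n_frames(movie)), function(f) {
    img <- movie_channel(movie, "histone", f)
    mask <- tryCatch(
      if (is.null(cfg$histone_threshold)) {
        threshold_positive(img)
      } else {
        threshold_positive(img, "fixed", value = cfg$histone_threshold)
      },
      nocutr_ambiguous_threshold = function(e) {
        matrix(FALSE, nrow(img), ncol(img))
      }
    )
    label_nuclei(mask, min_area_px = cfg$min_area_px, frame = f)
  })
  sets
}

#' Run one of the package workflows end to end
#'
#' Workflows: `"simulate"` writes a synthetic movie, its ground-truth event
#' table and a manifest; `"actin_index"` segments nuclei, builds per-frame
#' midzone ROIs, writes the actin-cluster index trace and the clearance
#' time; `"yeast_abscission"` profiles the membrane channel, classifies
#' single/double peaks per frame and writes the abscission time;
#' `"midbody"` renders or loads a midbody stack and writes the ellipse
#' quantification; `"stats"` summarises an event table (midbody lifetimes,
#' completion fractions, per-condition box summaries). Outputs are
#' deterministic given `config$seed`; every table carries the package
#' version and the hash of the effective configuration, which is also
#' written to `manifest.json`.
#'
#' @param config Named list or YAML file path; unknown keys are rejected.
#' @param workflow One of `"simulate"`, `"yeast_abscission"`,
#'   `"actin_index"`, `"midbody"`, `"stats"`.
#' @return Invisibly, a list with the written file paths and the main
#'   in-memory results.
#' @export
run_pipeline <- function(config = list(),
                         workflow = c("simulate", "yeast_abscission",
                                      "actin_index", "midbody", "stats")) {
  workflow <- match.arg(workflow)
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()

  if (workflow == "simulate") {
    sim <- pipeline_movie(cfg)
    movie_path <- file.path(cfg$out_dir, "movie.tif")
    write_movie(sim$movie, movie_path)
    artifacts$movie <- movie_path
    artifacts$events <- write_table(sim$ground_truth$events, cfg,
                                    cfg$out_dir, "ground_truth_events.csv")
    result <- sim
  } else if (workflow == "actin_index") {
    sim <- pipeline_movie(cfg)
    movie <- sim$movie
    sets <- segment_movie_nuclei(movie, cfg)
    kept <- select_two_nuclei_frames(sets)
    t_ana <- if (!is.null(sim$ground_truth)) {
      true_event_time(sim$ground_truth, "anaphase")
    } else {
      fr <- detect_anaphase_onset(chromatin_axis_trace(movie))
      frame_time(fr, movie$frame_interval_min)
    }
    tr <- actin_trace(
      movie, kept, t_ana,
      threshold_method = if (is.null(cfg$actin_threshold)) "otsu" else "fixed",
      threshold_value = cfg$actin_threshold,
      top_fraction = cfg$top_fraction, min_positive_px = cfg$min_positive_px,
      epsilon = cfg$epsilon
    )
    clr <- score_clearance(tr, tau_rel = cfg$tau_rel, k_frames = cfg$k_frames,
                           tau_abs = cfg$tau_abs)
    artifacts$trace <- write_table(as_tibble(tr), cfg, cfg$out_dir,
                                   "actin_trace.csv")
    artifacts$clearance <- write_table(
      tibble(t_anaphase_min = t_ana, clearance_min = clr,
             censored = is.na(clr)),
      cfg, cfg$out_dir, "actin_clearance.csv"
    )
    result <- list(trace = tr, clearance_min = clr)
  } else if (workflow == "yeast_abscission") {
    sim <- pipeline_movie(cfg)
    movie <- sim$movie
    axis <- if (!is.null(sim$ground_truth)) {
      sim$ground_truth$neck_axis
    } else {
      abort("yeast_abscission on external movies needs an axis annotation; supply a simulated scene.",
            class = "nocutr_config_error")
    }
    profiles <- map(seq_len(n_frames(movie)), function(f) {
      extract_neck_profile(movie, axis, half_width_px = cfg$half_width_px,
                           frame = f)
    })
    calls <- bind_rows(map(profiles, classify_profile,
                           prominence_rel = cfg$prominence_rel,
                           min_separation_um = cfg$min_separation_um))
    ing_frame <- detect_ingression(profiles)
    t_ing <- if (!is.na(ing_frame)) {
      frame_time(ing_frame, movie$frame_interval_min)
    } else {
      NA_real_
    }
    t_abs <- if (!is.na(t_ing)) {
      time_to_abscission(calls, t_ing, cfg$persistence_frames,
                         movie$frame_interval_min)
    } else {
      NA_real_
    }
    calls_out <- calls
    calls_out$peak_positions_um <- NULL
    artifacts$calls <- write_table(calls_out, cfg, cfg$out_dir,
                                   "peak_calls.csv")
    artifacts$abscission <- write_table(
      tibble(t_ingression_min = t_ing, abscission_min = t_abs,
             censored = is.na(t_abs)),
      cfg, cfg$out_dir, "abscission_time.csv"
    )
    result <- list(calls = calls, t_ingression_min = t_ing,
                   abscission_min = t_abs)
  } else if (workflow == "midbody") {
    mb <- do.call(generate_midbody_stack,
                  c(cfg$midbody, list(seed = cfg$seed)))
    d <- dim(mb$tubulin)
    roi <- list(y = c(1, d[1]), x = c(1, d[2]))
    zb <- select_best_focus(mb$tubulin, roi)
    proj_tub <- project_five(mb$tubulin, zb)
    proj_ch <- project_five(mb$channel, zb)
    ell <- fit_midbody_ellipse(proj_tub, roi)
    meas <- measure_total_intensity(proj_ch, ell, z_best = zb)
    artifacts$midbody <- write_table(meas, cfg, cfg$out_dir,
                                     "midbody_measurements.csv")
    result <- meas
  } else { # stats
    records <- if (is.null(cfg$events)) {
      abort("stats workflow needs `events` (CSV path or tibble).",
            class = "nocutr_config_error")
    } else if (is.character(cfg$events)) {
      as_tibble(read.csv(cfg$events))
    } else {
      as_tibble(cfg$events)
    }
    out <- list()
    if (all(c("t_midbody_form", "t_midbody_sever") %in% names(records))) {
      records <- midbody_lifetime(records)
      out$lifetimes <- records %>%
        group_by(.data$condition) %>%
        summarise(
          n = n(),
          median_lifetime_min = median(.data$midbody_lifetime_min, na.rm = TRUE),
          .groups = "drop"
        )
      artifacts$lifetimes <- write_table(out$lifetimes, cfg, cfg$out_dir,
                                         "midbody_lifetimes.csv")
    }
    if (all(c("t_ingression", "t_abscission") %in% names(records))) {
      ttimes <- records$t_abscission - records$t_ingression
      per_cond <- split(ttimes, records$condition)
      out$completion <- bind_rows(imap(per_cond, function(v, nm) {
        tibble(condition = nm,
               fraction_by_horizon = fraction_completed_by(v, cfg$horizon_min))
      }))
      artifacts$completion <- write_table(out$completion, cfg, cfg$out_dir,
                                          "completion_fractions.csv")
    }
    result <- out
  }

  jsonlite::write_json(
    list(
      workflow = workflow,
      package_version = as.character(utils::packageVersion("nocutr")),
      config_hash = config_hash(cfg),
      config = cfg[!vapply(cfg, is.null, logical(1))],
      artifacts = artifacts
    ),
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(list(artifacts = artifacts, result = result))
}
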