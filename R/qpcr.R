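# qPCR relative expression (2^-deltaCt, normalised to the control sample)
# and primer efficiency from a serial-dilution standard curve.

#' Normalised relative expression from a Ct table
#'
#' Per sample, delta-Ct is `mean Ct(target) - mean Ct(reference)` over
#' replicates (per-replicate variant by flag), relative expression is
#' `2^-deltaCt`, and the reported value is each sample's RE divided by the
#' control sample's RE. Adding a constant to every Ct of a run leaves the
#' result unchanged.
#'
#' @param table Tibble with columns `sample`, `ct_target`, `ct_reference`,
#'   `is_control` (exactly one control sample), e.g.
#'   [generate_qpcr_table()].
#' @param per_replicate If `TRUE`, compute RE per replicate and average the
#'   REs instead of the Cts.
#' @return Tibble: `sample`, `delta_ct`, `re`, `re_normalized`,
#'   `is_control`.
#' @export
qpcr_relative_expression <- function(table, per_replicate = FALSE) {
  needed <- c("sample", "ct_target", "ct_reference", "is_control")
  if (!all(needed %in% names(table))) {
    abort(sprintf("table needs columns: %s.", paste(needed, collapse = ", ")))
  }
  if (!any(table$is_control)) {
    abort("no control sample in the table.", class = "nocutr_no_control")
  }
  per_sample <- table %>%
    group_by(.data$sample) %>%
    summarise(
      delta_ct = if (per_replicate) {
        mean(.data$ct_target - .data$ct_reference)
      } else {
        mean(.data$ct_target) - mean(.data$ct_reference)
      },
      re = if (per_replicate) {
        mean(2^-(.data$ct_target - .data$ct_reference))
      } else {
        2^-(mean(.data$ct_target) - mean(.data$ct_reference))
      },
      is_control = .data$is_control[1],
      .groups = "drop"
    )
  ctrl <- per_sample$re[per_sample$is_control]
  if (length(ctrl) != 1) {
    abort("exactly one control sample is required.", class = "nocutr_no_control")
  }
  per_sample %>% mutate(re_normalized = .data$re / ctrl)
}

#' Primer amplification efficiency from a dilution series
#'
#' Least-squares slope of Ct against log10 dilution; efficiency is
#' `10^(-1/slope) - 1` (a perfect doubling per cycle has slope -log2(10)
#' = -3.32 and efficiency 1). Primers pass at efficiency > 0.90.
#'
#' @param dilution_log10 Numeric vector, log10 of the dilution factors.
#' @param ct Numeric vector of Ct values.
#' @return Object of class `primer_fit` with `slope`, `intercept`,
#'   `efficiency`, `pass`, and the underlying `lm` fit.
#' @export
primer_efficiency <- function(dilution_log10, ct) {
  if (length(dilution_log10) < 3 || length(ct) != length(dilution_log10)) {
    abort("need at least 3 matched dilution points.")
  }
  if (length(unique(dilution_log10)) < 2) {
    abort("dilution series is singular (all points identical).")
  }
  fit <- lm(ct ~ dilution_log10)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) abort("singular standard-curve fit.")
  eff <- 10^(-1 / slope) - 1
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         efficiency = eff, pass = eff > 0.90, fit = fit),
    class = "primer_fit"
  )
}

#' @export
print.primer_fit <- function(x, ...) {
  cat(sprintf(
    "<primer_fit> slope %.4f, efficiency %.1f%% (%s)\n",
    x$slope, 100 * x$efficiency, if (x$pass) "pass" else "fail"
  ))
  invisible(x)
}

#' @export
tidy.primer_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.primer_fit <- function(x, ...) {
  tibble(
    slope = x$slope,
    efficiency = x$efficiency,
    pass = x$pass,
    r_squared = suppressWarnings(summary(x$fit)$r.squared)
  )
}
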