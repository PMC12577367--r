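# Event-timing assembly and the statistical procedures used for completion
# fractions and group comparisons. Censored events are NA times; "fraction
# of cells" denominators keep censored cells throughout (no Kaplan-Meier:
# the readout is the raw fraction of all cells).

#' Midbody lifetime per cell
#'
#' Lifetime is the time from midbody formation to severing. Cells whose
#' severing is unobserved get a censored (`NA`) lifetime; severing before
#' formation is a data error.
#'
#' @param records Event tibble with `t_midbody_form` and `t_midbody_sever`
#'   columns (minutes, `NA` = censored), e.g. [generate_event_table()].
#' @return The input with a `midbody_lifetime_min` column appended.
#' @export
midbody_lifetime <- function(records) {
  form <- records$t_midbody_form
  sever <- records$t_midbody_sever
  if (is.null(form) || is.null(sever)) {
    abort("records need `t_midbody_form` and `t_midbody_sever` columns.")
  }
  bad <- !is.na(form) & !is.na(sever) & sever < form
  if (any(bad)) {
    abort(sprintf("midbody severing precedes formation for %d cell(s).",
                  sum(bad)), class = "nocutr_data_error")
  }
  records$midbody_lifetime_min <- ifelse(is.na(form), NA_real_, sever - form)
  records
}

#' Cumulative completion-fraction curve
#'
#' Non-decreasing step curve of the fraction of all cells that completed the
#' event by time t. Censored observations stay in the denominator at every
#' t, so a cohort that never completes plateaus below 1.
#'
#' @param times Numeric vector of completion times (minutes); `NA` =
#'   censored.
#' @param horizon_min Largest time on the grid.
#' @param grid Optional evaluation grid; defaults to the sorted observed
#'   times plus 0 and the horizon.
#' @return Tibble of class `completion_curve`: `t_min`, `fraction`.
#' @export
cumulative_fraction <- function(times, horizon_min, grid = NULL) {
  if (length(times) == 0) abort("`times` must be nonempty.")
  obs <- times[!is.na(times)]
  if (is.null(grid)) {
    grid <- sort(unique(c(0, obs[obs <= horizon_min], horizon_min)))
  }
  frac <- vapply(grid, function(t) mean(!is.na(times) & times <= t), numeric(1))
  out <- tibble(t_min = grid, fraction = frac)
  class(out) <- c("completion_curve", class(out))
  out
}

#' Fraction of cells completed by a horizon
#'
#' `count(observed time <= horizon) / n`, with censored cells in the
#' denominator.
#'
#' @inheritParams cumulative_fraction
#' @return Proportion in `[0, 1]`.
#' @export
fraction_completed_by <- function(times, horizon_min) {
  if (length(times) == 0) abort("`times` must be nonempty.")
  mean(!is.na(times) & times <= horizon_min)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test of two independent samples. The exact null distribution is
#' enumerated when both samples are small and tie-free; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Use the exact branch when `length(x) + length(y)` is at
#'   most this and there are no ties.
#' @return One-row tibble: `U`, `p_two_sided`, `n_x`, `n_y`, `exact`.
#' @export
mann_whitney <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_limit && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE,
                alternative = "two.sided")
  )
  tibble(
    U = unname(wt$statistic),
    p_two_sided = min(wt$p.value, 1),
    n_x = length(x), n_y = length(y),
    exact = exact
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than
#' that of the observed table. A zero row or column margin gives p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return One-row tibble: `p_two_sided`.
#' @export
fishers_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2.")
  if (any(table < 0) || any(table != round(table))) {
    abort("`table` must contain nonnegative integers.")
  }
  ft <- fisher.test(table)
  tibble(p_two_sided = min(ft$p.value, 1))
}

#' Tukey box-plot summary of a sample
#'
#' Median and quartiles (linear interpolation between order statistics);
#' whiskers at the most extreme data points within 1.5 IQR of the quartiles;
#' points beyond the fences reported as outliers.
#'
#' @param sample Numeric vector.
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `outliers` (list column).
#' @export
box_summary <- function(sample) {
  if (length(sample) == 0) abort("`sample` must be nonempty.")
  q <- quantile(sample, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- sample[sample >= lo_fence & sample <= hi_fence]
  tibble(
    n = length(sample),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(inside), whisker_hi = max(inside),
    outliers = list(sort(sample[sample < lo_fence | sample > hi_fence]))
  )
}

#' Per-group counts and proportions of a predicate
#'
#' Counts predicate-true cells per condition; the output feeds
#' [fishers_exact()]. Empty groups are excluded with a notice.
#'
#' @param records Event tibble with a `condition` column.
#' @param predicate Either a logical column name (string) or a function of
#'   the tibble returning a logical vector (e.g. binucleation).
#' @return Tibble: `condition`, `n`, `n_true`, `proportion`.
#' @export
frequency_table <- function(records, predicate) {
  if (nrow(records) == 0) abort("`records` must be nonempty.")
  flag <- if (is.character(predicate)) {
    records[[predicate]]
  } else {
    predicate(records)
  }
  keep <- !is.na(records$condition)
  df <- tibble(condition = records$condition[keep], flag = flag[keep])
  out <- df %>%
    group_by(.data$condition) %>%
    summarise(n = n(), n_true = sum(.data$flag), .groups = "drop") %>%
    mutate(proportion = .data$n_true / .data$n)
  empty <- out$n == 0
  if (any(empty)) {
    inform(sprintf("excluding %d empty group(s).", sum(empty)))
    out <- out[!empty, ]
  }
  out
}

#' @export
autoplot.completion_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$t_min, y = .data$fraction)) +
    geom_step() +
    labs(x = "time (min)", y = "fraction of cells completed") +
    theme_minimal()
}

#' @export
autoplot.actin_trace <- function(object, ...) {
  df <- object[object$valid, ]
  t_ana <- attr(object, "t_anaphase_min")
  dt <- attr(object, "frame_interval_min") %||% 1
  p <- ggplot(df, aes(x = frame_time(.data$frame, dt), y = .data$index)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "time (min)", y = "actin-cluster index") +
    theme_minimal()
  if (!is.null(t_ana)) {
    p <- p + ggplot2::geom_vline(xintercept = t_ana, linetype = 2)
  }
  p
}

#' @export
autoplot.neck_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position_um, y = .data$intensity)) +
    geom_line() +
    labs(x = "position along mother-daughter axis (um)",
         y = "membrane intensity") +
    theme_minimal()
}
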