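#' Peak uncertainty of a simulated trial
#'
#' The model's trial-level decision uncertainty measure: the maximum
#' firing rate the uncertainty-monitoring population attains over the
#' trial. For trials simulated with `store_traces = TRUE` this equals
#' the maximum of the stored `y_HU` trace; the simulator also computes
#' it as a streaming reduction, so it is available on every
#' [run_experiment()] row.
#'
#' @param trial A `com_trial` from [simulate_trial()], or a trace tibble
#'   with a `y_HU` column.
#' @return Peak rate in Hz.
#' @export
peak_uncertainty <- function(trial) {
  if (inherits(trial, "com_trial")) {
    return(trial$peak_uncertainty)
  }
  if (is.data.frame(trial) && "y_HU" %in% names(trial)) {
    return(max(trial$y_HU))
  }
  stop("need a com_trial or a trace with a y_HU column", call. = FALSE)
}

#' Min-max normalization
#'
#' Rescales values to \[0, 1\] via \eqn{X' = (X - X_{min}) /
#' (X_{max} - X_{min})}, the normalization applied to trial-level and
#' trial-averaged uncertainty before plotting and tertile splits.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Vector in \[0, 1\]; order preserved, min maps to 0 and max
#'   to 1.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    stop("min-max normalization needs at least two distinct finite values",
         call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Z-score values within groups
#'
#' Centres and scales to unit standard deviation within each group
#' (e.g. response times within each participant or simulated run).
#'
#' @param x Numeric vector.
#' @param group Grouping vector of the same length (default: one group).
#' @return Numeric vector with per-group mean 0 and s.d. 1.
#' @examples
#' zscore_within(c(1, 2, 3, 10, 20, 30), rep(c("a", "b"), each = 3))
#' @export
zscore_within <- function(x, group = rep(1L, length(x))) {
  stopifnot(length(x) == length(group))
  out <- numeric(length(x))
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(i) < 2L) {
      stop("group '", g, "' has fewer than 2 values", call. = FALSE)
    }
    s <- stats::sd(x[i])
    if (!is.finite(s) || s == 0) {
      stop("group '", g, "' has zero standard deviation", call. = FALSE)
    }
    out[i] <- (x[i] - mean(x[i])) / s
  }
  out
}

#' Pearson correlation with explicit validation
#'
#' Sample Pearson correlation between two vectors, rejecting degenerate
#' input (unequal lengths, fewer than 3 pairs, zero variance). Used for
#' the trial-level association between peak uncertainty and response
#' time; zero-uncertainty trials are excluded upstream.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

analysed_trials <- function(table) {
  stopifnot(is.data.frame(table))
  dplyr::filter(table, .data$decided, !.data$com_excluded)
}

new_summary_curve <- function(tbl, response, grouping) {
  structure(tibble::as_tibble(tbl), response = response,
            grouping = grouping,
            class = c("com_summary", class(tibble::tibble())))
}

curve_stats <- function(tbl, value_col, ...) {
  dplyr::summarise(
    dplyr::group_by(tbl, ...),
    mean = mean({{ value_col }}),
    se = stats::sd({{ value_col }}) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Psychometric curves split by change-of-mind
#'
#' Choice accuracy as a function of coherence level, separately for
#' change-of-mind and non-change-of-mind trials. Non-decision trials
#' and trials with more than one reversal are excluded, mirroring the
#' experimental exclusions.
#'
#' @param table A `com_experiment` tibble (or compatible data frame with
#'   columns `coherence`, `correct`, `is_com`, `decided`,
#'   `com_excluded`).
#' @return A `com_summary` tibble with columns `coherence`, `is_com`,
#'   `mean` (accuracy), `se`, `n`. Empty groups are absent rather than
#'   an error.
#' @export
psychometric_by_com <- function(table) {
  d <- analysed_trials(table)
  if (!nrow(d)) stop("no decided trials to analyse", call. = FALSE)
  out <- curve_stats(dplyr::mutate(d, correct = as.numeric(.data$correct)),
                     .data$correct, .data$coherence, .data$is_com)
  new_summary_curve(out, "accuracy", c("coherence", "is_com"))
}

add_tertile <- function(d, var, within_coherence) {
  if (within_coherence) {
    d <- dplyr::group_by(d, .data$coherence)
  }
  d <- dplyr::mutate(d, tertile = dplyr::ntile({{ var }}, 3))
  dplyr::ungroup(d)
}

#' Change-of-mind probability by coherence, RT tertile or uncertainty
#' tertile
#'
#' Probability of a change-of-mind per group, with standard errors.
#' Tertile boundaries are the empirical 1/3 and 2/3 quantiles of the
#' decided (non-excluded) trials: response-time tertiles are computed
#' within each coherence condition by default (matching per-coherence
#' psychometric panels), uncertainty tertiles across all trials on
#' min-max normalized peak uncertainty; both choices are exposed.
#'
#' @param table A `com_experiment` tibble.
#' @param grouping `"coherence"`, `"rt_tertile"` or
#'   `"uncertainty_tertile"`.
#' @param within_coherence Compute tertile boundaries within each
#'   coherence condition (defaults: `TRUE` for RT, `FALSE` for
#'   uncertainty).
#' @return A `com_summary` tibble of P(CoM) per group; for tertile
#'   groupings one row per coherence x tertile.
#' @export
com_probability_by <- function(table,
                               grouping = c("coherence", "rt_tertile",
                                            "uncertainty_tertile"),
                               within_coherence = NULL) {
  grouping <- match.arg(grouping)
  d <- analysed_trials(table)
  d <- dplyr::mutate(d, is_com = as.numeric(.data$is_com))
  if (grouping == "coherence") {
    out <- curve_stats(d, .data$is_com, .data$coherence)
    return(new_summary_curve(out, "p_com", "coherence"))
  }
  if (grouping == "rt_tertile") {
    if (is.null(within_coherence)) within_coherence <- TRUE
    d <- add_tertile(d, .data$response_time, within_coherence)
  } else {
    if (is.null(within_coherence)) within_coherence <- FALSE
    d <- dplyr::mutate(d,
      u_norm = minmax_normalize(.data$peak_uncertainty))
    d <- add_tertile(d, .data$u_norm, within_coherence)
  }
  if (min(table(d$tertile)) < 1 || dplyr::n_distinct(d$tertile) < 3) {
    stop("too few trials to form tertiles", call. = FALSE)
  }
  out <- curve_stats(d, .data$is_com, .data$coherence, .data$tertile)
  new_summary_curve(out, "p_com", c("coherence", "tertile"))
}

#' Mean normalized uncertainty by coherence and outcome
#'
#' The model's signature uncertainty pattern: mean (min-max normalized)
#' peak uncertainty as a function of coherence, separately for correct
#' and error trials. Uncertainty decreases with coherence for correct
#' choices and increases for errors, forming a '<' shape.
#'
#' @param table A `com_experiment` tibble.
#' @param normalize Normalization scope for the uncertainty values:
#'   `"run"` (across all analysed trials, default) or `"none"` (raw
#'   Hz).
#' @return A `com_summary` tibble with columns `coherence`, `correct`,
#'   `mean`, `se`, `n`.
#' @export
uncertainty_by_coherence_outcome <- function(table,
                                             normalize = c("run", "none")) {
  normalize <- match.arg(normalize)
  d <- analysed_trials(table)
  if (normalize == "run") {
    d <- dplyr::mutate(d, u = minmax_normalize(.data$peak_uncertainty))
  } else {
    d <- dplyr::mutate(d, u = .data$peak_uncertainty)
  }
  out <- curve_stats(d, .data$u, .data$coherence, .data$correct)
  new_summary_curve(out, "uncertainty", c("coherence", "correct"))
}

#' Run-level summary of a simulated experiment
#'
#' @param x A `com_experiment` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_trials`, `n_decided`,
#'   `non_decision_rate`, `com_rate` (among decided, non-excluded
#'   trials), `multi_reversal_rate`, `accuracy`,
#'   `r_uncertainty_rt` (Pearson correlation of peak uncertainty and
#'   response time over decided trials with nonzero uncertainty),
#'   `median_rt`, `master_seed`.
#' @export
glance.com_experiment <- function(x, ...) {
  d <- dplyr::filter(x, .data$decided)
  dd <- dplyr::filter(d, !.data$com_excluded)
  du <- dplyr::filter(d, .data$peak_uncertainty > 0)
  tibble::tibble(
    n_trials = nrow(x),
    n_decided = nrow(d),
    non_decision_rate = mean(!x$decided),
    com_rate = mean(dd$is_com),
    multi_reversal_rate = mean(d$com_excluded),
    accuracy = mean(dd$correct),
    r_uncertainty_rt = if (nrow(du) >= 3)
      pearson_r(du$peak_uncertainty, du$response_time) else NA_real_,
    median_rt = stats::median(d$response_time),
    master_seed = attr(x, "master_seed") %||% NA_integer_
  )
}

#' Per-condition summary of a simulated experiment
#'
#' @param x A `com_experiment` tibble.
#' @param ... Unused.
#' @return A tibble with one row per coherence: trial counts,
#'   non-decision rate, accuracy, CoM probability, mean RT and mean
#'   peak uncertainty.
#' @export
tidy.com_experiment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$coherence),
    n = dplyr::n(),
    non_decision_rate = mean(!.data$decided),
    accuracy = mean(.data$correct[.data$decided & !.data$com_excluded]),
    p_com = mean(.data$is_com[.data$decided & !.data$com_excluded]),
    mean_rt = mean(.data$response_time[.data$decided]),
    mean_peak_uncertainty = mean(.data$peak_uncertainty[.data$decided]),
    .groups = "drop"
  )
}

#' @export
tidy.com_bifurcation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.com_bifurcation <- function(x, ...) {
  tibble::tibble(
    n_feedback = dplyr::n_distinct(x$feedback),
    n_branches = dplyr::n_distinct(x$branch),
    max_stable = max(tapply(x$stability == "stable", x$feedback, sum)),
    fold_points = list(attr(x, "fold_points"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
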