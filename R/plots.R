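#' Plot a summary curve
#'
#' Mean with standard-error bars against the first grouping variable,
#' coloured by the second grouping variable when present.
#'
#' @param object A `com_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.com_summary <- function(object, ...) {
  grouping <- attr(object, "grouping")
  response <- attr(object, "response")
  xvar <- grouping[1]
  p <- if (length(grouping) > 1) {
    ggplot2::ggplot(object, ggplot2::aes(
      x = factor(.data[[xvar]]), y = .data$mean,
      colour = factor(.data[[grouping[2]]]),
      group = factor(.data[[grouping[2]]])))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(
      x = factor(.data[[xvar]]), y = .data$mean, group = 1))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = xvar, y = response,
                  colour = if (length(grouping) > 1) grouping[2] else NULL) +
    ggplot2::theme_minimal()
}

#' Plot the time course of a simulated trial
#'
#' Sensorimotor rates, uncertainty-population rate and hand rates at
#' integration-step resolution (requires `store_traces = TRUE`).
#'
#' @param object A `com_trial` with a stored trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.com_trial <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("trial was simulated without store_traces = TRUE", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    object$trace,
    c("H_L", "H_R", "y_HU", "y_HL", "y_HR"),
    names_to = "population", values_to = "rate")
  module <- c(H_L = "sensorimotor", H_R = "sensorimotor",
              y_HU = "uncertainty", y_HL = "hand", y_HR = "hand")
  long$module <- factor(module[long$population],
                        levels = c("sensorimotor", "uncertainty", "hand"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$rate,
                                          colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$module), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "time since stimulus onset (ms)",
                  y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
  if (!is.na(object$decision_time_raw)) {
    p <- p + ggplot2::geom_vline(xintercept = object$decision_time_raw,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a bifurcation diagram
#'
#' `S_L` of every fixed point against the constant uncertainty
#' feedback, solid for stable branches and dotted for saddles/unstable
#' points, with detected fold regions marked.
#'
#' @param object A `com_bifurcation` from [bifurcation_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.com_bifurcation <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    .data$feedback, .data$S_L, group = .data$branch,
    linetype = .data$stability == "stable")) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dotted"),
      labels = c(`TRUE` = "stable", `FALSE` = "saddle/unstable"),
      name = NULL) +
    ggplot2::labs(x = "uncertainty feedback (nA)", y = "S_L") +
    ggplot2::theme_minimal()
  folds <- attr(object, "fold_points")
  if (length(folds)) {
    p <- p + ggplot2::geom_vline(xintercept = folds, colour = "red",
                                 linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Plot a cursor trajectory
#'
#' @param object A trajectory tibble (`t`, `x`, `y`).
#' @param geom A [screen_geometry()] drawn behind the path.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.com_trajectory <- function(object, geom = screen_geometry(), ...) {
  targets <- tibble::tibble(
    x = c(geom$target_left[["x"]], geom$target_right[["x"]]),
    y = c(geom$target_left[["y"]], geom$target_right[["y"]]))
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(data = targets, shape = 1, size = 10,
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = geom$centre_x, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = geom$band_top, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, geom$width),
                         ylim = c(geom$height, 0)) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
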