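#' Plot a simulated trajectory
#'
#' Facets the 15 variables over time; when `data` (one mouse, same
#' frame) is supplied the observations are overlaid as points.
#'
#' @param object a `tme_traj` tibble.
#' @param data optional dataset rows for one mouse.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tme_traj
#' @export
autoplot.tme_traj <- function(object, data = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"day",
                              names_to = "variable", values_to = "value") |>
    dplyr::mutate(variable = factor(.data$variable, levels = tme_state_vars))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days from week 6)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    dl <- tidyr::pivot_longer(data[, c("day", tme_state_vars)], -"day",
                              names_to = "variable", values_to = "value") |>
      dplyr::mutate(variable = factor(.data$variable, levels = tme_state_vars))
    gg <- gg + ggplot2::geom_point(data = dl, color = "black", size = 1.5)
  }
  gg
}

#' Plot a sensitivity ranking
#'
#' Horizontal bars of the neighborhood-averaged sensitivities for the
#' top-ranked parameters, signed (a positive bar means increasing the
#' parameter increases the output).
#'
#' @param object a `tme_sensitivity` object.
#' @param n how many parameters to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tme_sensitivity
#' @export
autoplot.tme_sensitivity <- function(object, n = 12, ...) {
  d <- tidy.tme_sensitivity(object) |>
    dplyr::slice_head(n = n) |>
    dplyr::mutate(parameter = stats::reorder(.data$parameter,
                                             abs(.data$s_hat)))
  ggplot2::ggplot(d, ggplot2::aes(.data$s_hat, .data$parameter)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "neighborhood-averaged sensitivity",
      y = NULL,
      title = paste0("output: ", attr(object, "output", exact = TRUE))
    ) +
    ggplot2::theme_minimal()
}

#' Plot bifurcation curves
#'
#' @param object a `tme_bifurcation` tibble (possibly several
#'   parameters row-bound together).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tme_bifurcation
#' @export
autoplot.tme_bifurcation <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$value, .data$C42, color = factor(.data$mouse))
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "parameter value (per day)",
                  y = "cancer cells at day 42",
                  color = "mouse") +
    ggplot2::theme_minimal()
}

#' Plot perturbation envelopes
#'
#' @param object a `tme_envelope` tibble.
#' @param variables which variables to show (default all 15).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tme_envelope
#' @export
autoplot.tme_envelope <- function(object, variables = tme_state_vars, ...) {
  d <- dplyr::filter(object, .data$variable %in% variables) |>
    dplyr::mutate(variable = factor(.data$variable, levels = tme_state_vars))
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$baseline)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days from week 6)", y = NULL) +
    ggplot2::theme_minimal()
}
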