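#' Tidy a fitted parameter set
#'
#' @param x a `tme_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter: `parameter`,
#'   `estimate` (bounded), `unconstrained`, and `at_bound`.
#' @method tidy tme_fit
#' @export
tidy.tme_fit <- function(x, ...) {
  tibble::tibble(
    parameter = tme_param_names,
    estimate = unname(x$params$theta),
    unconstrained = unname(x$theta_unconstrained),
    at_bound = unname(x$active)
  )
}

#' One-row summary of a fit
#'
#' @param x a `tme_fit` object.
#' @param ... unused.
#' @return A one-row tibble: design size, numerical rank, residual
#'   norms, number of active bounds, KKT status.
#' @method glance tme_fit
#' @export
glance.tme_fit <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$system$A),
    n_params = ncol(x$system$A),
    rank = x$rank,
    rank_deficient = x$rank_deficient,
    residual_norm = x$residual_norm,
    residual_norm_unconstrained = x$residual_norm_unconstrained,
    n_at_bound = sum(x$active),
    kkt_ok = x$kkt_ok
  )
}

#' Tidy a sensitivity report
#'
#' @param x a `tme_sensitivity` object.
#' @param ... unused.
#' @return The report tibble ordered by rank.
#' @method tidy tme_sensitivity
#' @export
tidy.tme_sensitivity <- function(x, ...) {
  dplyr::arrange(tibble::as_tibble(x), .data$rank)
}

#' One-row summary of a sensitivity report
#'
#' @param x a `tme_sensitivity` object.
#' @param ... unused.
#' @method glance tme_sensitivity
#' @export
glance.tme_sensitivity <- function(x, ...) {
  tibble::tibble(
    output = attr(x, "output", exact = TRUE),
    horizon = attr(x, "horizon", exact = TRUE),
    step = attr(x, "step", exact = TRUE),
    fraction = attr(x, "fraction", exact = TRUE),
    n_nodes = attr(x, "n_nodes", exact = TRUE),
    mouse = attr(x, "mouse", exact = TRUE),
    top_parameter = x$parameter[x$rank == 1]
  )
}

#' Tidy a recovery report
#'
#' @param x a `tme_recovery` object.
#' @param ... unused.
#' @method tidy tme_recovery
#' @export
tidy.tme_recovery <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a recovery experiment
#'
#' @param x a `tme_recovery` object.
#' @param ... unused.
#' @method glance tme_recovery
#' @export
glance.tme_recovery <- function(x, ...) {
  tibble::tibble(
    rank = attr(x, "rank", exact = TRUE),
    rank_deficient = attr(x, "rank_deficient", exact = TRUE),
    residual_norm = attr(x, "residual_norm", exact = TRUE),
    median_rel_error = stats::median(x$rel_error),
    n_at_bound = sum(x$at_bound)
  )
}
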