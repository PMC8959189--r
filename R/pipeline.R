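#' Run the full analysis pipeline
#'
#' Wires the stages together: parameter fitting (or the published
#' parameter set), trajectory simulation per mouse, neighborhood-
#' averaged sensitivity ranking for the cancer output, and bifurcation
#' scans over the top-ranked parameters.  Every stage consumes and
#' returns tibbles, so the pieces can equally be called individually
#' and piped.
#'
#' @param data dataset tibble, default the built-in study data.
#' @param params `"table3"` (published values), `"fit"` (estimate from
#'   `data`), or a [tme_params] object.
#' @param stages which stages to run, a subset of
#'   `c("fit", "simulate", "sensitivity", "bifurcation")`.
#' @param horizon simulation/sensitivity horizon in days.
#' @param theta_min bound for the constrained fit.
#' @param sens_step forward-Euler step for sensitivities (days).
#' @param bif_grid bifurcation scan grid.
#' @param n_top how many top parameters to scan.
#' @param out_dir optional directory: CSV/JSON artifacts are written
#'   there (trajectories, parameters, sensitivity report, curves).
#' @return A named list with the computed components (`scales`, `fit`,
#'   `params`, `trajectories`, `sensitivity`, `bifurcation`), each
#'   present when its stage ran.
#' @export
tme_pipeline <- function(data = pymt_mice(),
                         params = "table3",
                         stages = c("simulate", "sensitivity", "bifurcation"),
                         horizon = 126,
                         theta_min = 1e-5,
                         sens_step = 0.01,
                         bif_grid = seq(0, 0.2, length.out = 201),
                         n_top = 6,
                         out_dir = NULL) {
  stages <- match.arg(stages,
                      c("fit", "simulate", "sensitivity", "bifurcation"),
                      several.ok = TRUE)
  if (is.null(.data_frame_of(data))) attr(data, "frame") <- "dimensional"
  scales <- tme_scales(data)
  data_nd <- tme_nondimensionalize(data, scales)
  inits <- tme_inits(data_nd)
  out <- list(scales = scales)

  if ("fit" %in% stages || identical(params, "fit")) {
    out$fit <- tme_fit(data, theta_min = theta_min)
  }
  p <- if (inherits(params, "tme_params")) {
    params
  } else if (identical(params, "table3")) {
    tme_params_table3()
  } else if (identical(params, "fit")) {
    out$fit$params
  } else {
    stop("`params` must be 'table3', 'fit', or a tme_params object",
         call. = FALSE)
  }
  out$params <- p

  if ("simulate" %in% stages) {
    out$trajectories <- purrr::imap_dfr(inits, function(x0, nm) {
      tr <- tme_simulate(p, x0, horizon = horizon)
      dplyr::mutate(tibble::as_tibble(tr),
                    mouse = as.integer(gsub("\\D", "", nm)),
                    .before = 1)
    })
  }
  if ("sensitivity" %in% stages) {
    out$sensitivity <- purrr::imap(inits, function(x0, nm) {
      tme_sensitivity(p, x0, output = "cancer", horizon = horizon,
                      step = sens_step,
                      mouse = as.integer(gsub("\\D", "", nm)))
    })
    top <- tme_top_parameters(out$sensitivity[[1]], n_top)
  } else {
    top <- c("delta_C", "lambda_C", "lambda_CA",
             "lambda_CIL6", "delta_A", "lambda_A")[seq_len(n_top)]
  }
  if ("bifurcation" %in% stages) {
    out$bifurcation <- purrr::map_dfr(
      top, tme_bifurcation,
      params = p, inits = inits, grid = bif_grid, scales = scales
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_params(p, file.path(out_dir, "params.json"))
    if (!is.null(out$trajectories)) {
      utils::write.csv(out$trajectories,
                       file.path(out_dir, "trajectories.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$sensitivity)) {
      jsonlite::write_json(
        lapply(out$sensitivity, function(s) tibble::as_tibble(s)),
        file.path(out_dir, "sensitivity.json"), digits = NA
      )
    }
    if (!is.null(out$bifurcation)) {
      utils::write.csv(out$bifurcation,
                       file.path(out_dir, "bifurcation.csv"),
                       row.names = FALSE)
    }
  }
  out
}
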