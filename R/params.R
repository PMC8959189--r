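#' Model parameter sets
#'
#' A `tme_params` object bundles the 57 nonnegative non-dimensional
#' interaction rates of the tumor-microenvironment model (units: per day)
#' with the three fixed dimensionless constants: the cancer carrying
#' capacity `C0`, the adipocyte carrying capacity `A0`, and the necrotic
#' fraction `alpha_NC` (the fraction of dying cancer cells that become
#' necrotic).  The constants default to `C0 = 2`, `A0 = 2`,
#' `alpha_NC = 1.5` and are never estimated.
#'
#' The canonical parameter order is fixed (see [tme_param_names]); every
#' matrix produced by the package indexes its 57 parameter columns in
#' this order.
#'
#' @param theta named numeric vector of the 57 rates.  Names must be a
#'   permutation of [tme_param_names]; values are reordered canonically.
#' @param constants named numeric vector with entries `C0`, `A0`,
#'   `alpha_NC`.
#' @return A `tme_params` object (list with elements `theta` and
#'   `constants`).
#' @seealso [tme_params_table3()] for the published fitted values.
#' @examples
#' p <- tme_params_table3()
#' p$theta[["delta_C"]]
#' @export
tme_params <- function(theta, constants = .tme_default_constants) {
  if (is.null(names(theta)) || !setequal(names(theta), tme_param_names)) {
    stop("`theta` must be named with the 57 canonical parameter names",
         call. = FALSE)
  }
  theta <- as.double(theta[tme_param_names])
  names(theta) <- tme_param_names
  if (anyNA(theta) || any(!is.finite(theta))) {
    stop("parameter values must be finite", call. = FALSE)
  }
  if (any(theta < 0)) {
    stop("all rate parameters must be nonnegative", call. = FALSE)
  }
  constants <- as.double(constants[c("C0", "A0", "alpha_NC")])
  names(constants) <- c("C0", "A0", "alpha_NC")
  if (anyNA(constants) || any(constants <= 0)) {
    stop("constants C0, A0, alpha_NC must be positive", call. = FALSE)
  }
  structure(list(theta = theta, constants = constants), class = "tme_params")
}

#' Published fitted parameter values
#'
#' The 57 non-dimensional rates obtained by the bound-constrained
#' least-squares fit to the three-mouse time-course dataset, as bundled
#' in `inst/extdata/table3_params.json`.
#'
#' @return A [tme_params] object.
#' @export
tme_params_table3 <- function() {
  path <- system.file("extdata", "table3_params.json", package = "pymtme",
                      mustWork = TRUE)
  read_params(path)
}

#' Read or write a parameter set as flat JSON
#'
#' Parameter files are flat key/value JSON using the canonical ASCII
#' names (e.g. `"lambda_ThH"`, `"delta_CTc"`, `"A_TN"`); the three fixed
#' constants may be present under `"C0"`, `"A0"`, `"alpha_NC"` and
#' default to their standard values when absent.
#'
#' @param path file path.
#' @param params a [tme_params] object.
#' @return `read_params()` returns a [tme_params] object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- unlist(raw)
  constants <- .tme_default_constants
  for (k in names(constants)) {
    if (k %in% names(raw)) constants[[k]] <- as.double(raw[[k]])
  }
  tme_params(raw[tme_param_names], constants = constants)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "tme_params"))
  out <- c(as.list(params$theta), as.list(params$constants))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.tme_params <- function(x, ...) {
  cat("<tme_params> 57 non-dimensional rates (per day)\n")
  cat("constants: C0 =", x$constants[["C0"]],
      " A0 =", x$constants[["A0"]],
      " alpha_NC =", x$constants[["alpha_NC"]], "\n")
  rng <- range(x$theta)
  cat("rate range: [", format(rng[1]), ",", format(rng[2]), "]\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a parameter set
#'
#' @param x a [tme_params] object.
#' @param ... unused.
#' @return A tibble with columns `parameter`, `value`, and `role`
#'   (production/activation, decay/inhibition, or source).
#' @method tidy tme_params
#' @export
tidy.tme_params <- function(x, ...) {
  role <- dplyr::case_when(
    startsWith(tme_param_names, "lambda") ~ "production",
    startsWith(tme_param_names, "delta")  ~ "decay",
    TRUE                                  ~ "source"
  )
  tibble::tibble(parameter = tme_param_names,
                 value = unname(x$theta),
                 role = role)
}

#' Canonical names
#'
#' `tme_param_names` is the fixed ordering of the 57 rate parameters
#' (the row-major reading order of the published parameter table);
#' `tme_state_vars` is the fixed ordering of the 15 state variables.
#'
#' @format Character vectors of length 57 and 15.
#' @name tme_param_names
#' @aliases tme_state_vars
#' @export tme_param_names tme_state_vars
NULL
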