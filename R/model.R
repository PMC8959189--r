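#' Right-hand side of the non-dimensional interaction model
#'
#' Evaluates the time derivative (per day) of the 15 non-dimensional
#' state variables: naive/helper/cytotoxic/regulatory T cells, naive and
#' activated dendritic cells, naive and activated macrophages, cancer
#' cells, necrotic cells, adipocytes, and the cytokines HMGB1, IL-12,
#' IL-10 and IL-6.  All interactions are mass-action except the logistic
#' growth of cancer cells and adipocytes; necrotic cells are produced as
#' the fraction `alpha_NC` of the cancer death flux.
#'
#' @param state named (or canonically ordered) nonnegative numeric
#'   vector of the 15 non-dimensional state variables.
#' @param params a [tme_params] object.
#' @return Named numeric vector of 15 derivatives (per day).
#' @examples
#' p <- tme_params_table3()
#' x <- stats::setNames(rep(0.5, 15), tme_state_vars)
#' tme_rhs(x, p)
#' @export
tme_rhs <- function(state, params) {
  x <- .check_state(state)
  stopifnot(inherits(params, "tme_params"))
  out <- .rhs_core(x, params$theta, params$constants)
  stats::setNames(out, tme_state_vars)
}

.check_state <- function(state) {
  if (!is.null(names(state))) {
    if (!setequal(names(state), tme_state_vars)) {
      stop("state names must be the 15 canonical variable names",
           call. = FALSE)
    }
    state <- state[tme_state_vars]
  }
  x <- as.double(state)
  if (length(x) != 15L) stop("state must have 15 components", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("state components must be finite", call. = FALSE)
  }
  if (any(x < 0)) stop("state components must be nonnegative", call. = FALSE)
  x
}

#' Jacobian of the model RHS with respect to the state
#'
#' Analytic 15 x 15 matrix of partial derivatives of [tme_rhs()] with
#' respect to the state variables.  Only the cancer and adipocyte
#' logistic terms contribute beyond bilinear entries.
#'
#' @inheritParams tme_rhs
#' @return 15 x 15 matrix with dimnames `tme_state_vars`.
#' @export
tme_jacobian_state <- function(state, params) {
  x <- .check_state(state)
  stopifnot(inherits(params, "tme_params"))
  tt <- .tme_terms
  xv <- .factor_values(x, params$constants)
  dxv <- .factor_derivs(x, params$constants)
  vals <- .contrib_mult(params$constants) * params$theta[tt$c_p] *
    dxv[tt$c_fd] * xv[tt$c_fo]
  J <- matrix(0, 15L, 15L, dimnames = list(tme_state_vars, tme_state_vars))
  agg <- rowsum(vals, (tt$c_v - 1L) * 15L + tt$c_e)
  J[as.integer(rownames(agg))] <- agg
  J
}

#' Jacobian of the model RHS with respect to the parameters
#'
#' The system is linear in the 57 rates, so each entry of the 15 x 57
#' matrix is a product of state variables (or a logistic factor, or a
#' constant) that does not involve the parameter vector.  Stacking this
#' matrix over observed states is exactly the least-squares design
#' matrix used by [tme_design()].
#'
#' @inheritParams tme_rhs
#' @return 15 x 57 matrix with rows `tme_state_vars` and columns
#'   `tme_param_names`.
#' @export
tme_jacobian_params <- function(state, params) {
  x <- .check_state(state)
  stopifnot(inherits(params, "tme_params"))
  .jac_params_core(x, params$constants)
}

.jac_params_core <- function(x, constants) {
  tt <- .tme_terms
  xv <- .factor_values(x, constants)
  J <- matrix(0, 15L, 57L, dimnames = list(tme_state_vars, tme_param_names))
  J[tt$ep_flat] <- .term_mult(constants) * xv[tt$f1] * xv[tt$f2]
  J
}

#' Closed-form adipocyte trajectory
#'
#' Adipocytes follow an autonomous logistic law
#' \eqn{dA/dt = \lambda_A A (1 - A/A_0) - \delta_A A}, i.e. a logistic
#' model with effective rate \eqn{r = \lambda_A - \delta_A} and
#' effective capacity \eqn{K = A_0 (1 - \delta_A/\lambda_A)}.  This
#' returns the exact solution, handling the degenerate
#' \eqn{\lambda_A = \delta_A} case (pure quadratic decay) continuously.
#'
#' @param A_init initial value (dimensionless, nonnegative).
#' @param lambda_A,delta_A growth and decay rates (per day);
#'   `lambda_A` must be positive.
#' @param A0 carrying capacity (dimensionless), default 2.
#' @param t time or vector of times (days).
#' @return Numeric vector of adipocyte values at `t`.
#' @examples
#' adipocyte_logistic(1, lambda_A = 0.003, delta_A = 0.001, t = c(10, 100))
#' @export
adipocyte_logistic <- function(A_init, lambda_A, delta_A, A0 = 2, t) {
  stopifnot(lambda_A > 0, A0 > 0)
  if (A_init < 0) stop("A_init must be nonnegative", call. = FALSE)
  r <- lambda_A - delta_A
  if (A_init == 0) return(rep(0, length(t)))
  if (abs(r) < 1e-12) {
    # r = 0: dA/dt = -lambda_A A^2 / A0, separable
    return(A_init / (1 + lambda_A * A_init * t / A0))
  }
  K <- A0 * (1 - delta_A / lambda_A)
  K / (1 + (K / A_init - 1) * exp(-r * t))
}

#' Total cell count of a dimensional state
#'
#' The tumor-size surrogate used for sensitivity analysis: the sum of
#' all tumor-resident cell populations, excluding naive T cells (which
#' reside in the lymphatic system) and counting naive macrophages at a
#' 20% weight (most polarize inside the tumor).  Cytokines are not
#' cells and are excluded.
#'
#' @param state a dimensional state: a named vector, or a data frame
#'   whose columns include the 15 variables (one row per observation).
#' @return Numeric vector of total cell counts (abundance units).
#' @examples
#' total_cells(pymt_mice()[1, ])
#' @export
total_cells <- function(state) {
  w <- total_cell_weights()
  if (is.data.frame(state)) {
    m <- as.matrix(state[, tme_state_vars, drop = FALSE])
    return(drop(m %*% w))
  }
  x <- .check_state(state)
  sum(w * x)
}

#' @rdname total_cells
#' @return `total_cell_weights()` returns the named 15-vector of weights.
#' @export
total_cell_weights <- function() {
  stats::setNames(
    c(0, 1, 1, 1, 1, 1, 0.2, 1, 1, 1, 1, 0, 0, 0, 0),
    tme_state_vars
  )
}
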