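# Forward (direct differential) sensitivity analysis and bifurcation
# scans.  The sensitivity system d/dt (dx/dtheta_i) =
# (df/dx)(dx/dtheta_i) + df/dtheta_i is advanced jointly with the state
# by forward Euler from zero initial sensitivities.  The engine is
# vectorized over K parameter vectors at once (the sparse-grid nodes of
# the neighborhood average), storing the sensitivities as a
# 15 x (57 K) matrix of per-node column blocks.

# TH: 57 x K; x0: 15-vector.  Returns X (15 x K) and S (15 x 57K).
# Thin dispatcher to the compiled kernel; the pure-R engine below is the
# reference implementation and is cross-checked in the tests.
.euler_sens_engine <- function(TH, x0, h, nsteps, constants) {
  tt <- .tme_terms
  .euler_sens_kernel(
    TH, as.double(x0), h, as.integer(nsteps),
    constants[["C0"]], constants[["A0"]],
    tt$p - 1L, tt$e - 1L, .term_mult(constants), tt$f1 - 1L, tt$f2 - 1L,
    tt$c_e - 1L, tt$c_v - 1L, tt$c_p - 1L, .contrib_mult(constants),
    tt$c_fd - 1L, tt$c_fo - 1L
  )
}

.euler_sens_engine_r <- function(TH, x0, h, nsteps, constants) {
  tt <- .tme_terms
  K <- ncol(TH)
  X <- matrix(x0, 15L, K)
  S <- matrix(0, 15L, 57L * K)
  ms <- .term_mult(constants)
  THp <- TH[tt$p, , drop = FALSE]                     # 70 x K, fixed
  CTH <- .contrib_mult(constants) * TH[tt$c_p, , drop = FALSE]  # ncontrib x K
  # flat indices of the dtheta entries of S-dot: term t, node k ->
  # row e_t, column (k-1)*57 + p_t
  cols <- outer(tt$p, (seq_len(K) - 1L) * 57L, `+`)   # 70 x K
  idxJ <- (cols - 1L) * 15L + tt$e
  nct <- length(tt$c_e)
  for (step in seq_len(nsteps)) {
    XV <- .factor_values_mat(X, constants)
    dXV <- .factor_derivs_mat(X, constants)
    TV <- ms * XV[tt$f1, , drop = FALSE] * XV[tt$f2, , drop = FALSE]
    FX <- tt$E %*% (TV * THp)
    Sdot <- matrix(0, 15L, 57L * K)
    for (ci in seq_len(nct)) {
      dval <- CTH[ci, ] * dXV[tt$c_fd[ci], ] * XV[tt$c_fo[ci], ]
      Sdot[tt$c_e[ci], ] <- Sdot[tt$c_e[ci], ] +
        rep(dval, each = 57L) * S[tt$c_v[ci], ]
    }
    Sdot[idxJ] <- Sdot[idxJ] + TV
    S <- S + h * Sdot
    X <- X + h * FX
    if (anyNA(X) || any(!is.finite(X))) {
      stop("forward Euler diverged at t = ", step * h,
           " days; reduce the step", call. = FALSE)
    }
  }
  list(X = X, S = S)
}

#' Forward sensitivities of the state at the horizon
#'
#' Advances the state together with its parameter sensitivities
#' \eqn{\partial \bar x / \partial \theta_i} by forward Euler (the
#' direct differential method), from zero initial sensitivities, and
#' returns the 15 x 57 sensitivity matrix at the horizon.
#'
#' @param params a [tme_params] object.
#' @param init non-dimensional initial state.
#' @param horizon days (default 126 = 18 weeks).
#' @param step forward-Euler step in days (default 0.01).
#' @return 15 x 57 matrix, rows `tme_state_vars`, columns
#'   `tme_param_names`.
#' @export
tme_forward_sensitivities <- function(params, init, horizon = 126,
                                      step = 0.01) {
  stopifnot(inherits(params, "tme_params"), step > 0)
  x0 <- .check_state(init)
  if (horizon == 0) {
    return(matrix(0, 15L, 57L,
                  dimnames = list(tme_state_vars, tme_param_names)))
  }
  nsteps <- round(horizon / step)
  sol <- .euler_sens_engine(matrix(params$theta, 57L, 1L), x0, step,
                            nsteps, params$constants)
  S <- sol$S
  dimnames(S) <- list(tme_state_vars, tme_param_names)
  S
}

#' Project a sensitivity matrix onto an output functional
#'
#' For `"cancer"` the projection is simply the cancer row.  For
#' `"total_cells"` rows are first rescaled to dimensional units by the
#' per-variable scales and then combined with the total-cell weights
#' (all tumor-resident populations, naive macrophages at 20%, naive T
#' cells and cytokines excluded), so the summed populations are
#' physically comparable.
#'
#' @param S a 15 x 57 sensitivity matrix.
#' @param output `"cancer"` or `"total_cells"`.
#' @param scales scales tibble (required for `"total_cells"`).
#' @return Named 57-vector.
#' @export
tme_output_functional <- function(S, output = c("cancer", "total_cells"),
                                  scales = NULL) {
  output <- match.arg(output)
  if (output == "cancer") {
    return(stats::setNames(S[9L, ], tme_param_names))
  }
  if (is.null(scales)) {
    stop("`scales` is required for the total_cells output", call. = FALSE)
  }
  w <- total_cell_weights() * .scales_vec(scales)
  stats::setNames(as.vector(w %*% S), tme_param_names)
}

# sparse quadrature nodes for the +/- fraction box around theta:
# level-1 Smolyak/Clenshaw-Curtis rule = center + 2 axial points per
# dimension (2d + 1 nodes), center weight 1 - d/3, axial weights 1/6;
# exact for all polynomials of total degree <= 3 on the box.
.sparse_box_nodes <- function(theta, fraction) {
  d <- length(theta)
  TH <- matrix(theta, d, 2L * d + 1L)
  for (i in seq_len(d)) {
    TH[i, 2L * i] <- theta[i] * (1 - fraction)
    TH[i, 2L * i + 1L] <- theta[i] * (1 + fraction)
  }
  w <- c(1 - d / 3, rep(1 / 6, 2L * d))
  list(TH = TH, w = w)
}

#' Neighborhood-averaged parameter sensitivities
#'
#' Computes the raw first-order sensitivity of an output functional
#' (cancer, or the total cell count) to each of the 57 parameters at
#' the horizon, and its average over the axis-aligned box of
#' `+/- fraction` multiplicative perturbations around `params`
#' (volume-normalized, so a zero-width box reproduces the raw value).
#' The box integral is approximated with a level-1 sparse quadrature
#' grid (`2 * 57 + 1 = 115` nodes), each node requiring one forward
#' sensitivity integration; the whole batch is advanced in one
#' vectorized forward-Euler sweep.  Parameters are ranked by the
#' absolute averaged sensitivity, ties broken by canonical order.
#'
#' With the default `scaling = "parameter"` the reported `s_hat` is the
#' box average multiplied by the nominal parameter value, i.e. the
#' unnormalized integral of the raw sensitivity over that parameter's
#' own perturbation interval (up to the constant width factor).  This
#' parameter-scaled (elasticity-like) statistic compares rates that
#' differ by orders of magnitude on a common footing and reproduces the
#' published ranking structure; `scaling = "none"` returns the plain
#' volume-normalized box average.
#'
#' @inheritParams tme_forward_sensitivities
#' @param output `"cancer"` or `"total_cells"`.
#' @param fraction half-width of the multiplicative neighborhood
#'   (default 0.10).  A zero parameter degenerates that coordinate of
#'   the box to a point; this is handled, not an error.
#' @param scaling `"parameter"` (default) or `"none"`, see Details.
#' @param scales required for `"total_cells"`.
#' @param mouse optional mouse id recorded in the result.
#' @return A `tme_sensitivity` object: tibble with columns `parameter`,
#'   `s_raw` (sensitivity at the nominal parameters), `s_hat`
#'   (neighborhood average) and `rank`; attributes record the horizon,
#'   step, fraction, grid size and output name.  Supports [tidy()] and
#'   [autoplot()].
#' @export
tme_sensitivity <- function(params, init, output = c("cancer", "total_cells"),
                            horizon = 126, step = 0.01, fraction = 0.10,
                            scaling = c("parameter", "none"),
                            scales = NULL, mouse = NA_integer_) {
  stopifnot(inherits(params, "tme_params"), step > 0)
  output <- match.arg(output)
  scaling <- match.arg(scaling)
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  x0 <- .check_state(init)
  nodes <- .sparse_box_nodes(params$theta, fraction)
  K <- ncol(nodes$TH)
  nsteps <- round(horizon / step)
  sol <- .euler_sens_engine(nodes$TH, x0, step, nsteps, params$constants)
  proj <- vapply(seq_len(K), function(k) {
    S_k <- sol$S[, (k - 1L) * 57L + seq_len(57L), drop = FALSE]
    tme_output_functional(S_k, output, scales)
  }, numeric(57L))                                    # 57 x K
  s_raw <- proj[, 1L]
  s_hat <- as.vector(proj %*% nodes$w)
  if (scaling == "parameter") s_hat <- s_hat * unname(params$theta)
  ord <- order(-abs(s_hat), seq_along(s_hat))
  rank <- integer(57L); rank[ord] <- seq_len(57L)
  out <- tibble::tibble(
    parameter = tme_param_names,
    s_raw = unname(s_raw),
    s_hat = s_hat,
    rank = rank
  )
  attr(out, "output") <- output
  attr(out, "scaling") <- scaling
  attr(out, "horizon") <- horizon
  attr(out, "step") <- step
  attr(out, "fraction") <- fraction
  attr(out, "n_nodes") <- K
  attr(out, "mouse") <- mouse
  class(out) <- c("tme_sensitivity", class(out))
  out
}

#' Top-ranked parameters of a sensitivity report
#'
#' @param report a `tme_sensitivity` object.
#' @param n how many parameters.
#' @return Character vector of parameter names, most sensitive first.
#' @export
tme_top_parameters <- function(report, n = 6) {
  stopifnot(inherits(report, "tme_sensitivity"))
  report$parameter[order(report$rank)][seq_len(n)]
}

#' Single-parameter bifurcation scan of the day-42 cancer load
#'
#' Sweeps one parameter over a grid (default 201 equally spaced points
#' on `[0, 0.2]`), holding all other parameters at their fitted values,
#' integrates from each mouse's day-0 state and records the dimensional
#' cancer value at `t_eval` days.  All grid values and mice are
#' integrated in a single vectorized fixed-step RK4 sweep.
#'
#' @param param_name one of the 57 parameter names.
#' @param params fitted [tme_params].
#' @param inits named list of non-dimensional day-0 states (one per
#'   mouse), as from [tme_inits()].
#' @param grid scan grid, within `[0, 0.2]` by convention (any
#'   nonnegative grid is accepted).
#' @param t_eval evaluation time in days (default 42, the last
#'   sampling day).
#' @param scales scales tibble used to redimensionalize cancer.
#' @param step RK4 step in days.
#' @return A `tme_bifurcation` tibble: `parameter`, `value`, `mouse`,
#'   `C42` (dimensional cancer at `t_eval`).
#' @export
tme_bifurcation <- function(param_name, params, inits,
                            grid = seq(0, 0.2, length.out = 201),
                            t_eval = 42, scales, step = 0.02) {
  stopifnot(inherits(params, "tme_params"))
  if (!param_name %in% tme_param_names) {
    stop("unknown parameter: ", param_name, call. = FALSE)
  }
  if (any(grid < 0)) stop("grid values must be nonnegative", call. = FALSE)
  sc <- .scales_vec(scales)
  pidx <- match(param_name, tme_param_names)
  n <- length(grid)
  m <- length(inits)
  # K = n * m columns: grid-major within each mouse
  TH <- matrix(params$theta, 57L, n * m)
  TH[pidx, ] <- rep(grid, times = m)
  X0 <- matrix(0, 15L, n * m)
  for (j in seq_len(m)) {
    X0[, (j - 1L) * n + seq_len(n)] <- .check_state(inits[[j]])
  }
  nsteps <- ceiling(t_eval / step)
  h <- t_eval / nsteps
  sol <- .rk4_engine(TH, X0, h, nsteps, params$constants)
  mouse_ids <- if (!is.null(names(inits))) {
    as.integer(gsub("\\D", "", names(inits)))
  } else {
    seq_len(m)
  }
  out <- tibble::tibble(
    parameter = param_name,
    value = rep(grid, times = m),
    mouse = rep(mouse_ids, each = n),
    C42 = as.vector(sol$X[9L, ]) * sc[["C"]]
  )
  attr(out, "t_eval") <- t_eval
  class(out) <- c("tme_bifurcation", class(out))
  out
}
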