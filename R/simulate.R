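#' Integrate the non-dimensional model
#'
#' Solves the 15-variable system with `deSolve::ode()` (lsoda, relative
#' tolerance `1e-8` by default, with the analytic state Jacobian
#' supplied) from a nonnegative non-dimensional initial state.
#'
#' @param params a [tme_params] object.
#' @param init named non-dimensional initial state (15 components).
#' @param horizon final time in days (default 126, i.e. 18 weeks).
#' @param times output time grid; defaults to daily steps on
#'   `[0, horizon]`.
#' @param rtol,atol solver tolerances.
#' @return A `tme_traj` tibble: column `day` plus the 15 variables
#'   (non-dimensional), with attributes `frame`, `method`, `rtol`,
#'   `atol`.
#' @examples
#' p <- tme_params_table3()
#' sc <- tme_scales(pymt_mice())
#' nd <- tme_nondimensionalize(pymt_mice(), sc)
#' tr <- tme_simulate(p, tme_inits(nd)$mouse1, horizon = 42)
#' @export
tme_simulate <- function(params, init, horizon = 126, times = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "tme_params"))
  x0 <- .check_state(init)
  if (is.null(times)) times <- seq(0, horizon, by = 1)
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  th <- params$theta
  cn <- params$constants
  f <- function(t, y, p) list(.rhs_core(y, th, cn))
  jac <- function(t, y, p) {
    names(y) <- tme_state_vars
    unname(tme_jacobian_state(pmax(y, 0), params))
  }
  sol <- deSolve::ode(y = stats::setNames(x0, tme_state_vars), times = times,
                      func = f, parms = NULL, jacfunc = jac, jactype = "fullusr",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed near t = ", max(sol[, "time"]), " days",
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "day"
  out[1, -1] <- as.list(x0)     # first state is the supplied init, exactly
  attr(out, "frame") <- "nondimensional"
  attr(out, "method") <- "lsoda"
  attr(out, "rtol") <- rtol
  attr(out, "atol") <- atol
  class(out) <- c("tme_traj", class(out))
  out
}

#' Rescale a trajectory to dimensional units
#'
#' @param traj a `tme_traj` tibble (non-dimensional).
#' @param scales scales tibble from [tme_scales()].
#' @return The trajectory in dimensional units (`frame` attribute
#'   flipped).
#' @export
tme_traj_redim <- function(traj, scales) {
  stopifnot(identical(attr(traj, "frame", exact = TRUE), "nondimensional"))
  sc <- .scales_vec(scales)
  for (v in tme_state_vars) traj[[v]] <- traj[[v]] * sc[[v]]
  attr(traj, "frame") <- "dimensional"
  traj
}

#' Compare a trajectory to observed data
#'
#' @param traj a `tme_traj` tibble whose grid covers the data days.
#' @param series dataset rows for one mouse (same frame as `traj`).
#' @return A tibble with one row per (day, variable): `prediction`,
#'   `datum`, `residual` (prediction minus datum), plus a per-variable
#'   `rms` column repeated within variable.
#' @export
tme_compare <- function(traj, series) {
  tf <- attr(traj, "frame", exact = TRUE)
  sf <- .data_frame_of(series)
  if (!is.null(tf) && !is.null(sf) && !identical(tf, sf)) {
    stop("trajectory and data are in different frames", call. = FALSE)
  }
  if (any(series$day < min(traj$day)) || any(series$day > max(traj$day))) {
    stop("data days outside the trajectory range", call. = FALSE)
  }
  long_d <- tidyr::pivot_longer(series[, c("day", tme_state_vars)],
                                -"day", names_to = "variable",
                                values_to = "datum")
  pred <- vapply(seq_len(nrow(long_d)), function(i) {
    stats::approx(traj$day, traj[[long_d$variable[i]]],
                  xout = long_d$day[i])$y
  }, 0)
  long_d |>
    dplyr::mutate(prediction = pred,
                  residual = .data$prediction - .data$datum) |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(rms = sqrt(mean(.data$residual^2))) |>
    dplyr::ungroup()
}

# ---- vectorized fixed-step RK4 over many parameter vectors -----------

# TH: 57 x K parameter matrix; X0: 15-vector or 15 x K matrix.
# Returns the 15 x K state at h*nsteps, optionally recording every
# `keep_every` steps (list with days and states array 15 x K x nkeep).
.rk4_engine <- function(TH, X0, h, nsteps, constants, keep_every = 0L) {
  K <- ncol(TH)
  X <- if (is.matrix(X0)) X0 else matrix(X0, 15L, K)
  ms <- .term_mult(constants)
  f <- function(Xc) .rhs_mat(Xc, TH, constants, ms)
  record <- keep_every > 0L
  if (record) {
    kept <- seq(0L, nsteps, by = keep_every)
    states <- array(NA_real_, c(15L, K, length(kept)))
    states[, , 1L] <- X
    ki <- 1L
  }
  for (i in seq_len(nsteps)) {
    k1 <- f(X)
    k2 <- f(X + (h / 2) * k1)
    k3 <- f(X + (h / 2) * k2)
    k4 <- f(X + h * k3)
    X <- X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (record && i %% keep_every == 0L) {
      ki <- ki + 1L
      states[, , ki] <- X
    }
  }
  if (record) list(X = X, days = kept * h, states = states) else list(X = X)
}

#' Perturbation envelopes around a baseline trajectory
#'
#' Integrates the model over a sample of parameter vectors in which
#' each named parameter is independently scaled within
#' `[1 - fraction, 1 + fraction]`, and returns the pointwise min/max
#' band per variable over time.  The unperturbed vector is always
#' included, so the baseline lies inside the band.
#'
#' @param params baseline [tme_params].
#' @param param_names character vector of parameters to perturb.
#' @param fraction perturbation fraction in `[0, 1)`, default 0.20.
#' @param init non-dimensional initial state.
#' @param horizon days, default 126.
#' @param sampling `"lhs"` (Latin hypercube, default, `n` samples) or
#'   `"corners"` (all `2^k` sign corners, `k <= 12`).
#' @param n number of Latin-hypercube samples (default 256).
#' @param seed RNG seed for the Latin hypercube (recorded in the
#'   output attributes).
#' @param step fixed RK4 step in days.
#' @return A `tme_envelope` tibble: `day`, `variable`, `baseline`,
#'   `lower`, `upper` (non-dimensional).
#' @export
tme_envelope <- function(params, param_names, fraction = 0.20, init,
                         horizon = 126, sampling = c("lhs", "corners"),
                         n = 256, seed = 1, step = 0.02) {
  stopifnot(inherits(params, "tme_params"))
  sampling <- match.arg(sampling)
  bad <- setdiff(param_names, tme_param_names)
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  x0 <- .check_state(init)
  k <- length(param_names)
  U <- switch(sampling,
    corners = {
      if (k > 12) stop("corner sampling limited to 12 parameters", call. = FALSE)
      as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    },
    lhs = {
      .with_seed(seed, 2 * lhs::randomLHS(n, k) - 1)
    }
  )
  U <- rbind(matrix(0, 1L, k), U)          # baseline first
  TH <- matrix(params$theta, 57L, nrow(U))
  idx <- match(param_names, tme_param_names)
  for (j in seq_len(k)) {
    TH[idx[j], ] <- params$theta[idx[j]] * (1 + fraction * U[, j])
  }
  keep_every <- max(1L, round(1 / step))
  nsteps <- ceiling(horizon / step)
  sol <- .rk4_engine(TH, x0, step, nsteps, params$constants,
                     keep_every = keep_every)
  days <- sol$days
  res <- purrr::map_dfr(seq_along(tme_state_vars), function(v) {
    M <- sol$states[v, , , drop = TRUE]        # K x ntimes
    tibble::tibble(
      day = days,
      variable = tme_state_vars[v],
      baseline = M[1, ],
      lower = apply(M, 2, min),
      upper = apply(M, 2, max)
    )
  })
  attr(res, "seed") <- seed
  attr(res, "sampling") <- sampling
  attr(res, "fraction") <- fraction
  class(res) <- c("tme_envelope", class(res))
  res
}

# evaluate expr with a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
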