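#' Finite-difference derivative estimates from a time course
#'
#' Estimates d(state)/dt at every sampling day of every mouse: interior
#' days use the central difference
#' \eqn{(x(t_{i+1}) - x(t_{i-1})) / (t_{i+1} - t_{i-1})}; the first and
#' last days use first-order one-sided differences so that every
#' sampled day contributes an estimate.
#'
#' @param data dataset tibble (any frame; rates are in its units per
#'   day).  Each mouse needs at least 3 strictly increasing days.
#' @return A tibble `mouse`, `day`, plus the 15 variable columns
#'   holding rate estimates (units of `data` per day).
#' @export
tme_rates <- function(data) {
  .check_dataset(data)
  data |>
    dplyr::group_by(.data$mouse) |>
    dplyr::group_modify(function(d, key) .rates_one(d)) |>
    dplyr::ungroup()
}

.rates_one <- function(d) {
  d <- dplyr::arrange(d, .data$day)
  t <- d$day
  n <- length(t)
  if (n < 3) stop("need at least 3 time points per mouse", call. = FALSE)
  if (anyDuplicated(t)) stop("duplicate sampling days", call. = FALSE)
  out <- d
  for (v in tme_state_vars) {
    x <- d[[v]]
    r <- numeric(n)
    r[1] <- (x[2] - x[1]) / (t[2] - t[1])
    r[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      r[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
    }
    out[[v]] <- r
  }
  out
}

#' Assemble the linear least-squares system for the rates
#'
#' Rearranges the non-dimensional ODE system, which is linear in the 57
#' parameters, into `A theta = b`: one row per (mouse, day, equation)
#' whose entries are the multiplier of each parameter evaluated at the
#' observed state, with `b` the matching finite-difference derivative
#' estimate.  No parameter appears inside `A`; the fixed constants
#' (carrying capacities and necrotic fraction) do.
#'
#' @param data_nd non-dimensional dataset tibble.
#' @param constants named vector `C0`, `A0`, `alpha_NC`.
#' @param endpoints `"onesided"` (default) keeps the one-sided
#'   derivative rows at the first and last day; `"interior"` restricts
#'   to central-difference rows only.
#' @return A `tme_design` object: list with the design matrix `A`
#'   (rows x 57), response `b`, and `row_index` tibble (`mouse`, `day`,
#'   `equation`).
#' @export
tme_design <- function(data_nd, constants = .tme_default_constants,
                       endpoints = c("onesided", "interior")) {
  .check_dataset(data_nd, frame = "nondimensional")
  endpoints <- match.arg(endpoints)
  rates <- tme_rates(data_nd)
  obs <- dplyr::arrange(data_nd, .data$mouse, .data$day)
  rates <- dplyr::arrange(rates, .data$mouse, .data$day)

  if (endpoints == "interior") {
    keep <- obs |>
      dplyr::group_by(.data$mouse) |>
      dplyr::mutate(row_keep = .data$day > min(.data$day) &
                      .data$day < max(.data$day)) |>
      dplyr::ungroup() |>
      dplyr::pull("row_keep")
    obs <- obs[keep, ]
    rates <- rates[keep, ]
  }

  blocks <- lapply(seq_len(nrow(obs)), function(i) {
    x <- stats::setNames(as.double(obs[i, tme_state_vars]), tme_state_vars)
    .jac_params_core(x, constants)
  })
  A <- do.call(rbind, blocks)
  b <- as.vector(t(as.matrix(rates[, tme_state_vars])))
  row_index <- tibble::tibble(
    mouse = rep(obs$mouse, each = 15L),
    day = rep(obs$day, each = 15L),
    equation = rep(tme_state_vars, times = nrow(obs))
  )
  structure(
    list(A = A, b = b, row_index = row_index, constants = constants,
         endpoints = endpoints),
    class = "tme_design"
  )
}

#' @export
print.tme_design <- function(x, ...) {
  cat("<tme_design> ", nrow(x$A), " rows x ", ncol(x$A), " parameters (",
      x$endpoints, " endpoints)\n", sep = "")
  invisible(x)
}

#' Unconstrained linear least squares
#'
#' Minimizes \eqn{\|A\theta - b\|_2^2} via the SVD pseudoinverse.  When
#' `A` is numerically rank deficient (expected with sparse sampling:
#' 57 unknowns and collinear regressors) the minimum-norm solution is
#' returned and the deficiency is reported, never silently inverted.
#'
#' @param system a `tme_design` object.
#' @param tol relative singular-value cutoff for the numerical rank;
#'   the default `1e-6` is a practical identifiability threshold (the
#'   derivative estimates in `b` carry far more than 1e-6 relative
#'   error, so directions amplified beyond that are meaningless), not
#'   the machine-precision rank.
#' @return List with `theta` (named 57-vector, possibly negative),
#'   `rank`, `rank_deficient`, and `residual_norm`.
#' @export
tme_solve_unconstrained <- function(system, tol = NULL) {
  stopifnot(inherits(system, "tme_design"))
  A <- system$A; b <- system$b
  sv <- svd(A)
  if (is.null(tol)) tol <- 1e-6
  keep <- sv$d > tol * sv$d[1]
  r <- sum(keep)
  theta <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  theta <- as.double(theta)
  if (ncol(A) == 57L) names(theta) <- tme_param_names
  list(theta = theta, rank = r, rank_deficient = r < ncol(A),
       residual_norm = sqrt(sum((A %*% theta - b)^2)))
}

#' Bound-constrained linear least squares
#'
#' Minimizes \eqn{\|A\theta - b\|_2^2} subject to
#' \eqn{\theta_e \ge \theta_{min}} for every component.  The problem is
#' shifted to a nonnegative least-squares problem and solved with the
#' Lawson-Hanson active-set algorithm, followed by a Karush-Kuhn-Tucker
#' (KKT) verification: every component strictly above the bound must
#' have (numerically) zero objective gradient, and components at the
#' bound a nonnegative gradient.  If the active-set solve does not meet
#' the KKT test (possible under heavy rank deficiency) a projected
#' quasi-Newton refinement is run from its solution.
#'
#' @param system a `tme_design` object.
#' @param theta_min scalar lower bound (default `1e-5`).
#' @param kkt_tol tolerance for the KKT verification, relative to
#'   `max(|A^T b|)`.
#' @return List with `theta` (all `>= theta_min`), `residual_norm`,
#'   `active` (logical: components at the bound), `kkt_ok`, and
#'   `kkt_violation`.
#' @export
tme_solve_bounded <- function(system, theta_min = 1e-5, kkt_tol = 1e-8) {
  stopifnot(inherits(system, "tme_design"))
  if (!is.finite(theta_min) || theta_min < 0) {
    stop("theta_min must be finite and nonnegative", call. = FALSE)
  }
  A <- system$A; b <- system$b
  bshift <- b - as.vector(A %*% rep(theta_min, ncol(A)))
  phi <- tryCatch(pracma::lsqnonneg(A, bshift)$x,
                  error = function(e) NULL)
  theta <- if (is.null(phi)) rep(theta_min, ncol(A)) else theta_min + phi

  chk <- .kkt_check(A, b, theta, theta_min, kkt_tol)
  if (!chk$ok) {
    theta <- .bounded_refine(A, b, theta, theta_min)
    chk <- .kkt_check(A, b, theta, theta_min, kkt_tol)
  }
  theta <- pmax(theta, theta_min)
  if (ncol(A) == 57L) names(theta) <- tme_param_names
  list(
    theta = theta,
    residual_norm = sqrt(sum((A %*% theta - b)^2)),
    active = theta <= theta_min * (1 + 1e-9),
    kkt_ok = chk$ok,
    kkt_violation = chk$violation
  )
}

.kkt_check <- function(A, b, theta, theta_min, kkt_tol) {
  g <- as.vector(crossprod(A, A %*% theta - b))
  scale <- max(abs(crossprod(A, b)), 1)
  at_bound <- theta <= theta_min + 1e-12 * max(theta_min, 1)
  v_free <- if (any(!at_bound)) max(abs(g[!at_bound])) else 0
  v_bound <- if (any(at_bound)) max(-pmin(g[at_bound], 0)) else 0
  violation <- max(v_free, v_bound) / scale
  list(ok = violation <= max(kkt_tol, 1e-10), violation = violation)
}

.bounded_refine <- function(A, b, start, theta_min) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  fn <- function(th) 0.5 * sum((A %*% th - b)^2)
  gr <- function(th) as.vector(AtA %*% th - Atb)
  opt <- stats::optim(pmax(start, theta_min), fn, gr, method = "L-BFGS-B",
                      lower = theta_min,
                      control = list(maxit = 5000, factr = 10))
  opt$par
}

#' Fit the interaction-rate parameters to a time-course dataset
#'
#' The full estimation pipeline: non-dimensionalize (if given a
#' dimensional dataset), estimate derivatives by finite differences,
#' assemble the linear system, and solve both the unconstrained
#' (pseudoinverse) and the bound-constrained least-squares problems.
#' All mice are fitted jointly into a single parameter vector; fit a
#' subset by filtering the dataset first.
#'
#' @param data dataset tibble; dimensional data are normalized with
#'   [tme_scales()] computed from the data themselves, non-dimensional
#'   data are used as is.
#' @param theta_min lower bound for the constrained fit.
#' @param endpoints passed to [tme_design()].
#' @param constants fixed model constants.
#' @return A `tme_fit` object with components `params` (a [tme_params]
#'   of the bounded estimates), `theta_unconstrained`, `system`,
#'   `scales`, `rank`, `rank_deficient`, residual norms, `active`, and
#'   `kkt` diagnostics.  Supports [tidy()], [glance()] and `print()`.
#' @examples
#' fit <- tme_fit(pymt_mice())
#' glance(fit)
#' @export
tme_fit <- function(data, theta_min = 1e-5,
                    endpoints = c("onesided", "interior"),
                    constants = .tme_default_constants) {
  endpoints <- match.arg(endpoints)
  frame <- .data_frame_of(data)
  if (is.null(frame) || frame == "dimensional") {
    if (is.null(frame)) attr(data, "frame") <- "dimensional"
    scales <- tme_scales(data)
    data_nd <- tme_nondimensionalize(data, scales)
  } else {
    scales <- NULL
    data_nd <- data
  }
  system <- tme_design(data_nd, constants = constants, endpoints = endpoints)
  unc <- tme_solve_unconstrained(system)
  bnd <- tme_solve_bounded(system, theta_min = theta_min)
  structure(
    list(
      params = tme_params(bnd$theta, constants = constants),
      theta_unconstrained = unc$theta,
      system = system,
      scales = scales,
      data_nd = data_nd,
      theta_min = theta_min,
      rank = unc$rank,
      rank_deficient = unc$rank_deficient,
      residual_norm = bnd$residual_norm,
      residual_norm_unconstrained = unc$residual_norm,
      active = bnd$active,
      kkt_ok = bnd$kkt_ok,
      kkt_violation = bnd$kkt_violation
    ),
    class = "tme_fit"
  )
}

#' @export
print.tme_fit <- function(x, ...) {
  cat("<tme_fit> bound-constrained least squares on",
      nrow(x$system$A), "rows\n")
  cat("  rank(A) =", x$rank, "of", ncol(x$system$A),
      if (x$rank_deficient) "(rank deficient: non-identifiable directions present)" else "",
      "\n")
  cat("  residual |A theta - b|: bounded", format(x$residual_norm, digits = 6),
      "| unconstrained", format(x$residual_norm_unconstrained, digits = 6), "\n")
  cat("  parameters at the bound:", sum(x$active), "of 57\n")
  invisible(x)
}

#' Per-equation residual summary of a fit
#'
#' @param fit a `tme_fit` object.
#' @return A tibble with one row per model equation: residual norm and
#'   root-mean-square over that equation's rows, for the bounded
#'   estimate.
#' @export
tme_fit_report <- function(fit) {
  stopifnot(inherits(fit, "tme_fit"))
  res <- as.vector(fit$system$A %*% fit$params$theta - fit$system$b)
  tibble::tibble(equation = fit$system$row_index$equation, r = res) |>
    dplyr::group_by(.data$equation) |>
    dplyr::summarise(
      norm = sqrt(sum(.data$r^2)),
      rms = sqrt(mean(.data$r^2)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$equation, tme_state_vars))
}
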