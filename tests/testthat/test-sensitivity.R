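test_that("sensitivities vanish at a zero horizon", {
  S <- tme_forward_sensitivities(fx_table3(), fx_inits()$mouse1, horizon = 0)
  expect_equal(max(abs(S)), 0)
  expect_identical(dim(S), c(15L, 57L))
})

test_that("a decoupled decay equation reproduces its closed form", {
  # with only necrotic cells present and no cancer, dN/dt = -delta_N N,
  # so dN/d(delta_N) = -t exp(-delta_N t)
  th <- stats::setNames(rep(0, 57), tme_param_names)
  th[["delta_N"]] <- 0.1
  p <- tme_params(th)
  x0 <- stats::setNames(rep(0, 15), tme_state_vars)
  x0[["N"]] <- 1
  S <- tme_forward_sensitivities(p, x0, horizon = 10, step = 0.01)
  expect_equal(S["N", "delta_N"], -10 * exp(-1), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("forward sensitivities match differenced trajectories", {
  p <- fx_table3()
  x0 <- fx_inits()$mouse1
  S <- tme_forward_sensitivities(p, x0, horizon = 30, step = 0.005)
  set.seed(7)
  for (i in sample(57, 5)) {
    h <- max(p$theta[i] * 1e-4, 1e-9)
    up <- p$theta; up[i] <- up[i] + h
    dn <- p$theta; dn[i] <- dn[i] - h
    tu <- tme_simulate(tme_params(up, p$constants), x0, horizon = 30,
                       times = c(0, 30))
    td <- tme_simulate(tme_params(dn, p$constants), x0, horizon = 30,
                       times = c(0, 30))
    fd <- (as.numeric(tu[2, tme_state_vars]) -
             as.numeric(td[2, tme_state_vars])) / (2 * h)
    expect_equal(unname(S[, i]), fd, tolerance = 1e-3)
  }
})

test_that("forward Euler converges at first order to the oracle", {
  p <- fx_table3()
  x0 <- fx_inits()$mouse2
  i <- match("delta_C", tme_param_names)
  h <- p$theta[i] * 1e-4
  up <- p$theta; up[i] <- up[i] + h
  dn <- p$theta; dn[i] <- dn[i] - h
  tu <- tme_simulate(tme_params(up, p$constants), x0, 20, times = c(0, 20))
  td <- tme_simulate(tme_params(dn, p$constants), x0, 20, times = c(0, 20))
  oracle <- (tu$C[2] - td$C[2]) / (2 * h)
  err <- vapply(c(0.2, 0.1, 0.05), function(st) {
    S <- tme_forward_sensitivities(p, x0, horizon = 20, step = st)
    abs(S["C", "delta_C"] - oracle)
  }, 0)
  expect_true(all(diff(err) < 0))
  ratio <- err[1] / err[3]
  expect_gt(ratio, 2.5)    # halving the step twice: ~4x for order 1
})

test_that("output projections apply the documented weights", {
  set.seed(9)
  S <- matrix(rnorm(15 * 57), 15, 57,
              dimnames = list(tme_state_vars, tme_param_names))
  expect_equal(unname(tme_output_functional(S, "cancer")),
               unname(S["C", ]))
  unit_scales <- tibble::tibble(variable = tme_state_vars, scale = 1)
  tot <- tme_output_functional(S, "total_cells", scales = unit_scales)
  expect_equal(unname(tot),
               unname(colSums(S) - S["T_N", ] - 0.8 * S["M_N", ] -
                        S["H", ] - S["IL12", ] - S["IL10", ] - S["IL6", ]))
  expect_error(tme_output_functional(S, "total_cells"), "scales")
})

test_that("the sparse box rule matches dense quadrature on a 2-parameter toy", {
  # closed-form sensitivity surface of dx/dt = lambda - delta x:
  # s(delta, lambda) = dx(t)/d(delta) at t = 25, x(0) = 2
  t <- 25; x0 <- 2
  s_fun <- function(delta, lambda) {
    -lambda / delta^2 + (lambda / delta^2) * exp(-delta * t) -
      (x0 - lambda / delta) * t * exp(-delta * t)
  }
  theta0 <- c(0.08, 0.4)
  nodes <- pymtme:::.sparse_box_nodes(theta0, 0.10)
  sparse <- sum(nodes$w * s_fun(nodes$TH[1, ], nodes$TH[2, ]))
  # dense tensor Gauss-Legendre oracle
  g1 <- pracma::gaussLegendre(12, theta0[1] * 0.9, theta0[1] * 1.1)
  g2 <- pracma::gaussLegendre(12, theta0[2] * 0.9, theta0[2] * 1.1)
  vals <- outer(g1$x, g2$x, s_fun)
  dense <- as.vector(g1$w %*% vals %*% g2$w) /
    (0.2 * theta0[1] * 0.2 * theta0[2])
  expect_equal(sparse, dense, tolerance = 0.01)
  # weights integrate constants exactly
  expect_equal(sum(nodes$w), 1)
})

test_that("a degenerate neighborhood reproduces the raw sensitivity", {
  p <- fx_table3()
  x0 <- fx_inits()$mouse1
  rep0 <- tme_sensitivity(p, x0, horizon = 10, fraction = 1e-9,
                          scaling = "none")
  S <- tme_forward_sensitivities(p, x0, horizon = 10)
  expect_equal(rep0$s_hat, unname(S["C", ]), tolerance = 1e-6)
  expect_equal(rep0$s_raw, rep0$s_hat, tolerance = 1e-6)
})

test_that("the compiled sweep matches the reference R engine", {
  p <- fx_table3()
  x0 <- pymtme:::.check_state(fx_inits()$mouse2)
  TH <- matrix(p$theta, 57, 4)
  TH[42, 2] <- p$theta[42] * 1.1
  TH[15, 3] <- p$theta[15] * 0.9
  a <- pymtme:::.euler_sens_engine(TH, x0, 0.05, 400, p$constants)
  b <- pymtme:::.euler_sens_engine_r(TH, x0, 0.05, 400, p$constants)
  expect_equal(a$X, b$X, tolerance = 1e-12)
  expect_equal(a$S, b$S, tolerance = 1e-12)
})

test_that("ranking is by absolute value with stable ties", {
  p <- fx_table3()
  x0 <- fx_inits()$mouse1
  rep1 <- tme_sensitivity(p, x0, horizon = 5, step = 0.05)
  expect_identical(sort(rep1$rank), 1:57)
  expect_identical(rep1$parameter[order(rep1$rank)][1],
                   rep1$parameter[which.max(abs(rep1$s_hat))])
  g <- glance(rep1)
  expect_identical(g$n_nodes, 115L)
  expect_identical(g$output, "cancer")
})

test_that("bifurcation scans pass through the baseline and are monotone", {
  p <- fx_table3()
  inits <- fx_inits()
  sc <- fx_scales()
  # grid containing the fitted value: curve hits the baseline C(42)
  fitted_dc <- p$theta[["delta_C"]]
  grid <- sort(unique(c(seq(0, 0.2, length.out = 21), fitted_dc)))
  curve <- tme_bifurcation("delta_C", p, inits, grid = grid, scales = sc)
  base <- tme_simulate(p, inits$mouse1, horizon = 42, times = c(0, 42))
  base_c42 <- base$C[2] * fx_scale_of("C")
  at_fit <- dplyr::filter(curve, .data$mouse == 1,
                          abs(.data$value - fitted_dc) < 1e-12)
  expect_equal(at_fit$C42, base_c42, tolerance = 1e-5)
  # increasing the death rate cannot increase day-42 cancer
  for (m in 1:3) {
    cm <- dplyr::filter(curve, .data$mouse == m)
    expect_true(all(diff(cm$C42) <= 1e-8 * max(cm$C42)))
  }
  expect_error(tme_bifurcation("not_a_rate", p, inits, scales = sc),
               "unknown")
})

test_that("adipocyte-growth scans agree with re-integration oracles", {
  p <- fx_table3()
  inits <- fx_inits()[1]
  sc <- fx_scales()
  grid <- seq(0, 0.2, length.out = 21)
  curve <- tme_bifurcation("lambda_CA", p, inits, grid = grid, scales = sc)
  expect_true(all(diff(curve$C42) >= -1e-8 * max(curve$C42)))
  set.seed(13)
  for (v in sample(grid, 5)) {
    pg <- p; pg$theta[["lambda_CA"]] <- v
    tr <- tme_simulate(pg, fx_inits()$mouse1, horizon = 42,
                       times = c(0, 42), rtol = 1e-10, atol = 1e-12)
    expect_equal(curve$C42[abs(curve$value - v) < 1e-12],
                 tr$C[2] * fx_scale_of("C"), tolerance = 1e-5)
  }
})

test_that("raw sensitivity signs agree with local bifurcation slopes", {
  p <- fx_table3()
  x0 <- fx_inits()$mouse1
  sc <- fx_scales()
  S <- tme_forward_sensitivities(p, x0, horizon = 42, step = 0.02)
  for (nm in c("delta_C", "lambda_C", "lambda_CA", "delta_A")) {
    v0 <- p$theta[[nm]]
    h <- v0 * 0.05
    curve <- tme_bifurcation(nm, p, fx_inits()[1],
                             grid = c(v0 - h, v0 + h), scales = sc)
    slope <- diff(curve$C42) / (2 * h)
    expect_equal(sign(slope), sign(S["C", nm]), ignore_attr = TRUE)
  }
})
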