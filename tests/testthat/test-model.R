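test_that("only source terms survive at the zero state", {
  p <- random_params(1)
  r <- tme_rhs(stats::setNames(rep(0, 15), tme_state_vars), p)
  expect_equal(r[["T_N"]], p$theta[["A_TN"]])
  expect_equal(r[["D_N"]], p$theta[["A_DN"]])
  expect_equal(r[["M_N"]], p$theta[["A_M"]])
  expect_equal(unname(r[setdiff(tme_state_vars, c("T_N", "D_N", "M_N"))]),
               rep(0, 12))
})

test_that("adipocyte derivative matches hand arithmetic", {
  # lambda_A = delta_A = 0.0024, A0 = 2, A = 1:
  # 0.0024 * 1 * (1 - 1/2) - 0.0024 * 1 = -0.0012
  p <- fx_table3()
  x <- stats::setNames(rep(0, 15), tme_state_vars)
  x[["A"]] <- 1
  expect_equal(tme_rhs(x, p)[["A"]], -0.0012, tolerance = 1e-12)
})

test_that("rhs agrees with a derivative of the integrated trajectory", {
  # second-order one-sided difference of a high-accuracy integration
  p <- fx_table3()
  x0 <- fx_inits()$mouse1
  h <- 1e-3
  tr <- tme_simulate(p, x0, horizon = 2 * h, times = c(0, h, 2 * h),
                     rtol = 1e-12, atol = 1e-14)
  fd <- (-3 * as.numeric(tr[1, tme_state_vars]) +
           4 * as.numeric(tr[2, tme_state_vars]) -
           as.numeric(tr[3, tme_state_vars])) / (2 * h)
  r <- tme_rhs(x0, p)
  expect_equal(unname(r), fd, tolerance = 1e-6)
})

test_that("invalid states and parameters are rejected", {
  p <- random_params(2)
  x <- random_state(3)
  xn <- x; xn[["C"]] <- -0.1
  expect_error(tme_rhs(xn, p), "nonnegative")
  expect_error(tme_rhs(stats::setNames(rep(NA_real_, 15), tme_state_vars), p),
               "finite")
  th <- p$theta; th[["delta_C"]] <- NaN
  expect_error(tme_params(th), "finite")
  expect_error(tme_params(p$theta[-1]), "57")
})

test_that("state Jacobian has the analytic special-case entries", {
  p <- random_params(4)
  x <- random_state(5)
  J <- tme_jacobian_state(x, p)
  # the Treg equation is linear in T_r with coefficient -delta_Tr
  expect_equal(J["T_r", "T_r"], -p$theta[["delta_Tr"]], ignore_attr = TRUE)
  # cancer diagonal at C = C0 with no cytotoxic kill: the logistic
  # bracket contributes minus the whole growth rate
  xc <- x; xc[["C"]] <- p$constants[["C0"]]; xc[["T_c"]] <- 0
  Jc <- tme_jacobian_state(xc, p)
  growth <- p$theta[["lambda_C"]] +
    p$theta[["lambda_CIL6"]] * xc[["IL6"]] +
    p$theta[["lambda_CA"]] * xc[["A"]]
  expect_equal(Jc["C", "C"], -growth - p$theta[["delta_C"]],
               ignore_attr = TRUE)
})

test_that("both Jacobians match finite differences at random draws", {
  h <- 1e-6
  for (s in 1:20) {
    p <- random_params(100 + s)
    x <- random_state(200 + s, max = 2)
    r0 <- tme_rhs(x, p)
    scale <- max(abs(r0), 1)

    Jx <- tme_jacobian_state(x, p)
    Jnum <- vapply(1:15, function(j) {
      up <- x; up[j] <- up[j] + h
      dn <- x; dn[j] <- max(dn[j] - h, 0)
      unname((tme_rhs(up, p) - tme_rhs(dn, p)) / (up[j] - dn[j]))
    }, numeric(15))
    expect_lt(max(abs(Jx - Jnum)) / scale, 1e-6)

    Jp <- tme_jacobian_params(x, p)
    th <- p$theta
    Jpnum <- vapply(1:57, function(j) {
      hp <- max(th[j] * 1e-6, 1e-9)
      up <- th; up[j] <- up[j] + hp
      dn <- th; dn[j] <- max(dn[j] - hp, 0)
      unname((tme_rhs(x, tme_params(up, p$constants)) -
                tme_rhs(x, tme_params(dn, p$constants))) / (up[j] - dn[j]))
    }, numeric(15))
    expect_lt(max(abs(Jp - Jpnum)) / scale, 1e-6)
  }
})

test_that("parameter Jacobian columns follow the equation structure", {
  p <- random_params(6)
  x <- random_state(7)
  J <- tme_jacobian_params(x, p)
  # naive T-cell source: unit entry on the T_N row only
  expect_equal(unname(J[, "A_TN"]),
               as.numeric(tme_state_vars == "T_N"))
  # adipocyte-promoted cancer growth: A * (1 - C/C0) * C on the C row
  expected <- x[["A"]] * (1 - x[["C"]] / p$constants[["C0"]]) * x[["C"]]
  expect_equal(J["C", "lambda_CA"], expected, ignore_attr = TRUE)
  expect_equal(sum(J[, "lambda_CA"] != 0), 1L)
})

test_that("activation fluxes are conserved between naive and activated pools", {
  for (s in 1:10) {
    p <- random_params(300 + s)
    x <- random_state(400 + s, max = 2)
    r <- tme_rhs(x, p)
    th <- p$theta
    # T cells: the four equations must sum to sources minus sinks only
    lhs <- r[["T_N"]] + r[["T_h"]] + r[["T_c"]] + r[["T_r"]]
    rhs <- th[["A_TN"]] - th[["delta_TN"]] * x[["T_N"]] -
      (th[["delta_ThTr"]] * x[["T_r"]] + th[["delta_ThIL10"]] * x[["IL10"]] +
         th[["delta_Th"]]) * x[["T_h"]] -
      (th[["delta_TcTr"]] * x[["T_r"]] + th[["delta_TcIL10"]] * x[["IL10"]] +
         th[["delta_Tc"]]) * x[["T_c"]] -
      th[["delta_Tr"]] * x[["T_r"]]
    expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
    # dendritic cells
    lhs <- r[["D_N"]] + r[["D"]]
    rhs <- th[["A_DN"]] - th[["delta_DN"]] * x[["D_N"]] -
      (th[["delta_DC"]] * x[["C"]] + th[["delta_D"]]) * x[["D"]]
    expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
    # macrophages
    lhs <- r[["M_N"]] + r[["M"]]
    rhs <- th[["A_M"]] - th[["delta_MN"]] * x[["M_N"]] -
      th[["delta_M"]] * x[["M"]]
    expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
    # necrosis production is alpha_NC times the cancer death flux
    death <- (th[["delta_CTc"]] * x[["T_c"]] + th[["delta_C"]]) * x[["C"]]
    expect_equal(r[["N"]] + th[["delta_N"]] * x[["N"]],
                 p$constants[["alpha_NC"]] * death,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("adipocyte closed form is exact", {
  # fixed point: starting at the effective capacity stays there
  K <- 2 * (1 - 0.001 / 0.003)
  expect_equal(adipocyte_logistic(K, 0.003, 0.001, 2, c(0, 50, 500)),
               rep(K, 3))
  # against a high-accuracy integration of the one-variable ODE
  one_var <- function(A0i, la, da, t) {
    f <- function(t, y, p) list(la * y * (1 - y / 2) - da * y)
    deSolve::ode(c(A = A0i), c(0, t), f, NULL,
                 rtol = 1e-12, atol = 1e-14)[-1, "A"]
  }
  for (t in c(10, 100, 1000)) {
    expect_equal(adipocyte_logistic(1, 0.003, 0.001, 2, t),
                 unname(one_var(1, 0.003, 0.001, t)), tolerance = 1e-8)
  }
  # degenerate lambda = delta: quadratic decay A0i/(1 + la*A0i*t/2)
  expect_equal(adipocyte_logistic(1, 0.0024, 0.0024, 2, 1000),
               1 / (1 + 0.0024 * 1000 / 2), tolerance = 1e-10)
  expect_equal(adipocyte_logistic(1, 0.0024, 0.0024, 2, 1000),
               unname(one_var(1, 0.0024, 0.0024, 1000)), tolerance = 1e-8)
  expect_error(adipocyte_logistic(-1, 0.003, 0.001, 2, 1), "nonnegative")
})

test_that("total cell count uses the published weights", {
  x0 <- stats::setNames(rep(0, 15), tme_state_vars)
  expect_equal(total_cells(x0), 0)
  # hand sum of the mouse-1 day-0 row
  row1 <- fx_mice()[1, ]
  expect_equal(total_cells(row1), 123.0067, tolerance = 1e-6)
  # linearity
  x <- random_state(8)
  expect_equal(total_cells(2 * x), 2 * total_cells(x))
  # naive T cells excluded, naive macrophages at 20%
  w <- total_cell_weights()
  expect_equal(w[["T_N"]], 0)
  expect_equal(w[["M_N"]], 0.2)
})
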