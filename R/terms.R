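# Internal structural encoding of the interaction network.
#
# Every equation of the non-dimensional system is linear in the 57 rate
# parameters: each rate multiplies a product of at most two state factors
# (or a logistic factor for the two carrying-capacity terms).  One term
# table therefore drives the right-hand side, both Jacobians, the
# design-matrix assembly for least squares, and the vectorized
# integration engines.  Factor codes 1..15 are the state variables in
# canonical order, 16 is the cancer logistic factor C(1 - C/C0), 17 the
# adipocyte logistic factor A(1 - A/A0), and 18 the constant 1.

tme_state_vars <- c(
  "T_N", "T_h", "T_c", "T_r", "D_N", "D", "M_N", "M",
  "C", "N", "A", "H", "IL12", "IL10", "IL6"
)

tme_param_names <- c(
  "lambda_ThH", "lambda_ThD", "lambda_ThIL12", "lambda_TcD", "lambda_TcIL12",
  "lambda_TrD", "lambda_DC", "lambda_DH", "lambda_MIL10", "lambda_MIL12",
  "lambda_MTh", "lambda_C", "lambda_CIL6", "lambda_CA", "lambda_A",
  "lambda_HD", "lambda_HN", "lambda_HM", "lambda_HTc", "lambda_HC",
  "lambda_IL12M", "lambda_IL12D", "lambda_IL12Th", "lambda_IL12Tc",
  "lambda_IL10M", "lambda_IL10D", "lambda_IL10Tr", "lambda_IL10Th",
  "lambda_IL10Tc", "lambda_IL10C", "lambda_IL6A", "lambda_IL6M",
  "lambda_IL6D", "delta_Th", "delta_Tc", "delta_Tr", "delta_TN",
  "delta_DN", "delta_D", "delta_MN", "delta_M", "delta_C", "delta_A",
  "delta_N", "delta_H", "delta_IL12", "delta_IL10", "delta_IL6",
  "delta_ThTr", "delta_ThIL10", "delta_TcTr", "delta_TcIL10", "delta_DC",
  "delta_CTc", "A_TN", "A_DN", "A_M"
)

.tme_default_constants <- c(C0 = 2, A0 = 2, alpha_NC = 1.5)

# one row per additive term: parameter, target equation, sign, two factor
# codes (".one" = constant factor), and whether the alpha_NC necrotic
# fraction multiplies the term
.tme_terms <- local({
  rows <- list()
  trm <- function(p, e, s, f1 = ".one", f2 = ".one", nc = FALSE) {
    rows[[length(rows) + 1L]] <<- list(p = p, e = e, s = s, f1 = f1, f2 = f2, nc = nc)
  }

  # helper T cells: activation by HMGB1, dendritic cells and IL-12 acting
  # on the naive pool; inhibition by Tregs and IL-10; natural decay
  trm("lambda_ThH",    "T_h", +1, "H",    "T_N")
  trm("lambda_ThD",    "T_h", +1, "D",    "T_N")
  trm("lambda_ThIL12", "T_h", +1, "IL12", "T_N")
  trm("delta_ThTr",    "T_h", -1, "T_r",  "T_h")
  trm("delta_ThIL10",  "T_h", -1, "IL10", "T_h")
  trm("delta_Th",      "T_h", -1, "T_h")

  # cytotoxic cells (CD8 + NK)
  trm("lambda_TcD",    "T_c", +1, "D",    "T_N")
  trm("lambda_TcIL12", "T_c", +1, "IL12", "T_N")
  trm("delta_TcTr",    "T_c", -1, "T_r",  "T_c")
  trm("delta_TcIL10",  "T_c", -1, "IL10", "T_c")
  trm("delta_Tc",      "T_c", -1, "T_c")

  # regulatory T cells
  trm("lambda_TrD", "T_r", +1, "D", "T_N")
  trm("delta_Tr",   "T_r", -1, "T_r")

  # naive T cells: constant source minus every activation flux above
  trm("A_TN",          "T_N", +1)
  trm("lambda_ThH",    "T_N", -1, "H",    "T_N")
  trm("lambda_ThD",    "T_N", -1, "D",    "T_N")
  trm("lambda_ThIL12", "T_N", -1, "IL12", "T_N")
  trm("lambda_TcD",    "T_N", -1, "D",    "T_N")
  trm("lambda_TcIL12", "T_N", -1, "IL12", "T_N")
  trm("lambda_TrD",    "T_N", -1, "D",    "T_N")
  trm("delta_TN",      "T_N", -1, "T_N")

  # dendritic cells, naive and activated; cancer promotes both the
  # activation and the death of the activated pool
  trm("A_DN",      "D_N", +1)
  trm("lambda_DC", "D_N", -1, "C", "D_N")
  trm("lambda_DH", "D_N", -1, "H", "D_N")
  trm("delta_DN",  "D_N", -1, "D_N")
  trm("lambda_DC", "D",   +1, "C", "D_N")
  trm("lambda_DH", "D",   +1, "H", "D_N")
  trm("delta_DC",  "D",   -1, "C", "D")
  trm("delta_D",   "D",   -1, "D")

  # macrophages: single activated pool fed by IL-10, IL-12 and Th cells
  trm("A_M",         "M_N", +1)
  trm("lambda_MIL10", "M_N", -1, "IL10", "M_N")
  trm("lambda_MIL12", "M_N", -1, "IL12", "M_N")
  trm("lambda_MTh",   "M_N", -1, "T_h",  "M_N")
  trm("delta_MN",     "M_N", -1, "M_N")
  trm("lambda_MIL10", "M", +1, "IL10", "M_N")
  trm("lambda_MIL12", "M", +1, "IL12", "M_N")
  trm("lambda_MTh",   "M", +1, "T_h",  "M_N")
  trm("delta_M",      "M", -1, "M")

  # cancer: logistic growth promoted by IL-6 and adipocytes, killed by
  # cytotoxic cells and everything lumped into delta_C
  trm("lambda_C",    "C", +1, ".LC")
  trm("lambda_CIL6", "C", +1, "IL6", ".LC")
  trm("lambda_CA",   "C", +1, "A",   ".LC")
  trm("delta_CTc",   "C", -1, "T_c", "C")
  trm("delta_C",     "C", -1, "C")

  # necrotic cells: fraction alpha_NC of the cancer death flux
  trm("delta_CTc", "N", +1, "T_c", "C", nc = TRUE)
  trm("delta_C",   "N", +1, "C",   nc = TRUE)
  trm("delta_N",   "N", -1, "N")

  # adipocytes: independent logistic
  trm("lambda_A", "A", +1, ".LA")
  trm("delta_A",  "A", -1, "A")

  # HMGB1
  trm("lambda_HD",  "H", +1, "D")
  trm("lambda_HN",  "H", +1, "N")
  trm("lambda_HM",  "H", +1, "M")
  trm("lambda_HTc", "H", +1, "T_c")
  trm("lambda_HC",  "H", +1, "C")
  trm("delta_H",    "H", -1, "H")

  # IL-12
  trm("lambda_IL12M",  "IL12", +1, "M")
  trm("lambda_IL12D",  "IL12", +1, "D")
  trm("lambda_IL12Th", "IL12", +1, "T_h")
  trm("lambda_IL12Tc", "IL12", +1, "T_c")
  trm("delta_IL12",    "IL12", -1, "IL12")

  # IL-10
  trm("lambda_IL10M",  "IL10", +1, "M")
  trm("lambda_IL10D",  "IL10", +1, "D")
  trm("lambda_IL10Tr", "IL10", +1, "T_r")
  trm("lambda_IL10Th", "IL10", +1, "T_h")
  trm("lambda_IL10Tc", "IL10", +1, "T_c")
  trm("lambda_IL10C",  "IL10", +1, "C")
  trm("delta_IL10",    "IL10", -1, "IL10")

  # IL-6
  trm("lambda_IL6A", "IL6", +1, "A")
  trm("lambda_IL6M", "IL6", +1, "M")
  trm("lambda_IL6D", "IL6", +1, "D")
  trm("delta_IL6",   "IL6", -1, "IL6")

  codes <- c(tme_state_vars, ".LC", ".LA", ".one")
  p  <- match(vapply(rows, `[[`, "", "p"), tme_param_names)
  e  <- match(vapply(rows, `[[`, "", "e"), tme_state_vars)
  f1 <- match(vapply(rows, `[[`, "", "f1"), codes)
  f2 <- match(vapply(rows, `[[`, "", "f2"), codes)
  s  <- vapply(rows, `[[`, 0, "s")
  nc <- vapply(rows, `[[`, FALSE, "nc")
  stopifnot(!anyNA(p), !anyNA(e), !anyNA(f1), !anyNA(f2))

  nterm <- length(p)
  E <- matrix(0, 15L, nterm)
  E[cbind(e, seq_len(nterm))] <- 1

  # which state variable each factor code depends on (0 = constant)
  var_of <- c(seq_len(15L), 9L, 11L, 0L)

  # state-Jacobian contributions: one per (term, factor slot) whose
  # factor depends on a state variable (product rule)
  ce <- integer(0); cv <- integer(0); cp <- integer(0)
  cs <- numeric(0); cnc <- logical(0); cfd <- integer(0); cfo <- integer(0)
  for (slot in 1:2) {
    fd <- if (slot == 1L) f1 else f2
    fo <- if (slot == 1L) f2 else f1
    keep <- var_of[fd] > 0L
    ce <- c(ce, e[keep]); cv <- c(cv, var_of[fd[keep]])
    cp <- c(cp, p[keep]); cs <- c(cs, s[keep]); cnc <- c(cnc, nc[keep])
    cfd <- c(cfd, fd[keep]); cfo <- c(cfo, fo[keep])
  }

  list(
    n = nterm, p = p, e = e, s = s, nc = nc, f1 = f1, f2 = f2,
    E = E, var_of = var_of,
    ep_flat = (p - 1L) * 15L + e,
    c_e = ce, c_v = cv, c_p = cp, c_s = cs, c_nc = cnc,
    c_fd = cfd, c_fo = cfo
  )
})

# signed term multipliers, folding in alpha_NC where it applies
.term_mult <- function(constants) {
  .tme_terms$s * ifelse(.tme_terms$nc, constants[["alpha_NC"]], 1)
}

.contrib_mult <- function(constants) {
  .tme_terms$c_s * ifelse(.tme_terms$c_nc, constants[["alpha_NC"]], 1)
}

# factor values (18-vector) and their derivatives w.r.t. the factor's
# underlying state variable, for a single state
.factor_values <- function(x, constants) {
  c(x,
    x[9L] * (1 - x[9L] / constants[["C0"]]),
    x[11L] * (1 - x[11L] / constants[["A0"]]),
    1)
}

.factor_derivs <- function(x, constants) {
  c(rep(1, 15L),
    1 - 2 * x[9L] / constants[["C0"]],
    1 - 2 * x[11L] / constants[["A0"]],
    0)
}

# matrix versions: X is 15 x K (one column per node)
.factor_values_mat <- function(X, constants) {
  rbind(X,
        X[9L, ] * (1 - X[9L, ] / constants[["C0"]]),
        X[11L, ] * (1 - X[11L, ] / constants[["A0"]]),
        1)
}

.factor_derivs_mat <- function(X, constants) {
  K <- ncol(X)
  rbind(matrix(1, 15L, K),
        1 - 2 * X[9L, ] / constants[["C0"]],
        1 - 2 * X[11L, ] / constants[["A0"]],
        0)
}

# fast unvalidated right-hand side for a single state
.rhs_core <- function(x, theta, constants) {
  tt <- .tme_terms
  xv <- .factor_values(x, constants)
  drop(tt$E %*% (.term_mult(constants) * xv[tt$f1] * xv[tt$f2] * theta[tt$p]))
}

# right-hand side for K states / K parameter vectors at once
.rhs_mat <- function(X, TH, constants, ms = .term_mult(constants)) {
  tt <- .tme_terms
  XV <- .factor_values_mat(X, constants)
  .tme_terms$E %*% (ms * XV[tt$f1, , drop = FALSE] * XV[tt$f2, , drop = FALSE] *
                      TH[tt$p, , drop = FALSE])
}
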