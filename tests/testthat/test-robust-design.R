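# LMI machinery: scalar oracles, monotonicity, decomposition, HJI.

test_that("scalar feasibility matches the closed-form quadratic analysis", {
  # a = -2: p^2 - 3.75 p + 1 < 0 has real roots -> feasible, and any
  # certificate lies inside the root interval
  pr <- assemble_lmi_blocks(scalar_model(-2, 0.5), scalar_C, H = 1,
                            R = matrix(1), rho = 1)
  r <- solve_feasibility(pr)
  expect_equal(r$status, "feasible")
  roots <- sort(Re(polyroot(c(1, -3.75, 1))))
  expect_gt(r$P[1, 1], roots[1] - 1e-4)
  expect_lt(r$P[1, 1], roots[2] + 1e-4)
  # independent margin verification is part of the result
  expect_lte(max(r$margins), -pr$eps / 2)

  # a = -1: negative discriminant -> infeasible
  pr2 <- assemble_lmi_blocks(scalar_model(-1, 0.5), scalar_C, H = 1,
                             R = matrix(1), rho = 1)
  expect_equal(solve_feasibility(pr2)$status, "infeasible")
})

test_that("bisection recovers the closed-form optimal filtering level", {
  cases <- list(c(a = -2, aw = 0.5, h = 1, r = 1),
                c(a = -3, aw = 0.2, h = 2, r = 1),
                c(a = -1.5, aw = 0.8, h = 0.7, r = 2))
  for (cs in cases) {
    want <- scalar_rho0(cs["a"], cs["aw"], cs["h"], cs["r"])
    got <- min_rho(scalar_model(cs["a"], cs["aw"]), scalar_C,
                   H = cs[["h"]], R = matrix(cs[["r"]]),
                   bracket = c(0, 4 * want), tol = 1e-4)
    expect_equal(unname(got$rho0), unname(want), tolerance = 1e-3)
    # certificate at rho0 re-verifies
    expect_true(all(got$margins <= 0))
  }
})

test_that("feasibility is monotone in rho and brackets shrink to tolerance", {
  for (s in 1:5) {
    rules <- random_rules(d = 3, L = 2, seed = s)
    model <- list(rules = rules)
    C1 <- matrix(0, 1, 1)
    mr <- min_rho(model, C1, H = rep(1, 3), bracket = c(0, 32),
                  tol = 1e-3, effort = "fast")
    expect_lt(mr$trace$rho[which.max(mr$trace$rho)] -
                min(mr$trace$rho[mr$trace$status == "feasible"]), 32)
    # feasible at rho0 implies feasible at every larger rho tested
    for (mult in c(1.5, 4)) {
      pr <- assemble_lmi_blocks(model, C1, H = rep(1, 3),
                                rho = mult * mr$rho0)
      expect_equal(solve_feasibility(pr, effort = "fast")$status,
                   "feasible")
    }
    # bracket width at termination is below the tolerance
    feas_rho <- mr$trace$rho[mr$trace$status == "feasible"]
    infe_rho <- mr$trace$rho[mr$trace$status != "feasible"]
    if (length(infe_rho))
      expect_lt(min(feas_rho) - max(infe_rho[infe_rho < min(feas_rho)]),
                1e-3 + 1e-12)
  }
})

test_that("unsynchronizable models are reported as such", {
  # an unstable local block admits no Lyapunov certificate at any rho
  bad <- list(rules = list(list(A = matrix(0.5), B = matrix(0),
                                A_W = matrix(0), B_W = matrix(0))))
  expect_error(min_rho(bad, scalar_C, H = 1, bracket = c(0, 8),
                       effort = "fast"),
               "unsynchronizable under this model")
})

test_that("N = 1 single-rule problem reduces to the Lyapunov inequality", {
  set.seed(2)
  A <- matrix(rnorm(9, sd = 0.4), 3) - 1.2 * diag(3)
  model <- list(rules = list(list(A = A, B = matrix(0, 3, 3),
                                  A_W = matrix(0, 3, 3),
                                  B_W = matrix(0, 3, 3))))
  # H = 0, R ~ 0: feasibility is exactly "A is Hurwitz"
  pr <- assemble_lmi_blocks(model, scalar_C, H = rep(0, 3),
                            R = 1e-9 * diag(3), rho = 1)
  expect_equal(solve_feasibility(pr)$status, "feasible")
  model$rules[[1]]$A <- A + 3 * diag(3)  # push eigenvalues across zero
  pr2 <- assemble_lmi_blocks(model, scalar_C, H = rep(0, 3),
                             R = 1e-9 * diag(3), rho = 1)
  expect_true(solve_feasibility(pr2)$status != "feasible")
})

test_that("robustness decomposition is equivalent to the LMI via Schur complement", {
  set.seed(31)
  agree <- 0
  for (t in 1:20) {
    d <- 3
    A <- matrix(rnorm(d * d, sd = 0.4), d) - runif(1, 0.8, 2.5) * diag(d)
    rules <- list(list(A = A, B = matrix(0, d, d),
                       A_W = matrix(rnorm(d * d, sd = 0.15), d),
                       B_W = matrix(0, d, d)))
    rho <- runif(1, 0.5, 6)
    prob <- assemble_lmi_blocks(list(rules = rules), scalar_C,
                                H = rep(1, d), rho = rho)
    P <- crossprod(matrix(rnorm(d * d), d)) + 0.1 * diag(d)
    dec <- robustness_decomposition(P, prob)[[1]]
    # intrinsic term is PSD for any P > 0
    expect_gte(min(eigen((dec$intrinsic + t(dec$intrinsic)) / 2,
                         only.values = TRUE)$values), -1e-12)
    block_margin <- max(quorumsync:::lmi_margins(prob$constraints, P))
    if (abs(dec$margin) > 1e-9 && abs(block_margin) > 1e-9) {
      expect_equal(dec$margin >= 0, block_margin <= 0)
      agree <- agree + 1
    }
  }
  expect_gte(agree, 15)  # non-degenerate instances actually exercised
  expect_error(robustness_decomposition(matrix(c(1, 2, 0, 1), 2), NULL),
               "symmetric")
})

test_that("decomposition reduces to the Lyapunov bound without noise terms", {
  set.seed(7)
  d <- 3
  A <- matrix(rnorm(d * d, sd = 0.3), d) - 2 * diag(d)
  rules <- list(list(A = A, B = matrix(0, d, d), A_W = matrix(0, d, d),
                     B_W = matrix(0, d, d)))
  prob <- assemble_lmi_blocks(list(rules = rules), scalar_C,
                              H = rep(0, d), rho = 1)
  P <- lyap_P <- quorumsync:::lyapunov_solve(A, 2 * diag(d))
  dec <- robustness_decomposition(P, prob)[[1]]
  expect_equal(unname(dec$intrinsic), matrix(0, d, d))
  expect_equal(unname(dec$extrinsic), diag(d), tolerance = 1e-12)
  # sync - extrinsic = -(PA + A'P) - R = 2I - I = I by construction
  expect_equal(dec$margin, 1, tolerance = 1e-8)
})

test_that("HJI residual: origin, linear identity, block vs full P", {
  p <- fig_params(); d <- fig_amplitudes()
  C <- build_coupling_matrix(4, p$eta_s, p$Q_e, 0.3)
  lc <- quorumsync:::find_limit_cycle(p)
  s <- lc$states[25, ]
  x <- matrix(s, 7, 4)
  expect_equal(hji_residual(rep(0, 28), x, s, diag(7), p, d, C,
                            rho = 0.56), 0)

  # linear instances satisfy the algebraic identity with the Schur form
  set.seed(42)
  m <- 3; N <- 4
  A <- matrix(rnorm(m * m), m) - 4 * diag(m)
  B <- matrix(0, m, m); B[m, m] <- 1
  AW <- 0.2 * matrix(rnorm(m * m), m); BW <- 0.05 * B
  Cs <- matrix(1 / N, N, N) - diag(N)  # symmetric zero-row-sum
  P7 <- crossprod(matrix(rnorm(m * m), m)) + diag(m)
  h <- c(1, 0.5, 2); rho <- 0.8
  Phi <- kronecker(diag(N), A) + kronecker(Cs, B)
  Psi <- kronecker(diag(N), AW) + kronecker(Cs, BW)
  Pf <- kronecker(diag(N), P7)
  Hf <- kronecker(diag(N), matrix(h, m, 1))
  M <- diag(m * N) + Pf %*% Phi + t(Phi) %*% Pf +
    t(Psi) %*% Pf %*% Psi + Pf %*% Hf %*% t(Hf) %*% Pf / rho^2
  for (rep in 1:10) {
    e <- rnorm(m * N)
    r_blk <- hji_residual(e, NULL, NULL, P7, NULL, NULL, Cs, H = h,
                          rho = rho,
                          linear = list(A = A, B = B, A_W = AW, B_W = BW))
    expect_lt(abs(r_blk - sum(e * (M %*% e))), 1e-8)
    r_full <- hji_residual(e, NULL, NULL, Pf, NULL, NULL, Cs, H = h,
                           rho = rho,
                           linear = list(A = A, B = B, A_W = AW,
                                         B_W = BW))
    expect_lt(abs(r_full - r_blk), 1e-8)
  }
})

test_that("reduced certificates verify against the full stacked LMIs", {
  rules <- random_rules(d = 3, L = 2, seed = 4)
  # give the rules a nontrivial coupling block
  for (k in 1:2) rules[[k]]$B <- diag(c(0, 0, 1))
  model <- list(rules = rules)
  N <- 3
  C <- matrix(0.4 / N, N, N); diag(C) <- -0.4 * (1 - 1 / N)
  red <- assemble_lmi_blocks(model, C, H = rep(1, 3), rho = 3,
                             deflate = FALSE)
  r <- solve_feasibility(red)
  expect_equal(r$status, "feasible")
  full <- assemble_lmi_blocks(model, C, H = rep(1, 3), rho = 3,
                              reduce = FALSE)
  margins_full <- quorumsync:::lmi_margins(full$constraints, r$P_full)
  expect_lte(max(margins_full), -red$eps / 2)
})

test_that("design_Q reports a clean diagnostic on a hopeless grid", {
  p <- fig_params(); d <- fig_amplitudes()
  fm <- build_fuzzy_model(p, d, 2)
  res <- design_Q(p, d, rho = 0.01, Q_grid = 0, model = fm,
                  n_cells = 4)
  expect_false(isTRUE(res$feasible))
  expect_true(is.na(res$Q))
  expect_match(res$message, "no feasible Q")
  expect_equal(nrow(res$trace), 1)
  expect_true(all(res$trace$margin > 0))
  expect_error(design_Q(p, d, rho = 0.5, Q_grid = c(1, 0.5)),
               "ascending")
})

test_that("kinetic-parameter co-design: validation and singleton grids", {
  p <- fig_params(); d <- fig_amplitudes()
  C <- build_coupling_matrix(4, p$eta_s, p$Q_e, 0.66)
  expect_error(tune_kinetic_parameters(p, d, data.frame(), C),
               "nonempty")
  expect_error(tune_kinetic_parameters(p, d,
                 data.frame(nope = 1), C), "unknown parameter")
  expect_error(tune_kinetic_parameters(p, d,
                 data.frame(alpha_a = 1, alpha_b = 1, alpha_c = 1,
                            beta_A = 1), C), "at most 3")
  # singleton grid at the nominal point: the trace contains exactly that
  # candidate; with the analytic-Jacobian rules the model is reported
  # unsynchronizable (see the methods vignette), hence rho0 is NA
  res <- tune_kinetic_parameters(p, d, data.frame(gamma_p = p$gamma_p),
                                 C, bracket = c(0, 16), tol = 0.05,
                                 L = 2)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$trace$gamma_p, p$gamma_p)
  if (is.na(res$trace$rho0)) {
    expect_match(res$message, "unsynchronizable")
  } else {
    expect_equal(res$best, 1)
    expect_gt(res$rho0, 0)
  }
})
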