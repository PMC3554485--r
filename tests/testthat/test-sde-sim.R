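# Euler-Maruyama integration, synchronization errors, energy ratios.

test_that("Euler-Maruyama step: identity, exponential decay, first-order bias", {
  # no drift, no noise: identity
  x <- runif(7)
  expect_equal(euler_maruyama_step(x, rep(0, 7), rep(0, 7), rep(0, 7),
                                   0.1, 0, 0), x)
  # scalar decay dx = -x dt
  x1 <- euler_maruyama_step(1, -1, 0, 0, 0.1, 0, 0)
  expect_equal(x1, 0.9)
  decay_run <- function(dt, nstep) {
    x <- 1
    for (k in seq_len(nstep)) x <- euler_maruyama_step(x, -x, 0, 0, dt, 0, 0)
    x
  }
  e1 <- abs(decay_run(0.1, 100) - exp(-10))
  e2 <- abs(decay_run(0.05, 200) - exp(-10))
  expect_lt(e1, 2e-4)              # Euler bias is small but nonzero
  expect_gt(e1 / e2, 1.5)          # and halves with the step (1st order)
  expect_lt(e1 / e2, 2.5)
})

test_that("pure-noise step reproduces the Wiener variance law", {
  set.seed(21)
  nrep <- 2000L
  x <- matrix(0, 1, nrep)
  dt <- 0.05; nstep <- 100L
  for (k in seq_len(nstep))
    x <- euler_maruyama_step(x, matrix(0, 1, nrep), matrix(1, 1, nrep),
                             0, dt, rnorm(nrep, 0, sqrt(dt)),
                             rep(0, nrep))
  tf <- dt * nstep
  sv <- var(as.vector(x))
  se <- tf * sqrt(2 / (nrep - 1))
  expect_lt(abs(sv - tf), 3 * se)
})

test_that("network simulation is deterministic and respects the manifold", {
  p <- fig_params(); d <- fig_amplitudes(); nz <- extrinsic_noise_spec()
  C <- build_coupling_matrix(3, p$eta_s, p$Q_e, 0)
  cfg <- tiny_sim(seed = 7)
  e1 <- simulate_network(p, d, C, nz, cfg)
  e2 <- simulate_network(p, d, C, nz, cfg)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$v_record, e2$v_record)

  # zero noise + identical initial conditions: cells stay bit-identical
  x0 <- matrix(rep(c(1, 2, 3, 1, 2, 3, 0.5), 3), 7, 3)
  cfg0 <- tiny_sim(init = x0)
  ens <- simulate_network(p, zero_fluctuations(), C,
                          extrinsic_noise_spec(sigma_v = 0), cfg0)
  err <- compute_errors(ens)
  expect_equal(max(abs(err$e)), 0)
})

test_that("single isolated cell matches the deterministic ODE solution", {
  p <- fig_params()
  x0 <- matrix(c(1, 2, 3, 1, 2, 3, 0.5), 7, 1)
  cfg <- sim_config(dt = 0.002, t_final = 2, seed = 1, n_cells = 1,
                    init = x0)
  ens <- simulate_network(p, zero_fluctuations(),
                          build_coupling_matrix(1, p$eta_s, p$Q_e, 0),
                          extrinsic_noise_spec(sigma_v = 0), cfg)
  ref <- integrate_cell_ode(x0[, 1], p, dt = 0.002, n_steps = 1000)
  end_em <- ens$states[1, 1001, 1, ]
  expect_lt(max(abs(end_em - ref$x)) / max(abs(ref$x)), 5e-3)
  # Richardson check on the ODE reference itself: RK4 is step-insensitive
  ref2 <- integrate_cell_ode(x0[, 1], p, dt = 0.001, n_steps = 2000)
  expect_lt(max(abs(ref2$x - ref$x)), 1e-8)
})

test_that("error computation: centering, two-cell case, nominal reference", {
  p <- fig_params()
  C <- build_coupling_matrix(2, p$eta_s, p$Q_e, 0)
  x0 <- cbind(rep(1, 7), rep(3, 7))
  cfg <- sim_config(dt = 0.01, t_final = 0.05, seed = 1, n_cells = 2,
                    init = x0)
  ens <- simulate_network(p, zero_fluctuations(), C,
                          extrinsic_noise_spec(sigma_v = 0), cfg)
  err <- compute_errors(ens)
  expect_equal(unname(err$e[1, 1, 1, ]), rep(-1, 7))
  expect_equal(unname(err$e[1, 1, 2, ]), rep(1, 7))
  sums <- apply(err$e, c(1, 2, 4), sum)
  expect_lt(max(abs(sums)), 1e-12)

  nom <- compute_errors(ens, "nominal")
  expect_equal(nom$reference, "nominal")
  # nominal reference starts at the mean initial condition
  expect_equal(unname(nom$s[1, 1, ]), rep(2, 7))
})

test_that("filtering ratio arithmetic on constant errors and noise", {
  fx <- constant_err_ens(2, 1)
  fr <- filtering_ratio(fx$err, fx$ens)
  # e' e per time = 2 cells * 7 species * 4; v'v = 2 cells * 1
  expect_equal(fr$ratio, (2 * 7 * 4) / 2, tolerance = 1e-12)

  fx0 <- constant_err_ens(0, 1)
  expect_equal(filtering_ratio(fx0$err, fx0$ens)$ratio, 0)

  fxz <- constant_err_ens(1, 0)
  expect_error(filtering_ratio(fxz$err, fxz$ens), "undefined")

  # block R and full R agree; a scaled R scales the ratio
  R7 <- diag(7) * 0.5
  fr2 <- filtering_ratio(fx$err, fx$ens, R = R7)
  expect_equal(fr2$ratio, fr$ratio / 2, tolerance = 1e-12)
  Rfull <- diag(14 * 0 + 2 * 7) * 0.5
  fr3 <- filtering_ratio(fx$err, fx$ens, R = Rfull)
  expect_equal(fr3$ratio, fr2$ratio, tolerance = 1e-12)

  # initial-condition variant subtracts e(0)' P e(0), floored at zero
  fr4 <- filtering_ratio(fx$err, fx$ens, include_initial = TRUE,
                         P = diag(14))
  expect_equal(fr4$numerator,
               max(0, fr$numerator - sum(rep(2, 14)^2)))
})

test_that("left Riemann sums are stable under time-grid thinning", {
  p <- fig_params(); d <- fig_amplitudes(); nz <- extrinsic_noise_spec()
  C <- build_coupling_matrix(5, p$eta_s, p$Q_e, 0.66)
  cfg <- sim_config(dt = 0.005, t_final = 20, seed = 3, n_cells = 5)
  ens <- simulate_network(p, d, C, nz, cfg)
  err <- compute_errors(ens)
  full <- filtering_ratio(err, ens)$ratio
  # same data, every 2nd step: the integral estimator moves < 2%
  K <- dim(err$e)[2] - 1L
  sel <- seq(1, K, by = 2)
  num2 <- sum(err$e[1, sel, , ]^2) * 2 * cfg$dt
  den2 <- sum(ens$v_record[1, sel, ]^2) * 2 * cfg$dt
  expect_lt(abs(num2 / den2 - full) / full, 0.02)
})

test_that("Monte-Carlo estimator: determinism, pooling, jackknife fields", {
  p <- fig_params(); d <- fig_amplitudes(); nz <- extrinsic_noise_spec()
  C <- build_coupling_matrix(3, p$eta_s, p$Q_e, 0.66)
  cfg <- tiny_sim(seed = 11, Q = 0.66)
  m1 <- monte_carlo_filtering(p, d, C, nz, cfg, n_runs = 3)
  m2 <- monte_carlo_filtering(p, d, C, nz, cfg, n_runs = 3)
  expect_identical(m1$ratio, m2$ratio)
  expect_equal(m1$ratio,
               sum(m1$per_run$numerator) / sum(m1$per_run$denominator))
  expect_equal(m1$sqrt_ratio, sqrt(m1$ratio))
  expect_true(is.finite(m1$se) && m1$se >= 0)
  expect_error(monte_carlo_filtering(p, d, C, nz, cfg, n_runs = 1),
               ">= 2")
})

test_that("ratio estimator is consistent with the analytic H-infinity norm", {
  # two decoupled scalar cells dx_i = a x_i dt + v_i dt; population-mean
  # errors have transfer 1/(s - a) from the centered disturbance, so the
  # L2 gain is 1/|a|. The white-noise energy ratio cannot exceed it.
  a <- -2; sigv <- 0.05; dt <- 0.01; K <- 4000L
  nruns <- 8L
  nums <- dens <- numeric(nruns)
  for (r in seq_len(nruns)) {
    set.seed(100 + r)
    x <- matrix(0, 1, 2)
    num <- den <- 0
    for (k in seq_len(K)) {
      v <- rnorm(2, 0, sigv)
      e <- x - mean(x)
      num <- num + sum(e^2) * dt
      den <- den + sum(v^2) * dt
      x <- euler_maruyama_step(x, a * x, matrix(0, 1, 2), 1, dt,
                               c(0, 0), v)
    }
    nums[r] <- num; dens[r] <- den
  }
  ratio <- sum(nums) / sum(dens)
  loo <- (sum(nums) - nums) / (sum(dens) - dens)
  se_sqrt <- sqrt((nruns - 1) / nruns * sum((sqrt(loo) -
                                               mean(sqrt(loo)))^2))
  expect_lte(sqrt(ratio), 1 / abs(a) + 3 * se_sqrt)
})

test_that("extrinsic-only response scales linearly in sigma_v", {
  p <- fig_params()
  lc <- quorumsync:::find_limit_cycle(p)
  x0 <- matrix(lc$states[1, ], 7, 4)
  C <- build_coupling_matrix(4, p$eta_s, p$Q_e, 0.66)
  cfg <- sim_config(dt = 0.01, t_final = 10, seed = 5, n_cells = 4,
                    init = x0, Q = 0.66)
  r1 <- monte_carlo_filtering(p, zero_fluctuations(), C,
                              extrinsic_noise_spec(sigma_v = 0.02),
                              cfg, n_runs = 4)
  r2 <- monte_carlo_filtering(p, zero_fluctuations(), C,
                              extrinsic_noise_spec(sigma_v = 0.04),
                              cfg, n_runs = 4)
  expect_lt(abs(r1$ratio - r2$ratio), 3 * (r1$se + r2$se) + 0.05 * r1$ratio)
})

test_that("blow-up is reported with the failure time", {
  p <- repressilator_params(alpha_a = 1e6, gamma_m = 0.001)
  C <- build_coupling_matrix(2, p$eta_s, p$Q_e, 0)
  cfg <- sim_config(dt = 50, t_final = 2000, seed = 1, n_cells = 2,
                    clip_negative = FALSE)
  expect_error(simulate_network(p, zero_fluctuations(), C,
                                extrinsic_noise_spec(sigma_v = 0), cfg),
               "blow-up at t")
})

test_that("trajectory CSV export is tidy", {
  p <- fig_params()
  C <- build_coupling_matrix(2, p$eta_s, p$Q_e, 0)
  ens <- simulate_network(p, zero_fluctuations(), C,
                          extrinsic_noise_spec(sigma_v = 0),
                          tiny_sim(n_cells = 2, t_final = 0.2))
  f <- tempfile(fileext = ".csv")
  write_trajectories(ens, f, every = 5)
  df <- read.csv(f)
  expect_named(df, c("run", "time", "cell", "species", "value"))
  expect_true(all(df$species %in% c("x_a", "x_b", "x_c", "x_A", "x_B",
                                    "x_C", "x_S")))
})
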