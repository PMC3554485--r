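# Shared fixtures and independent oracles used across the suite.

fig_params <- function() repressilator_params()
fig_amplitudes <- function() fluctuation_amplitudes()

# small, fast simulation setup used by non-acceptance tests
tiny_sim <- function(n_cells = 3L, t_final = 2, dt = 0.01, seed = 1L,
                     Q = 0, ...) {
  sim_config(dt = dt, t_final = t_final, seed = seed, n_cells = n_cells,
             Q = Q, ...)
}

# central finite-difference Jacobian (independent of the analytic path)
fd_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    hj <- if (is.null(h)) 1e-6 * max(1, abs(x[j])) else h
    xp <- x; xm <- x
    xp[j] <- xp[j] + hj; xm[j] <- max(0, xm[j] - hj)
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  J
}

# closed-form optimal filtering level of the 1-D instance
# (Schur complement of the scalar block: (h^2/rho^2) p^2 + (2a + aw^2) p + r)
scalar_rho0 <- function(a, aw, h, r) 2 * h * sqrt(r) / abs(2 * a + aw^2)

scalar_model <- function(a, aw) {
  list(rules = list(list(A = matrix(a), B = matrix(0),
                         A_W = matrix(aw), B_W = matrix(0))))
}
scalar_C <- matrix(0, 1, 1)

# random multi-rule linear models with comfortably stable local blocks
random_rules <- function(d, L, seed, stability = 2) {
  set.seed(seed)
  lapply(seq_len(L), function(k) {
    A <- matrix(rnorm(d * d, sd = 0.3), d) - stability * diag(d)
    list(A = A, B = matrix(0, d, d),
         A_W = matrix(rnorm(d * d, sd = 0.1), d),
         B_W = matrix(0, d, d))
  })
}

# dense Kronecker assembly of the stacked error drift (oracle for the
# fuzzy interpolation with a single rule)
dense_kron_drift <- function(e, rule, C) {
  N <- nrow(C)
  m <- nrow(rule$A)
  (kronecker(diag(N), rule$A) + kronecker(unclass(C), rule$B)) %*% e
}

# literal diffusive quorum-coupling term of the model equations:
# -eta (Qe + Q) (x_Si - mean_j x_Sj) on the autoinducer component only
literal_coupling_term <- function(XS, eta, Qe, Q = 0) {
  -eta * (Qe + Q) * (XS - mean(XS))
}

# minimal error/ensemble pair with prescribed constant error and noise
# records (for exercising filtering_ratio arithmetic in isolation)
constant_err_ens <- function(e_value, v_value, K = 50L, N = 2L, dt = 0.1) {
  e <- array(e_value, c(1, K + 1, N, 7))
  vrec <- array(v_value, c(1, K, N))
  err <- structure(list(e = e, s = NULL, reference = "population-mean",
                        time = seq(0, by = dt, length.out = K + 1)),
                   class = "error_trajectory")
  ens <- list(v_record = vrec, config = list(dt = dt))
  list(err = err, ens = ens)
}
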