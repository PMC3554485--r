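# Euler-Maruyama integration of the coupled network SDE, synchronization
# errors, and the empirical H-infinity noise-filtering ratio.

#' Simulation configuration
#'
#' @param dt integration step (default 0.005)
#' @param t_final horizon (default 100, the energy-integral horizon of the
#'   worked example)
#' @param seed integer RNG seed; fully determines initial conditions and
#'   both noise sources
#' @param n_cells population size N
#' @param init either a `7 x n_cells` matrix of initial states, or a list
#'   `list(kind = "uniform", lower, upper)` for per-cell uniform draws
#'   (default `U[0, 5]` per species: the example's uncertain initial state)
#' @param Q external control gain entering the coupling matrix
#' @param clip_negative clip states at 0 after each step (concentrations)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 0.005, t_final = 100, seed = 1L, n_cells = 10L,
                       init = list(kind = "uniform", lower = 0, upper = 5),
                       Q = 0, clip_negative = TRUE) {
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  check_scalar(t_final, "t_final", lower = dt)
  if (!is.numeric(n_cells) || n_cells < 1 || n_cells != round(n_cells))
    qs_stop("'n_cells' must be a positive integer")
  if (is.matrix(init)) {
    if (nrow(init) != .qs_nspecies || ncol(init) != n_cells)
      qs_stop("explicit 'init' must be a 7 x n_cells matrix")
  } else if (!is.list(init) || !identical(init$kind, "uniform")) {
    qs_stop("'init' must be a 7 x n_cells matrix or list(kind = 'uniform', lower, upper)")
  }
  structure(list(dt = dt, t_final = t_final, seed = as.integer(seed),
                 n_cells = as.integer(n_cells), init = init, Q = Q,
                 clip_negative = isTRUE(clip_negative)),
            class = "sim_config")
}

#' One Euler-Maruyama step
#'
#' `x + (drift + extrinsic * v) * dt + intrinsic * dW`, optionally clipped
#' at zero. Operates on vectors or on `7 x N` matrices columnwise (then
#' `dW` and `v` are length-N and `extrinsic` a length-7 column pattern).
#'
#' @param state current state (vector or `7 x N` matrix)
#' @param drift drift evaluated at `state` (same shape)
#' @param intrinsic intrinsic-noise coefficient (same shape as `state`)
#' @param extrinsic extrinsic noise-coupling column (length 7)
#' @param dt step size (> 0)
#' @param dW Wiener increment(s), one per cell
#' @param v extrinsic noise value(s), one per cell
#' @param clip_negative clip the result at 0
#' @return next state, same shape as `state`
#' @export
euler_maruyama_step <- function(state, drift, intrinsic, extrinsic, dt, dW,
                                v, clip_negative = FALSE) {
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  hv <- if (is.matrix(state)) outer(extrinsic, v) else extrinsic * v
  nxt <- state + (drift + hv) * dt +
    intrinsic * (if (is.matrix(state)) rep(dW, each = nrow(state)) else dW)
  if (any(!is.finite(nxt)))
    qs_stop("non-finite state in Euler-Maruyama step")
  if (clip_negative) nxt[nxt < 0] <- 0
  nxt
}

#' Simulate the coupled stochastic network
#'
#' Integrates the Ito SDE of N coupled oscillators by Euler-Maruyama.
#' Each cell carries one independent Wiener path (intrinsic
#' parameter-fluctuation noise, state-dependent coefficient) and one
#' independent extrinsic noise path, realized as per-step Gaussian draws
#' `N(0, sigma_v^2)` held constant over each step (band-limited white
#' noise, so the disturbance energy integral is finite). Identical seeds
#' give bit-identical output.
#'
#' @param params [repressilator_params()]
#' @param amplitudes [fluctuation_amplitudes()]
#' @param coupling a [build_coupling_matrix()] result (its `Q` should match
#'   `config$Q`; the matrix is what is used)
#' @param noise [extrinsic_noise_spec()]
#' @param config [sim_config()]
#' @return an object of class `trajectory_ensemble`: list with `time`
#'   (length K+1), `states` (array `[run = 1, K+1, cell, species]`),
#'   `v_record` (array `[1, K, cell]`), `config`, `seed`
#' @export
simulate_network <- function(params, amplitudes, coupling, noise, config) {
  N <- config$n_cells
  if (nrow(coupling) != N)
    qs_stop("coupling matrix dimension (", nrow(coupling),
            ") does not match n_cells (", N, ")")
  dt <- config$dt
  K <- round(config$t_final / dt)
  set.seed(config$seed)

  X <- if (is.matrix(config$init)) {
    matrix(as.numeric(config$init), .qs_nspecies, N)
  } else {
    matrix(runif(.qs_nspecies * N, config$init$lower, config$init$upper),
           .qs_nspecies, N)
  }
  if (config$clip_negative) X[X < 0] <- 0

  intrinsic_on <- any(unlist(amplitudes) > 0)
  ratio_eta <- amplitudes$d_eta_s / params$eta_s
  h <- noise$h_cell
  sigv <- noise$sigma_v
  Cm <- unclass(coupling)

  states <- array(NA_real_, c(1L, K + 1L, N, .qs_nspecies))
  vrec <- array(NA_real_, c(1L, K, N))
  states[1L, 1L, , ] <- t(X)
  sqdt <- sqrt(dt)

  for (k in seq_len(K)) {
    v <- rnorm(N, 0, sigv)
    dW <- rnorm(N, 0, sqdt)
    Fm <- drift_matrix(X, params)
    Fm[7, ] <- Fm[7, ] + as.vector(Cm %*% X[7, ])
    if (intrinsic_on) {
      S <- intrinsic_noise_matrix(X, amplitudes, params)
      S[7, ] <- S[7, ] + ratio_eta * as.vector(Cm %*% X[7, ])
      X <- X + (Fm + outer(h, v)) * dt + S * rep(dW, each = .qs_nspecies)
    } else {
      X <- X + (Fm + outer(h, v)) * dt
    }
    if (config$clip_negative) X[X < 0] <- 0
    if (any(!is.finite(X)) || max(abs(X)) > 1e8)
      qs_stop(sprintf("integration blow-up at t = %.4f (step %d)",
                      k * dt, k))
    states[1L, k + 1L, , ] <- t(X)
    vrec[1L, k, ] <- v
  }

  structure(list(time = seq(0, by = dt, length.out = K + 1L),
                 states = states, v_record = vrec, config = config,
                 params = params, amplitudes = amplitudes, noise = noise,
                 coupling = coupling, seed = config$seed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<trajectory_ensemble> %d run(s), %d time points, %d cells, %d species\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Synchronization errors of an ensemble
#'
#' Deviation of every cell from a synchronization reference. The default
#' reference is the population mean (errors then sum to zero exactly over
#' cells at every time); the alternative is the noise-free nominal
#' trajectory integrated from the mean initial condition.
#'
#' @param ens a [simulate_network()] result
#' @param reference `"population-mean"` or `"nominal"`
#' @param params required for `reference = "nominal"` (defaults to the
#'   parameters stored in the ensemble)
#' @return object of class `error_trajectory`: list with `e` (array like
#'   `states`), `s` (reference, `[run, time, species]`), `reference`
#' @export
compute_errors <- function(ens, reference = c("population-mean", "nominal"),
                           params = NULL) {
  reference <- match.arg(reference)
  st <- ens$states
  dims <- dim(st)
  e <- st
  s <- array(NA_real_, c(dims[1], dims[2], dims[4]))
  for (r in seq_len(dims[1])) {
    if (reference == "population-mean") {
      # mean over cells at each (time, species)
      sbar <- apply(st[r, , , , drop = FALSE], c(2, 4), mean)
      s[r, , ] <- sbar
      for (i in seq_len(dims[3])) e[r, , i, ] <- st[r, , i, ] - sbar
    } else {
      p <- if (is.null(params)) ens$params else params
      x0 <- colMeans(st[r, 1, , ])
      x0[x0 < 0] <- 0
      ref <- integrate_cell_ode(x0, p, dt = ens$config$dt,
                                n_steps = dims[2] - 1L)$states
      s[r, , ] <- ref
      for (i in seq_len(dims[3])) e[r, , i, ] <- st[r, , i, ] - ref
    }
  }
  structure(list(e = e, s = s, reference = reference, time = ens$time),
            class = "error_trajectory")
}

#' Empirical noise-filtering energy ratio
#'
#' The ratio of synchronization-error energy to extrinsic-disturbance
#' energy, `[E int e' R e dt] / [E int v' v dt]`, with expectations taken
#' as ensemble means and integrals as left Riemann sums. Optionally the
#' initial-condition energy `E[e(0)' P e(0)]` is subtracted from the
#' numerator (floored at zero), which is the initial-condition variant of
#' the filtering bound with quadratic storage `V(e) = e' P e`.
#'
#' @param err a [compute_errors()] result
#' @param ens the matching [simulate_network()] result (for the noise
#'   record)
#' @param R error weighting: `NULL` (identity), a `7 x 7` per-cell block,
#'   or a full `7N x 7N` symmetric positive semidefinite matrix
#' @param include_initial subtract the `P`-weighted initial error energy
#' @param P certificate matrix for `include_initial` (`7N x 7N` or `7 x 7`
#'   per-cell block)
#' @return list with `ratio`, `numerator`, `denominator`
#' @export
filtering_ratio <- function(err, ens, R = NULL, include_initial = FALSE,
                            P = NULL) {
  dims <- dim(err$e)
  nrun <- dims[1]; K <- dims[2] - 1L; N <- dims[3]; m <- dims[4]
  dt <- ens$config$dt
  num <- den <- 0
  e0E <- 0
  for (r in seq_len(nrun)) {
    # stack errors: rows = time, cols = (cell-major) 7N
    E <- matrix(aperm(err$e[r, seq_len(K), , , drop = FALSE],
                      c(2, 4, 3, 1)), K, N * m)
    num <- num + sum(quad_rows(E, R, N, m)) * dt
    den <- den + sum(ens$v_record[r, , ]^2) * dt
    if (include_initial) {
      # cell-major stacking, species fastest within cell
      e0 <- as.vector(aperm(err$e[r, 1, , , drop = FALSE], c(4, 3, 1, 2)))
      e0E <- e0E + quad_vec(e0, P, N, m)
    }
  }
  num <- num / nrun; den <- den / nrun
  if (den <= 0)
    qs_stop("zero disturbance energy (sigma_v = 0?): the filtering ratio ",
            "is undefined; use deterministic synchronization diagnostics")
  if (include_initial) num <- max(0, num - e0E / nrun)
  list(ratio = num / den, numerator = num, denominator = den)
}

# rowwise quadratic form e' R e for stacked rows; R NULL = identity,
# 7 x 7 = per-cell block, full = dense. Columns are ordered with species
# fastest within cell (cell-major stacking).
quad_rows <- function(E, R, N, m) {
  if (is.null(R)) return(rowSums(E * E))
  if (all(dim(R) == c(m, m))) {
    out <- 0
    for (i in seq_len(N)) {
      Ei <- E[, (i - 1L) * m + seq_len(m), drop = FALSE]
      out <- out + rowSums((Ei %*% R) * Ei)
    }
    return(out)
  }
  if (all(dim(R) == c(N * m, N * m))) return(rowSums((E %*% R) * E))
  qs_stop("'R' must be NULL, 7 x 7, or 7N x 7N")
}

quad_vec <- function(e, P, N, m) {
  if (is.null(P)) return(sum(e * e))
  if (all(dim(P) == c(m, m))) {
    s <- 0
    for (i in seq_len(N)) {
      ei <- e[(i - 1L) * m + seq_len(m)]
      s <- s + sum(ei * (P %*% ei))
    }
    return(s)
  }
  if (all(dim(P) == c(N * m, N * m))) return(sum(e * (P %*% e)))
  qs_stop("'P' must be NULL, 7 x 7, or 7N x 7N")
}

#' Time-averaged mean-square synchronization error
#'
#' `(1/N) sum_i |e_i(t)|^2` averaged over a time window and over runs;
#' the standard scalar summary used to compare synchronized and
#' desynchronized regimes.
#'
#' @param err a [compute_errors()] result
#' @param window time window `c(from, to)`
#' @return scalar
#' @export
sync_error_ms <- function(err, window = c(50, 100)) {
  sel <- which(err$time >= window[1] & err$time <= window[2])
  if (!length(sel)) qs_stop("empty averaging window")
  Esub <- err$e[, sel, , , drop = FALSE]
  sum(Esub^2) / (dim(Esub)[1] * length(sel) * dim(Esub)[3])
}

#' Monte-Carlo estimate of the filtering ratio
#'
#' Repeats [simulate_network()] with per-run derived seeds
#' (`base seed + run index`), pools error and disturbance energies across
#' runs before dividing (a ratio of expectations, not an expectation of
#' ratios), and reports a jackknife standard error.
#'
#' @inheritParams simulate_network
#' @param n_runs number of Monte-Carlo runs (>= 2)
#' @param R,include_initial,P passed to [filtering_ratio()]
#' @param reference passed to [compute_errors()]
#' @return object of class `mc_filtering`: list with `ratio`, `sqrt_ratio`,
#'   `se` (jackknife SE of the ratio), `se_sqrt`, `n_runs`, `seed`,
#'   `per_run` (data frame of per-run energies)
#' @export
monte_carlo_filtering <- function(params, amplitudes, coupling, noise,
                                  config, n_runs = 100L, R = NULL,
                                  reference = "population-mean",
                                  include_initial = FALSE, P = NULL) {
  if (n_runs < 2) qs_stop("'n_runs' must be >= 2")
  nums <- dens <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + r
    ens <- tryCatch(
      simulate_network(params, amplitudes, coupling, noise, cfg),
      error = function(e) qs_stop("run ", r, ": ", conditionMessage(e)))
    err <- compute_errors(ens, reference)
    fr <- filtering_ratio(err, ens, R = R,
                          include_initial = include_initial, P = P)
    nums[r] <- fr$numerator
    dens[r] <- fr$denominator
  }
  ratio <- sum(nums) / sum(dens)
  # leave-one-out jackknife on the pooled ratio
  loo <- (sum(nums) - nums) / (sum(dens) - dens)
  se <- sqrt((n_runs - 1) / n_runs * sum((loo - mean(loo))^2))
  loo_s <- sqrt(loo)
  se_sqrt <- sqrt((n_runs - 1) / n_runs * sum((loo_s - mean(loo_s))^2))
  structure(list(ratio = ratio, sqrt_ratio = sqrt(ratio), se = se,
                 se_sqrt = se_sqrt, n_runs = n_runs, seed = config$seed,
                 per_run = data.frame(run = seq_len(n_runs), numerator = nums,
                                      denominator = dens)),
            class = "mc_filtering")
}

#' @export
print.mc_filtering <- function(x, ...) {
  cat(sprintf("<mc_filtering> %d runs: ratio = %.4g (sqrt = %.4g, jackknife SE of ratio = %.2g)\n",
              x$n_runs, x$ratio, x$sqrt_ratio, x$se))
  invisible(x)
}

#' Export an ensemble as tidy CSV
#' @param ens a [simulate_network()] result
#' @param path output path
#' @param every keep every `every`-th time point (thinning)
#' @return `path`, invisibly
#' @export
write_trajectories <- function(ens, path, every = 10L) {
  d <- dim(ens$states)
  keep <- seq(1L, d[2], by = every)
  grid <- expand.grid(time_idx = keep, cell = seq_len(d[3]),
                      species = seq_len(d[4]))
  df <- data.frame(run = 1L, time = ens$time[grid$time_idx],
                   cell = grid$cell, species = .qs_species[grid$species],
                   value = ens$states[cbind(1L, grid$time_idx, grid$cell,
                                            grid$species)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
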