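# Coupled stochastic repressilator network: drift, coupling decomposition,
# intrinsic-noise fields and their analytic Jacobians.
#
# State ordering per cell is fixed as (x_a, x_b, x_c, x_A, x_B, x_C, x_S):
# mRNAs of tetR/cI/lacI, proteins TetR/CI/LacI, intracellular autoinducer.

#' Nominal single-cell drift
#'
#' Deterministic rate vector f(x) of one isolated oscillator, excluding the
#' quorum-sensing diffusive exchange (which is carried by the coupling
#' matrix): Hill-repressed transcription of the three mRNAs, saturating
#' autoinducer activation of lacI, linear translation, degradation, and
#' autoinducer synthesis.
#'
#' @param x cell state, length-7 nonnegative numeric
#' @param p a [repressilator_params()] object
#' @return numeric length-7 rate vector
#' @export
drift_single_cell <- function(x, p) {
  x <- validate_cell_state(x)
  c(-p$gamma_m * x[[1]] + p$alpha_a / (p$mu + x[[6]]^p$n),
    -p$gamma_m * x[[2]] + p$alpha_b / (p$mu + x[[4]]^p$n),
    -p$gamma_m * x[[3]] + p$alpha_c / (p$mu + x[[5]]^p$n) +
      p$alpha_S * x[[7]] / (p$mu_S + x[[7]]),
    -p$gamma_p * x[[4]] + p$beta_A * x[[1]],
    -p$gamma_p * x[[5]] + p$beta_B * x[[2]],
    -p$gamma_p * x[[6]] + p$beta_C * x[[3]],
    -p$gamma_s * x[[7]] + p$beta_s * x[[4]])
}

# vectorized drift over a 7 x N state matrix (no validation; hot path)
drift_matrix <- function(X, p) {
  rbind(-p$gamma_m * X[1, ] + p$alpha_a / (p$mu + X[6, ]^p$n),
        -p$gamma_m * X[2, ] + p$alpha_b / (p$mu + X[4, ]^p$n),
        -p$gamma_m * X[3, ] + p$alpha_c / (p$mu + X[5, ]^p$n) +
          p$alpha_S * X[7, ] / (p$mu_S + X[7, ]),
        -p$gamma_p * X[4, ] + p$beta_A * X[1, ],
        -p$gamma_p * X[5, ] + p$beta_B * X[2, ],
        -p$gamma_p * X[6, ] + p$beta_C * X[3, ],
        -p$gamma_s * X[7, ] + p$beta_s * X[4, ], deparse.level = 0)
}

#' Inner coupling function of the quorum-sensing exchange
#'
#' The diffusive autoinducer exchange between cells is `sum_j c_ij g(x_j)`
#' with `g(x) = (0, 0, 0, 0, 0, 0, x_S)`: only the intracellular
#' autoinducer is exchanged, linearly.
#'
#' @inheritParams drift_single_cell
#' @return numeric length-7 vector
#' @export
coupling_function <- function(x) {
  x <- validate_cell_state(x)
  c(rep(0, 6), x[[7]])
}

#' Intrinsic parameter-fluctuation field
#'
#' Coefficient f_W(x) of the per-cell scalar Wiener increment: every
#' nominal kinetic parameter in the drift is replaced by the standard
#' deviation of its fluctuation. The fluctuation of the diffusion rate
#' eta_s is not included here; it is carried through the coupling matrix by
#' [coupling_noise_function()].
#'
#' @inheritParams drift_single_cell
#' @param d a [fluctuation_amplitudes()] object
#' @return numeric length-7 vector
#' @export
intrinsic_noise_field <- function(x, d, p) {
  x <- validate_cell_state(x)
  c(-d$d_gamma_m * x[[1]] + d$d_alpha_a / (p$mu + x[[6]]^p$n),
    -d$d_gamma_m * x[[2]] + d$d_alpha_b / (p$mu + x[[4]]^p$n),
    -d$d_gamma_m * x[[3]] + d$d_alpha_c / (p$mu + x[[5]]^p$n) +
      d$d_alpha_S * x[[7]] / (p$mu_S + x[[7]]),
    -d$d_gamma_p * x[[4]] + d$d_beta_A * x[[1]],
    -d$d_gamma_p * x[[5]] + d$d_beta_B * x[[2]],
    -d$d_gamma_p * x[[6]] + d$d_beta_C * x[[3]],
    -d$d_gamma_s * x[[7]] + d$d_beta_s * x[[4]])
}

# vectorized intrinsic field over 7 x N (hot path)
intrinsic_noise_matrix <- function(X, d, p) {
  rbind(-d$d_gamma_m * X[1, ] + d$d_alpha_a / (p$mu + X[6, ]^p$n),
        -d$d_gamma_m * X[2, ] + d$d_alpha_b / (p$mu + X[4, ]^p$n),
        -d$d_gamma_m * X[3, ] + d$d_alpha_c / (p$mu + X[5, ]^p$n) +
          d$d_alpha_S * X[7, ] / (p$mu_S + X[7, ]),
        -d$d_gamma_p * X[4, ] + d$d_beta_A * X[1, ],
        -d$d_gamma_p * X[5, ] + d$d_beta_B * X[2, ],
        -d$d_gamma_p * X[6, ] + d$d_beta_C * X[3, ],
        -d$d_gamma_s * X[7, ] + d$d_beta_s * X[4, ], deparse.level = 0)
}

#' Fluctuation of the diffusive coupling
#'
#' The eta_s fluctuation is factored through the same coupling matrix as
#' the nominal exchange: `g_W(x) = (d_eta_s / eta_s) * g(x)`, so that
#' `sum_j c_ij g_W(x_j)` reproduces the fluctuation of the diffusive term
#' with a single shared coupling matrix.
#'
#' @inheritParams drift_single_cell
#' @param d_eta_s fluctuation amplitude of the diffusion rate (>= 0)
#' @param eta_s nominal diffusion rate (> 0)
#' @return numeric length-7 vector
#' @export
coupling_noise_function <- function(x, d_eta_s, eta_s) {
  check_scalar(eta_s, "eta_s", lower = 0, strict = TRUE)
  check_scalar(d_eta_s, "d_eta_s", lower = 0)
  (d_eta_s / eta_s) * coupling_function(x)
}

#' Quorum-sensing coupling configuration matrix
#'
#' All-to-all mean-field coupling through the extracellular autoinducer.
#' Diagonal entries are `-eta_s (1 - 1/N) (Q_e + Q)` and off-diagonals
#' `eta_s (Q_e + Q) / N`, so every row sums to zero and the coupling
#' vanishes on the synchronization manifold. `Q = 0` gives the
#' uncontrolled network; `Q > 0` models externally added inducer.
#'
#' @param n_cells population size N (>= 1)
#' @param eta_s autoinducer membrane diffusion rate (> 0)
#' @param Q_e baseline extracellular coupling fraction
#' @param Q external control gain (`Q_e + Q >= 0`)
#' @return an `N x N` matrix of class `coupling_matrix` with attributes
#'   `eta_s`, `Q_e`, `Q`
#' @export
#' @examples
#' C <- build_coupling_matrix(10, 2, 0.09, 0)
#' diag(C)[1]      # -0.162
#' rowSums(C)      # all zero
build_coupling_matrix <- function(n_cells, eta_s, Q_e, Q = 0) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells))
    qs_stop("'n_cells' must be a positive integer")
  check_scalar(eta_s, "eta_s", lower = 0, strict = TRUE)
  if (Q_e + Q < 0) qs_stop("'Q_e + Q' must be >= 0")
  N <- as.integer(n_cells)
  C <- matrix(eta_s * (Q_e + Q) / N, N, N)
  diag(C) <- -eta_s * (1 - 1 / N) * (Q_e + Q)
  structure(C, class = c("coupling_matrix", "matrix", "array"),
            eta_s = eta_s, Q_e = Q_e, Q = Q)
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> N = %d, eta_s = %g, Q_e = %g, Q = %g\n",
              nrow(x), attr(x, "eta_s"), attr(x, "Q_e"), attr(x, "Q")))
  print(unclass(x)[seq_len(min(4, nrow(x))), seq_len(min(4, ncol(x))),
                   drop = FALSE])
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Export a coupling matrix as delimited text
#' @param C a coupling matrix
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_coupling_matrix <- function(C, path) {
  df <- as.data.frame(unclass(C))
  names(df) <- paste0("cell", seq_len(ncol(C)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- analytic Jacobians (shared by the fuzzy module) ------------------------

# d f / d x at one state; only x_A, x_B, x_C, x_S enter nonlinearly.
drift_jacobian <- function(x, p) {
  x <- validate_cell_state(x)
  hill_d <- function(alpha, xr) {
    # d/dx [alpha / (mu + x^n)] = -alpha n x^(n-1) / (mu + x^n)^2
    -alpha * p$n * xr^(p$n - 1) / (p$mu + xr^p$n)^2
  }
  J <- matrix(0, 7, 7, dimnames = list(.qs_species, .qs_species))
  J[1, 1] <- -p$gamma_m; J[1, 6] <- hill_d(p$alpha_a, x[[6]])
  J[2, 2] <- -p$gamma_m; J[2, 4] <- hill_d(p$alpha_b, x[[4]])
  J[3, 3] <- -p$gamma_m; J[3, 5] <- hill_d(p$alpha_c, x[[5]])
  J[3, 7] <- p$alpha_S * p$mu_S / (p$mu_S + x[[7]])^2
  J[4, 4] <- -p$gamma_p; J[4, 1] <- p$beta_A
  J[5, 5] <- -p$gamma_p; J[5, 2] <- p$beta_B
  J[6, 6] <- -p$gamma_p; J[6, 3] <- p$beta_C
  J[7, 7] <- -p$gamma_s; J[7, 4] <- p$beta_s
  J
}

# d f_W / d x: same sparsity, nominal rates replaced by amplitudes
# (mu, mu_S, n are not fluctuating and keep their nominal values).
intrinsic_noise_jacobian <- function(x, d, p) {
  x <- validate_cell_state(x)
  hill_d <- function(amp, xr) -amp * p$n * xr^(p$n - 1) / (p$mu + xr^p$n)^2
  J <- matrix(0, 7, 7, dimnames = list(.qs_species, .qs_species))
  J[1, 1] <- -d$d_gamma_m; J[1, 6] <- hill_d(d$d_alpha_a, x[[6]])
  J[2, 2] <- -d$d_gamma_m; J[2, 4] <- hill_d(d$d_alpha_b, x[[4]])
  J[3, 3] <- -d$d_gamma_m; J[3, 5] <- hill_d(d$d_alpha_c, x[[5]])
  J[3, 7] <- d$d_alpha_S * p$mu_S / (p$mu_S + x[[7]])^2
  J[4, 4] <- -d$d_gamma_p; J[4, 1] <- d$d_beta_A
  J[5, 5] <- -d$d_gamma_p; J[5, 2] <- d$d_beta_B
  J[6, 6] <- -d$d_gamma_p; J[6, 3] <- d$d_beta_C
  J[7, 7] <- -d$d_gamma_s; J[7, 4] <- d$d_beta_s
  J
}

# constant coupling Jacobians: B has a single 1 at (7,7); B_W scales it.
coupling_jacobian <- function() {
  B <- matrix(0, 7, 7, dimnames = list(.qs_species, .qs_species))
  B[7, 7] <- 1
  B
}
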