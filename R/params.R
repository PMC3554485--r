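# Parameter containers and their invariants.

qs_stop <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = NULL, upper = NULL, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    qs_stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (!is.null(lower)) {
    ok <- if (strict) x > lower else x >= lower
    if (!ok) qs_stop(sprintf("'%s' must be %s %g (got %g)", name,
                             if (strict) ">" else ">=", lower, x))
  }
  if (!is.null(upper) && x > upper)
    qs_stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  invisible(x)
}

#' Kinetic parameters of one repressilator cell
#'
#' Nominal kinetic constants of a single synthetic oscillator: a
#' three-gene repressilator (tetR -| cI -| lacI -| tetR) augmented with the
#' quorum-sensing module, in dimensionless units. Defaults are the worked
#' in-silico example of the source model: maximal transcription rates
#' `alpha_a = alpha_b = alpha_c = 216`, autoinducer-induced lacI
#' transcription `alpha_S = 20`, repression coefficient `mu = 1.2`,
#' activation coefficient `mu_S = 1`, Hill coefficient `n = 2`, translation
#' rates `beta_A = beta_B = beta_C = 1`, autoinducer synthesis
#' `beta_s = 0.1`, degradation rates `gamma_m = 6.9315` (mRNA),
#' `gamma_p = 1.1552` (protein), `gamma_s = 1` (autoinducer), membrane
#' diffusion `eta_s = 2` and extracellular coupling fraction `Q_e = 0.09`.
#'
#' @param alpha_a,alpha_b,alpha_c maximal transcription rates (> 0)
#' @param alpha_S maximal autoinducer-induced lacI transcription (> 0)
#' @param mu repression coefficient (> 0)
#' @param mu_S activation coefficient (> 0)
#' @param n Hill coefficient (>= 1, real)
#' @param beta_A,beta_B,beta_C translation rates (> 0)
#' @param beta_s autoinducer synthesis rate (> 0)
#' @param gamma_m,gamma_p,gamma_s degradation rates of mRNA, protein and
#'   autoinducer (> 0)
#' @param eta_s autoinducer membrane diffusion rate (> 0)
#' @param Q_e baseline extracellular coupling fraction, in `[0, 1]`
#' @return an object of class `repressilator_params`
#' @export
#' @examples
#' p <- repressilator_params()
#' drift_single_cell(rep(0, 7), p)[1]  # 216 / 1.2 = 180
repressilator_params <- function(alpha_a = 216, alpha_b = 216, alpha_c = 216,
                                 alpha_S = 20, mu = 1.2, mu_S = 1, n = 2,
                                 beta_A = 1, beta_B = 1, beta_C = 1,
                                 beta_s = 0.1, gamma_m = 6.9315,
                                 gamma_p = 1.1552, gamma_s = 1,
                                 eta_s = 2, Q_e = 0.09) {
  p <- list(alpha_a = alpha_a, alpha_b = alpha_b, alpha_c = alpha_c,
            alpha_S = alpha_S, mu = mu, mu_S = mu_S, n = n,
            beta_A = beta_A, beta_B = beta_B, beta_C = beta_C,
            beta_s = beta_s, gamma_m = gamma_m, gamma_p = gamma_p,
            gamma_s = gamma_s, eta_s = eta_s, Q_e = Q_e)
  for (nm in setdiff(names(p), c("Q_e", "n")))
    check_scalar(p[[nm]], nm, lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 1)
  check_scalar(Q_e, "Q_e", lower = 0, upper = 1)
  structure(p, class = "repressilator_params")
}

#' @export
print.repressilator_params <- function(x, ...) {
  cat("<repressilator_params>\n")
  cat(paste(sprintf("  %s = %g", names(x), unlist(x)), collapse = "\n"), "\n")
  invisible(x)
}

#' Standard deviations of the stochastic kinetic-parameter fluctuations
#'
#' Each field is the standard deviation of the white-noise fluctuation of
#' the corresponding kinetic parameter (same units as the nominal value).
#' A zero vector recovers deterministic intrinsic dynamics. Defaults are
#' the worked example's amplitudes (roughly 1% of each nominal rate).
#'
#' @param d_alpha_a,d_alpha_b,d_alpha_c,d_alpha_S transcription-rate
#'   fluctuation amplitudes (>= 0)
#' @param d_beta_A,d_beta_B,d_beta_C,d_beta_s translation/synthesis
#'   fluctuation amplitudes (>= 0)
#' @param d_gamma_m,d_gamma_p,d_gamma_s degradation-rate fluctuation
#'   amplitudes (>= 0)
#' @param d_eta_s autoinducer-diffusion fluctuation amplitude (>= 0)
#' @return an object of class `fluctuation_amplitudes`
#' @export
fluctuation_amplitudes <- function(d_alpha_a = 2.16, d_alpha_b = 2.16,
                                   d_alpha_c = 2.16, d_alpha_S = 0.2,
                                   d_beta_A = 0.01, d_beta_B = 0.01,
                                   d_beta_C = 0.01, d_beta_s = 0.001,
                                   d_gamma_m = 0.06, d_gamma_p = 0.01,
                                   d_gamma_s = 0.01, d_eta_s = 0.02) {
  d <- list(d_alpha_a = d_alpha_a, d_alpha_b = d_alpha_b,
            d_alpha_c = d_alpha_c, d_alpha_S = d_alpha_S,
            d_beta_A = d_beta_A, d_beta_B = d_beta_B, d_beta_C = d_beta_C,
            d_beta_s = d_beta_s, d_gamma_m = d_gamma_m,
            d_gamma_p = d_gamma_p, d_gamma_s = d_gamma_s,
            d_eta_s = d_eta_s)
  for (nm in names(d)) check_scalar(d[[nm]], nm, lower = 0)
  structure(d, class = "fluctuation_amplitudes")
}

#' Zero fluctuation amplitudes (deterministic intrinsic dynamics)
#' @return a `fluctuation_amplitudes` object with every amplitude 0
#' @export
zero_fluctuations <- function() {
  do.call(fluctuation_amplitudes,
          as.list(setNames(rep(0, 12), names(fluctuation_amplitudes()))))
}

#' @export
print.fluctuation_amplitudes <- function(x, ...) {
  cat("<fluctuation_amplitudes>\n")
  cat(paste(sprintf("  %s = %g", names(x), unlist(x)), collapse = "\n"), "\n")
  invisible(x)
}

#' Extrinsic molecular-noise coupling specification
#'
#' One scalar extrinsic environmental noise source per cell, entering the
#' state equation through the column `h_cell`. The default injects the
#' noise into all seven state equations equally (`h_cell = rep(1, 7)`)
#' with standard deviation `sigma_v = 0.02`; the synchronization reference
#' is taken noise-free (`h_ref = 0`), so the stacked noise-coupling matrix
#' is block-diagonal in `h_cell`.
#'
#' @param h_cell length-7 numeric: per-cell noise-coupling column
#' @param sigma_v standard deviation of the extrinsic noise (>= 0)
#' @param h_ref length-7 numeric: reference-trajectory noise coupling
#' @return an object of class `extrinsic_noise_spec`
#' @export
extrinsic_noise_spec <- function(h_cell = rep(1, .qs_nspecies),
                                 sigma_v = 0.02,
                                 h_ref = rep(0, .qs_nspecies)) {
  if (length(h_cell) != .qs_nspecies || !all(is.finite(h_cell)))
    qs_stop("'h_cell' must be a finite numeric vector of length 7")
  if (length(h_ref) != .qs_nspecies || !all(is.finite(h_ref)))
    qs_stop("'h_ref' must be a finite numeric vector of length 7")
  check_scalar(sigma_v, "sigma_v", lower = 0)
  structure(list(h_cell = as.numeric(h_cell), sigma_v = sigma_v,
                 h_ref = as.numeric(h_ref)),
            class = "extrinsic_noise_spec")
}

# Validate one cell state (length 7, finite, nonnegative).
validate_cell_state <- function(x, allow_negative = FALSE) {
  if (!is.numeric(x) || length(x) != .qs_nspecies)
    qs_stop("cell state must be a numeric vector of length 7")
  if (any(!is.finite(x))) qs_stop("cell state contains non-finite values")
  if (!allow_negative && any(x < 0))
    qs_stop("cell state has negative components (concentrations must be >= 0)")
  x <- as.numeric(x)
  names(x) <- .qs_species
  x
}
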