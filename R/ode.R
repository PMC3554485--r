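# Deterministic single-cell integration and limit-cycle detection.
# A fixed-step classical Runge-Kutta integrator is sufficient here: the
# system is 7-dimensional, smooth, and the attractor period is ~5 time
# units, so dt = 0.01 resolves it to ~1e-8 local error.

#' Integrate the noise-free single-cell dynamics
#'
#' Classical fourth-order Runge-Kutta with fixed step. On the
#' synchronization manifold the quorum coupling cancels exactly, so the
#' isolated-cell equations also describe the synchronized population.
#'
#' @param x0 initial state, length 7
#' @param p a [repressilator_params()] object
#' @param dt time step
#' @param n_steps number of steps
#' @param keep if `TRUE` return the whole trajectory
#' @return list with `x` (final state), `time`, and (if `keep`) `states`
#'   as an `(n_steps + 1) x 7` matrix
#' @export
integrate_cell_ode <- function(x0, p, dt = 0.01, n_steps = 1000L,
                               keep = TRUE) {
  x <- validate_cell_state(x0)
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  f <- function(s) {
    c(-p$gamma_m * s[1] + p$alpha_a / (p$mu + s[6]^p$n),
      -p$gamma_m * s[2] + p$alpha_b / (p$mu + s[4]^p$n),
      -p$gamma_m * s[3] + p$alpha_c / (p$mu + s[5]^p$n) +
        p$alpha_S * s[7] / (p$mu_S + s[7]),
      -p$gamma_p * s[4] + p$beta_A * s[1],
      -p$gamma_p * s[5] + p$beta_B * s[2],
      -p$gamma_p * s[6] + p$beta_C * s[3],
      -p$gamma_s * s[7] + p$beta_s * s[4])
  }
  S <- if (keep) matrix(NA_real_, n_steps + 1L, 7L,
                        dimnames = list(NULL, .qs_species)) else NULL
  if (keep) S[1L, ] <- x
  for (k in seq_len(n_steps)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (keep) S[k + 1L, ] <- x
  }
  list(x = setNames(x, .qs_species), time = seq(0, by = dt,
       length.out = if (keep) n_steps + 1L else 1L), states = S)
}

#' Locate the periodic attractor of the single cell
#'
#' Integrates past the transient, then detects the oscillation period from
#' successive maxima of the tetR mRNA (first state component). Fails with
#' a diagnostic when no consistent periodic attractor is found.
#'
#' @param p a [repressilator_params()] object
#' @param x0 initial state (default a generic interior point)
#' @param t_transient settle time before period detection
#' @param t_observe observation window
#' @param dt integration step
#' @param tol relative tolerance on successive peak heights and spacings
#' @return list with `period`, `dt`, and `states`: a `K x 7` matrix
#'   sampling one period (row 1 at a peak of x_a)
#' @export
find_limit_cycle <- function(p, x0 = c(1, 2, 3, 1, 2, 3, 0.5),
                             t_transient = 200, t_observe = 60,
                             dt = 0.01, tol = 0.05) {
  key <- paste(c(unlist(p), x0, t_transient, t_observe, dt, tol),
               collapse = "|")
  hit <- .qs_lc_cache[[key]]
  if (!is.null(hit)) return(hit)
  settle <- integrate_cell_ode(x0, p, dt, round(t_transient / dt),
                               keep = FALSE)
  obs <- integrate_cell_ode(settle$x, p, dt, round(t_observe / dt))
  xa <- obs$states[, 1]
  peaks <- which(diff(sign(diff(xa))) == -2) + 1L
  if (length(peaks) < 3L)
    qs_stop("no periodic attractor detected (fewer than 3 maxima of x_a); ",
            "consider the 'grid' operating-point method")
  gaps <- diff(peaks) * dt
  heights <- xa[peaks]
  if (max(abs(gaps - mean(gaps))) > tol * mean(gaps) ||
      max(abs(heights - mean(heights))) > tol * mean(abs(heights)))
    qs_stop("inconsistent successive maxima of x_a (tolerance ", tol,
            "); no clean periodic attractor - ",
            "consider the 'grid' operating-point method")
  period <- mean(gaps)
  nper <- round(period / dt)
  states <- obs$states[peaks[1L] + 0:(nper - 1L), , drop = FALSE]
  out <- list(period = period, dt = dt, states = states)
  .qs_lc_cache[[key]] <- out
  out
}

# memo for the (deterministic) limit-cycle computation
.qs_lc_cache <- new.env(parent = emptyenv())
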