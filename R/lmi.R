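# LMI feasibility machinery for robust synchronization.
#
# Each rule k of the fuzzy error system contributes the block constraint
#
#   M_k(P) = [ R + P Phi_k + Phi_k' P + Psi_k' P Psi_k   P H  ]
#            [ H' P                                      -rho^2 I ]  <= -eps I
#
# together with P >= eps I, all affine in the decision matrix P. No SDP
# backend is available in this environment, so feasibility is solved by
# minimizing a smoothed maximum eigenvalue (log-sum-exp over all block
# eigenvalues) with analytic gradients, multi-start from Lyapunov-equation
# solutions, and a staged sharpening of the smoothing parameter. Any
# returned certificate is re-verified by direct eigenvalue computation,
# independent of the optimizer.

# ---- low-level helpers -----------------------------------------------------

vech_index <- function(d) which(upper.tri(diag(d), diag = TRUE),
                                arr.ind = TRUE)

vech_to_sym <- function(th, d, ii) {
  P <- matrix(0, d, d)
  P[ii] <- th
  P <- P + t(P)
  diag(P) <- diag(P) / 2
  P
}

sym_to_vech <- function(P, ii) P[ii]

# Lyapunov solve A'P + P A = -Q via the Kronecker linear system (small d)
lyapunov_solve <- function(A, Qm = diag(nrow(A))) {
  d <- nrow(A)
  P <- tryCatch(
    matrix(solve(kronecker(diag(d), t(A)) + kronecker(t(A), diag(d)),
                 -as.vector(Qm)), d, d),
    error = function(e) NULL)
  if (is.null(P)) return(NULL)
  P <- (P + t(P)) / 2
  if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    return(NULL)
  P
}

# one constraint block at P
constraint_block <- function(cn, P) {
  M11 <- cn$R + P %*% cn$Phi + t(cn$Phi) %*% P +
    t(cn$Psi) %*% P %*% cn$Psi
  if (ncol(cn$H) == 0L) return((M11 + t(M11)) / 2)
  M12 <- P %*% cn$H
  M <- rbind(cbind(M11, M12),
             cbind(t(M12), -cn$rho^2 * diag(ncol(cn$H))))
  (M + t(M)) / 2
}

# true worst margin over all constraints (independent verification path)
lmi_margins <- function(constraints, P) {
  vapply(constraints, function(cn)
    max(eigen(constraint_block(cn, P), symmetric = TRUE,
              only.values = TRUE)$values), 0)
}

# smoothed objective: (1/beta) log sum exp(beta * eigenvalues) over all
# blocks plus the (delta*I - P) block; analytic gradient wrt vech(P).
lmi_objective <- function(th, constraints, d, ii, beta, delta) {
  P <- vech_to_sym(th, d, ii)
  vals <- c()
  parts <- vector("list", length(constraints))
  for (q in seq_along(constraints)) {
    cn <- constraints[[q]]
    M <- constraint_block(cn, P)
    ee <- eigen(M, symmetric = TRUE)
    vals <- c(vals, ee$values)
    parts[[q]] <- ee
  }
  eP <- eigen(P, symmetric = TRUE)
  vals <- c(vals, delta - eP$values)
  mx <- max(vals)
  wraw <- exp(beta * (vals - mx))
  sw <- sum(wraw)
  f <- mx + log(sw) / beta
  G <- matrix(0, d, d)
  pos <- 0L
  for (q in seq_along(constraints)) {
    cn <- constraints[[q]]
    nv <- ncol(cn$H)
    nb <- d + nv
    ee <- parts[[q]]
    w <- wraw[pos + seq_len(nb)] / sw
    pos <- pos + nb
    W <- ee$vectors %*% (w * t(ee$vectors))
    W11 <- W[seq_len(d), seq_len(d), drop = FALSE]
    Gc <- W11 %*% t(cn$Phi) + cn$Phi %*% W11 +
      cn$Psi %*% W11 %*% t(cn$Psi)
    if (nv > 0L) {
      W12 <- W[seq_len(d), d + seq_len(nv), drop = FALSE]
      Gc <- Gc + 2 * W12 %*% t(cn$H)
    }
    G <- G + (Gc + t(Gc)) / 2
  }
  wP <- wraw[pos + seq_len(d)] / sw
  G <- G - eP$vectors %*% (wP * t(eP$vectors))
  gr <- 2 * G[ii]
  di <- ii[, 1] == ii[, 2]
  gr[di] <- gr[di] / 2
  structure(f, gradient = gr)
}

# effort presets for the nonsmooth solve
lmi_effort <- function(effort) {
  switch(effort,
    fast = list(betas = c(4, 32, 256, 2048), maxit = 300,
                max_starts = 2L, stall = 2L),
    standard = list(betas = c(0.5, 2, 8, 32, 128, 512, 2048),
                    maxit = 1200, max_starts = 4L, stall = 3L),
    thorough = list(betas = c(0.5, 2, 8, 32, 128, 512, 2048, 8192),
                    maxit = 4000, max_starts = 8L, stall = 99L),
    qs_stop("unknown effort level '", effort, "'"))
}

# core multi-start solve; returns best P and its true margin
lmi_solve_core <- function(constraints, d, eps, delta, P0 = NULL,
                           effort = "standard") {
  ctl <- lmi_effort(effort)
  ii <- vech_index(d)
  starts <- list(diag(d))
  lyaps <- list()
  for (cn in constraints) {
    Pl <- lyapunov_solve(cn$Phi)
    if (!is.null(Pl)) lyaps[[length(lyaps) + 1L]] <- Pl * d / sum(diag(Pl))
  }
  if (length(lyaps)) {
    starts <- c(starts, list(Reduce(`+`, lyaps) / length(lyaps)))
    starts <- c(starts, lyaps[seq_len(min(length(lyaps),
                                          ctl$max_starts - 2L))])
  }
  if (!is.null(P0)) starts <- c(list((P0 + t(P0)) / 2), starts)
  starts <- starts[seq_len(min(length(starts), ctl$max_starts))]

  best <- list(margin = Inf, P = diag(d))
  for (P0c in starts) {
    if (min(eigen(P0c, symmetric = TRUE, only.values = TRUE)$values)
        < delta)
      P0c <- P0c + (delta + 1e-8) * diag(d)
    th <- sym_to_vech(P0c, ii)
    scale0 <- max(1, abs(max(lmi_margins(constraints, P0c))))
    prev <- Inf
    stalls <- 0L
    for (b in ctl$betas / min(scale0, 100)) {
      fn <- function(t_) as.numeric(
        lmi_objective(t_, constraints, d, ii, b, delta))
      gr <- function(t_) attr(
        lmi_objective(t_, constraints, d, ii, b, delta), "gradient")
      o <- tryCatch(
        optim(th, fn, gr, method = "BFGS",
              control = list(maxit = ctl$maxit, reltol = 1e-14)),
        error = function(e) NULL)
      if (is.null(o)) break
      th <- o$par
      P <- vech_to_sym(th, d, ii)
      mg <- max(lmi_margins(constraints, P))
      pmin <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
      if (mg < best$margin && pmin > 0) best <- list(margin = mg, P = P)
      if (mg <= -eps && pmin >= delta / 2) return(best)
      # clearly-positive margin no longer improving: stop burning effort
      if (mg > 0.02 && prev - mg < 0.005 * max(1, abs(prev))) {
        stalls <- stalls + 1L
        if (stalls >= ctl$stall) break
      } else stalls <- 0L
      prev <- mg
    }
  }
  best
}

# ---- problem assembly ------------------------------------------------------

# accept a fuzzy_model or a bare list(rules = ...) with A/B/A_W/B_W blocks
rules_of <- function(model) {
  if (inherits(model, "fuzzy_model") || !is.null(model$rules))
    return(model$rules)
  qs_stop("'model' must be a fuzzy_model or a list with a 'rules' field")
}

#' Assemble the robust-synchronization LMI problem
#'
#' Builds, for each fuzzy rule, the block constraint of the
#' noise-filtering criterion at level `rho`, in the decision matrix `P`.
#' For a symmetric coupling matrix with per-cell noise column and
#' block-diagonal weighting, the stacked `7N`-dimensional problem is
#' reduced by the eigendecomposition of `C`: the certificate is restricted
#' to the Kronecker form `I_N (x) P7` and one 7-dimensional constraint is
#' generated per rule and per distinct eigenvalue of `C` (a sufficient
#' condition; any feasible reduced certificate yields a feasible full
#' one). For the all-to-all quorum topology the distinct eigenvalues are
#' `0` (the synchronous mode) and `-eta_s (Q_e + Q)` (all transverse
#' modes).
#'
#' By default the synchronous mode is excluded (`deflate = TRUE`):
#' population-mean synchronization errors sum to zero over cells, so the
#' error never has a component along that mode. Set `deflate = FALSE` to
#' keep it.
#'
#' @param model a [build_fuzzy_model()] result, or any list with a
#'   `rules` field of `A`/`B`/`A_W`/`B_W` blocks (arbitrary dimension)
#' @param C coupling matrix (`N x N`)
#' @param H per-cell noise-coupling column (length d), an
#'   [extrinsic_noise_spec()] (its `h_cell` is used), or `NULL` for the
#'   all-ones default; with `reduce = FALSE` a full `dN x N` matrix is
#'   also accepted
#' @param R error weighting: `NULL` (identity), a `d x d` per-cell block,
#'   or (non-reduced only) a full matrix
#' @param rho filtering level (> 0)
#' @param eps strictness margin replacing the strict inequalities
#' @param reduce use the Kronecker eigenmode reduction (requires symmetric
#'   `C`)
#' @param deflate drop the synchronous (constant-eigenvector) mode of `C`
#' @return an object of class `lmi_problem`
#' @export
assemble_lmi_blocks <- function(model, C, H = NULL, R = NULL, rho,
                                eps = 1e-6, reduce = TRUE, deflate = TRUE) {
  check_scalar(rho, "rho", lower = 0, strict = TRUE)
  check_scalar(eps, "eps", lower = 0, strict = TRUE)
  rules <- rules_of(model)
  d <- nrow(rules[[1]]$A)
  N <- nrow(C)
  if (inherits(H, "extrinsic_noise_spec")) H <- H$h_cell
  if (is.null(H)) H <- rep(1, d)
  if (is.null(R)) R <- diag(d)
  if (is.matrix(H) && reduce)
    qs_stop("a full H matrix requires reduce = FALSE")
  Cm <- unclass(C)

  if (reduce) {
    if (max(abs(Cm - t(Cm))) > 1e-10)
      qs_stop("the eigenmode reduction requires a symmetric coupling matrix")
    if (!all(dim(R) == c(d, d)))
      qs_stop("reduced problems take a d x d weighting block")
    ee <- eigen((Cm + t(Cm)) / 2, symmetric = TRUE)
    lam <- ee$values
    keep <- rep(TRUE, N)
    if (deflate && N > 1L) {
      # drop the mode aligned with the constant vector (row sums are zero,
      # so it always exists and carries no population-mean error)
      sync_mode <- which.max(abs(colSums(ee$vectors)))
      keep[sync_mode] <- FALSE
    }
    modes <- unique(round(lam[keep], 12))
    h7 <- matrix(as.numeric(H), d, 1)
    constraints <- list()
    for (rl in rules) {
      for (lm in modes) {
        constraints[[length(constraints) + 1L]] <- list(
          Phi = rl$A + lm * rl$B, Psi = rl$A_W + lm * rl$B_W,
          H = h7, R = R, rho = rho)
      }
    }
    structure(list(constraints = constraints, d = d, rho = rho, eps = eps,
                   reduced = TRUE, n_cells = N, modes = modes,
                   deflate = deflate, n_rules = length(rules),
                   R = R, H = h7, C = Cm),
              class = "lmi_problem")
  } else {
    D <- d * N
    Hfull <- if (is.matrix(H)) H else kronecker(diag(N), matrix(H, d, 1))
    Rfull <- if (all(dim(R) == c(d, d))) kronecker(diag(N), R) else R
    if (!all(dim(Rfull) == c(D, D))) qs_stop("'R' has wrong dimensions")
    constraints <- lapply(rules, function(rl) list(
      Phi = kronecker(diag(N), rl$A) + kronecker(Cm, rl$B),
      Psi = kronecker(diag(N), rl$A_W) + kronecker(Cm, rl$B_W),
      H = Hfull, R = Rfull, rho = rho))
    structure(list(constraints = constraints, d = D, rho = rho, eps = eps,
                   reduced = FALSE, n_cells = N, modes = NULL,
                   deflate = FALSE, n_rules = length(rules),
                   R = Rfull, H = Hfull, C = Cm),
              class = "lmi_problem")
  }
}

#' @export
print.lmi_problem <- function(x, ...) {
  cat(sprintf("<lmi_problem> %d constraint(s), decision dim %d, rho = %g%s\n",
              length(x$constraints), x$d, x$rho,
              if (x$reduced) sprintf(" (reduced; modes %s%s)",
                                     paste(signif(x$modes, 4),
                                           collapse = ", "),
                                     if (x$deflate) ", sync mode dropped"
                                     else "")
              else ""))
  invisible(x)
}

#' Solve an LMI feasibility problem
#'
#' Runs the smoothed max-eigenvalue solver and then re-verifies any
#' claimed certificate by direct eigenvalue computation of every block
#' (defense against optimizer slack). Status is `"feasible"` only for a
#' verified certificate; `"infeasible"` when the best margin found is
#' clearly positive; `"solver-inconclusive"` in between.
#'
#' @param prob an [assemble_lmi_blocks()] result
#' @param P0 optional warm-start matrix
#' @param effort `"fast"`, `"standard"` or `"thorough"`
#' @return object of class `feasibility_result` with `status`, `P`
#'   (decision-dimension certificate), `P_full` (Kronecker-expanded for
#'   reduced problems), `margins` (true per-constraint eigen margins),
#'   `min_eig_P`
#' @export
solve_feasibility <- function(prob, P0 = NULL, effort = "standard") {
  eps <- prob$eps
  # cheap necessary condition for multi-rule problems: the first single
  # constraint must be feasible on its own; if it is clearly not, the
  # joint problem is infeasible without running the full solve
  if (length(prob$constraints) > 2L && effort == "fast") {
    pre <- lmi_solve_core(prob$constraints[1], prob$d, eps = eps,
                          delta = eps, P0 = P0, effort = "fast")
    if (pre$margin > max(10 * eps, 1e-4)) {
      P <- pre$P
      return(structure(list(status = "infeasible", P = P,
                            P_full = if (prob$reduced)
                              kronecker(diag(prob$n_cells), P) else P,
                            margins = lmi_margins(prob$constraints, P),
                            min_eig_P = min(eigen(P, symmetric = TRUE,
                              only.values = TRUE)$values),
                            rho = prob$rho, eps = eps,
                            prefilter = TRUE),
                       class = "feasibility_result"))
    }
  }
  sol <- lmi_solve_core(prob$constraints, prob$d, eps = eps, delta = eps,
                        P0 = P0, effort = effort)
  P <- sol$P
  margins <- lmi_margins(prob$constraints, P)
  pmin <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  feas <- max(margins) <= -eps / 2 && pmin > 0
  status <- if (feas) "feasible"
    else if (max(margins) > eps) "infeasible" else "solver-inconclusive"
  if (feas && (max(margins) > -eps / 2 || pmin <= 0))
    qs_stop("internal error: certificate failed independent verification")
  structure(list(status = status, P = P,
                 P_full = if (prob$reduced)
                   kronecker(diag(prob$n_cells), P) else P,
                 margins = margins, min_eig_P = pmin,
                 rho = prob$rho, eps = eps),
            class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat(sprintf("<feasibility_result> %s at rho = %g (worst margin %.3g, min eig P %.3g)\n",
              x$status, x$rho, max(x$margins), x$min_eig_P))
  invisible(x)
}

#' Optimal noise-filtering level by bisection
#'
#' Feasibility is monotone in `rho` (enlarging `rho` only loosens the
#' disturbance block), so the minimal certified level is found by
#' bisection on a bracket whose upper end must be feasible.
#'
#' @inheritParams assemble_lmi_blocks
#' @param bracket `c(rho_lo, rho_hi)`: `rho_lo` infeasible (0 allowed),
#'   `rho_hi` feasible
#' @param tol absolute bisection tolerance on rho
#' @param effort solver effort
#' @param ... passed to [assemble_lmi_blocks()] (`reduce`, `deflate`)
#' @return object of class `design_result` with `rho0`, certificate `P`
#'   (at `rho0 + tol`), `trace` (data frame of evaluations)
#' @export
min_rho <- function(model, C, H = NULL, R = NULL, bracket = c(0, 64),
                    tol = 1e-3, eps = 1e-6, effort = "standard", ...) {
  lo <- bracket[1]; hi <- bracket[2]
  if (lo < 0 || hi <= lo) qs_stop("invalid bracket")
  probe <- function(rho, P0 = NULL, eff = effort) solve_feasibility(
    assemble_lmi_blocks(model, C, H, R, rho = rho, eps = eps, ...),
    P0 = P0, effort = eff)
  top <- probe(hi, eff = effort)
  if (top$status != "feasible")
    qs_stop("unsynchronizable under this model: the LMIs are infeasible ",
            "even at rho = ", hi,
            " (worst margin ", signif(max(top$margins), 3),
            "); the local robustness criterion fails")
  trace <- data.frame(rho = hi, status = top$status,
                      margin = max(top$margins))
  Pcert <- top$P
  if (lo > 0) {
    bot <- probe(lo)
    trace <- rbind(trace, data.frame(rho = lo, status = bot$status,
                                     margin = max(bot$margins)))
    if (bot$status == "feasible") {
      warning("bracket lower end already feasible; returning it")
      return(finish_design(lo, bot, trace, model, C))
    }
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- probe(mid, P0 = Pcert)
    trace <- rbind(trace, data.frame(rho = mid, status = r$status,
                                     margin = max(r$margins)))
    if (r$status == "feasible") {
      hi <- mid
      Pcert <- r$P
      top <- r
    } else lo <- mid
  }
  finish_design(hi, top, trace, model, C)
}

finish_design <- function(rho0, res, trace, model, C, Q = attr(C, "Q")) {
  structure(list(rho0 = rho0, rho = rho0, Q = Q, P = res$P,
                 P_full = res$P_full, feasible = TRUE,
                 margins = res$margins, trace = trace),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  if (isTRUE(x$feasible))
    cat(sprintf("<design_result> feasible: rho0 = %.4g%s\n", x$rho0,
                if (!is.null(x$Q) && !is.na(x$Q))
                  sprintf(", Q = %g", x$Q) else ""))
  else
    cat("<design_result> no feasible design",
        if (!is.null(x$message)) paste0(": ", x$message), "\n")
  invisible(x)
}

#' Design the external control gain Q
#'
#' Scans an ascending grid of control gains, rebuilding the controlled
#' coupling matrix `C_e(Q)` for each, and returns the smallest gain for
#' which the LMIs are feasible at the target level `rho`. Candidate
#' feasibility found at scan effort is re-confirmed at full effort, and
#' the certificate is re-verified by direct eigenvalue margins. The
#' deterministic single-cell attractor does not depend on the coupling
#' gain (coupling cancels on the synchronization manifold), so the fuzzy
#' rules are built once and shared across the grid; `rebuild_fuzzy`
#' forces a rebuild per gain anyway.
#'
#' @param p [repressilator_params()]
#' @param d_amp [fluctuation_amplitudes()]
#' @param rho target filtering level
#' @param Q_grid ascending gains to try (default `seq(0, 2, by = 0.02)`)
#' @param n_cells population size
#' @param H,R,eps as in [assemble_lmi_blocks()]
#' @param L,method fuzzy model size / operating-point method
#' @param model optional prebuilt fuzzy model (overrides `L`, `method`)
#' @param rebuild_fuzzy rebuild the fuzzy model per grid point
#' @param report_rho0 after finding a feasible gain, also run [min_rho()]
#'   there and report the achieved optimum
#' @param deflate drop the synchronous coupling mode (see
#'   [assemble_lmi_blocks()])
#' @return a `design_result`; if no gain is feasible, `feasible = FALSE`
#'   with the per-Q margin trace
#' @export
design_Q <- function(p, d_amp, rho, Q_grid = seq(0, 2, by = 0.02),
                     n_cells = 10L, H = NULL, R = NULL, eps = 1e-6,
                     L = 8L, method = "limit-cycle", model = NULL,
                     rebuild_fuzzy = FALSE, report_rho0 = FALSE,
                     deflate = TRUE) {
  if (length(Q_grid) < 1L || is.unsorted(Q_grid))
    qs_stop("'Q_grid' must be an ascending grid")
  if (is.null(model)) model <- build_fuzzy_model(p, d_amp, L, method)
  trace <- data.frame(Q = numeric(0), status = character(0),
                      margin = numeric(0))
  for (Q in Q_grid) {
    fm <- if (rebuild_fuzzy) build_fuzzy_model(p, d_amp, L, method)
          else model
    C <- build_coupling_matrix(n_cells, p$eta_s, p$Q_e, Q)
    prob <- assemble_lmi_blocks(fm, C, H, R, rho = rho, eps = eps,
                                deflate = deflate)
    scan <- solve_feasibility(prob, effort = "fast")
    if (scan$status != "feasible" && length(Q_grid) > 10L) {
      trace <- rbind(trace, data.frame(Q = Q, status = scan$status,
                                       margin = max(scan$margins)))
      next
    }
    conf <- if (scan$status == "feasible") scan
            else solve_feasibility(prob, effort = "standard")
    trace <- rbind(trace, data.frame(Q = Q, status = conf$status,
                                     margin = max(conf$margins)))
    if (conf$status == "feasible") {
      out <- finish_design(rho, conf, trace, fm, C, Q = Q)
      out$rho0 <- NA_real_
      if (report_rho0) {
        mr <- min_rho(fm, C, H, R, bracket = c(0, max(2 * rho, 1)),
                      eps = eps, deflate = deflate)
        out$rho0 <- mr$rho0
      }
      return(out)
    }
  }
  structure(list(feasible = FALSE, Q = NA_real_, rho = rho,
                 rho0 = NA_real_, P = NULL, trace = trace,
                 message = sprintf(
                   "no feasible Q on the grid at rho = %g (best margin %.3g)",
                   rho, min(trace$margin))),
            class = "design_result")
}

#' Robustness decomposition of a certified design
#'
#' Splits each rule's criterion into the three symmetric terms of the
#' local robustness balance: intrinsic robustness `Psi' P Psi` (cost of
#' tolerating parameter fluctuations), extrinsic robustness
#' `R + P H H' P / rho0^2` (cost of filtering environmental noise), and
#' synchronization robustness `-(P Phi + Phi' P)` (contraction provided
#' by the coupled dynamics). The criterion holds when synchronization
#' robustness dominates the other two; the reported margin is the minimum
#' eigenvalue of their difference.
#'
#' @param P certificate matrix (decision dimension of the problem)
#' @param prob the [assemble_lmi_blocks()] problem it certifies
#' @return list (one entry per constraint) of lists with `intrinsic`,
#'   `extrinsic`, `sync`, `margin`
#' @export
robustness_decomposition <- function(P, prob) {
  if (max(abs(P - t(P))) > 1e-8)
    qs_stop("'P' must be symmetric")
  rho0 <- prob$rho
  lapply(prob$constraints, function(cn) {
    intr <- t(cn$Psi) %*% P %*% cn$Psi
    extr <- cn$R + (P %*% cn$H %*% t(cn$H) %*% P) / rho0^2
    sync <- -(P %*% cn$Phi + t(cn$Phi) %*% P)
    mg <- min(eigen((sync - intr - extr +
                       t(sync - intr - extr)) / 2,
                    symmetric = TRUE, only.values = TRUE)$values)
    list(intrinsic = intr, extrinsic = extr, sync = sync, margin = mg)
  })
}

#' Hamilton-Jacobi inequality residual under a quadratic storage function
#'
#' Evaluates the left-hand side of the robust-synchronization HJI at one
#' population state, with `V(e) = e' P e`:
#' `e' R e + 2 e' P [F + (C x I) G] + e' P H H' P e / rho^2 +
#' sum_i b_i' P b_i`, where `b_i` is cell i's stacked intrinsic-noise
#' column `f_W(x_i) - f_W(s) + sum_j c_ij (g_W(x_j) - g_W(s))`. Negative
#' values certify the criterion at that state.
#'
#' @param e stacked error vector (length `7N`, cell-major)
#' @param x population state: `7 x N` matrix
#' @param s reference state (length 7)
#' @param P certificate: `7 x 7` (expanded as `I_N (x) P`) or full
#'   `7N x 7N`
#' @param p [repressilator_params()]
#' @param d_amp [fluctuation_amplitudes()]
#' @param C coupling matrix
#' @param H per-cell noise column (length 7; default all-ones)
#' @param R weighting (`NULL` identity, `7 x 7` block, or full)
#' @param rho filtering level
#' @param linear optional linear instance: a list with blocks `A`, `B`,
#'   `A_W`, `B_W` of any common dimension `m`. When given, the drift and
#'   noise columns are the linear forms `A e_i + B sum_j c_ij e_j` and
#'   `A_W e_i + B_W sum_j c_ij e_j` (then `x`, `s`, `p`, `d_amp` may be
#'   `NULL`), and the residual equals the quadratic form of the Schur
#'   complement of the corresponding LMI block exactly
#' @return scalar residual
#' @export
hji_residual <- function(e, x, s, P, p, d_amp, C, H = NULL, R = NULL,
                         rho, linear = NULL) {
  N <- nrow(C)
  m <- if (is.null(linear)) .qs_nspecies else nrow(linear$A)
  if (length(e) != N * m) qs_stop("'e' must have length m * N")
  if (is.null(H)) H <- rep(1, m)
  blockP <- all(dim(P) == c(m, m))
  if (!blockP && !all(dim(P) == c(N * m, N * m)))
    qs_stop("'P' must be m x m or mN x mN")

  Em0 <- matrix(e, m, N)
  drift <- matrix(0, m, N)   # F + (C x I) G, columnwise
  noise <- matrix(0, m, N)   # cell i's dw_i coefficient b_i
  if (is.null(linear)) {
    X <- matrix(x, m, N)
    s <- validate_cell_state(s, allow_negative = TRUE)
    fs <- drift_single_cell(pmax(s, 0), p)
    fWs <- intrinsic_noise_field(pmax(s, 0), d_amp, p)
    gX <- X[7, ]; gs <- s[[7]]
    gWX <- (d_amp$d_eta_s / p$eta_s) * gX
    gWs <- (d_amp$d_eta_s / p$eta_s) * gs
    for (i in seq_len(N)) {
      xi <- pmax(X[, i], 0)
      drift[, i] <- drift_single_cell(xi, p) - fs
      drift[7, i] <- drift[7, i] + sum(C[i, ] * (gX - gs))
      noise[, i] <- intrinsic_noise_field(xi, d_amp, p) - fWs
      noise[7, i] <- noise[7, i] + sum(C[i, ] * (gWX - gWs))
    }
  } else {
    CE <- Em0 %*% t(unclass(C))
    drift <- linear$A %*% Em0 + linear$B %*% CE
    noise <- linear$A_W %*% Em0 + linear$B_W %*% CE
  }

  Em <- matrix(e, m, N)
  Pe <- if (blockP) as.vector(P %*% Em) else as.vector(P %*% e)
  term_R <- quad_vec(e, R, N, m)
  term_drift <- 2 * sum(Pe * as.vector(drift))
  # H' P e per cell (one scalar disturbance channel per cell)
  PeM <- matrix(Pe, m, N)
  w <- colSums(H * PeM)
  term_H <- sum(w^2) / rho^2
  term_noise <- if (blockP) {
    sum(vapply(seq_len(N), function(i)
      sum(noise[, i] * (P %*% noise[, i])), 0))
  } else {
    sum(vapply(seq_len(N), function(i) {
      b <- numeric(N * m)
      b[(i - 1L) * m + seq_len(m)] <- noise[, i]
      sum(b * (P %*% b))
    }, 0))
  }
  term_R + term_drift + term_H + term_noise
}

#' Thin kinetic-parameter co-design wrapper
#'
#' Evaluates the achieved optimal filtering level over a small grid of
#' candidate kinetic-parameter settings, rebuilding the fuzzy rules per
#' candidate, and returns the best candidate with the full trace. A
#' candidate whose LMIs are infeasible at the bracket top is recorded as
#' `NA` (unsynchronizable) rather than dropped.
#'
#' @param p base [repressilator_params()]
#' @param d_amp [fluctuation_amplitudes()]
#' @param grid data frame; each row is a candidate, columns name the
#'   parameters to override (at most 3)
#' @param C coupling matrix used for every candidate
#' @param H,R,eps,bracket,tol as in [min_rho()]
#' @param L,method fuzzy settings
#' @param deflate see [assemble_lmi_blocks()]
#' @return list with `best` (row index or NA), `params` (best parameter
#'   set), `rho0`, `trace` (grid with an appended `rho0` column)
#' @export
tune_kinetic_parameters <- function(p, d_amp, grid, C, H = NULL, R = NULL,
                                    eps = 1e-6, bracket = c(0, 64),
                                    tol = 1e-3, L = 8L,
                                    method = "limit-cycle",
                                    deflate = TRUE) {
  if (!is.data.frame(grid) || nrow(grid) < 1L)
    qs_stop("'grid' must be a nonempty data frame of candidates")
  if (ncol(grid) > 3L)
    qs_stop("co-design supports at most 3 parameters (thin wrapper)")
  bad <- setdiff(names(grid), names(p))
  if (length(bad)) qs_stop("unknown parameter(s): ",
                           paste(bad, collapse = ", "))
  rho0s <- rep(NA_real_, nrow(grid))
  for (r in seq_len(nrow(grid))) {
    pr <- do.call(repressilator_params, modifyList(unclass(p),
                                                   as.list(grid[r, ,
                                                   drop = FALSE])))
    res <- tryCatch({
      fm <- build_fuzzy_model(pr, d_amp, L, method)
      min_rho(fm, C, H, R, bracket = bracket, tol = tol, eps = eps,
              deflate = deflate)
    }, error = function(e) NULL)
    if (!is.null(res)) rho0s[r] <- res$rho0
  }
  trace <- cbind(grid, rho0 = rho0s)
  if (all(is.na(rho0s)))
    return(list(best = NA_integer_, params = NULL, rho0 = NA_real_,
                trace = trace,
                message = "all candidates unsynchronizable under this model"))
  best <- which.min(rho0s)
  bestp <- do.call(repressilator_params, modifyList(unclass(p),
                                                    as.list(grid[best, ,
                                                    drop = FALSE])))
  list(best = best, params = bestp, rho0 = rho0s[best], trace = trace)
}
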