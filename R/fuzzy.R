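# Takagi-Sugeno fuzzy approximation of the synchronization-error
# dynamics: operating points, analytic local linearizations, triangular
# memberships, and the interpolated error drift.
#
# Premise variables are fixed to (x_A, x_B, x_C, x_S): the only state
# components that enter the drift nonlinearly (Hill repression terms and
# the saturating autoinducer activation).

#' Local linearization at an operating point
#'
#' Analytic Jacobians of the drift, the coupling function, the intrinsic
#' noise field and the coupling-noise function at one state. `B` is the
#' elementary matrix with a single 1 at (7,7) at every point (the coupling
#' is linear in x_S), and `B_W` scales it by `d_eta_s / eta_s`.
#'
#' @param point an operating point: either a length-7 state or a list with
#'   a `state` entry
#' @param p [repressilator_params()]
#' @param d [fluctuation_amplitudes()]
#' @return list with matrices `A`, `B`, `A_W`, `B_W` (all 7 x 7)
#' @export
linearize_at <- function(point, p, d) {
  x <- if (is.list(point)) point$state else point
  A <- drift_jacobian(x, p)
  A_W <- intrinsic_noise_jacobian(x, d, p)
  if (any(!is.finite(A)) || any(!is.finite(A_W)))
    qs_stop("non-finite Jacobian entry at the operating point")
  B <- coupling_jacobian()
  list(A = A, B = B, A_W = A_W, B_W = (d$d_eta_s / p$eta_s) * B)
}

#' Select fuzzy operating points
#'
#' `"limit-cycle"` integrates the noise-free single cell to its periodic
#' attractor and samples `L` states at equal time spacing over one period
#' (starting at a peak of x_a); `"grid"` places `L` points on a lattice
#' over the premise ranges observed on the attractor, holding the
#' non-premise states at their attractor means. Deterministic given the
#' arguments; `seed` is recorded for provenance.
#'
#' @param p [repressilator_params()]
#' @param L number of rules (>= 2)
#' @param method `"limit-cycle"` or `"grid"`
#' @param seed recorded in the provenance (selection itself is
#'   deterministic)
#' @return list of operating points, each `list(state, z)` with `z` the
#'   premise values `(x_A, x_B, x_C, x_S)`
#' @export
select_operating_points <- function(p, L = 8L,
                                    method = c("limit-cycle", "grid"),
                                    seed = 1L) {
  method <- match.arg(method)
  if (L < 2) qs_stop("'L' must be >= 2")
  lc <- find_limit_cycle(p)
  K <- nrow(lc$states)
  if (method == "limit-cycle") {
    idx <- unique(round(seq(1L, K, length.out = L + 1L)))[seq_len(L)]
    pts <- lapply(idx, function(i) {
      st <- lc$states[i, ]
      list(state = st, z = st[.qs_premise_idx], phase = (i - 1) / K)
    })
    # per-rule membership support: the observed premise excursion over the
    # two cycle segments adjacent to the rule's sample (plus slack), so
    # that every on-attractor premise value is covered by the rules of its
    # segment even where the state coordinates are non-monotone in phase
    Zc <- lc$states[, .qs_premise_idx, drop = FALSE]
    slack <- 0.05 * (apply(Zc, 2, max) - apply(Zc, 2, min))
    support <- array(NA_real_, c(L, length(.qs_premise_idx), 2))
    bounds <- c(idx, K + idx[1])
    for (k in seq_len(L)) {
      lo <- bounds[if (k == 1L) L else k - 1L] - (if (k == 1L) K else 0L)
      hi <- bounds[k + 1L]
      seg <- ((seq(lo, hi) - 1L) %% K) + 1L
      support[k, , 1] <- apply(Zc[seg, , drop = FALSE], 2, min) - slack
      support[k, , 2] <- apply(Zc[seg, , drop = FALSE], 2, max) + slack
    }
    attr(pts, "support") <- support
  } else {
    rng <- apply(lc$states[, .qs_premise_idx, drop = FALSE], 2, range)
    base <- colMeans(lc$states)
    # evenly spaced points along each premise range, interleaved so L
    # points cover the 4-dimensional box diagonally
    frac <- seq(0, 1, length.out = L)
    pts <- lapply(seq_len(L), function(k) {
      st <- base
      st[.qs_premise_idx] <- rng[1, ] + frac[k] * (rng[2, ] - rng[1, ])
      list(state = st, z = st[.qs_premise_idx], phase = NA_real_)
    })
  }
  attr(pts, "method") <- method
  attr(pts, "seed") <- seed
  attr(pts, "period") <- lc$period
  pts
}

#' Triangular membership specification
#'
#' One triangle per rule per premise variable: the triangle of rule `k`
#' for variable `j` peaks at that rule's premise coordinate and falls
#' linearly to zero at its neighbours' coordinates. Neighbours are taken
#' in rule order when the rules sample a closed orbit (`adjacency =
#' "cyclic"`, with a safety margin so the attractor tube stays covered),
#' or in sorted coordinate order for scattered/grid rules
#' (`adjacency = "sorted"`). End triangles are shoulders (clamped).
#'
#' @param points_z `L x g` matrix of rule premise coordinates (or a list
#'   of operating points)
#' @param adjacency `"cyclic"` or `"sorted"`
#' @param margin relative widening of cyclic supports (fraction of the
#'   per-variable range), used when no explicit `support` is available
#' @param support optional `[L, g, 2]` array of per-rule per-variable
#'   support bounds (taken from the attractor segments by
#'   [select_operating_points()]); overrides neighbour-based supports
#' @return object of class `membership_spec` with fields `L`, `g`,
#'   `tri` (array `[L, g, 3]` of left/peak/right; `+-Inf` marks shoulders)
#' @export
membership_spec <- function(points_z, adjacency = c("sorted", "cyclic"),
                            margin = 0.1, support = NULL) {
  adjacency <- match.arg(adjacency)
  if (is.list(points_z) && !is.matrix(points_z)) {
    if (is.null(support)) support <- attr(points_z, "support")
    points_z <- do.call(rbind, lapply(points_z, function(pt) pt$z))
  }
  Z <- as.matrix(points_z)
  L <- nrow(Z); g <- ncol(Z)
  if (L < 1) qs_stop("need at least one rule")
  tri <- array(NA_real_, c(L, g, 3))
  for (j in seq_len(g)) {
    zj <- Z[, j]
    rngj <- diff(range(zj))
    if (adjacency == "sorted") {
      ord <- order(zj)
      for (pos in seq_len(L)) {
        k <- ord[pos]
        lft <- if (pos == 1L) -Inf else zj[ord[pos - 1L]]
        rgt <- if (pos == L) Inf else zj[ord[pos + 1L]]
        tri[k, j, ] <- c(lft, zj[k], rgt)
      }
    } else if (!is.null(support)) {
      for (k in seq_len(L))
        tri[k, j, ] <- c(min(support[k, j, 1], zj[k]), zj[k],
                         max(support[k, j, 2], zj[k]))
    } else {
      m <- margin * rngj
      for (k in seq_len(L)) {
        prv <- zj[if (k == 1L) L else k - 1L]
        nxt <- zj[if (k == L) 1L else k + 1L]
        tri[k, j, ] <- c(min(prv, zj[k]) - m, zj[k], max(nxt, zj[k]) + m)
      }
    }
    # degenerate (all rules share this coordinate): constant membership
    zero <- tri[, j, 3] - tri[, j, 1] <= 0
    if (any(zero & is.finite(tri[, j, 1]) & is.finite(tri[, j, 3])))
      tri[zero, j, c(1, 3)] <- cbind(-Inf, Inf)[rep(1, sum(zero)), ]
  }
  structure(list(L = L, g = g, tri = tri, peaks = Z, adjacency = adjacency),
            class = "membership_spec")
}

# single triangle evaluation with shoulder (+-Inf) handling
tri_eval <- function(z, lft, pk, rgt) {
  if (z <= pk) {
    if (!is.finite(lft)) 1 else if (z <= lft) 0 else (z - lft) / (pk - lft)
  } else {
    if (!is.finite(rgt)) 1 else if (z >= rgt) 0 else (rgt - z) / (rgt - pk)
  }
}

#' Normalized fuzzy membership weights
#'
#' Products of per-variable triangular memberships, normalized to sum to
#' one. Premise values outside the breakpoint range are clamped to the
#' nearest peak coordinate before evaluation.
#'
#' @param z premise vector (length `g`)
#' @param spec a [membership_spec()]
#' @return numeric length-L weight vector (nonnegative, sums to 1)
#' @export
membership_weights <- function(z, spec) {
  if (length(z) != spec$g) qs_stop("premise vector has wrong length")
  if (any(!is.finite(z))) qs_stop("premise vector must be finite")
  z <- pmin(pmax(z, apply(spec$peaks, 2, min)), apply(spec$peaks, 2, max))
  w <- vapply(seq_len(spec$L), function(k) {
    prod(vapply(seq_len(spec$g), function(j)
      tri_eval(z[j], spec$tri[k, j, 1], spec$tri[k, j, 2],
               spec$tri[k, j, 3]), 0))
  }, 0)
  s <- sum(w)
  if (s <= 0)
    qs_stop("all raw membership products are zero after clamping; the ",
            "membership specification does not cover this premise value")
  w / s
}

#' Build the fuzzy model of the error dynamics
#'
#' Selects operating points, linearizes analytically at each, and packs
#' the rule blocks with the membership definitions. The local models share
#' one coupling Jacobian `B` (and its fluctuation scaling `B_W`), so the
#' stacked error system has the Kronecker form
#' `sum_k mu_k [ (I_N x A_k) + (C x B_k) ] e`.
#'
#' @param p [repressilator_params()]
#' @param d [fluctuation_amplitudes()]
#' @param L number of rules
#' @param method operating-point selection method
#' @param seed provenance seed
#' @return object of class `fuzzy_model`
#' @export
build_fuzzy_model <- function(p, d, L = 8L, method = "limit-cycle",
                              seed = 1L) {
  pts <- select_operating_points(p, L, method, seed)
  rules <- lapply(pts, linearize_at, p = p, d = d)
  spec <- membership_spec(pts, adjacency = if (identical(method,
    "limit-cycle")) "cyclic" else "sorted")
  structure(list(rules = rules, membership = spec, points = pts,
                 params = p, amplitudes = d,
                 provenance = list(method = method, seed = seed,
                                   L = length(pts),
                                   period = attr(pts, "period"))),
            class = "fuzzy_model")
}

#' @export
print.fuzzy_model <- function(x, ...) {
  cat(sprintf("<fuzzy_model> L = %d rules (%s), premise (x_A, x_B, x_C, x_S)\n",
              length(x$rules), x$provenance$method))
  invisible(x)
}

#' Interpolated fuzzy drift of the stacked error system
#'
#' For each cell `i`, `sum_k mu_k(z_i) [ A_k e_i + B_k sum_j c_ij e_j ]`.
#' With a single rule this reduces to the Kronecker-structured linear
#' system `(I_N x A_1 + C x B_1) e`.
#'
#' @param e stacked error vector, length `7 N` (cell-major, species
#'   fastest)
#' @param z premise values: a single length-g vector shared by all cells,
#'   or an `N x g` matrix of per-cell premises
#' @param model a [build_fuzzy_model()] result (or any list with `rules`
#'   and `membership`)
#' @param C coupling matrix (`N x N`)
#' @return stacked rate vector, length `7 N`
#' @export
fuzzy_error_drift <- function(e, z, model, C) {
  N <- nrow(C)
  m <- .qs_nspecies
  if (length(e) != N * m)
    qs_stop("'e' must have length 7 * N = ", N * m)
  Zm <- if (is.matrix(z)) z else matrix(z, N, length(z), byrow = TRUE)
  if (nrow(Zm) != N) qs_stop("per-cell premise matrix must have N rows")
  E <- matrix(e, m, N)             # columns = cells
  CE <- E %*% t(C)                 # column i = sum_j c_ij e_j
  out <- matrix(0, m, N)
  for (i in seq_len(N)) {
    w <- membership_weights(Zm[i, ], model$membership)
    for (k in seq_along(model$rules)) {
      if (w[k] == 0) next
      rk <- model$rules[[k]]
      out[, i] <- out[, i] + w[k] * (rk$A %*% E[, i] + rk$B %*% CE[, i])
    }
  }
  as.vector(out)
}

#' Audit the fuzzy approximation against the nonlinear error drift
#'
#' Samples states on the attractor and random errors of bounded norm,
#' and compares the interpolated fuzzy drift with the true nonlinear
#' error drift `f(x_i) - f(s) + sum_j c_ij (g(x_j) - g(s))`. The premise
#' is evaluated at the reference state (the same local model serves all
#' cells). Returns the distribution of relative discrepancies; the mean
#' is the empirical fuzzy-approximation error that the design treats as
#' additional external disturbance.
#'
#' @param model [build_fuzzy_model()]
#' @param C coupling matrix
#' @param n_samples number of sampled (state, error) pairs
#' @param e_norm error-ball radius per cell
#' @param seed RNG seed
#' @return list with `mean_rel`, `median_rel`, `q90_rel`, `rel` (vector)
#' @export
fuzzy_approximation_audit <- function(model, C, n_samples = 200L,
                                      e_norm = 0.5, seed = 1L) {
  p <- model$params
  N <- nrow(C)
  lc <- find_limit_cycle(p)
  set.seed(seed)
  rel <- numeric(n_samples)
  for (t in seq_len(n_samples)) {
    s <- lc$states[sample.int(nrow(lc$states), 1L), ]
    Emat <- matrix(rnorm(.qs_nspecies * N), .qs_nspecies, N)
    Emat <- Emat / rep(pmax(1e-12, sqrt(colSums(Emat^2))),
                       each = .qs_nspecies) *
      rep(runif(N, 0, e_norm), each = .qs_nspecies)
    X <- pmax(Emat + s, 0)
    Emat <- X - s
    true <- matrix(0, .qs_nspecies, N)
    gX <- X[7, ]; gs <- s[[7]]
    fs <- drift_single_cell(s, p)
    for (i in seq_len(N)) {
      true[, i] <- drift_single_cell(X[, i], p) - fs
      true[7, i] <- true[7, i] + sum(C[i, ] * (gX - gs))
    }
    fz <- fuzzy_error_drift(as.vector(Emat), s[.qs_premise_idx], model, C)
    rel[t] <- sqrt(sum((fz - as.vector(true))^2)) /
      max(1e-12, sqrt(sum(true^2)))
  }
  list(mean_rel = mean(rel), median_rel = stats::median(rel),
       q90_rel = unname(quantile(rel, 0.9)), rel = rel)
}

#' Serialize a fuzzy model to JSON
#' @param model a [build_fuzzy_model()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fuzzy_model <- function(model, path) {
  obj <- list(
    L = length(model$rules),
    rules = lapply(model$rules, function(r)
      lapply(r, function(M) as.vector(t(M)))),  # row-major blocks
    membership = list(tri = as.vector(model$membership$tri),
                      peaks = model$membership$peaks,
                      adjacency = model$membership$adjacency),
    provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
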