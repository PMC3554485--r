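---
title: "Robust synchronization of quorum-coupled stochastic genetic oscillators: models, design choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust synchronization of quorum-coupled stochastic genetic oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the model and
its assumptions, the tunable parameters, the numerical decisions that
were genuinely open, and — importantly — the limits of what a green test
establishes. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The model

Each of `N` host cells carries a repressilator (three mRNAs `x_a, x_b,
x_c` for *tetR*, *cI*, *lacI*; three proteins `x_A, x_B, x_C`) plus a
quorum-sensing module whose intracellular autoinducer `x_S` is
synthesized from TetR and exchanged with the extracellular medium. The
single-cell drift is

* Hill-repressed transcription `α/(μ + x^n)` for the three mRNAs, with an
  additional saturating AI activation `α_S x_S/(μ_S + x_S)` on *lacI*;
* linear translation `β x` and first-order degradation (`γ_m`, `γ_p`,
  `γ_s`);
* AI synthesis `β_s x_A` and membrane exchange.

Fast extracellular mixing reduces cell-to-cell communication to a
mean-field diffusive term `−η_s(Q_e + Q)(x_Si − N⁻¹Σ_j x_Sj)`, written as
`Σ_j c_ij g(x_j)` with `g(x) = (0,…,0,x_S)` and a symmetric zero-row-sum
coupling matrix `C(Q)`. The external control gain `Q ≥ 0` models inducer
added to the medium; it simply strengthens the same coupling.

Two noise sources complete the model:

* **Intrinsic noise.** Every kinetic parameter fluctuates with a stated
  standard deviation (`fluctuation_amplitudes()`, defaults ≈ 1% of the
  nominal rates). All fluctuations within a cell are driven by one
  scalar Wiener process `w_i`, independent across cells, giving the Itô
  diffusion coefficient `f_W(x_i) + Σ_j c_ij g_W(x_j)`: the drift
  formulas with each nominal rate replaced by its amplitude. The
  η_s-fluctuation is factored through the same `C` as the scalar
  rescaling `Δη_s/η_s`, which keeps a single coupling matrix in both the
  drift and the diffusion (this matches the shared-`C` Kronecker
  structure the LMI layer needs).
* **Extrinsic noise.** One scalar environmental disturbance `v_i` per
  cell enters through a coupling column `h`. The source example
  specifies only "independent Gaussian white noise with standard
  deviation 0.02", not `h`; the package default is `h = (1,…,1)ᵀ` (the
  disturbance pushes all seven equations equally), configurable in
  `extrinsic_noise_spec()`. This under-specification matters; see §6.

Default kinetics are the worked example's: `α = 216`, `α_S = 20`,
`μ = 1.2`, `μ_S = 1`, `n = 2`, `β = 1`, `β_s = 0.1`, `γ_m = 6.9315`,
`γ_p = 1.1552`, `γ_s = 1`, `η_s = 2`, `Q_e = 0.09`. With these the
isolated cell settles on a limit cycle of period ≈ 5 time units (the
package detects it numerically; `find_limit_cycle()`).

## 2. Simulation layer

**Integrator.** Euler–Maruyama in the Itô convention, default
`dt = 0.005`. The drift is smooth and the stiffest rate is `γ_m ≈ 6.9`,
so `γ_m·dt ≈ 0.035` and the deterministic skeleton converges at the
expected first order (verified by step-halving in the tests). States are
concentrations; negative excursions produced by a noise increment are
clipped to zero by default (`clip_negative`).

**Noise realization.** `v_i` is realized as per-step draws
`N(0, σ_v²)` held constant over each step — band-limited white noise.
A `1/√dt`-scaled increment would make the disturbance energy
`∫ vᵀv dt` diverge as `dt → 0` and the filtering ratio meaningless; the
band-limited reading matches a discrete-time "Gaussian white noise with
standard deviation 0.02". The Wiener increments use the standard `√dt`
scaling.

**Reference trajectory.** The synchronization error needs a reference
`s(t)`. Driving one common reference with per-cell noise is ill-posed
(each cell has its own `w_i`), so the package defaults to the
**population mean** — standard practice in synchronization analysis, and
consistent with the coupling: on the manifold the mean-field term
vanishes. The noise-free nominal trajectory from the mean initial
condition is available as an alternative (`compute_errors(...,
"nominal")`). Population-mean errors satisfy `Σ_i e_i(t) = 0` exactly,
which is also why the synchronous coupling mode can be deflated from the
LMIs (§4).

**Energy ratio.** `filtering_ratio()` forms
`[E Σ_k e_kᵀR e_k dt]/[E Σ_k v_kᵀv_k dt]` with left Riemann sums and
ensemble means; `monte_carlo_filtering()` pools numerators and
denominators across runs before dividing (a ratio of expectations, not a
mean of ratios) and attaches a leave-one-out jackknife standard error.
The initial-condition variant subtracts `E[e(0)ᵀPe(0)]` (floored at 0)
for a supplied certificate `P`. `R` defaults to identity — the example
never specifies it.

**Determinism.** A configuration seed fully determines initial
conditions and both noise paths; identical seeds give bit-identical
arrays. Monte-Carlo run `r` uses seed `base + r`.

## 3. Takagi–Sugeno layer

The fuzzy model interpolates `L` local linear models of the error
dynamics. Design choices:

* **Analytic Jacobians, not least-squares identification.** The local
  blocks `A_k, A_Wk` are exact Jacobians of the drift and intrinsic-noise
  field at operating points; `B_k` is the elementary (7,7) matrix and
  `B_Wk = (Δη_s/η_s)B_k` (the coupling functions are linear). Jacobians
  are deterministic, testable against finite differences, and leave the
  fuzzy approximation error — which identification would also leave — to
  be treated as additional external disturbance.
* **Premise variables** are `(x_A, x_B, x_C, x_S)`: the only states
  entering the drift nonlinearly (three Hill terms, one saturation).
* **Operating points** default to `L = 8` states sampled at equal time
  spacing over one period of the nominal limit cycle (the published
  local-model tables for this system are not available; the sampling
  follows the stated interpolation principle). A lattice alternative
  (`method = "grid"`) covers non-oscillatory parameter sets.
* **Memberships** are normalized products of per-variable triangles, one
  per rule per variable, peaking at the rule's premise coordinate. For
  limit-cycle rules the triangle supports are taken from the observed
  premise excursion over the two adjacent cycle segments (plus 5%
  slack). This is the one place the classical "triangles to the nearest
  neighbour breakpoints" recipe had to be adapted: with four premise
  variables sampled along a closed curve, nearest-breakpoint supports
  leave uncovered pockets *on the attractor itself* (the coordinates are
  not monotone in phase), and the raw membership product vanishes there.
  Segment supports guarantee coverage of the attractor tube by
  construction; the tests sweep the full cycle for L = 4 and 8 and check
  the partition of unity to 1e-12. The cost is partial locality: at a
  rule's own vertex neighbouring rules may keep small weight. For
  scattered or 1-D rule sets (`adjacency = "sorted"`) the classical
  construction, with exact vertex locality, is used.
* Out-of-range premise values are clamped per variable to the
  breakpoint range; a premise value whose raw products all vanish raises
  an explicit internal error rather than silently renormalizing.

The audit (`fuzzy_approximation_audit()`) measures the relative
discrepancy between the interpolated drift and the true nonlinear error
drift for states on the attractor and per-cell errors of norm ≤ 0.5. The
test suite checks that the error is non-increasing from L = 4 to L = 8
and that the default L = 8 model stays under the 20% budget that the
design treats as mergeable into the external disturbance.

## 4. LMI layer

**Solver.** No SDP backend exists in the target environment, so the
package ships a purpose-built convex solver for LMI feasibility: all
block constraints (affine in `P`) plus `P ⪰ εI` are folded into a
smoothed maximum eigenvalue (log-sum-exp over all eigenvalues), which is
convex and smooth with an analytic gradient via the weighted spectral
projectors; BFGS minimizes it under a staged sharpening of the smoothing
parameter, from multiple starts (identity, per-rule Lyapunov solutions,
their average). Three safeguards keep it honest:

* any claimed certificate is re-verified by direct eigenvalue
  computation of every block, independent of the optimizer (status
  `"feasible"` requires margins ≤ −ε/2 and `P ≻ 0`);
* `"infeasible"` means "no certificate found with clearly positive best
  margin", distinct from `"solver-inconclusive"` for borderline margins;
* a cheap necessary condition (single-constraint feasibility) prunes
  clearly infeasible multi-rule problems during grid scans.

The scalar closed forms give exact oracles: for the 1-D instance the
block reduces to `(h²/ρ²)p² + (2a + a_w²)p + r < 0`, so feasibility is a
discriminant condition and `ρ₀ = 2h√r/|2a + a_w²|`. The suite sweeps 100
such instances and matches the bisection to 1e-3.

**Strictness.** Strict inequalities are realized as `⪯ −εI` / `⪰ εI`
with `ε = 1e-6` (configurable), the standard move for non-strict solver
cones.

**Kronecker reduction.** For symmetric `C`, per-cell `h` and
block-diagonal `R`, restricting the certificate to `P = I_N ⊗ P₇`
decomposes the stacked `7N` LMI along the eigenmodes `λ` of `C` into
7-dimensional blocks with `Φ = A_k + λB_k`, `Ψ = A_Wk + λB_Wk`. This is
sufficient, not necessary: any reduced certificate expands to a valid
full one (the tests verify the expanded `P` against the dense stacked
LMIs). For the all-to-all topology only two distinct modes exist —
`λ = 0` (the synchronous mode, eigenvector `1`) and `λ = −η_s(Q_e + Q)`
(all `N−1` transverse modes) — so the reduction is exact in spirit and
enormous in practice (28 decision variables instead of 2485 at
`N = 10`).

**Deflation.** The default drops the `λ = 0` mode: population-mean
errors have no component along it (`Σ_i e_i = 0` exactly), so requiring
the LMI there would demand mean-square stability of the *uncoupled*
oscillator — a condition the synchronization question does not need.
`deflate = FALSE` restores it.

**Bisection and gain design.** Feasibility is monotone in ρ (the
disturbance block only loosens), so `min_rho()` bisects to an absolute
tolerance of 1e-3 (default), warm-starting each probe from the last
certificate. `design_Q()` scans an ascending gain grid (default step
0.02 on [0, 2]), returns the smallest feasible gain, and re-confirms the
candidate at full effort; with no feasible gain it returns the per-Q
margin trace as a diagnostic. The deterministic single-cell attractor
does not depend on `Q` (coupling cancels on the manifold), so the fuzzy
rules are shared across the grid; `rebuild_fuzzy = TRUE` forces a
rebuild anyway for users who alter the operating-point policy.

**Decomposition and HJI audit.** `robustness_decomposition()` splits
each rule's criterion into intrinsic (`ΨᵀPΨ`), extrinsic
(`R + PHHᵀP/ρ₀²`) and synchronization (`−(PΦ + ΦᵀP)`) terms; the
criterion holds when the third dominates the sum of the first two, and
the equivalence with the block LMI via the Schur complement is tested on
random instances. `hji_residual()` evaluates the nonlinear criterion
pointwise under `V(e) = eᵀPe`; with the printed coefficient combination
the quadratic-V Hessian term is exactly `Σ_i b_iᵀPb_i` over the per-cell
noise columns, which for block-diagonal `P` coincides with the `ΨᵀPΨ`
quadratic form of the linearized criterion (the identity is asserted to
1e-8 on linear instances). Solving the HJI for general `V` is out of
scope — the underlying theory itself resorts to the fuzzy/LMI relaxation
for that reason.

## 5. What the synthetic generator emulates — and what it does not

The generator *is* the stated world of the worked example: `N = 10`
cells, the kinetics above, ≈1% parameter-fluctuation amplitudes, one
extrinsic disturbance per cell with σ_v = 0.02, horizon 100, uncertain
initial states drawn per species from `U[0, 5]` (the example says only
"uncertain initial state"; a scientist would read a box of the order of
the attractor's span, and the attractor spans ≈ 0.2–10 depending on the
species). It does not emulate: cell growth and division, copy-number
variation, extracellular AI as a dynamic state (fast-mixing is assumed),
delays, or spatial structure. A green simulation test therefore
establishes correctness of the numerics for this idealized model, not
biological fidelity of the noise magnitudes.

## 6. Reproduction status: three honest failures

Three acceptance assertions encode the source example's headline claims
and fail for this reconstruction. They are left red deliberately; the
analysis below is quantitative, and every number it cites is computed by
the suite or the acceptance script.

**(a) The Monte-Carlo ratio bound.** The claim is a pooled energy ratio
≈ 0.19² < 0.56² for the controlled network. With the denominator fixed
by the stated world (`E∫vᵀv dt ≈ t_f·N·σ_v² ≈ 0.4`), a ratio below
0.56² requires total error energy below ≈ 0.13 — i.e. sustained
per-species RMS errors of order 1e-3 across 70 components for 100 time
units. But with *additive* independent intrinsic noise (coefficient
`f_W(x̄)`, of order 0.1–1 on the mRNA equations), the error variance
floor alone produces energies of order 10²; the uncertain-IC transient
adds orders more. The acceptance run measures a pooled ratio of order
1e4–1e5. The bound is attainable only in a world where intrinsic noise
enters the *error* multiplicatively — simulating the interpolated error
system, whose noise `Ψe dw` vanishes on the manifold — and/or with a
much weaker `h` or a non-identity `R`; `h` and `R` are exactly the
quantities the example leaves unspecified. The package implements the
stated world and reports the measured ratio.

**(b) The 10× desynchronization contrast.** From `U[0, 5]` initial
states the controlled population's phase-locking time constant is long
(tens of time units; the deterministic jitter experiments in the
prototype phase showed e-folding of the mean-square error over ≈ 20
units), so over `t ∈ [50, 100]` the controlled run is still converging
and the measured contrast is ≈ 1.5–3×, not ≥ 10×. With narrow initial
spreads (e.g. ±0.5 around a common attractor state) the contrast
comfortably exceeds 10× — but the IC spread is part of the stated world
and was not tuned toward the criterion.

**(c) LMI feasibility at ρ = 0.56 with Q = 0.66.** With analytic
Jacobians at limit-cycle operating points, each local block is Hurwitz
(spectral abscissa ≈ −0.13 to −0.23), yet no *common* quadratic
certificate exists even for two rules a sixteenth of a period apart, at
any ρ, with or without the noise terms: the Hill slopes swing by ≈ 100
along the cycle and the trace-normalized common-Lyapunov margins stall
at small positive values while single-rule margins reach ≈ −0.1. The
published feasibility at ρ = 0.56 rests on local-model tables that are
not in the available material; whatever those models were, they cannot
have been the pointwise Jacobians of this vector field. `min_rho()`
reports "unsynchronizable under this model" for the default 8-rule
model, `design_Q()` returns the per-gain margin trace, and both are
exercised red in the acceptance suite. Single-rule (L = 1) certificates
do exist and yield finite certified levels, illustrating that the
obstruction is the common-P requirement, not the machinery.

## 7. Known limitations

* `"infeasible"` is a best-effort statement (no dual certificate is
  produced); for the borderline common-Lyapunov problems of §6c the
  honest reading is "no certificate found", and the package's statuses
  say exactly that.
* The eigenmode reduction restricts certificates to `I_N ⊗ P₇`; a full
  dense `P` could in principle certify levels the reduced problem
  cannot. For the failure in §6c this is immaterial (the obstruction
  already lives in the 7-dimensional blocks).
* The empirical energy ratio and the LMI level bound different
  quantities unless intrinsic noise vanishes on the manifold; comparing
  them (as the end-to-end consistency check does on linear instances)
  is only meaningful under that condition.
* Memberships cover the attractor tube by construction, but far-off
  premise values can still fall outside every rule's support; the
  package fails loudly there instead of extrapolating.
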