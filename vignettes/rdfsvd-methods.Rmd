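---
title: "Compressing fluid structure: event-driven dynamics, g(r) sweeps, and SVD surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing fluid structure: event-driven dynamics, g(r) sweeps, and SVD surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rdfsvd)
```

## The problem

The radial distribution function g(r) is the central structural observable
of a simple fluid: it gives the probability, relative to an ideal gas, of
finding a particle pair at separation r, and its Fourier transform is the
experimentally measurable static structure factor S(q).  Tabulating g(r)
accurately over a *continuous* range of state parameters — packing fraction
φ, attractive strength ε, well width λ — is expensive, because each
parameter point needs its own equilibrated simulation.

`rdfsvd` implements a pipeline that makes such a tabulation compact and
continuous for hard-sphere (HS) and square-well (SW) fluids:

1. simulate each parameter point with event-driven (discrete) molecular
   dynamics, which propagates stepwise potentials *exactly*;
2. estimate g(r) on a fixed radial grid and stack the k curves into a k × m
   matrix G (rows = parameter points, columns = radial bins, m > k);
3. decompose G = U Σ Vᵀ; with the singular values ordered decreasingly, the
   columns of V are *basis vectors* (functions of r) and the columns of U
   *coefficient vectors* (functions of the swept parameter);
4. keep only the p leading triplets (for sweeps in φ or ε the spectrum
   decays fast, so p ≈ 5–6 suffices) and replace each retained coefficient
   vector by a low-order polynomial in the swept parameter, with the degree
   growing linearly in the rank index;
5. the stored model — p singular values, p basis vectors, p polynomial
   coefficient sets and the parameter domain — reconstructs
   g(r; θ) = Σₙ σₙ Pₙ(θ) vₙ(r) at *any* interpolated θ.

Everything is in reduced units: σ (core diameter) = 1, particle mass m = 1,
kT = 1, so the time unit is σ√(m/kT).  A square well of strength ε at kT = 1
is equivalent to ε = 1 at temperature kT = 1/ε, which is how state points
should be mapped onto published coexistence data.

## The event-driven engine

Between events every particle moves ballistically; events are the exact
roots of |Δr + Δv t|² = d² for each boundary d ∈ {σ, λᵢσ} of the stepwise
potential, under the minimum-image convention.  At a boundary the engine
applies the exact equal-mass impulse: core contacts reverse the radial
relative velocity; well crossings change the radial relative speed so that
(μ/2)v_r′² = (μ/2)v_r² − Δu with μ = m/2, and an escape attempt with
insufficient radial kinetic energy reflects elastically (a *bounce*).  Total
momentum is conserved exactly and total energy to machine precision; the
test suite asserts a relative energy drift below 1e-8 over 10⁵ square-well
events (measured drift is ~1e-14).

Two engines share one prediction kernel:

* a **brute-force reference**: at every step, a fresh scan over all pairs —
  no queue, no cells, no caches;
* the **production engine**: a binary min-heap with lazy invalidation via
  per-particle event counters, plus cell lists (cell edge ≥ the interaction
  range) with cell-crossing events; crossings only re-predict pairs in the
  newly adjacent cell plane.

A deliberate design constraint makes the two engines *bit-identical*: pair
prediction is a pure function of the two particles' states (position at
last update, update time, velocity), so the floating-point arithmetic does
not depend on *when* a prediction is computed.  Particle state changes only
at impulses and at per-particle "resync" events whose times are themselves
pure functions of state; resyncs re-wrap coordinates and refresh the
minimum image.  A predicted root is only trusted up to the next resync of
either particle; with the resync displacement h chosen so that
range + 2h < L/2, the nearest image chosen at prediction time is provably
the colliding image.  The test suite replays N = 32 square-well systems for
thousands of events and asserts the two engines' event logs and final
states are `identical()` — not merely close.

## Equilibration and sampling

Each state point starts from randomly occupied FCC lattice sites (no
overlaps by construction) with Maxwell–Boltzmann velocities rescaled to
KE/N = 3/2 exactly and zero total momentum.  Equilibration runs in two
phases: first with all shells stripped (pure hard spheres) to decorrelate
the lattice, then with the full potential, holding kT = 1 by velocity
rescaling at window boundaries.

Steadiness is judged on windowed virial pressures,
P = ρkT + (3VΔt)⁻¹ Σ m(Δvᵢ·r_ij).  A phase ends when the last five window
means agree within 1% of a pressure scale floored at ρkT, *or* — because
windowed virial noise at desk-scale system sizes can exceed 1% even at
equilibrium, especially for square wells where core and well contributions
cancel — when the drift between the two most recent five-window blocks is
indistinguishable from the window-to-window noise (1.5 standard errors).
Window length doubles (up to 16×) while the signal is noisy, and a phase
must accumulate a minimum number of pair events per particle
(`equil_min_events`, default 30) before it can be declared steady: dilute
systems would otherwise pass on pressure noise long before well occupancy
has relaxed.

Production is free NVE by default; energy and momentum invariants then hold
over the whole run.  NVE pins the kinetic temperature at whatever value the
last rescale produced, which for small dilute systems can sit a few percent
away from 1 and visibly shift Boltzmann-weighted observables
(the well plateau scales like e^{ε/kT}).  For checks that are quantitative
against kT = 1, `thermostat = "andersen"` re-draws a random half of the
velocities from the Maxwell distribution between snapshot segments: the
configurational sampling is then canonical at kT = 1 while each segment
remains exact NVE.

The RDF estimator is the standard minimum-image pair histogram with exact
shell-volume normalization; default resolution Δr = 0.01σ on (0, 6σ],
clipped to L/2 when the box is smaller (at N = 256 and φ = 0.45 the window
ends near 3.3σ — a desk-scale limitation discussed below).

## The compression layer

`decompose()` uses the LAPACK thin SVD with a deterministic sign fix (the
largest-magnitude entry of each basis vector is made positive).  Surrogate
fits are least squares in a Chebyshev basis on the parameter mapped to
[−1, 1] — plain monomials in φ are badly conditioned by degree ~9 on small
grids — with degree(n) = n + 3 by default, growing linearly with rank;
coefficients can be exported to monomials in the original variable
(`surrogate_monomials()`).  Two-parameter sweeps use a total-degree-capped
bivariate basis under the same linear rule.  Per-rank fit quality is
reported as log₁₀ RMS over the training points.  The truncation threshold δ
is relative to σ₁ (default 1e-6).  The compact model serializes to JSON at
17 significant digits, so save → load → evaluate round-trips bit-for-bit.

## Physical validation

* **Structure factor.** S(q) = 1 + 4πρ∫(g−1) r sin(qr)/q dr by trapezoidal
  quadrature; physical S(q) must be non-negative.  When the radial window
  is short and g(r) still oscillates at r_max, the bare integral acquires
  truncation ripple that can push the small-q region spuriously negative;
  the `taper = "lorch"` window (the standard truncation treatment in
  scattering analysis) suppresses it.  Desk-scale positivity checks use the
  Lorch window for exactly this reason.
* **Equation of state.** Hard-sphere virial pressure against the
  Carnahan–Starling closed form (2% at N = 512), and the collision rate
  against the Enskog estimate (10%).
* **Dilute limit.** At φ ≤ 0.02, g(r) → exp(−u(r)/kT): a step of height
  e^ε inside the well.  Bins straddling a potential discontinuity are
  excluded from the comparison.
* **Reconstruction error.** The sweep-averaged normalized L1 distance
  E = mean_θ [∫|g − g̃| dr / ∫ g dr] over [σ, 6σ] (clipped to the grid),
  trapezoidal; the alternative normalization by the window length is
  available behind a flag.

## Integral-equation baselines

`solve_oz()` solves the Ornstein–Zernike relation with the PY, HNC, or
Rogers–Young closure by Picard iteration with mixing on γ = h − c
(default mixing 0.2, halved adaptively on divergence), alternating the
closure in real space with the OZ relation in Fourier space via a fast sine
transform (M = 4096 nodes, Δr = 0.005σ by default).  Grid nodes that land
exactly on a potential discontinuity take the mean of the two one-sided
limits of e^{−βu}, which keeps the discretization second order through the
step.  The RY switching function f(r) = 1 − e^{−αr} recovers PY as α → 0
and HNC as α → ∞ (asserted to 1e-4); α must be supplied by the user — the
thermodynamic self-consistency search that canonically fixes α is out of
scope, and comparisons should state the α used.  The solver's discrete
error lives in the transform variable r·c(r); relative to the scale of c,
the hard-sphere PY solution matches Wertheim's closed form to better than
1e-4 for φ ≤ 0.4 at Δr = 0.0025.

## Desk-scale study conditions

The package's default problem sizes are chosen so the full pipeline runs in
minutes on one core, and the tests pin their behavior at exactly these
sizes:

* engine-equivalence oracle: N = 32, φ = 0.12, thousands of events;
* equation of state: N = 512, φ ∈ {0.1, 0.2, 0.3, 0.4}, 2% of CS;
* dilute limit: N = 640, φ = 0.01, Andersen sampling, 5% of e^ε;
* flagship sweep: HS, k = 32 points, φ ∈ [0.05, 0.45], N = 256,
  300 snapshots per point — 5-vector error ≤ 0.05 (measured ≈ 0.009);
* the λ contrast: matched k = 8, N = 192 sweeps of λ ∈ [1.05, 1.35] versus
  φ ∈ [0.05, 0.45] for the single well at ε = 1.

Sweep ranges respect a conservative single-phase guard: φ < 0.494
(freezing), and for square wells 1/ε must exceed the critical temperature
for the given λ (interpolated from published square-well coexistence
studies) by 2%.  λ ∈ [1.05, 1.35] at ε = 1 keeps every point supercritical;
wider wells at ε = 1 would enter the liquid–vapor dome where a canonical
g(r) is not well defined.  The guard is deliberately rectangular and
user-replaceable.

What desk scale does *not* show: with ~300 correlated snapshots per point,
the per-bin noise of g(r) sets a singular-value floor around σ₅–σ₆, so only
the first four or five triplets rise cleanly above it, and polynomial fit
residuals sit near log₁₀ RMS ≈ −4 for the dominant rank rather than the
much deeper values attainable with thousands of decorrelated snapshots and
k ~ 10³ parameter points.  The *structure* of the results — fast spectral
decay in φ and ε, slow decay and an order-of-magnitude larger 5-vector
error for λ sweeps (a moving discontinuity produces Gibbs-type undershoot
at r = λσ that no small basis captures), positivity of reconstructed S(q)
with five vectors — is reproduced at desk scale and is what the acceptance
checks assert.  Paper-scale presets (N = 2¹²–2¹³, 10⁴ snapshots, k ~ 10³)
are reachable through `sim_config()`/`sweep_spec()` arguments but are
long-running and not exercised by the tests.

## Numerical choices and edge cases

* Potential boundary values are left-closed: u(λᵢσ) takes the inner-shell
  value; the event mechanics use the same convention (the choice is
  measure-zero but must be consistent).
* Histogram bins are half-open [r_b, r_{b+1}); a distance exactly at r_max
  is excluded.
* Event roots within 1e-9 (relative) of a boundary are classified by the
  sign of the radial velocity, which cleanly separates "just crossed" from
  "about to cross" states after an impulse.
* The engine refuses boxes with L ≤ 2.05 × interaction range (minimum-image
  ambiguity) and falls back to the brute-force engine when fewer than
  3 cells fit per side.
* Per-point sweep seeds are a pure function of (master seed, point index);
  sweeps are bit-reproducible, cacheable, and resumable, and the resumed
  matrix is identical to a straight-through run.
* Reconstructed g(r) may dip slightly negative near sharp features (Gibbs
  phenomenon); values are returned unclipped so that downstream checks see
  the artifact.  Extrapolation outside the swept domain errors under
  `strict = TRUE` (default) because the polynomial surrogates are only
  trustworthy inside the interpolated region.

## Known limitations

* Single component, equal masses, stepwise potentials only; no mixtures,
  polydispersity, continuous potentials, or phase-coexistence machinery.
* g(r) windows are limited to L/2; at desk-scale N this truncates the
  [σ, 6σ] analysis window at high φ and makes the bare S(q) quadrature
  ripple-prone (use the Lorch taper).
* The RY α is user-supplied; no self-consistency search.
* The equilibration plateau test detects "steady at the resolution of this
  schedule", not absolute convergence; `equil_min_events` is the guard
  against premature exits and should be raised for slowly relaxing states.
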