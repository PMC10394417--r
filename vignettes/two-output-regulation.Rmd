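---
title: "Regulating two coupled outputs with sequestration-based integral controllers"
author: "crnControl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulating two coupled outputs with sequestration-based integral controllers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnControl)
```

## The problem

A synthetic circuit with two outputs of interest — say two proteins whose
concentrations matter jointly — is rarely two independent problems. When
the outputs activate each other, a perturbation entering through one
(e.g. a change in a production rate) shifts the steady state of both.
Classical single-output biomolecular integral controllers do not address
this: regulation of two co-dependent outputs needs architectures designed
for the multi-input multi-output setting, and those architectures come
with their own pairing and stability pitfalls.

`crnControl` implements a family of such architectures as mass-action
chemical reaction networks (CRNs), simulates them deterministically, and
certifies the two properties everything else rests on: that the closed
loop is locally asymptotically stable, and that at any stable steady
state the regulated quantity sits exactly at its set-point.

## Model and assumptions

Every object is a `ReactionNetwork`: species with initial concentrations
(nM), mass-action reactions with integer stoichiometry, and a table of
strictly positive rate constants (min^-1, nM·min^-1 or nM^-1·min^-1
according to reaction order). The deterministic rate equations are
`dx/dt = S r(x)` with `S` the stoichiometry matrix and
`r_j(x) = k_j * prod_i x_i^{s_ij}`. The deterministic description assumes
molecule counts high enough that stochastic fluctuations average out;
no stochastic (chemical master equation) semantics are provided.

The plant is the mutual-activation pair

$$\dot Y_1 = b_1 - d_1 Y_1 + \alpha_1 Y_2, \qquad
  \dot Y_2 = b_2 - d_2 Y_2 + \alpha_2 Y_1,$$

whose unique positive equilibrium
$Y_1^* = (\alpha_1 b_2 + b_1 d_2)/(d_1 d_2 - \alpha_1\alpha_2)$,
$Y_2^* = (\alpha_2 b_1 + b_2 d_1)/(d_1 d_2 - \alpha_1\alpha_2)$
exists and is exponentially stable exactly when
$d_1 d_2 > \alpha_1\alpha_2$; `plantSteadyState()` enforces that
condition and serves as the analytic oracle for the simulator.

Each regulator family is a reaction fragment written against abstract
targets Y1/Y2 and bound to the plant's designated outputs by
`closeLoop()`:

* **R** — sensing `Yi -> Yi + Zi`, inhibition `Y2 + Z2 -> Z2`,
  annihilation `Z1 + Z2 -> 0`. The memory variable `Z1 - Z2` integrates
  `k1 Y1 - k2 Y2`, forcing `Y1*/Y2* = k2/k1`.
* **R_PRODUCT** — the R motif with sensing replaced by `0 -> Z1` and
  `Y1 + Y2 -> Z2`; `Z1 - Z2` then integrates `k1 - k2 Y1 Y2`, forcing
  the product `Y1* Y2* = k1/k2`. The bimolecular sensing reaction
  consumes both outputs, so actuation-side feasibility (a positive
  equilibrium) constrains the usable gains; `assessStability()` should
  always be consulted before trusting a parameter choice.
* **LC** — R plus constitutive production `0 -> Z1` (rate θ1) and
  `0 -> Z2` (rate θ2); the same memory variable forces
  `k1 Y1* - k2 Y2* = θ2 - θ1`.
* **D1** — two independent sequestration loops: sensing as in R on both
  outputs, inhibitory actuation `Yi + Zi -> Zi`, references
  `0 -> Z3, 0 -> Z4`, comparisons `Z1 + Z3 -> 0`, `Z2 + Z4 -> 0`. Two
  memory variables `Z3 - Z1`, `Z4 - Z2` force `Y1* = θ1/k1`,
  `Y2* = θ2/k2` independently.
* **D2** — same controller ODEs as D1 (the identity is asserted in the
  test suite at random states) but with catalytic actuation
  `Z3 -> Z3 + Y1`, `Z4 -> Z4 + Y2`; same set-points, different
  transients.
* **D3** — a complex-mediated variant with three controller species plus
  the complex C: comparison `Z1 + Z3 -> C` feeds a second comparison
  `Z2 + C -> 0`, so one reference rate θ1 sets both outputs,
  `Y1* = θ1/k1` and `Y2* = θ1/k2`.
* **D2_MISPAIRED** — D2 with the annihilation pairs swapped
  (`Z1 + Z4`, `Z2 + Z3`). The architecture looks plausible — each
  actuator influences both outputs anyway through the coupling — but
  admits no stabilizing parameters (below).

Two augmentations are available: `extraInhibition` adds
`Y1 + Z1 -> Z1` (rate k4) to the R/LC families, which applies control
action to both outputs without touching the controller equations (the
test suite asserts the Z-components of the right-hand side are unchanged);
`degradationRate` appends first-order decay to every controller species,
the non-ideal dilution scenario discussed under *Controller dilution*.

The set-point guarantees are steady-state statements conditional on
closed-loop stability. They are independent of the plant's parameters —
that is the robust-perfect-adaptation property — but not of its
structure: a plant can simply fail to admit a positive equilibrium under
a given objective (the product regulator above is the clearest case).

## Parameters that matter

* `k1, k2` (min^-1; nM^-1·min^-1 for the product variant's k2) — sensing
  gains; their ratio or quotient with θ sets the set-point.
* `k3, k4` — actuation rates (nM^-1·min^-1 when inhibitory,
  min^-1 when catalytic); they shape transients and stability margins
  but never the set-point.
* `θ1, θ2` (nM·min^-1) — constitutive reference rates; numerators of the
  decoupled set-points and offsets of the linear combination.
* `η, η1, η2` (nM^-1·min^-1) — annihilation (comparison) rates; ideally
  fast. Values around 10 nM^-1·min^-1 make the system moderately stiff,
  which drives the solver choice below.
* Plant rates `b1, b2` (nM·min^-1), `d1, d2, α1, α2` (min^-1) — the
  disturbance entry points; the bundled scenarios step b1 from 2 to 4 at
  t = 50 min.

The scenario registry (`scenario()`, ids `fig3b` … `fig6`) pins every
one of these to its reference values and is the single source for the
tests and the acceptance script.

## Numerical choices

* **Integrator** — `deSolve::lsoda` (switches to BDF when stiff),
  relative tolerance 1e-8, absolute 1e-10 nM. The right-hand side clamps
  states at zero before evaluating rates, so integrator round-off below
  zero cannot feed back into the dynamics; output entries below zero are
  clipped and counted (`@clipped`), and a dip below 1e-6 nM is flagged
  in `@notes` rather than silently absorbed.
* **Disturbances** — piecewise integration with a restart at each exact
  event time; the parameter steps instantaneously between segments. No
  interpolation is attempted across the discontinuity.
* **Initial conditions** — all species start at 0 nM unless overridden.
  Nothing in the circuit definitions fixes initial values; zero-initialized
  species are the conventional reading for synthetic circuits, and the
  steady-state claims are initial-condition independent inside the basin
  of attraction, which is all the package asserts.
* **Steady-state declaration** — trailing 5% of the horizon must show
  relative drift < 1e-6 for every species and the final-state residual
  must satisfy ‖dx/dt‖∞ < 1e-8 nM·min^-1. Default horizon 500 min
  (the bundled loops settle well within ~50 min of each event; the long
  horizon buys residuals at integrator precision). Non-convergence is a
  reported state (`@converged = FALSE`), not an error — the mispaired
  scenario relies on this.
* **Equilibria** — damped Newton with the exact analytic Jacobian
  (mass-action right-hand sides are polynomial, so differentiation is
  closed-form), tried from the supplied seed, a short simulation
  endpoint, and a deterministic ladder of constant states; roots with
  negative components are refused. For the D2 family (either pairing) on
  the standard plant the equilibrium has a closed form — annihilation
  flux balance pins the outputs, the plant balance pins the actuators,
  and the sensors follow — and is unique; `pairingScan` uses it so that
  a scan verdict of "no stable point" cannot be an artifact of Newton
  non-convergence.
* **Stability** — eigenvalues of the analytic Jacobian are authoritative;
  real parts within ±1e-9 are reported as `marginal`, never coerced. The
  Routh–Hurwitz criterion is computed independently on the monic
  characteristic polynomial (assembled from the eigenvalues — never by
  naive determinant expansion) as a cross-check; a decisive disagreement
  raises a hard error. In the Routh test, a negative coefficient
  short-circuits to `unstable` (coefficient positivity is necessary for
  Hurwitz stability); an exact zero in the first column without negative
  coefficients returns `marginal` with no epsilon perturbation.
* **Scan grid** — log-spaced, 4 points per decade over [0.01, 100] in
  every scanned unit, full factorial subsampled to at most 10^4
  combinations by a fixed stride (deterministic, no seeds). The bounds
  operationalize "realistic parameter ranges" and are configurable.

## Controller dilution and its mitigation

Appending dilution `Z -> 0` at rate δ to every controller species leaks
the integral action: at steady state the memory balance becomes
`k1 Y1* = θ1 - δ(Z3* - Z1*)` (and analogously per family), so the
set-point error grows from zero linearly in δ at small δ. The package's
mitigation (`degradationStudy(..., tuned = TRUE)`) rescales the
annihilation rates *together with* the sensing gains (k1, k2) and
reference rates (θ1, θ2) by a common factor. Every set-point is a ratio
of scaled quantities and is preserved, while the leak term is divided by
the factor. Scaling the annihilation rate alone does not help here: the
sensor-side species is pinned by the plant balance, so the leak is
dominated by a term that η cannot reduce. The study is comparative — it
demonstrates monotone degradation in δ and its suppression under
retuning — no specific externally tuned values are reproduced.

## What the bundled scenarios do and do not show

The scenarios exercise one plant structure (two mutually activating
birth–death species) at one reference parameter set per scenario, plus the
step disturbance on b1. Passing tests therefore demonstrate: exact
steady-state tracking of all five objectives across that disturbance,
robustness of the objectives to ±50% rescaling of any plant rate (within
the stable region), loss of integral action under dilution and its
mitigation, and infeasibility of the mispaired D2 configuration over the
scanned grid. They do not demonstrate: behaviour on other plant
structures (indirect actuation, more outputs), global stability (all
certificates are local; basins of attraction are not estimated),
stochastic performance at low copy numbers, or transient-quality metrics
(overshoot, settling time). The regulator fragments are written against
abstract targets precisely so other plants can be composed, but any new
composition needs its own stability certificate.

## Problem sizes

Default runs integrate 2–6 species over 500 min on a 0.1-min output grid
(5001 points, ~0.3 s each). The quadrature-identity tests use a 0.01-min
grid over 80 min so that trapezoidal error (~dt²) sits an order of
magnitude below the 1e-4 assertion tolerance. The pairing scan evaluates
10^4 grid points (~1 s total, closed-form equilibria). The Routh–Hurwitz
cross-validation draws 1000 polynomials of degree 2–7 from constructed
root sets.

## Known limitations

* Mass-action kinetics only — no Hill/Michaelis–Menten rate laws, no
  delays, no spatial effects, and no SBML interchange (the JSON
  serialization is package-specific and lossless).
* Rate-constant tables are value-copied (R's copy-on-modify semantics);
  disturbance propagation is owned by the integrator, which patches the
  table between segments. Networks composed from the same plant object
  do not share subsequent parameter edits.
* `findEquilibrium` is a local root finder; for multistable networks
  outside the bundled families it returns the root its seeds reach, and
  equilibrium uniqueness is only guaranteed where the closed form
  applies.
* The positive-real balance residual (`prBalanceCheck`) reports the
  equilibrium rate-balance condition under which the augmented R/LC
  controller block is passive; it is a diagnostic, not a stability proof,
  and no conclusion is drawn from it alone.
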