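---
title: "Constrained allocation FBA: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained allocation FBA: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafbar)
```

## The model

Flux balance analysis (FBA) predicts steady-state metabolic fluxes $v_i$ by
maximizing the biomass flux $\lambda$ subject to mass balance
$\sum_i S_{\mu i} v_i = 0$ and bounds $\ell_i \le v_i \le u_i$. Constrained
allocation FBA adds a single genome-wide constraint derived from the
empirical organization of the bacterial proteome into growth-rate-dependent
sectors — ribosomal (R), biosynthetic enzymes (E) and carbon catabolic (C) —
on top of a growth-rate-independent housekeeping share. Because the sector
fractions must sum to a fixed budget, the variable parts obey

$$ w_C v_C + \sum_i w_i |v_i| + w_R \lambda \;=\; \phi_{\max}, $$

where $v_C \ge 0$ is the carbon-source uptake flux, the sum runs over
enzyme-catalyzed reactions (excluding transports, exchanges, the carbon
intake pathway, the biomass flux and the ATP maintenance reaction), and

* $w_R$ (units h) is the ribosomal proteome cost per unit growth rate;
  the carbon-limited *E. coli* value is $w_{R,0} = 0.169$ h. Increasing
  $w_R$ above this baseline emulates translation-inhibiting antibiotics.
* $w_C$ (g h/mmol) is the catabolic cost per unit carbon influx. It is the
  control parameter for carbon limitation: under Michaelis–Menten uptake
  kinetics $w_C = w_{C,0}(1 + K_M/[g])$ (`wc_from_sugar_level()`), so
  dialing $w_C$ up emulates diluting the medium.
* $w_i$ (g h/mmol) is the enzyme cost per unit flux of reaction $i$; the
  absolute value reflects that a reversible enzyme must be expressed
  whichever direction its net flux takes.
* $\phi_{\max}$ (dimensionless) is the proteome fraction available to the
  growth-rate-dependent sector parts; the *E. coli* K-12 estimate is 0.484.

The sector offsets at zero growth drop out of the formulation entirely;
only the four kinds of coefficients above appear.

Maximizing $\lambda$ under this constraint captures the tug-of-war between
sectors: faster growth needs more ribosomes ($w_R\lambda$ up), which
squeezes the budget available for enzymes and carbon intake. The package's
central empirical phenomenon is overflow metabolism: at fast growth the
optimum abandons high-yield respiration for low-yield fermentation because
the latter is proteome-cheaper per unit growth, and the fermentation
byproduct (acetate) is secreted.

## The optimization is a plain LP

The absolute values make the problem look mixed-integer, but splitting each
flux into non-negative forward and backward components
$v_i = v_i^+ - v_i^-$ with $v_i^+ \in [0, u_i]$, $v_i^- \in [0, -\ell_i]$
and charging $w_i (v_i^+ + v_i^-)$ in the allocation row yields an exact
linear program: at a growth-rate maximum, $v_i^+ + v_i^-$ is minimized at
fixed net flux for every weighted reaction, so one of the two components
vanishes. `build_cafba_lp()` constructs this program (irreversible
reactions stay unsplit), `solve_cafba()` solves it, verifies the
no-simultaneous-flux property post hoc (repairing and warning if a
zero-cost degenerate vertex carries a common component), and
`milp_oracle()` provides an independent check by brute-force enumeration of
all sign patterns of the reversible weighted reactions — exponential, hence
reserved for the synthetic test networks.

Two analytic results anchor the test suite:

* a linear intake → enzymes → biomass chain with yield $y$ has
  $\lambda^* = \phi_{\max}\, y / (w_C + \sum_i w_i + y\, w_R)$, a
  Michaelis–Menten-shaped (hyperbolic) function of $1/w_C$;
* with two routes of yields $y_H > y_F$ and costs $w_H > w_F$ the optimum
  minimizes $(w_C + w_p)/y_p$, so the solution switches from the cheap
  low-yield route to the expensive high-yield one exactly at
  $w_C^* = (w_H y_F - w_F y_H)/(y_H - y_F)$ — a minimal model of the
  overflow crossover.

```{r chain}
chain <- make_linear_chain(k = 1, y = 1, w = 0.1, w_C = 0.1, w_R = 0.3,
                           phi_max = 0.5)
solve_cafba(chain$model, chain$weights)
```

### Equality versus inequality

The allocation constraint is stated as an equality: unused proteome
capacity would be wasted. The package imposes it as
$\le \phi_{\max}$ and reports the slack, because a strict equality can make
models infeasible when some *other* bound (an uptake cap, a disabled
reaction) limits growth first, in which case the cell simply cannot fill
the budget. At any allocation-limited optimum the row binds and the two
formulations coincide; `verify_solution()` and the test suite check a
binding slack below $10^{-6}$ whenever growth is allocation-limited.

### Degeneracy and futile loops

Zero-cost reversible cycles among excluded reactions (typically transports)
leave the LP degenerate. Following the model's own remedy, excluded
categories can be given an arbitrarily small weight
(`eps_weight`, default $10^{-9}$ g h/mmol, applied to transports), which
removes loop flux without measurably perturbing the optimum. With
heterogeneous weights, ties between alternative pathways are
measure-zero, so each realization has an essentially unique solution; in
the homogeneous case the returned vertex may be one of several optima and
is reported as such.

## Weight schemes

With per-reaction costs essentially unmeasurable at genome scale, two
limiting schemes are supported:

* **homogeneous** — every enzymatic reaction gets the same $w_E$;
* **heterogeneous** — each $w_i$ is drawn i.i.d. from a log-uniform density
  $p(w) \propto 1/w$ on $[w_{\min}, w_{\max}]$, parameterized by its mean
  $\langle w \rangle$ and decade width
  $\delta = \log_{10}(w_{\max}/w_{\min})$ (default $\delta = 1$: a 10-fold
  spread). A log-normal family is included as a robustness alternative.

The density does not uniquely define the $(\langle w\rangle, \delta) \to
(w_{\min}, w_{\max})$ inversion; this package fixes it by matching the
analytic mean exactly: with $r = 10^\delta$,
$w_{\min} = \langle w\rangle \ln(r)/(r-1)$ and $w_{\max} = r\, w_{\min}$.
A convention matching, say, the median instead would shift calibrated
$\langle w\rangle$ values by a few percent.

Both schemes are calibrated against a single observable, the maximal growth
rate at saturating carbon ($w_C = 0$): `calibrate_homogeneous()` bisects
$w_E$ on the monotone map $w_E \mapsto \lambda^*$, and
`calibrate_mean_weight()` bisects $\langle w\rangle$ on the Monte-Carlo
mean of $\lambda^*$ over realizations. The calibration reuses one set of
per-realization uniform quantiles across all bisection steps (common random
numbers), which makes the simulated mean numerically monotone in
$\langle w\rangle$ so the bisection terminates cleanly; the default
tolerance is $10^{-3}$/h with 500 realizations per step.

## Ensemble averaging and sweeps

Single heterogeneous realizations fluctuate; the reproducible predictions
are ensemble averages. `run_ensemble()` draws $n$ weight sets (each
realization's sub-seed derives deterministically from the master seed, so
ensembles are bit-reproducible and individual realizations can be replayed),
solves each, and summarizes growth rate, carbon intake, sector fractions,
yield and user-mapped reporter fluxes by mean, SD and SE. Failed solves are
excluded from the averages and counted separately rather than imputed.
`sweep_wc()` (carbon limitation) and `sweep_wr()` (translational
limitation) run one ensemble per grid point with fresh realizations per
point by default — matching the per-point-ensemble protocol — with an
option to hold realizations common across the grid for trajectory studies.
Yield is computed per realization as $\lambda/(v_C\,\mu_{\rm s})$ (with
$\mu_{\rm glc} = 0.18$ g/mmol for glucose) and then averaged.

Downstream statistics mirror the standard analyses of overflow metabolism:
`fit_acetate_onset()` fits $v_{\rm ac} = s(\lambda - \lambda_{\rm ac})$ by
ordinary least squares over the points above an activity threshold (default
1 mmol/gDW/h at genome scale; scale it to the network at hand) — the
threshold restricts the fit to the overflow regime and is reported with the
fit; `solve_pfba()` provides the parsimonious FBA reference;
`flux_overlap()` computes the similarity
$q_R = \langle 2 v_i z_i / (v_i^2 + z_i^2) \rangle_{i \in R}$, with the
convention that a reaction off in both solutions ($v = z = 0$) counts as
agreement ($+1$); `interpolate_reference()` aligns the reference curve to
the ensemble's growth rates.

## Growth-rate-dependent biomass

Biomass composition itself shifts with growth rate. The package represents
it as a `biomass_function`: piecewise-linear coefficient knots over
$\lambda$ plus the linear ATP law $v_{\rm ATP} = v_{\rm ATPM} +
\beta_{\rm ATP}\lambda$, with the maintenance part imposed as the ATPM
lower bound and the growth-associated part folded into the biomass column
(the COBRA convention). `solve_variable_biomass()` runs the fixed-point
iteration — solve at the current composition, update the composition to the
optimal growth rate, repeat — converging to $|\Delta\lambda| \le 10^{-6}$/h
typically within a handful of iterations; a damping factor is available
should a composition ever make the undamped iteration cycle, and the full
iterate trace is returned. On the chain fixture the converged value matches
an independent scalar root-finder to $10^{-6}$.

## Synthetic networks and what the tests do and do not show

All shipped validation runs on synthetic networks built in code: linear
chains (closed-form optimum), two-route overflow toys (closed-form
crossover, optional acetate-like byproduct), a futile-loop fixture, and
seeded random networks (a weighted backbone plus random extra reactions
with integer stoichiometries in $\pm\{1,2\}$, keeping the LPs
well-conditioned). These exercise every code path — splitting, the
allocation row, classification, ensembles, calibration, the iteration — and
the oracle-equivalence suite demonstrates exactness of the LP reduction.
What they deliberately do not emulate is the scale and redundancy of a real
reconstruction: hundreds of alternative pathways, compartments, cofactor
coupling and realistic biomass stoichiometry. Quantitative genome-scale
statements (e.g. the calibrated *E. coli* weight values, the measured
acetate onset near 0.79/h) therefore require loading a published
reconstruction via `load_model()`/`fetch_bigg_model()` and are not asserted
by the test suite.

## Numerical choices

* LP backend: a two-phase dense simplex (`boot::simplex`) behind an
  internal standard-form wrapper that shifts variables to the non-negative
  orthant, turns finite upper bounds into rows, and normalizes signs of
  right-hand sides. Pivot tolerance $10^{-9}$; residuals reported at
  $10^{-6}$. A dense simplex is entirely adequate for the synthetic
  networks and small models this package validates on; genome-scale models
  load and classify, but single solves become slow well before iJR904 size,
  so large-scale studies should treat the backend abstraction as the place
  to plug in a sparse LP engine.
* Presolve: zero-rhs mass-balance rows whose terms are single-signed force
  their variables to zero (dead ends, e.g. downstream of a disabled
  reaction); these are fixed before the solve. Degenerate vertices where an
  inequality with zero right-hand side binds can upset the backend's pivot
  bookkeeping; the wrapper retries with a $10^{-11}$ rhs nudge, far below
  every reported tolerance.
* Infinite bounds are replaced by $\pm 1000$ mmol/gDW/h (the COBRA
  convention, configurable) so all variables are boxed and the LP can never
  be unbounded.
* Transport detection strips compartment suffixes (`_c`, `[c]`, ...) and
  calls a reaction a transport when the multiset of base species consumed
  equals the multiset produced across at least two compartments; ambiguous
  reactions default to enzymatic, and explicit category overrides are the
  escape hatch.
* Seeds: every stochastic routine takes an explicit integer seed, restores
  the caller's RNG state, and derives per-realization sub-seeds
  deterministically, so all ensembles and calibrations are reproducible
  bit-for-bit.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run on networks of 4–30 reactions:
50 random toys for oracle equivalence, 20 random two-route toys for the
crossover, ensembles of 300–500 realizations, and a 10-point carbon sweep —
all chosen as the smallest sizes that exercise the full pipeline while
keeping a complete run in well under a minute per check.

## Known limitations

* The dense simplex backend limits routine use to small and mid-size
  networks (see above).
* No QP/NLP variants, no thermodynamic loopless constraints beyond the
  $\varepsilon$-weights, and no explicit macromolecular species: the
  allocation constraint is an effective, top-down description, not a
  mechanistic expression model.
* Per-reaction empirical weights from proteomics are not fitted; the
  homogeneous and log-uniform schemes are deliberate limiting cases.
* The sector classification heuristics (exchange, transport, intake
  pathway) follow common reconstruction conventions and should be reviewed
  per model; the category report (`write_category_report()`) exists for
  exactly that audit.
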