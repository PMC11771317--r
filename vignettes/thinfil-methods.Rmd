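---
title: "Modeling near-neighbor cooperative activation of cardiac thin filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling near-neighbor cooperative activation of cardiac thin filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinfil)
```

## The model

Cardiac contraction is regulated by the thin filament: a troponin–tropomyosin
regulatory unit (RU) spanning seven actin monomers gates whether myosin
crossbridges (XBs) can bind. `thinfil` implements a coupled four-state kinetic
scheme for an ensemble of RU/XB sites:

* **B** — blocked RU, no crossbridge can attach (the non-cycling pool);
* **C** — closed RU, calcium bound, the nearest crossbridge detached or
  weakly bound;
* **M1** — open RU, crossbridge strongly bound, pre-power-stroke;
* **M2** — open RU, crossbridge strongly bound and generating force.

Occupancies are fractions of a fixed site pool normalised to one, so
`B + C + M1 + M2 = 1` at all times. Isometric force is taken proportional to
the `M2` occupancy (proportionality constant 1 throughout; only `M2` ratios
ever matter for the outputs). The `M2 -> C` return step is the unidirectional,
ATP-consuming step of the cycle.

Three balance equations (for `C`, `M1`, `M2`) are integrated and `B` is
recovered from conservation; the fourth (blocked-state) equation serves as a
test oracle since the four derivatives must sum to zero exactly.

Calcium enters through the blocked–closed rates only:
`kBC = kBC0 + (kBC_Ca - kBC0) * r` with
`r = [Ca] / (Ca50 + [Ca])` computed from `pCa` and `pCa50`
(`ca_ratio()`), and analogously for `kCB`. All other reference rates are
calcium independent.

### Near-neighbor cooperativity

Under a Bragg–Williams mean-field closure (states assumed randomly
distributed along the filament), the probability that a neighbor is blocked
or open is replaced by the global fractions `lamB = B` and
`lamM = M1 + M2`. Three interaction families scale the four regulated
transitions, each as a perfect square so rates can never turn negative:

* **RU–RU** (`ru_factor_fwd()`, `ru_factor_rev()`): forward factor
  `[1 - lamB (1 - 1/a1) + lamM (a2 - 1)]^2`, with `(a1, a2) = (u1, u2)` on
  the blocked–closed step and `(z1, z2)` on the closed–open step. `a2 > 1`
  means open neighbors promote the forward transition; `a1 > 1` means blocked
  neighbors promote the reverse one.
* **XB–XB** (`v`) and **XB–RU** (`w`): force-generating crossbridges act
  through `[1 + M2 (exp(c - 1) - 1)]^2` forward and
  `[1 + M2 (exp(1 - c) - 1)]^2` reverse, on the closed–open (`c = v`) and
  blocked–closed (`c = w`) steps respectively.

Interaction factors `alpha`, `alpha_bar`, `beta`, `beta_bar` in [0, 1] mix
the RU-mediated and XB-mediated factor for each of `kBC`, `kCB`, `kCM1`,
`kM1C` as a convex combination (`transition_rates()`). Setting every
cooperative coefficient to 1 collapses all factors to 1, for any mixing
weights — the model then reduces to a linear four-state scheme.

Eight regime templates (`param_set_spec()`) switch the three families on and
off: set 1 disables all cooperativity, sets 2–4 isolate one family each,
sets 5–7 pair families, and set 8 frees all six coefficients and all four
mixing factors. Fitted parameter columns for sets 1, 2 and 8 in murine and
porcine ventricular myocardium ship as JSON fixtures
(`fixture_params()`).

## Numerical choices

* **Integration.** Fixed-step fourth-order Runge–Kutta, implemented in C++
  for the stiff porcine rate scales (the porcine non-cooperative
  closed-to-blocked reference is ~5.9e3 1/s). The step is
  `min(1e-4 s, 0.1 / k_max)` where `k_max` bounds the largest rate reachable
  anywhere on the state simplex, including worst-case cooperative
  amplification (the RU forward factor is at most `u2^2`, the XB factor at
  most `exp(2(v-1))`, and so on). That safety fraction sits ~30x inside the
  RK4 stability limit; an in-loop guard detects any excursion beyond
  [-1e-6, 1 + 1e-6] and retries with a halved step, erroring only after six
  halvings. `integrate_model(check_dt = TRUE)` additionally refines the step
  until two successive halvings agree to 1e-8 per component.
* **Steady state.** Integration from the all-blocked state (`B = 1`, the
  zero-force initial condition of the force-redevelopment protocol) until
  the maximal state derivative stays below 1e-10 1/s for 100 consecutive
  steps, with a hard cap of 200 simulated seconds. Because an RK4 step fixes
  exactly the points where the right-hand side vanishes, the converged state
  is insensitive to the step size. The test suite checks every shipped
  parameter column against an independent Broyden root solve of the same
  nonlinear system and probes for multistability by restarting from the
  all-closed and uniform states.
* **Force–pCa.** Equilibrium `M2` per grid point, normalised by the value at
  the most acidic (highest-calcium) grid point (`force_pca_curve()`).
  `hill_fit()` estimates `pCa50` and the Hill coefficient by nonlinear least
  squares of `1 / (1 + 10^(n (pCa - pCa50)))`, seeded by a logit-linear
  regression; the `scaleOffset` control keeps the convergence criterion
  meaningful on noise-free (zero-residual) curves. Note that the fitted
  half-activation of a cooperative force curve lies well to the left of the
  `pCa50` rate parameter — the two are distinct quantities.
* **ktr protocol** (`ktr_protocol()`). The slack–restretch maneuver is
  abstracted as a transient lowering of the crossbridge duty cycle
  `delta = fCM1_0 / (fCM1_0 + fM1C_0)`: (i) normal-duty equilibrium gives
  the steady force `F_ss`; (ii) the duty cycle is dropped to 1e-8 by scaling
  the closed–open reference rate with `fM1C_0` held fixed (the minimal
  single-parameter change realizing the stated duty cycle; the
  state-dependent cooperative factors keep acting), and the slack steady
  state gives the residual force `F_resid`; (iii) the duty cycle is
  restored and the half-rise time `t_half` to
  `F_resid + 0.5 (F_ss - F_resid)` is located by linear interpolation
  between trajectory samples (1e-4 s spacing). `ktr = ln(2) / t_half`.
  Halving the slack duty cycle again changes ktr by under 0.1%.
* **Derived factors** (`derived_quantities()`). The activation factor
  `K = kBC/kCB` and recruitment factor `N = kCM1/kM1C` are reported with the
  zero-calcium reference rates scaled by the state-dependent ensemble
  factors. This convention — rather than calcium-evaluated baselines —
  is the one that makes `K` reduce exactly to `kBC0/kCB0` in the
  non-cooperative regime and reproduces the published porcine ensemble
  values; it is validated in the acceptance tests.

## Fitting

`ktr_fit()` estimates parameters from a contractility table (columns `pCa`,
`force_mean`, `force_sem`, `ktr_mean`, `ktr_sem`, `n`) by minimising the
unweighted RMSE between simulated and observed mean curves (SEM weighting is
available behind a flag; the default target is the ktr curve, with `force`
and `both` modes for force–pCa work). The free set defaults to the nine
reference rates, `pCa50`, and whatever the regime template leaves free;
cooperative coefficients are bounded below by 1 and above by a configurable
cap (default 50, sized for porcine-scale cooperativity), mixing factors by
[0, 1].

The RMSE surface is multimodal — a narrow, deep basin at the generating
parameters can sit beside broad shallow ones, and a gradient line search
from a poor start will jump straight across the narrow basin. The optimiser
therefore samples `n_starts` Latin-hypercube candidates, evaluates the
objective at each, and polishes only the best `n_refine` (plus the
user-supplied `init`) with box-constrained quasi-Newton iterations,
returning the best polished result. Everything is deterministic given
`seed`. `compare_sets()` repeats the fit across regime templates so that the
qualitative question — does removing the RU–RU interaction degrade the fit —
can be answered on any dataset.

## Synthetic data

`synth_dataset()` emulates the summary tables produced by steady-state
mechanical experiments on permeabilized myocardium: per pCa it simulates the
true relative force and ktr from a known parameter set, draws `n_preps`
Gaussian pseudo-preparations with standard deviation proportional to the
true value, and reports mean, SEM and n. Defaults — `n_preps = 8`,
single-preparation scales of 5% (force) and 10% (ktr) — were chosen once as
typical of permeabilized-preparation variability at these sample sizes;
negative draws are clipped at zero and counted in an attribute. The
generator reproduces exactly from its seed.

What it deliberately does not emulate: preparation-to-preparation covariance
between force and ktr, run-down over repeated activations, non-Gaussian
outliers, and pCa-dependent noise floors. Passing recovery tests on this
generator therefore demonstrate estimator correctness under the stated noise
model, not robustness to every failure mode of real preparations.

## Problem sizes used in the shipped tests

The test suite solves steady states on all six shipped parameter columns at
four calcium levels against the root-finding oracle, runs the full u2/z2
sensitivity grid (12 columns x 2 pCa), and performs the parameter-recovery
study on murine-scale synthetic data (4-point pCa grids, one free
coefficient, 10 noise seeds with a coarsened 1e-3 s fitting step). These
sizes keep the full suite around a minute on a single core while exercising
every code path; all tolerances quoted above are asserted at full precision.

## Known limitations

* The mean-field closure ignores spatial correlation along the filament; no
  stochastic/spatially explicit simulation is attempted.
* Sarcomere-length dependence, inter-filament coupling, thick-filament
  regulation and regulatory-protein phosphorylation are outside the model.
* The fitted parameter columns are reproduced from their printed (rounded)
  precision; quantities evaluated near the murine activation threshold
  (pCa ~6.1) amplify that rounding strongly, which bounds how closely the
  published low-activation murine entries can be recomputed.
* `K` is undefined when `kCB0 = 0`; columns whose zero-calcium references
  round to 0 cannot have their activation factor recomputed.
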