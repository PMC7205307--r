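---
title: "xapswitch: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{xapswitch: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xapswitch)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the parameters and their
conventions, the numerical machinery, and the design decisions taken
where more than one reasonable choice existed.

## The circuit and its model

The *xapABR* circuit couples a transcription factor (XapR,
constitutively expressed as dimers), a xanthosine transporter (XapB)
and a xanthosine-degrading enzyme (XapA) expressed from one operon.
Intracellular xanthosine activates XapR, active XapR activates the
*xapAB* promoter, and XapB imports more xanthosine: a positive
feedback loop through membrane transport, with a weaker negative
feedback through degradation by XapA.

Three quasi-equilibrium assumptions shape the regulatory input:

* **Two-state MWC induction.** Each XapR dimer binds up to two
  xanthosine molecules and interconverts between an inactive and an
  active conformation. `xapr_active_fraction()` implements the active
  fraction; at zero inducer it collapses to the leak level
  `1/(1 + exp(deps_x))`, and for `K_IA > 1` it rises monotonically to
  `1/(1 + exp(deps_x)/K_IA^2)`.
* **Thermodynamic promoter occupancy.** The promoter carries two
  identical XapR sites and an independently binding polymerase.
  `promoter_state_weights()` enumerates the eight occupancy states;
  only the fully occupied state transcribes (default policy).
* **Lumped protein.** XapA and XapB share transcription, translation
  and decay rates, so a single protein variable stands for both.

Transport combines Michaelis–Menten import and export by XapB with a
linearized non-specific (Nup) exchange `k_eta (c_a - xi x_a)`; XapA
degradation is Michaelis–Menten with the concentration scale `K_a`
that also nondimensionalizes the system. Time is measured in units of
`1/gamma_p` and concentrations in units of `K_a`; the polymerase
saturation factor `P/(K_P + P)` is folded into the transcription
strength `rho_m`, so the nondimensional interface never carries the
polymerase concentration separately (the dimensional interface,
`dimensional_params()` and `xap_rhs_dimensional()`, carries it
explicitly, and `nondimensionalize()`/`dimensionalize()` map between
the two).

The protein equation uses the instantaneous mRNA level, so the full
system is a genuine three-dimensional flow; the analytic stationary
mean of the mRNA equation is exposed separately through `mean_mrna()`
and is exactly the mRNA coordinate of every fixed point.

## The cooperativity convention

The interaction between the two promoter-bound XapR dimers is the one
place where we deliberately fixed a sign convention by the circuit's
observable behaviour. The doubly occupied promoter states carry the
statistical weight factor `exp(deps_coop)` with `deps_coop > 0` a
*favourable* interaction: cooperativity enhances double occupancy.
With the default `deps_coop = 5` (about 3 kcal/mol, a typical
protein–protein contact energy) and the remaining defaults, the
circuit is bistable with roughly 5 and 250 protein copies in the two
states and about one mRNA at the switch point — the copy-number
regime the circuit is known to operate in. Under the opposite
(anti-cooperative) reading the doubly bound state is suppressed a
hundredfold, maximal promoter activity stays below `1e-6`, and no
parameter set within the estimated ranges is bistable at all; since a
bistable regime is the circuit's documented phenotype, we regard the
favourable convention as the physically meaningful one and use it
throughout. Setting `deps_coop = 0` removes promoter cooperativity
entirely; at the reference parameters this destroys bistability (the
window only reappears if the expression strength `rho` is raised
roughly tenfold), which is why the package treats inducer-side and
promoter-side cooperativity symmetrically in the ablation variants.

## Parameters

All sixteen nondimensional parameters are validated on construction;
`xap_params()` with no arguments is the frozen reference configuration
(`table1_params()` is an alias). The defaults are mid-range estimates
for the *xap* system:

| field | meaning | default |
|---|---|---|
| `rho_m` | transcription strength (incl. polymerase saturation) | `1e-3` |
| `gamma_mp` | mRNA/protein decay ratio | `10` |
| `rho_p` | translation rate over protein decay | `100` |
| `XapR_R` | XapR dimers over their promoter dissociation constant | `1` |
| `c_a` | extracellular xanthosine over `K_a` | `13` |
| `k_beta_i`, `k_beta_e` | XapB import/export turnover | `5e4`, `1e3` |
| `K_beta_i`, `K_beta_e` | XapB import/export Michaelis constants | `10`, `100` |
| `k_alpha` | XapA turnover | `100` |
| `k_eta`, `xi` | non-specific exchange rate and asymmetry | `0.5`, `0.8` |
| `K_chiA`, `K_IA` | MWC dissociation constant and ratio | `100`, `100` |
| `deps_x`, `deps_coop` | conformational gap, pair interaction (k_BT) | `5`, `5` |

`k_beta_i > k_beta_e` with `K_beta_i < K_beta_e` makes import dominate
at low intracellular xanthosine, which is what lets the transporter
accumulate its own inducer. The derived lumped strength is
`rho = rho_m * rho_p / gamma_mp = 0.01`: the protein nullcline of the
reduced system is `p_a = rho * p_active(x_a)`.

## Deterministic analysis

Steady states satisfy a single scalar equation in `x_a` after the mRNA
and protein equations are eliminated analytically
(`m_a = (rho_m/gamma_mp) p_active`, `p_a = rho p_active`). The
resulting function is transcendental (equivalent to a quintic under
rational regulatory input), so `find_fixed_points()` brackets sign
changes on a 2000-point logarithmic grid over `x_a` in `[1e-6, 1e8]`
(bounds configurable; the origin is checked separately for the
`c_a = 0` degenerate case) and refines each bracket by bisection to
relative `1e-10`. Robust bracketing was preferred over polynomial
root-finding because the parameters span ten orders of magnitude and
the rational-coefficient expansion is badly conditioned. Each root is
back-substituted into the full three-dimensional right-hand side and
verified component-wise relative to the magnitudes of its constituent
terms (tolerance `1e-9`); duplicate roots within relative `1e-6` are
merged, and a root at the scan boundary raises a warning.

Stability comes from the eigenvalues of the analytic Jacobian. Because
fold detection needs an explicit dead zone, eigenvalue real parts
within `1e-9` of zero are classified `"marginal"` rather than forced
into stable/unstable.

`reduce_mrna_qss()` performs the standard quasi-steady-state
elimination of the (fast) mRNA variable. It is a convenience view —
the fixed points and their stability classes coincide with the 3D
system at the reference parameters, and the test suite asserts this —
but the reduction is not used internally by the solvers, because for
parameter sets where xanthosine dynamics are faster than mRNA dynamics
the transient behaviour of the reduced flow differs.

Trajectories are integrated with `deSolve::lsoda` with the analytic
Jacobian supplied, absolute tolerance `1e-12` (the mRNA coordinate is
of order `1e-4` at the reference scale) and relative tolerance `1e-8`.
`bifurcation_diagram()` links branches between neighbouring control
values by nearest distance in `log(p_a)` with ties broken toward
preserving the stability class, and refines fold locations by
bisection on the branch count; `bistable_range()` does the same
bisection along any single parameter.

## Stochastic simulation

`build_network()` maps the rate laws onto nine reaction channels over
integer counts `(M, P, X)` with density-preserving scaling: at counts
`Omega * (m_a, p_a, x_a)` the expected net rates equal `Omega` times
the macroscopic right-hand side exactly, so the ODE system is the
large-volume limit of the jump process. The MWC/promoter functions are
evaluated on the concentration-converted count `X/Omega` — the
quasi-equilibrium regulatory layer is kept continuous rather than
discretized, consistent with its derivation.

The conversion constant is `Omega = N_A * V * K_a`. The default cell
geometry uses `V = 1 fL` and `K_a = 5e-5 M`, hence
`Omega ≈ 3.01e4`. This puts the reference scenario at ≈5 proteins in
the off state, ≈250 in the on state, of order one mRNA at the switch
point and xanthosine counts up to `~2.5e7` — the copy-number regime
the circuit operates in. The volume is a configuration knob of
`cell_geometry()`, never hard-coded in the dynamics, and all
copy-number statements in the package are convention-dependent on it.

Two simulators share the C++ core:

* `simulate_direct()` — Gillespie's direct method, statistically
  exact, bit-reproducible for a given seed (counts are carried as
  doubles holding integers, so xanthosine counts far beyond 2^31 are
  exact).
* `simulate_hybrid()` — a partitioned exact/tau-leap scheme. At every
  macro-step a channel is *leapable* when each species it changes
  exceeds a count threshold (default 100) and its propensity exceeds a
  rate threshold (default `1e3` per unit tau); leapable channels
  advance by Poisson firing numbers over a leap chosen by the
  bounded-relative-change criterion (`eps = 0.03`, change bound
  `max(eps*x, 1)` against both the mean and the variance of the
  aggregate drift), non-leapable channels advance by the exact method,
  and the leap is capped at the exponentially sampled time of the next
  slow event. A candidate leap that would drive any count negative is
  resampled with halved step (60 halvings raise a tau-underflow
  error). The partition is re-evaluated every macro-step, so runs that
  cross between the low- and high-expression states switch regimes
  automatically.

This partitioning matters because the two expression states live at
incompatible scales: mRNA stays below ~10 copies in both states (its
channels remain exact), while xanthosine channels at the on state fire
`~1e7` times per unit tau and would make the exact method infeasible.
The hybrid scheme is validated distributionally against the direct
method on low-copy networks (two-sample KS) and via the Poisson
stationary law of the constitutive birth–death limit; these checks are
part of the test suite.

Optional geometric bursts can be attached to transcription and
translation (`bursts = TRUE`). Burst sizes follow a geometric law on
`{1, 2, ...}` with configurable means; the defaults of 1 (no burst)
are deliberate, since burst statistics for this operon are not
established — enabling bursts preserves means but inflates the Fano
factor, which is asserted in the tests. XapR copy-number fluctuations
are *not* simulated: the transcription factor enters only through the
quasi-equilibrium regulatory function, a deliberate simplification
(its ~10 copies are long-lived, so their relative fluctuations are
slow and small compared to mRNA noise). Cell division and growth
dilution are likewise absorbed into the first-order decay rates.

## Ensemble statistics

`run_ensemble()` runs independently seeded replicates (seeds
`base_seed + 0:(n-1)`), keeps truncated runs flagged rather than
dropping them, and records endpoints, optional trajectories on a
sampling grid, and optional first-passage monitors evaluated event-by-
event in the simulator core.

`split_bimodal()` estimates a kernel density on the `log1p` scale,
takes the two largest interior maxima, and splits the sample at the
density minimum between them, reporting per-part means and weights; a
valley shallower than a 1.2-fold drop from the lower peak degrades to
a single mode. One behaviour worth knowing: in the *off* state the
protein distribution is itself zero-inflated (translation occurs in
bursts of ~10 proteins per rare mRNA), so at low concentrations the
splitter may resolve fine structure *within* the low state. Both
sub-modes sit far below the unstable branch; "bimodality" in the
switch sense means modes on *both sides* of the unstable branch, and
that is how the tests phrase it.

`adaptation_times()` reports the first time the protein count reaches
a threshold fraction (default 90%) of its on-state value, with
non-crossing runs returned as censored; at the reference parameters
with `c_a = 25` the deterministic crossing is `~1.5e5 s` and the
ensemble median agrees within a factor of two, with the deterministic
time inside the interquartile range. `hysteresis_protocol()` runs the
dual-initialization experiment (naive cells at zero counts, induced
cells at the upper fixed point) across a concentration grid; inside
the bistable window the two branch means straddle the unstable branch
and track the respective stable fixed points.

## Problem sizes

The test suite runs scaled-down study sizes chosen to keep the full
suite under a few minutes while leaving the assertions statistically
meaningful: ensembles of 200 runs over `tau = 500` (`1e6 s`) for the
endpoint-distribution checks, 100 monitored runs over `tau = 250`
(`5e5 s`) for adaptation times, 2000 replicate pairs for the
hybrid-vs-direct comparison, and 1500 replicates for the Poisson
stationary-law checks. The bundled `fixture_scenarios()` carry the
full-scale settings (5000 runs, `1e6 s`) for users who want the
complete ensembles.

## Known limitations

* Copy-number statements depend on the declared cell volume; only the
  nondimensional results are volume-free.
* The hybrid scheme freezes slow-channel propensities across a leap;
  drift of the transcription propensity within a leap is bounded by
  the 3% relative-change criterion but not resampled mid-leap. All
  distributional validation is against the exact method on systems
  where both run.
* No Hill-equation mode is provided, deliberately: the mechanistic
  occupancy model keeps the partially bound states and the interaction
  energy explicit, which is the point of the package.
* Fold (saddle-node) bifurcations are the only bifurcation type
  detected; the flow is non-oscillatory in the explored regime (the
  nullcline geometry yields trapping regions, and the tests assert the
  absence of oscillations along representative trajectories), so Hopf
  machinery was not built.
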