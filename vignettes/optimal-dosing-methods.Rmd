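---
title: "Methods: optimal Daratumumab scheduling under CD38 expression switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal Daratumumab scheduling under CD38 expression switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(daraopt)
```

## The model

`daraopt` studies how an anti-CD38 monoclonal antibody (Daratumumab)
should be scheduled against multiple myeloma when the tumour can evade
the drug by switching off its target. Three cell populations share the
bone-marrow compartment, each expressed as a fraction of the marrow
carrying capacity:

* `A` — healthy marrow cells, replenished at rate $\beta_A$ from an
  implicit stem-cell compartment;
* `P` — CD38+ myeloma, the drug-susceptible clone;
* `N` — CD38− myeloma, shielded from the drug but less fit (lower
  proliferation, higher death rate).

With control $u(t) \ge 0$ the dosage rate, the dynamics are

$$\dot A = \beta_A + \rho_A A S - \mu_A A - \mu_{Au} u A,$$
$$\dot P = \rho_P P S - \delta_P P + \delta_N N - \delta_{Pu} u P
           - \mu_P P - \mu_{Pu} u P - \frac{\alpha P}{\gamma + P + N},$$
$$\dot N = \rho_N N S + \delta_P P - \delta_N N + \delta_{Pu} u P
           - \mu_N N - \frac{\alpha N}{\gamma + P + N},$$

where $S = 1 - A - P - N$ is the shared space-competition factor. Three
mechanisms distinguish the model from a plain two-population
competition:

* **Expression switching** ($\delta_P$, $\delta_N$): spontaneous,
  reversible loss and regain of CD38. We take $\delta_N = 10\,\delta_P$
  (CD38 is strongly overexpressed in myeloma, so the expressing state is
  heavily favoured).
* **Drug-induced expression loss** ($\delta_{Pu}$): direct,
  non-lethal escape into the shielded state under drug pressure.
* **Off-target mortality** ($\mu_{Au}$): the drug also kills healthy
  cells; because CD38 is overexpressed in the tumour,
  $\mu_{Au} \ll \mu_{Pu}$ at realistic values.

The immune term is a saturating (Michaelis–Menten) removal with maximum
capacity $\alpha$ and half-saturation $\gamma$. Saturation is essential:
it permits bistability — a stable cancer-free state *and* a stable
persistent-cancer state — so that finite treatment can push the system
into the immune-controlled basin permanently. A linear immune response
cannot do this (it only shifts effective death rates).

Time is abstract; no parameter is calibrated to clock time or clinical
data, and results are qualitative statements about regime structure, not
dosing recommendations.

Two presets are shipped (`default_parameters()`, `null_n_parameters()`).
The Null-N preset zeroes every `N`-related rate and the off-target
effect; with $N(0) = 0$ the third compartment stays identically zero and
the model collapses to its two-compartment antecedent. We use it as a
negative control: every new phenomenon should disappear under Null-N.
The Null-N initial condition is $N(0)=0$ — the only choice under which
"the CD38− population is suppressed" is literally true.

## The optimal-control problem

Treatment quality is scored by
$J = \int_{t_0}^{t_f} \mathcal{L}(\mathbf{x}, u)\,dt$ with no terminal
cost, where the running cost is either

* linear: $\mathcal{L} = u + P + N$ with $0 \le u \le 1$ (the bound is
  required for well-posedness of a control-affine problem), or
* quadratic: $\mathcal{L} = u^2 + (P+N)^2$ (no upper bound needed; the
  solver applies a purely numerical safety cap of 10 and flags if it
  ever activates), or
* mixed: explicit non-negative weights on all four terms.

Setting the terminal cost to zero is deliberate: we have no defensible
price for residual cancer at $t_f$, so instead horizons are extended
(200 or 400 time units for a phenomenon living in the first 50–120) and
`horizon_extension_check()` verifies the reported window is free of
finite-horizon artefacts. One consequence is worth remembering whenever
you look at a solution: the costate vanishes at $t_f$, so the control
*always* drops to zero at the very end of the window. That terminal dip
is a property of the finite-window formulation, not of the treatment.

Pontryagin's principle gives the costate system
$\dot\lambda = -\partial H/\partial \mathbf{x}$,
$\lambda(t_f) = 0$, with
$H = \mathcal{L} + \lambda \cdot f$. The control enters $H$ through
$\partial H/\partial u = w_{u,lin} + 2 w_{u,quad}\,u
 - \lambda_A \mu_{Au} A - \lambda_P(\mu_{Pu} + \delta_{Pu})P
 + \lambda_N \delta_{Pu} P.$
For the quadratic form the pointwise minimiser is the clipped stationary
point; for the linear form the sign of the switching function
$\phi = \partial H/\partial u$ dictates bang levels, and an interval
with $\phi \approx 0$ is a singular arc. All partial derivatives are
analytic (shared competition factor and immune denominator included) and
are gate-checked against central finite differences of $H$ in the test
suite.

## The solver

`solve_optimal_control()` is a forward–backward sweep: integrate the
state forward under the current control, integrate the costate backward
along it, form the pointwise Hamiltonian-minimising candidate, and relax
$u \leftarrow (1-\omega)u + \omega\,u_{cand}$. Both passes use classical
fixed-step RK4 on the same grid (control and stored state linearly
interpolated at half steps); fixed stepping keeps the two passes
consistent, which adaptive integrators would break. Default steps:
0.001 for plain simulation, 0.005 for control solves (halving the step
changes every reported cost by well under 0.1%; the suite asserts this).

Three numerical choices required design work beyond the textbook scheme,
and each was forced by an observed failure mode:

* **Monotone line search on $\omega$.** Plain damping rules that shrink
  $\omega$ whenever the control-change metric grows collapse $\omega$
  during the initial transient; the iteration then creeps and can pass a
  change-based convergence test while the Pontryagin conditions are
  badly violated. We instead accept a relaxed step only if $J$ does not
  increase (with a scale-aware slack of $10^{-10} + 10^{-8}|J|$ to
  absorb quadrature rounding), halving $\omega$ on rejection and
  re-growing it by 1.5× after acceptance. Divergence is declared only
  after 20 consecutive forced acceptances at the $\omega$ floor.
* **Singular deadband with annealing.** Where $|\phi| < \varepsilon$ the
  candidate keeps its previous value instead of snapping to a bound;
  this lets the damped iteration settle onto singular arcs without an
  explicit singular-control formula. No single $\varepsilon$ works
  across the parameter space: $10^{-3}$ lets marginal nodes on long
  (>100 time unit) near-singular arcs flap and stalls the line search,
  while $10^{-2}$ freezes genuine short second bang pulses into smooth
  humps (verified against an independent switch-time optimisation, which
  finds a 0.7-unit second maximal pulse with lower J in the
  high-off-target scenario). Control-affine solves therefore converge
  first at $\varepsilon = 10^{-2}$ and re-converge warm-started at the
  target $10^{-3}$.
* **Two stopping rules.** Control-affine solves stop on the relative L1
  control change ($<10^{-6}$ for 3 consecutive iterations — looser
  tolerances leave the bang plateaus measurably short of the bound).
  Strictly convex solves may instead stop when the projected KKT
  residual of $\partial H/\partial u$ falls below $10^{-4}$ (the
  pointwise optimality condition itself), which avoids grinding on long
  horizons where the change metric contracts slowly.

The initial guess is $u \equiv 0$ everywhere; warm starts are accepted
through the config to probe local optimality (the sweep does not
guarantee a global optimum). Every result carries PMP diagnostics —
pointwise $H$, the stationarity residual or switching function, and the
fraction of nodes violating the bang rule — and the tests gate on these,
not on iteration counts.

A further known artefact: a transient oscillation appears at the
bang-to-singular interface and contracts only slowly with further
iterations. It is local, does not affect the arc level, and is handled
downstream by the classifier's median smoothing rather than by burning
iterations.

## Independent validation

Two routes guard the solver:

* `direct_transcription_optimum()` re-poses the problem over
  piecewise-constant controls (20 segments by default) and minimises the
  *simulated* objective with L-BFGS-B from seeded random restarts. It
  shares only the RK4 simulator with the production path. On the
  quadratic 20-unit problem the two optima agree within 1%, and the
  transcription optimum is structurally prevented from beating the sweep
  by more than its own discretisation gap.
* `finite_difference_gradient()` perturbs single control nodes and
  re-simulates, cross-checking the adjoint-based gradient
  $\partial J/\partial u_i = (\partial H/\partial u_i)\,\Delta t$.

## Regime classification

`classify_control_form()` turns a converged control into one of the
qualitative labels (`bang_bang`, `bang_singular`, `bang_gap_bang`,
`bang_gap_singular`, `cyclic`, `constant_maintenance`, `zero`,
`other`). The choices that matter:

* **Median, not mean, smoothing** (width 0.5 time units): a mean filter
  turns every bang edge into a ramp one window wide, which both
  mislabels clean bang-bang switches as singular and erases genuine
  ~1-unit second pulses; a running median suppresses the interface
  oscillation while preserving edges.
* Node classes `max` / `off` / `intermediate` at thresholds 0.01; runs
  shorter than 0.5 time units merge into their longer neighbour.
* **Cyclic** requires ≥ 3 maximal runs — two pulses is `bang_gap_bang` —
  and takes precedence over maintenance (an indefinitely repeating pulse
  train is still "active" late in the window).
* **Maintenance** is detected by sustained dosing: a non-off run
  covering at least 30% of the horizon and still active at 90% of it,
  with no steep decline over the 80–90% stretch. An absolute flatness
  bound does not work here: the deadband leaves a node-scale wiggle on
  long flat arcs, and the terminal dip forced by $\lambda(t_f)=0$ means
  no linear-cost control is literally nonzero at $t_f$.
* Anything that matches no rule is returned as `other` together with
  the full segment table — the classifier never silently guesses.

## What the experiments establish (and what they do not)

`run_scenario()`, `sweep_parameter()`, `cyclic_regime_suite()` and
`horizon_extension_check()` reproduce the computational experiments that
map the regime structure: the Null-N model gives bang-bang (linear cost)
or continuously tapering (quadratic cost) schedules; switching and
off-target effects produce the bang-singular form, i.e. sustained
intermediate dosing after the initial maximal burst; $\mu_{Au}$ near 1
splits the schedule into two maximal pulses; high off-target effect with
slow switching and weak immunity produces cyclic pulsed dosing; zero
immune capacity produces indefinite maintenance.

All inputs are generated internally — equilibria computed from the
presets are the initial states, and there is no external data anywhere.
Consequently a green suite establishes internal consistency with the
stated model and parameter table, not fit to any clinical observation;
the generator emulates the stated world exactly and nothing else (no
measurement noise, no pharmacokinetics, no discrete infusions, no
patient variability).

Equilibria are found as the spec of the problem dictates: the healthy
state in closed form (positive root of the logistic balance, residual
checked at $10^{-12}$), the cancerous state by long simulation from the
near-empty marrow state $(0, 0.1, 0)$ followed by a damped Newton polish
with the analytic Jacobian (residual $10^{-12}$, asserted $10^{-10}$).

## Known limitations

* The sweep finds local optima; the intuitive shapes and the agreement
  of warm-started solves are evidence, not proof, of global optimality.
* Bang-singular interfaces converge imperfectly (the documented local
  oscillation); switch times are resolved to roughly the smoothing
  window, not to machine precision.
* The cyclic regime's cycle timing is biased by the window length; the
  horizon-extension check flags this class as window-sensitive by
  design rather than pretending the timing is converged.
* Costs with a fixed per-session component cannot be expressed in the
  integral form used here, so intrinsically intermittent clinical dosing
  is outside the model.
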