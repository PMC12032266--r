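---
title: "The tripartite regulation game: model, dynamics and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tripartite regulation game: model, dynamics and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripgame)
```

## The model

Smart health senior-care service platforms sit between three boundedly
rational players, each choosing repeatedly between two strategies:

* **government** — positive regulation (costly monitoring with rewards and
  penalties) with probability $x$, versus passive regulation;
* **platform operator** — opportunism (fraudulent subsidies, unfair terms)
  with probability $y$, versus reciprocity;
* **senior-care enterprises** — positive cooperation (standards-compliant
  joint services) with probability $z$, versus passive cooperation.

Eighteen nonnegative parameters describe the stakes. Fractions: seniors'
willingness to use smart services $\rho_1$, the platform's service
conversion rate $\rho_2$, the enterprises' age-coverage rate $\rho_3$, and
the regulation level $\mu_1$, all in $[0,1]$. Payoffs (common units): the
government's ideal reward $R_{g1}$, regulation cost $C_{g1}$, accountability
penalty $P_{g1}$ and indirect loss $P_{g2}$ under passive regulation, with
the standing assumption $P_{g1} > C_{g1}$; the platform's base benefits
$R_{b1}$ (reciprocity) and $R_{b2}$ (opportunism), reward cap $R_{b3}$,
synergy benefit $R_{b4}$ and penalty cap $P_{b1}$; analogously $R_{h1},
R_{h2}, R_{h3}, R_{h4}, P_{h1}$ for the enterprises. A regulating government
collects $\mu_1 P_{b1}$ from an opportunistic platform and $\mu_1 P_{h1}$
from a passively cooperating enterprise; rewards are scaled by the
conversion/coverage rates ($\rho_2 R_{b3}$, $\rho_3 R_{h3}$), and the
synergy benefits $\rho_2 R_{b4}$, $\rho_3 R_{h4}$ are paid only when the
platform reciprocates *and* the enterprises cooperate positively.

`payoff_tensor()` evaluates all three payoffs at the eight pure-strategy
profiles. The publicly available rendering of the payoff table is
typographically corrupted (penalty symbols swapped between cells, repeated
base benefits), so the tensor is reconstructed from the behavioural
assumptions above, attaching each penalty to the misbehaving actor. The
reconstruction is validated by an exactness check: combined with the
replicator linearization it reproduces, symbol for symbol, all platform and
enterprise rows of the published corner-eigenvalue table (frozen verbatim
into the test suite).

## Replicator dynamics and the two government algebras

Each player's frequency follows a replicator equation,
$$\dot x = x(1-x)\,\Delta_g,\qquad \dot y = y(1-y)\,\Delta_b,\qquad
\dot z = z(1-z)\,\Delta_h,$$
where each $\Delta$ is the expected-payoff difference between the actor's
first and second strategy given the opponents' current mixture
(`fitness_difference()`), and $\Delta_b$ is oriented so that positive values
favour opportunism.

The government difference is provided in two algebras, because the source
material is internally inconsistent. Direct expectation over the payoff
tensor gives (in opportunism coordinates)
$$\Delta_g^{\text{derived}} = \rho_1 R_{g1} - C_{g1} + \mu_1 P_{b1} y +
\mu_1 P_{h1}(1-z) + (P_{g1}+P_{g2})\bigl(1-(1-y)z\bigr),$$
whereas the published replicator display carries $(1+\cdot)$-type factors
on the penalty terms and translates to
$$\Delta_g^{\text{as\_printed}} = -C_{g1} + \bigl(P_{b1}(2-y) +
P_{h1}(1+z)\bigr)\mu_1 + \rho_1 R_{g1} +
(P_{g1}+P_{g2})\bigl(1-(1-y)z\bigr).$$
The two coincide exactly when the platform is fully opportunistic and the
enterprises fully passive, which is why the first three validation
scenarios behave identically under both. They genuinely disagree at the
cooperative corners: the published algebra prices the regulator's outside
option at $\rho_1 R_{g1} + 2\mu_1(P_{b1}+P_{h1})$, the derived algebra at
$\rho_1 R_{g1}$. Scenario IV (convergence to full cooperation under
regulation, E8) validates only under the published algebra; scenario V
(cooperation without regulation, E4) only under the derived one. Rather
than silently endorsing either, both are first-class `mode` arguments
throughout, every report is tagged with its mode, and the ESS census tries
both and records the witnessing mode.

### Coordinate conventions

Internally $y$ is always the **opportunism** probability. Published corner
labels E1–E8 use the opposite orientation (their middle coordinate is a
reciprocity indicator: E5 = $(1,0,0)$ means "positive regulation,
opportunism, passive cooperation"). `corner_table()` stores both coordinate
systems plus the strategy words, and every printed report shows the words —
a bare coordinate triple is never the only identification.

## Stability analysis

The Jacobian of the system is computed symbolically
(`jacobian_matrix()`); at any cube vertex it is diagonal, so the corner
eigenvalues are closed-form: $(1-2x^*)\Delta_g$, $(1-2y^*)\Delta_b$,
$(1-2z^*)\Delta_h$ evaluated at the vertex. A corner is classified
(Lyapunov indirect method, `classify_equilibrium()`) as an ESS when all
three eigenvalues are below $-\lambda_{tol}$, unstable when any exceeds
$+\lambda_{tol}$, and marginal otherwise, with $\lambda_{tol} = 10^{-10}$
separating genuine sign information from roundoff. All condition
inequalities are strict; an equality never satisfies a condition.

Because $P_{g1} > C_{g1}$ and every other government term at E1–E3 is
nonnegative, those three passive-regulation corners have a positive
government eigenvalue for *every* admissible parameter set — they can never
be ESS. The five regimes under which E5, E6, E7, E8 and E4 are ESS are the
conditions I–V of `check_condition()`. The government inequality in
conditions IV and V is mode-dependent (`Cg1` against
`rho1*Rg1 + 2*mu1*(Pb1+Ph1)` in the published algebra, against `rho1*Rg1`
in the derived one); notably the printed scenario-V parameters violate the
published form of their own condition (30 > 36 is false) while satisfying
the derived form (30 > 24), which is exactly why scenario V needs the
derived algebra.

## Numerical integration

`simulate_game()` integrates the free coordinates on the logit scale,
$u = \operatorname{logit}(s)$, where the system becomes
$\dot u_i = \Delta_i(\sigma(u))$ with a globally bounded right-hand side
(integrated with `deSolve::lsodar`, rtol $10^{-8}$, atol $10^{-10}$, early
stop when the cube-coordinate velocity sup-norm falls below $10^{-9}$).
This choice is deliberate:

* the unit cube is forward-invariant *exactly* — no clamping is ever
  applied, and the corresponding test asserts `states >= 0 & states <= 1`
  with no tolerance;
* the logit tracks the log-distance to a face. Trajectories of this game
  routinely pass within less than machine epsilon of a face (a fast
  eigenvalue pushes $z$ to within $e^{-130}$ of 1 while a slow coordinate
  is still mid-flight) and later leave it again. In plain cube coordinates
  such a state rounds onto the face and, because faces are invariant, the
  simulation freezes at a corner the true flow would exit — we observed
  exactly this, a condition-I sample absorbing at an unstable corner.
  Integrating unclamped cube coordinates instead lets roundoff excursions
  escape the cube entirely (the logistic factor turns repelling outside).
  The logit form has neither failure mode.

Components of the initial state lying exactly on a face are held constant
(faces are invariant under the exact dynamics), so corner starts yield
constant trajectories. `classify_outcome()` labels a trajectory `corner`
when it settles within $10^{-3}$ (Chebyshev) of a vertex, `oscillating`
when any velocity component changes sign at least four times over the
final half without settling, `interior` when it settles elsewhere, and
`undetermined` when truncated at the horizon (default 200 time units)
still moving. The integrator is cross-checked against a fixed-step RK4
oracle at step $10^{-3}$ and against tolerance-halving (terminal states
stable to $10^{-6}$).

## Scenarios and the sampler

`builtin_scenario()` returns the five printed validation parameter sets
(II–IV overlay the base scenario I; V overlays IV, as its adjustment list
states). `sample_scenario()` rejection-samples parameter sets until the
requested condition holds: fractions uniform on $[0.05, 0.95]$, payoffs
uniform on $[1, 100]$ — ranges that bracket all printed values while
avoiding degenerate extremes — with $P_{g1} > C_{g1}$ enforced by
redrawing. Sampling is deterministic given a seed and restores the
caller's RNG state.

The sampler emulates unexplored corners of the parameter space, not any
empirical population: parameters are drawn independently, so sampled
economies can be far more extreme than calibrated ones (synergy benefits
up to 100 where the printed scenarios use 0–10). Two genuine model
behaviours surface at these extremes and are worth stating plainly,
because a naive reading of the stability conditions would miss both:

* **the conditions are not mutually exclusive.** Condition I constrains
  behaviour near E5 but says nothing about the synergy terms $R_{b4},
  R_{h4}$; large sampled synergies can make E8 a strict ESS at the same
  time (all eigenvalues negative — bistability), and the centre of the
  cube may lie in E8's basin. In a 50-sample condition-I batch, 4 sets
  converged to E8 instead of E5.
* **boundary cycling is real.** Some sampled sets settle at no corner and
  spiral along a heteroclinic boundary cycle (government relaxes once
  conduct is good, misconduct returns once regulation lapses, and so on);
  these are flagged `oscillating`. The package flags oscillation only — it
  makes no claim of strict periodicity, which would need analysis the
  model source does not provide.

Passing convergence tests on the five printed scenarios therefore shows
the model reproduces its published validation runs, not that the regimes
are globally attracting, and none of this says anything about real
administrative data, to which the model is not fitted.

## Sensitivity analysis and critical thresholds

Every corner eigenvalue is affine in every parameter, so the critical
value at which an actor's corner eigenvalue changes sign is an exact root
(`analytic_threshold()`). `empirical_threshold()` estimates the same
quantity independently by bisection (default tolerance $10^{-3}$ on the
parameter) on the simulated terminal strategy of the watched actor, read
as the rounded terminal coordinate. The two agree to bisection tolerance
whenever the flip is governed by the corner eigenvalue.

Sweeps default to the published government algebra because the cooperative
corner E8 they flip into is unstable under the derived algebra for the
printed scenario bases ($C_{g1} = 25$ just above $\rho_1 R_{g1} = 24$);
the regulation-cost sweep follows scenario V and uses the derived algebra.

Of the published critical values, only the two regulation-level thresholds
agree with the eigenvalue algebra: $\mu_1 = 22.5/47 \approx 0.48$
(enterprises) and $\mu_1 = 28.5/53 \approx 0.54$ (platform).
The published $\rho_2 = 0.45$, $P_{b1} = 29$, $P_{h1} = 23$, $R_{h3} = 25$
and $C_{g1} = 20$ disagree with the closed-form roots of the published
eigenvalue expressions themselves (0.55, 28.33, 30, 35, and 24 or 36
depending on the government algebra). `discussion_thresholds()` reports
both numbers side by side; the package does not force agreement. Two of
the printed sweep grids are additionally self-inconsistent: the $P_{h1}$
grid $\{5,20,25,30\}$ ends exactly at the eigenvalue root 30 (the
enterprise is marginal there and never flips on the grid), and the
$C_{g1}$ grid $\{5,18,35,40\}$ ends at $C_{g1} = P_{g1} = 40$, violating
the model's own assumption $P_{g1} > C_{g1}$ — that substitution is
rejected by validation, and the sweep runs on the admissible sub-grid.

## Problem sizes and runtime choices

The test suite integrates the five validation scenarios under their
recommended modes, checks cube invariance on 1000 random parameter sets
(horizon 30 suffices: invariance is exact by construction, the run merely
exercises the integrator), compares closed-form and numeric eigenvalues on
100 random sets at all corners, verifies the Jacobian against central
differences at 100 interior points, and runs the 50-sample condition-I
convergence batch. The RK4 cross-check uses horizon 40, by which all five
scenarios have settled. These sizes keep the full suite around two minutes
on a single core while leaving each property with enough random mass to be
informative.

## Known limitations

* Interior (mixed) equilibria are not located, beyond the government's
  indifference frequency `government_indifference()`; basin boundaries are
  not mapped.
* The oscillation flag is a sign-change heuristic, not a limit-cycle
  proof.
* The two government algebras are both carried because the sources
  conflict; results that depend on the choice (stability of E4/E8,
  condition IV/V checks, the regulation-cost threshold 24 vs 36) are
  always reported per mode.
* No stochastic (finite-population) dynamics, no delay or network
  structure, and no parameter estimation from data.
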