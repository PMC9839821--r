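---
title: "Stochastic May-Leonard models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic May-Leonard models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mlcycle)
```

This vignette documents the models implemented in `mlcycle`, the numerical
choices behind the simulators and solvers, and the reasoning at the points
where the design was genuinely open. It states no empirical number that the
test suite or `scripts/acceptance.R` does not itself compute.

## The three models

All three models are continuous-time Markov jump processes on the lattice of
nonnegative integer 3-vectors, built from mass-action reaction networks whose
mean field is a May-Leonard competition system. Stochasticity is purely
demographic: the only randomness is the discreteness of individual birth,
death and state-switching events. No Gaussian/Langevin approximation is used
anywhere; the simulator is an exact Gillespie implementation and the exact
analyses work directly with the master equation's generator.

**General-variance (GV) model.** Five reaction templates per species
(cyclic index arithmetic): birth `A_i -> 2A_i` at per-capita rate `b`, death
`A_i -> 0` at rate `d`, homocidal competition `2A_i -> A_i` with rate
constant `2/omega`, and heterocidal competition `A_i + A_{i+1} -> A_{i+1}`
(`alpha/omega`) and `A_i + A_{i+2} -> A_{i+2}` (`beta/omega`). The net
growth rate is `r = b - d`; at fixed `r` the short-time variance of the
growth process scales with `b + d`, which is what "general variance" refers
to. Because individuals can die spontaneously, every population can reach
zero and the chain's unique stationary distribution is the point mass at the
origin: eventual total extinction. The package verifies this numerically
(exact hitting probabilities equal to one, and ensembles absorbing at the
origin); it does not re-prove the complex-balance argument.

**Minimal model.** The `d = 0` member of the same family, i.e. the
minimum-variance model consistent with the mean field. Removing the death
reaction changes the connectivity of the state space: the sole death channel
left, homocide, needs at least two individuals, so no transition into the
origin exists and a lone survivor persists forever. Its stationary law is a
Poisson distribution of mean `r*omega` conditioned on `N >= 1`
(`truncated_poisson()`), which the package cross-checks against the null
space of the single-species generator to near machine precision.

**Three-pool model.** A central pattern generator abstraction: three pools
of `omega` cells, each cell active (`A_i`) or inactive (`I_i`).
Self-activation `A_i + I_i -> 2A_i` (`1/(tau*omega)`), inhibition of pool
`i` by pool `i+1`, `A_i + A_{i+1} -> I_i + A_{i+1}` (`gamma/(tau*omega)`),
and endogenous activation `I_i -> A_i` (`mu/tau`). Every reaction toggles
one cell, so `N_i + M_i = omega` is conserved and the state space is the
finite box `[0, omega]^3`; with `mu > 0` a fully silent pool always
reactivates, so cycling persists indefinitely with random period.

### Parameters

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| `b`, `d` | per-capita birth/death rates (GV) | 1/time | 2, 1 | smallest integer split with `d > 0` (required for total extinction) giving `r = 1`; the `b/d` decomposition only affects noise, not the mean field, and is configurable |
| `r` | net growth rate (minimal) | 1/time | 1 | the standard nondimensionalised choice |
| `alpha`, `beta` | competition of species `i+1`/`i+2` on `i` | - | 0.8, 1.3 | the classic heteroclinic regime `alpha + beta > 2`, `alpha < 1` |
| `omega` | system size: carrying capacity (GV/minimal), cells per pool (three-pool) | - | 30 / 10 | desk-scale sizes; `omega` is a positive real for GV/minimal (it only scales rate constants; states remain integers, and sub-unit values such as 0.1 are legitimate) but must be a positive integer for the three-pool model because it bounds the lattice |
| `tau` | three-pool time constant | time | 1 | sets the unit of time |
| `gamma` | inhibition strength | - | 2.4 | strong-inhibition regime in which the deterministic model cycles |
| `mu` | endogenous activation | - | 1e-5 | small activation steers orbits away from the saddles and converts heteroclinic cycling into finite-period oscillation |

## Exact simulation

`gillespie()` implements the direct method: exponential waiting time with
rate equal to the total propensity, reaction chosen proportionally to its
propensity. No tau-leaping or other acceleration is offered - exactness is
the point at desk scale. Propensities use combinatorial stochastic mass
action (`c*N` first order, `c*N_A*N_B` mixed second order, `c*N(N-1)/2` for
`2A`), so the homocidal channel with `c = 2/omega` fires at rate
`N(N-1)/omega`. This is the convention under which the expected increment
rate of the stochastic model equals the mean-field drift up to the
combinatorial correction `+N_i/omega` from the homocidal term (the drift
uses `N^2`, the chain uses `N(N-1)`), and the package asserts this algebraic
identity at random states in its tests. The three-pool propensities match
their drift exactly.

The inner loop is compiled (Rcpp) and draws from R's own RNG stream, so
`set.seed()` gives byte-identical trajectories; the test suite checks the
compiled core step-for-step against a pure-R Gillespie loop consuming the
same stream. Ensembles derive per-replicate seeds as `base_seed + k`, making
results independent of execution order. Heavy reductions (first-extinction
times, cycle lengths) are accumulated inside the compiled loop so that
10^4-replicate ensembles avoid per-replicate R overhead.

## Poincare sections and the discrete crossing rule

Cycle lengths are defined by three sections `P_i`: triangles with vertices
`(0,0,0)`, `(omega,omega,omega)` and `omega*e_i`, i.e.
`{N_{i+1} = N_{i+2}, N_i >= max(N_{i+1}, N_{i+2})}`. A full circuit
`P_1 -> P_2 -> P_3 -> P_1` (or the mirror order, depending on the model's
rotation sense) bounds one cycle; the cycle length is the circuit time.

The crossing orientation is fixed once per model by the sign of the
mean-field flux `d(N_{i+1} - N_{i+2})/dt` at the section centroid
`(omega/2)(1,1,1) + (omega/4)e_i`; with the package defaults the minimal/GV
models rotate `1 -> 3 -> 2` and the three-pool model `1 -> 2 -> 3`, and the
implementation discovers this automatically rather than hard-coding it.

On the integer lattice a trajectory can sit exactly on a section
(`D_i = N_{i+1} - N_{i+2} = 0`), so a tie rule is needed; nothing forces a
specific choice, and the rule below is flagged as a design decision:

* a visit to `P_i` occurs at a jump where `D_i` changes sign in the model's
  orientation; `D_i = 0` is attributed to the side being left, so ties break
  toward "crossing completed";
* the triangle condition `N_i >= max(N_{i+1}, N_{i+2})` must hold at the
  crossing jump, which excludes the mirror of the section through the
  diagonal (dominance handovers between the other two species);
* only transitions to a *different* section count as visits, which absorbs
  back-and-forth jitter around a section plane;
* a start on a section (the canonical `(omega,0,0)` start lies on `P_1`)
  counts as a visit at `t = 0`.

Circuits are anchored at the first section visited and completed on return
to it after both other sections have been seen. For continuous mean-field
trajectories the same geometry is used, but crossings are located by
interpolated sign changes (local spline refinement of the dense solver
output), not step endpoints, because heteroclinic orbits approach the
coordinate planes exponentially fast.

## Mean-field integration

`integrate_meanfield()` uses `deSolve`'s lsoda with defaults
`rtol = 1e-8`, `atol = 1e-10`. Components are clamped at zero when the
right-hand side is evaluated: in the heteroclinic regime populations decay
below any tolerance, and an unclamped integrator that steps slightly
negative would see `dn/dt = n(...) < 0` run away. With clamping the reported
solution stays within `-atol` of the nonnegative orthant. For the
periodic-orbit and period-convergence checks the tests tighten tolerances to
`rtol = 1e-10`, `atol = 1e-12`; cycle-over-cycle period agreement then
reaches well below `1e-6` relative. `deterministic_period()` integrates in
doubling windows until successive circuit durations agree to `rtol`
(default `1e-6`), erroring out for `mu = 0`, where cycling is heteroclinic
and no finite period exists.

## The truncated generator and first-passage solves

`build_generator()` assembles the sparse rate operator `Q` over the lattice
`{0..n_max}^d` from the same propensity code the simulator uses. Boundary
handling:

* transitions that would leave the lattice are deleted. This is the
  probability-conserving realisation of "reflecting at the top": no
  fictitious transitions are invented, rows still sum to zero, and for the
  default truncation `n_max = 2*omega` the cut flux is negligible for the
  regimes studied;
* states matching the absorbing specification (`"any_zero"` for the
  extinction planes, `"origin"` for total extinction, arbitrary index sets
  or predicates otherwise) have their outgoing rates zeroed.

Row sums are zero to `1e-12` by construction and asserted in tests.

First-passage quantities use the standard absorbing-chain backward systems
on the transient block `Q_TT`: hitting probabilities solve
`Q_TT h + Q_TA 1_class = 0` and mean absorption times solve
`Q_TT tau = -1`. Per-absorbing-state hitting densities (needed for the
conditional second-extinction analysis) use one adjoint solve,
`Q_TT' w = -p_0`, followed by a sparse product with `Q_TA`. All solves use
sparse LU factorisation (Matrix), report the maximum backward-equation
residual (about `1e-12` at the sizes used, bounded in tests at `1e-10`), and
error - naming the likely cause - on singular systems. Exact analyses are
practical up to roughly `3e5` states on one core; the test suite and
acceptance checks use `omega = 12` for the 3-D problems (`25^3` states),
with `omega = 30` supported but slow.

The conditional second-extinction pipeline chains two exact solves: the 3-D
problem started at `round(omega/3)*(1,1,1)` yields the hitting density on
the plane `N_3 = 0`; restricted to `N_1, N_2 >= 1` and renormalised, that
density seeds the 2-species subsystem (species 1 killed at rate
`alpha/omega` per pair, species 2 at `beta/omega`), whose absorbing states
on the two axes give the densities of the survivor at the moment of the
second extinction. Their masses are the conditional probabilities of the
two extinction orders and sum to one by construction.

`stationary_distribution()` first restricts the chain to the set reachable
from the supplied initial state, finds the closed communicating classes via
strongly connected components (igraph), and solves the adjoint null space on
the unique closed class (replacing one equation by the normalisation). If
several closed classes are reachable - e.g. the three single-survivor axes
of the full minimal model - the problem is genuinely ambiguous and the
function says so rather than pick silently.

Two reference-point ambiguities were resolved as follows. The interior
equilibrium of the minimal model is `omega*r/(1+alpha+beta)*(1,1,1)`, which
for the default `alpha = 0.8, beta = 1.3` is close to, but not equal to,
the convenient symmetric point `omega/3*(1,1,1)`; the package computes the
exact equilibrium where an equilibrium is meant and uses `omega/3` only as
the canonical symmetric initial condition. And the plane used to display
extinction-time fields defaults to `N_1 + N_2 + N_3 = omega` - the plane
that actually contains the symmetric initial condition - with any other
coordinate-sum plane selectable through `plane_slice()`.

## Stationary occupancy of the survivor

The empirical check of the truncated-Poisson law runs the minimal model past
its second extinction, discards a burn-in of ten mean reaction times, and
then samples the survivor's count at equally spaced clock times. Sampling at
deterministic clock times is an unbiased discretisation of the time-weighted
occupancy of the continuous-time chain (jump counting would be biased toward
short-lived states); the spacing, default `5/r`, is several relaxation times
of the logistic birth-death chain, so the sampled counts are approximately
independent and suitable for a chi-squared test. `chi2_gof()` merges
adjacent support points until every expected count reaches 5 (the classical
rule; the binning is reported alongside the statistic) and refers the
statistic to a chi-squared law with bins-minus-one degrees of freedom.

## Cycle-length statistics

`cycle_summary()` reports mean, unbiased variance and CV with standard
errors; the CV standard error uses the delta method with sample moments
(a bootstrap alternative is available). For three-pool parameters it also
attaches the rate-limiting-step approximants `T_a = 3*tau/(omega*mu)` and
`CV_a = 1/sqrt(3)` and the discrepancy `delta_cv = cv - CV_a`. The
approximation's logic: out of a saturated corner such as `(omega,0,0)` the
only cycle-advancing transition is a single endogenous activation in the
next pool, an exponential waiting time of rate `omega*mu/tau`; three such
legs per circuit give a Gamma(3, `tau/(mu*omega)`) cycle length. The
approximation is good for small `omega` and small `mu` (the acceptance
checks use `omega = 3`, `mu = 1e-3`, where the simulated mean, CV and MLE
Gamma shape land within a few percent of the predictions) and degrades as
`omega` grows and many transition paths contribute; the grid checks
(`omega` in {3, 10, 30} x `mu` in {1e-3, 1e-2, 1e-1}) only assert the
monotone trends of mean and variance in both parameters. `fit_gamma()` is a
plain two-parameter maximum-likelihood fit (via `MASS::fitdistr`) and
refuses degenerate (zero-variance) input.

## What the study conditions do and do not show

All quantitative checks run at reduced, desk-scale sizes chosen as the
package's own study conditions: `omega = 8..12` for exact lattice analyses,
`10^4`-replicate ensembles, 1000-2000 cycles per parameter point, and the
`(omega, mu)` grid above. These sizes make the exact/empirical
cross-validation loops (generator solve vs Gillespie ensemble) tight enough
to detect percent-level implementation errors. They do not probe the
large-`omega` asymptotics (e.g. convergence of the mean cycle length to the
deterministic period, or exponentially long survivor lifetimes), and the
models themselves idealise real systems: symmetric cyclic competition,
no environmental stochasticity, no immigration in the ecological variants,
and no sensory feedback in the neural variant. Passing tests certify the
mathematics of these idealised chains, not the fit of any particular
biological dataset.

## Known limitations

* Exact solves scale as `O(omega^3)` states; beyond ~`3e5` states memory
  and factorisation time grow quickly, which is intrinsic to the
  master-equation approach.
* The discrete crossing rule is one reasonable convention among several;
  cycle counts could differ slightly under a different tie rule at very
  small `omega`, where ties are common.
* `ensemble()` is sequential; replicate seeds are derived as
  `base_seed + k` precisely so the design could be parallelised without
  changing results, but no parallel backend is shipped.
* The GV model's `b/d` split is not identifiable from the mean field; all
  split-dependent results are reported at the configurable default
  `b = 2, d = 1`.
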