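# mlcycle

Stochastic May–Leonard models: extinction, stationary distributions and
cycle-length statistics for heteroclinic cycling with demographic noise.

## The problem

The May–Leonard system is the classic three-species competition model

```
dn_i/dt = n_i (1 − n_i − α n_{i+1} − β n_{i+2}),   i = 1,2,3 (cyclic),
```

which for `α + β > 2`, `α < 1` exhibits a heteroclinic cycle: dominance
passes from one species to the next in "rock–paper–scissors" fashion, each
cycle taking longer than the last as the orbit creeps ever closer to the
single-species saddle points. Real populations, however, are made of
discrete individuals; demographic (copy-number) noise makes the
near-extinction dwell phases of the heteroclinic cycle lethal. `mlcycle`
provides exact discrete-state, continuous-time Markov implementations of
this system for researchers in theoretical ecology and computational
neuroscience who want to study what demographic stochasticity does to
heteroclinic cycling — extinction orders and times, stationary laws, and
cycle-length statistics — with both Gillespie simulation and exact
generator-based (master-equation) solves.

Three mass-action reaction networks share the May–Leonard mean field but
differ qualitatively in their stochastic fate:

* **General-variance (GV) model** — birth `A_i → 2A_i` (rate `b`), death
  `A_i → ∅` (rate `d` with `b − d = r > 0`), homocidal competition
  `2A_i → A_i` (rate constant `2/Ω`), and heterocidal competition
  `A_i + A_{i+1} → A_{i+1}` (`α/Ω`), `A_i + A_{i+2} → A_{i+2}` (`β/Ω`).
  Its unique stationary distribution is total extinction, `π(N) = δ(N)`.
* **Minimal model** — the `d = 0` member of the family (minimum demographic
  variance at fixed `r`). Two species die out, but the survivor can only be
  killed by homocide, which needs two individuals: the sole survivor
  persists forever with the truncated Poisson stationary law
  `π(N) = (rΩ)^N / (N! (e^{rΩ} − 1))`, `N ≥ 1`.
* **Three-pool model** — a central pattern generator of three neural pools
  (`Ω` cells each) with self-activation `A_i + I_i → 2A_i` (`1/(τΩ)`),
  cyclic inhibition `A_i + A_{i+1} → I_i + A_{i+1}` (`γ/(τΩ)`) and
  endogenous activation `I_i → A_i` (`μ/τ`). Activity can never die
  permanently; the system cycles forever with random period. In the
  small-`Ω`, small-`μ` regime each leg of a cycle is dominated by one
  rate-`Ωμ/τ` activation event, so the cycle length is approximately
  Gamma(shape 3, scale `τ/(μΩ)`):

  ```
  T_a ≈ 3τ/(Ωμ),    CV_a ≈ 1/√3.
  ```

Extinction questions are posed exactly on a truncated lattice via the
infinitesimal generator `𝓛`: hitting locations solve the backward system
`𝓛π = e_s` and mean first-passage times solve `𝓛τ = −1`, with absorbing
boundaries on the coordinate planes `N_i = 0` and probability-conserving
truncation at `N_i = 2Ω`.

## Worked example

```r
library(mlcycle)

params <- minimal_params(r = 1, alpha = 0.8, beta = 1.3, omega = 12)
net    <- build_minimal_network(params)

# one stochastic realisation: who dies, and when?
traj <- gillespie(net, init = c(4, 4, 4), t_max = 200, seed = 1)
extinction_events(traj)
#> # A tibble: 2 × 2
#>   species  time
#>     <int> <dbl>
#> 1       3  1.30
#> 2       1  3.91

# exact mean time to first extinction from the symmetric state
G   <- build_generator(net, n_max = 24, absorbing = "any_zero")
fpt <- mean_absorption_time(G)
fpt$tau[fpt$N1 == 4 & fpt$N2 == 4 & fpt$N3 == 4]
#> [1] 2.831201

# conditioned on species 3 dying first, who goes next?
conditional_second_extinction(params)
#> <conditional second-extinction densities | species 3 extinct first>
#>   P(species 2 extinct second) = 0.731074
#>   P(species 1 extinct second) = 0.268926

# three-pool CPG cycle statistics in the rate-limiting regime
tp  <- three_pool_params(tau = 1, gamma = 2.4, mu = 1e-3, omega = 3)
cyc <- collect_cycles(tp, 2000, seed = 1)
cycle_summary(cyc, params = tp)
#> # A tibble: 1 × 10
#>       n  mean se_mean     var se_var    cv   se_cv   T_a  CV_a delta_cv
#>   <int> <dbl>   <dbl>   <dbl>  <dbl> <dbl>   <dbl> <dbl> <dbl>    <dbl>
#> 1  2000 1000.    12.8 329377. 13842. 0.574 0.00987  1000 0.577 -0.00343
fit_gamma(cyc)
#> Gamma MLE: shape = 3.0208 (se 0.0765), scale = 331.03  n = 2000
```

The first trajectory shows the typical minimal-model fate: two quick
extinctions (here species 3, then species 1) leaving one survivor. The
exact backward solve gives the mean first-extinction time (≈ 2.83 time
units from the symmetric state at `Ω = 12`). The conditional densities
quantify the "enemy of my enemy" ordering: once species 3 dies, species 2
— which species 1 kills at the faster rate `β/Ω` — dies second 73% of the
time. In the three-pool run the empirical mean cycle length (≈ 1000), CV
(≈ 0.574) and fitted Gamma shape (≈ 3.02) all match the rate-limiting-step
prediction `T_a = 3τ/(Ωμ) = 1000`, `CV_a = 1/√3 ≈ 0.577`, shape 3.

Every result type has an `autoplot()` method (trajectories, mean-field
orbits, conditional extinction curves, Gamma fits) and fitted objects
support `tidy()`/`glance()`. A command-line front end over the same
functions lives at `inst/cli/mlcycle.R` with subcommands `simulate`,
`meanfield`, `fpt`, `cycles` and `stationary-check`, driven by flat
YAML/JSON run configurations.

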