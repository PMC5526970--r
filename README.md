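# phagegame

Why do temperate bacteriophages lysogenize 5–15% of the time — and why do
some of them "count", going lytic when they infect a cell alone but
lysogenic when several phage co-infect? `phagegame` addresses these
questions with a competition framework: two phage variants, identical except
for their lysogeny propensity, invade one growing bacterial host population,
and the variant ending up with the larger share of lysogens wins. The
package is aimed at researchers in phage ecology, evolutionary game theory
and theoretical microbiology who want to simulate, analyze or extend this
kind of within-host-population competition.

## The model and the game

Competition is modelled by stiff ODEs for uninfected bacteria $B_0$,
infected bacteria $B_i$, lysogens $L_i$ and free phage $P_i$ ($i = 1, 2$),
with logistic host growth (rate $\gamma$, carrying capacity $K$),
mass-action infection (rate constant $\eta$), decisions at rate $\delta$
sending a fraction $f_i$ of infected cells to lysogeny and the rest to lysis
with burst size $\beta$:

$$\dot B_0 = \gamma B_0 (1 - B_{tot}/K) - \eta P_{tot} B_0, \qquad
  \dot B_i = \gamma B_i (1 - B_{tot}/K) + \eta P_i B_0 - \delta B_i,$$
$$\dot L_i = \gamma L_i (1 - B_{tot}/K) + f_i \delta B_i, \qquad
  \dot P_i = \beta (1 - f_i) \delta B_i - \eta P_i B_{tot}.$$

At steady state only lysogens (and sometimes uninfected bacteria) remain,
and variant 1 scores the payoff $(L_1 - L_2)/(L_1 + L_2)$ — a two-player
zero-sum game over the propensities. The package:

* integrates the dynamics (compiled right-hand sides, `deSolve::lsoda`) and
  extracts the three invasion phases — buildup, crash, lysogenic growth —
  and the crash onset time $t^*$ where $P_{tot} = \gamma/\eta$;
* builds payoff matrices over propensity grids and finds the
  **minimax-optimal propensity** $f_{opt}$ as the unique saddle point of the
  payoff surface (coarse-to-fine refinement in `findFopt()`);
* runs an **iterated evolutionary game** over MOI-dependent strategies
  $(f(1), f(2), f(3))$ — winner keeps its strategy, loser is replaced by a
  mutated copy, $f(m) \to (1 + 0.01 r_m) f(m)$, $r_m$ integer uniform on
  $[-3,3]$ — which converges to the switch strategy $(0, 1, 1)$;
* evaluates the analytic approximation
  $f_{opt} = (1 - 1/\beta)\,/\,(1 + \ln[\gamma/(\eta P_{tot}(0))])$ and the
  crash-time scaling $f_{opt} \sim e^{-\gamma t^*}$, and compares both
  against simulation;
* sweeps parameters one at a time over biological or wider ranges to show
  the robustness of $f_{opt}$.

## Worked example

```r
library(phagegame)
params <- modelParams()   # gamma = 1, K = 1, K*eta = 20, beta = 100, delta = 1

## one invasion: two variants with propensities 0.25 and 0.29
traj <- integrateDynamics("fixed", params, strategies = list(0.25, 0.29),
                          t_end = 60)
detectPhases(traj)
#> $t_buildup_end
#> [1] 3.9
#> $t_crash_end
#> [1] 4.56
#> $crash_detected
#> [1] TRUE
crashTime(traj)$t_star    # P_tot crosses gamma/eta = 0.05 here
#> [1] 3.91119

ss <- runToSteadyState("fixed", params, strategies = list(0.25, 0.29))
ss
#> Steady state (fixed model) at t = 100: converged
#>   L1 = 0.570297, L2 = 0.429703, B0 = 7.35863e-19
payoffScore(ss$L1, ss$L2) # the lower-propensity variant wins this pairing
#> [1] 0.1405948

## the optimal propensity: saddle point of the payoff matrix
findFopt(params, resolution = 0.01)
#> Optimal lysogeny propensity f_opt = 0.11 (unique saddle)

## the analytic approximation (exact-decision limit)
foptClosedForm(params, P0 = 1e-7)
#> Analytic optimal propensity: f_opt = 0.0737

## evolution of MOI-dependent strategies: converges to the switch strategy
evolveStrategies(seed = 1)
#> Evolutionary game trace: 1473 iterations, converged at iteration 1473
#>   final winner: f(1) = 0.001, f(2) = 1.000, f(>=3) = 1.000
```

The invasion shows the characteristic three phases (bacteria peak at
t ≈ 3.9 h, the crash infects almost everyone within ~0.7 h, lysogens then
fill the carrying capacity). The saddle at $f_{opt} \approx 0.1$ means: no
propensity beats 0.11, and any variant that deviates can be beaten — the
band of observed lysogeny propensities emerges as a competitive optimum. The
closed form lands ~0.03 below the simulated optimum at $\delta = 1$ because
it neglects the decision time.

A thin command-line wrapper with subcommands `simulate`, `payoff-matrix`,
`fopt`, `evolve`, `sweep` and `theory-compare` is installed at
`inst/cli/phagegame.R` (run `Rscript <path> <subcommand> --help`).

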