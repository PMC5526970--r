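---
title: "Competition, games and evolution of lysis-lysogeny strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition, games and evolution of lysis-lysogeny strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagegame)
```

## The question

Temperate phages infecting a bacterium choose between lysis (replicate and
burst the host) and lysogeny (integrate and ride along as a prophage). The
probability of choosing lysogeny — the lysogeny propensity $f$ — is observed
in a curiously narrow band, roughly 5–15%, across unrelated phage species,
and in some phages it switches with the multiplicity of infection (MOI):
single infections go lytic, multiple infections go lysogenic. `phagegame`
implements a competition framework that explains both observations without
appeal to fluctuating environments: when two phage variants that differ only
in $f$ compete for one host population, there is a minimax-optimal propensity,
and it falls in the observed band for essentially any reasonable parameters.

## The competition model

Two variants ($i = 1, 2$) infect one host. We track uninfected bacteria
$B_0$, infected-undecided bacteria $B_i$, lysogens $L_i$ and free phage
$P_i$, all as densities in units of the carrying capacity $K$, with time in
units of the bacterial division time:

$$\dot B_0 = \gamma B_0 (1 - B_{tot}/K) - \eta P_{tot} B_0$$
$$\dot B_i = \gamma B_i (1 - B_{tot}/K) + \eta P_i B_0 - \delta B_i$$
$$\dot L_i = \gamma L_i (1 - B_{tot}/K) + f_i \delta B_i$$
$$\dot P_i = \beta (1 - f_i) \delta B_i - \eta P_i B_{tot}$$

with $B_{tot} = B_0 + B_1 + B_2 + L_1 + L_2$ and $P_{tot} = P_1 + P_2$.

The parameters, their units, and the package defaults:

| parameter | meaning | default | biological range |
|---|---|---|---|
| $\gamma$ (h$^{-1}$) | bacterial growth rate | 1 | 0.5–10 |
| $K\eta$ (h$^{-1}$) | infection rate constant | 20 | 0.45–100 |
| $\beta$ (–) | burst size | 100 | 20–1000 |
| $\delta$ (h$^{-1}$) | decision rate | 1 | 0.5–10 |
| $B_0(0)/K$ (–) | initial bacteria | $10^{-3}$ | $10^{-9}$–1 |
| $P_i(0)/K$ (–) | initial phage, per variant | $10^{-7}$ | $\ge 10^{-9}$ |

Because populations are expressed in units of $K$, the infection rate enters
only as the product $K\eta$; `modelParams()` therefore fixes $K = 1$ and the
`eta` field holds $K\eta$. The defaults are the canonical invasion scenario:
a small bacterial inoculum growing toward carrying capacity, invaded by a
tiny, equal amount of each phage variant ($P_i(0) = 10^{-4} B_0(0)$).

Modelling assumptions worth making explicit: lysogens are immune to
superinfection, and cross- or super-infecting phage DNA is simply lost (the
$-\eta P_i B_{tot}$ sink), so there are no double lysogens and no
state-changing cross-infections; free phage do not decay on these timescales;
spontaneous induction of lysogens is ignored; the system is well mixed (pure
ODEs — no demographic noise, no spatial structure).

Every invasion passes through three phases, which `detectPhases()` and
`crashTime()` extract: the **buildup** (bacteria grow exponentially, phage
grow double-exponentially but remain rare), the **crash** (phage suddenly
infect nearly all uninfected bacteria, within about a generation), and
**lysogenic growth** (phage die out by adsorption; lysogens regrow to $K$).
The buildup ends where $B_0$ peaks; the crash begins, to excellent
approximation, when $P_{tot}$ reaches $\gamma/\eta$ — the point where
infection overtakes bacterial growth; the crash is over when
$B_0 < 0.01\,(L_1 + L_2)$ ("much smaller" is not otherwise quantified; the
1% threshold is an argument of `detectPhases()`).

## The zero-sum game

At steady state only lysogens (and sometimes uninfected bacteria) survive,
so the natural score for variant 1 is its lysogen share advantage,
$(L_1 - L_2)/(L_1 + L_2) \in [-1, 1]$. The two scores sum to zero: a
two-player zero-sum game whose strategies are the propensities $f_1, f_2$.
`buildPayoffMatrix()` plays every grid strategy against every other, and
`minimaxSolution()` finds the minimax strategy: for each column (player 2's
strategy) take player 1's best payoff; player 2 plays the column minimizing
that maximum. In this symmetric game the solution is a saddle point of the
payoff surface — simultaneously a column maximum and a row minimum — and
across all parameter sets we have examined it is unique. Its diagonal
location means no propensity beats $f_{opt}$, while any deviation from
$f_{opt}$ can be beaten: an equilibrium in the game-theoretic sense.

`findFopt()` wraps this coarse-to-fine: a 0.05-step pass over $[0,1]$
locates the saddle, then a 0.01-step pass (configurable) on a window one
coarse step wide around it refines the location. The refinement reproduces
the full fine-grid minimax exactly at the defaults (asserted in the test
suite) because the saddle is unique and the best response to any near-optimal
strategy is itself near-optimal.

Two numeric conventions: antisymmetry is exploited by default (only the
upper triangle is simulated; a validation mode simulates both and the test
suite checks $\max|M + M^T| < 10^{-6}$), and a game in which neither variant
produces lysogens — possible only at $f_1 = f_2 = 0$ — is scored as a draw.
Saddle comparisons use an absolute tolerance of $10^{-8}$; exact ties are
reported in full, with the midpoint of the tie set as `f_opt`.

## The MOI-dependent model and the evolutionary game

To let strategies depend on the multiplicity of infection, infected cells
are subdivided by how many phage of their variant have entered:
$B_{i,1}, B_{i,2}, B_{i,3}$, with MOI truncated at 3 (equivalently, the
propensity is the same for all MOI $\ge 3$). Re-adsorption of the same
variant moves a cell up one class; the top class receives inflow but has no
adsorption outflow; free phage adsorbing to *any* bacterium are removed.
Decisions occur at the same rate $\delta$ in every class, with
class-specific propensities $f(1), f(2), f(3)$. As printed, the infected
compartments of this model carry no logistic growth term (unlike $B_i$ in
the fixed model); we implement the equations exactly as stated and note,
without reconciling, that the two models treat infected-cell growth
differently. The discrepancy vanishes as $\delta$ grows, and the test suite
checks that the MOI model with a flat strategy $(f, f, f)$ reproduces the
fixed model's steady-state lysogen ratio in the large-$\delta$ limit.

The strategy space $[0,1]^3$ is too large for exhaustive payoff matrices, so
the optimum is found by an iterated game (`evolveStrategies()`): two random
strategies compete to steady state; the winner keeps its strategy, the loser
is replaced by a mutated copy of the winner, $f(m) \to (1 + 0.01 r_m) f(m)$
with $r_m$ integer uniform on $[-3, 3]$ drawn independently per class,
clipped to $[0,1]$; repeat until the winner stops changing. A tie (payoff
below $10^{-10}$) retains the incumbent: a mutant must strictly win to
invade. One seeded generator drives initialization and all mutations, so a
seed fully determines the trace.

"Stops changing" needs quantifying. We stop when the winner's strategy has
varied by less than 0.005 in max-norm over the last 300 iterations (cap
3000). The window must be generous because the mutation kernel is
multiplicative: a component near zero moves by at most 3% *of its own value*
per step, so a component still under positive selection can drift by less
than 0.005 over 50 iterations while slowly escaping zero — short windows
freeze runs mid-escape. With the 300-iteration window, runs at the default
parameters converge in roughly 1000–1800 iterations (about two seconds
each).

The typical outcome is the **switch strategy**: $f(1) \approx 0$,
$f(2) \approx f(3) \approx 1$ — lyse when alone, lysogenize in company — and
we verify directly that $(0, 1, 1)$ beats every flat strategy head-to-head.
Occasionally (roughly one seed in fifteen) a run settles instead on the
alternative switch $f(1) \approx f(2) \approx 0$, $f(3) \approx 1$. This
outcome is metastable: it loses a direct pairwise game against $(0,1,1)$,
but escaping it requires weakly selected $f(2)$ mutations whose payoff
advantage is of order $10^{-5}$, so the escape time far exceeds any
practical iteration budget. We log such runs rather than engineering them
away, and summarise converged strategies across seeds by the median, which
estimates the typical-case winner in the presence of this rare mode.

The order of convergence events reflects the ranking of selection pressures:
$f(1)$ is pushed to zero first (lysing when alone maximizes phage production
during buildup), then $f(3)$ rises to one, and finally — under the weakest
pressure — $f(2)$. `convergenceOrder()` reports, per component, the first
entry into a neighbourhood of the converged values; we use the
0.1-neighbourhood ($f(1) < 0.1$, $f(2), f(3) > 0.9$) because, again due to
the multiplicative kernel, reaching a tighter threshold near zero measures
mutation kinetics (a tenfold decay at $\le 3$% per step) rather than
selection order. The ordering holds in the mean across seeds; individual
runs can scramble it when a component happens to start inside its target
neighbourhood.

## The analytic approximation

When decisions are fast ($\delta \gg \gamma$), three observations give a
closed form for the optimum. During buildup, $B_0 \approx B_0(0)
e^{\gamma t}$ and the infected pool is in quasi-steady state, so free phage
grow double-exponentially with the *net* multiplication factor
$\beta(1 - f_i) - 1$ (one phage is spent per infection):

$$\ln \frac{P_i(t)}{P_i(0)} = \left(\beta(1 - f_i) - 1\right)
  \frac{\eta B_0(0)}{\gamma} \left(e^{\gamma t} - 1\right).$$

The crash starts when $P_{tot}(t^*) = \gamma/\eta$, and if it is practically
instantaneous, the remaining bacteria are infected in proportion to
$P_i(t^*)$ and the final lysogen ratio is
$f_1 P_1(t^*) / f_2 P_2(t^*)$ — frozen from then on, since both lysogen
populations grow identically afterwards. The winning propensity therefore
maximizes $f\,P(t^*)$, which yields the scaling
$f_{opt} \sim e^{-\gamma t^*}$ (`foptScaling()`): the later the crash, the
lower the optimum. Eliminating $t^*$ through the crash condition gives

$$f_{opt} = \frac{1 - 1/\beta}{1 + \ln\!\left[\gamma / (\eta P_{tot}(0))\right]},$$

implemented in `foptClosedForm()`. In the symmetric game
$P_{tot}(0) = 2 P(0)$ with $P(0)$ the per-variant inoculum; this is the
package default, with `p0_scope = "total"` available for the other
convention (the two differ by $\ln 2$ inside the logarithm, about 0.004 in
$f_{opt}$ at the defaults). The derivation was validated against
fast-decision simulations away from $\gamma = 1$, where alternative
algebraic readings of the formula separate; the test suite asserts agreement
within 0.02 at $\gamma = 2$, $\delta = 100$.

Neither $K$, $B_0(0)$ nor $\delta$ appears in the formula, and $\beta$
matters only through $1 - 1/\beta \approx 1$: this is why the optimum is so
robust. At biologically reasonable decision rates ($\delta \approx 1$) the
formula underestimates the simulated optimum by about 0.03, because it
ignores the time taken to decide; the offset shrinks by an order of
magnitude at $\delta = 100$ (`compareFormulaVsSimulation()` tabulates both
regimes). The formula is flagged invalid when its logarithm's argument drops
below 1 (enormous inocula), outside its derivation's validity.

## Sweeps, problem sizes and reproducibility

`runSweep()` varies one parameter at a time — log-spaced, 5 points per
parameter by default, over either the biological or the wider explored
preset of `sweepRanges()` — recomputing $f_{opt}$ at each value and
attaching the crash time and the analytic prediction. `trendReport()`
classifies the direction of each trend by comparing consecutive points.
The headline robustness result: over the biological ranges of $\gamma$,
$K\eta$, $\beta$ and $\delta$, every $f_{opt}$ stays within $[0.05, 0.15]$;
only a very large phage inoculum ($P(0)/K = 10^{-3}$) pushes it up, to about
0.3. Trends are increasing in $\eta$, $\beta$, $P(0)$ and $B_0(0)$ and
decreasing in $\delta$ and $\gamma$, all as the crash-time argument
predicts. Sweep points are independent (they could be evaluated
concurrently); results are ordered by parameter value, and every result file
carries the preset, a configuration hash and the package version.

Problem sizes throughout the package's tests and acceptance script are
chosen for a laptop-class single core: minimax at 0.01 resolution via
coarse-to-fine (265 pairwise games, a few seconds), 5-point sweeps, 3–5
evolution seeds. A full 101 × 101 payoff matrix is a few minutes if wanted;
the coarse-to-fine result is identical when the saddle is unique.

## Numerical choices

* **Integrator.** `deSolve::lsoda` (switching Adams/BDF), with the
  right-hand sides compiled in C; an R implementation of both systems is
  exported (`phageRhsFixed()`, `phageRhsMoi()`) and cross-checked against
  the compiled one in the tests. Tolerances `rtol = 1e-8`, `atol = 1e-12`:
  densities span $10^{-9}$ to 1 and payoffs near the saddle differ in the
  third decimal, so the steady-state lysogen densities must be accurate well
  beyond that.
* **Steady state.** Integration proceeds in windows of doubling length
  (first window 100 h, cap $10^5$ h) until $\max|\dot X| < 10^{-10}$ and
  $P_{tot} < 10^{-12}$. The derivative criterion alone is insufficient: a
  fully lytic pair ($f_1 = f_2 = 0$) leaves a static phage population over
  extinct bacteria, which is reported as non-converged rather than as a
  steady state with lysogens.
* **No extinction cutoff.** Populations are continuous ODE variables; tiny
  densities are never zeroed during integration. Solver-induced negatives
  (within `atol`) are clipped to zero in reported trajectories and states
  only. Consequently a structurally zero compartment (e.g. $L_1$ when
  $f_1 = 0$) is numerically of order $10^{-22}$, not exactly zero.
* **Degenerate games.** `payoffScore(0, 0)` is defined as a draw; the
  payoff-matrix diagonal is set to 0 exactly (identical strategies and
  inocula give identical dynamics), which also sidesteps the non-convergent
  $f_1 = f_2 = 0$ corner.

## Limitations

The model is a well-mixed, deterministic caricature: no spatial structure,
no stochastic decision noise or demographic noise, no phage decay, no
spontaneous induction, no double lysogens, no cross-infection effects on
cell fate, and MOI truncated at three. The game considers exactly two
co-circulating variants differing only in lysogeny propensity — burst size
and other parameters are not evolvable here. The closed form further assumes
instantaneous decisions and degrades for very large $\eta$, $\beta$ or
inocula. Agreement of the simulations with these analytic expectations shows
internal consistency of the framework, not validation against experimental
population dynamics.
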