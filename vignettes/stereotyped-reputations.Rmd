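---
title: "Reputations, stereotypes, and the maintenance of cooperation: model and methods"
author: "stereorecip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputations, stereotypes, and the maintenance of cooperation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereorecip)
```

## The model

An infinitely large population is partitioned into `K` non-overlapping
groups with fractions `nu` (the headline configuration is two equal groups).
Individuals repeatedly play one-shot donation games: a donor may pay a cost
`c` to confer a benefit `b > c` on the recipient. Whether a donor cooperates
depends on her strategy:

* **ALLC** intends to cooperate with everyone, **ALLD** with no one.
* **DISC** (a discriminator with stereotype-use propensity `p`) consults the
  recipient's *individual* reputation with probability `1 - p`, paying a
  per-lookup access cost `eta`, and the *stereotyped* reputation of the
  recipient's group with probability `p` (free of charge). She intends to
  cooperate iff the consulted view is good.
* **TAG** (an optional extension) cooperates unconditionally with in-group
  recipients and defects against out-groups.

Intended cooperation fails with probability `u_e` (execution error).
Observers assign good/bad standing under a second-order social norm
parameterized by `(q_C, q_D)` — the probabilities that cooperating with,
respectively defecting against, a *bad* recipient earns good standing — and
every assignment is flipped with probability `u_a` (assessment error). The
four canonical norms are Stern Judging (0, 1), Simple Standing (1, 1),
Scoring (1, 0) and Shunning (0, 0). Folding both error rates into the norm
gives the assessment kernel returned by `assessment_probabilities()`: the
probability that a donor intending action Y toward a recipient the observer
views as X ends up in good standing.

Reputation information is disseminated at one of three *monitoring scales*,
independently for individual and stereotyped reputations: `private` (each
individual holds her own views), `group-wise` (one shared view per group),
`public` (one population-wide view). The mean-field bookkeeping reduces each
scale to an agreement indicator: the probability that a donor and an
observer consult the same view is 0 (private), `1{same group}` (group-wise),
or 1 (public).

## Equilibrium reputations

Because reputations update much faster than strategies, all downstream
quantities are evaluated at the self-consistent equilibrium of the
reputation recursions: for each strategy, donor group, and observer group,
the probability of good individual standing, plus a `K x K` matrix of
stereotyped standings. The recursions couple through population aggregates
(the fraction viewed good by each observer group, and four "agreement"
terms giving the probability that donor and observer simultaneously view a
random third party as good, for the four combinations of individual versus
stereotyped information on either side).

`solve_reputation_equilibrium()` iterates the update map with damped
synchronous iteration `x <- (1 - lambda) x + lambda F(x)`:

* `damping = 0.5` by default — the undamped map oscillates on reflections
  such as `g' = 1 - g`, which arises for error-free defector populations;
* `init = 0.5`, `tol = 1e-12` (sup-norm residual), `max_iter = 1e5`.
  When several equilibria coexist the root reached depends on `init`; 0.5 is
  the canonical root reported everywhere, and callers doing branch
  continuation can pass `warm_start`.
* Degenerate neutrality: with no errors, unconditional cooperators under
  Stern Judging satisfy `g' = g` at every point; the solver detects the
  identity map at the starting point, returns it unchanged, and flags
  `neutral = TRUE` rather than pretending a unique root exists.

Monomorphic populations collapse to scalar fixed points, which is the basis
of the exact checks used in the tests: defectors and unconditional
cooperators under Stern Judging with `u_a = u_e = 0.02` both equilibrate at
`g = 1/2`, and non-stereotyping discriminators under public individual
monitoring at `g = 0.98/1.0192`. The private-monitoring discriminator
equilibrium solves a cubic that the test suite verifies against an
independent bisection oracle.

## Fitness, cooperation, and their structure

`strategy_fitness()` evaluates expected per-round payoffs per strategy and
group: benefits flow from donors whose rule cooperates with the focal
individual, costs from the focal individual's own intended cooperation, and
the access cost `eta (1 - p)` is charged per interaction whenever an
individual reputation is consulted — including when the donor then defects.
`cooperation_rates()` summarizes donor-to-recipient cooperation
probabilities by group pair; they are independent of `b`, `c`, and `eta` by
construction, which the tests assert over random payoff draws.

Two structural facts are worth stating because the package's tests lean on
them. First, when both monitoring scales are private, all views are
uncorrelated draws with a common marginal, so the equilibrium is independent
of the stereotype propensity `p`; selection on `p` then reduces exactly to
the access-cost term (the gradient equals `eta`). Second, in-group
favoritism — higher realized cooperation within than between groups — can
emerge only under group-wise monitoring, where agreement differs within and
between groups; under public or private monitoring with equal groups the
in/out gap vanishes identically.

## Adaptive dynamics of the stereotype propensity

`invasion_fitness()` implements the rare-mutant limit *exactly*: the
resident reputation field is solved with the mutant at literal zero
frequency, and the mutant's reputations are then explicit functions of the
resident aggregates (a measure-zero type feeds back into no aggregate). A
two-type solve at mutant frequency `1e-6` is kept as an independent
cross-check in the test suite. The selection gradient is a central finite
difference in the mutant propensity (step `h = 1e-3`, one-sided at the
boundaries).

`find_singular_points()` scans the gradient on a grid (101 points by
default), brackets sign changes, and bisects to `1e-4` in `p`. Sign change
from + to − is an attractive (convergence-stable) singular point, − to + a
repeller; boundaries are classified from one-sided gradients. We classify by
convergence stability only, matching the attractive/repulsive dichotomy the
analysis targets; separate ESS classification is out of scope. A gradient
that touches zero without changing sign is recorded as degenerate rather
than as a singular point, and an identically neutral gradient (private
monitoring with `eta = 0`) yields an empty set flagged `neutral`.

`bifurcation_sweep()` repeats this along a parameter grid (`eta` by
default, 101 points on [0, 1]; the bifurcation analyses in the literature
report `eta` values between 0.1 and 1.0) and labels each value's regime:
`p0-only`, `bistable`, `high-p-only`, or `neutral`. Under public/public
monitoring at the standard payoffs this machinery locates the fold at
`eta = 0.35`, where an interior attractor near `p = 0.84` appears alongside
the `p = 0` attractor — the hysteresis loop that makes established
stereotyping hard to dislodge.

## Replicator dynamics

`replicator_rhs()` evaluates the group-size-weighted replicator equation,
re-solving the reputation equilibrium at every call (warm-started for
speed). `integrate_trajectory()` wraps `deSolve::ode` (lsoda, `rtol 1e-8`)
with renormalization guards; a `clamp` argument holds one strategy's
frequency fixed to study, e.g., adaptation of discriminators against a
frozen 20% defector background. `classify_equilibria()` enumerates
vertices, scans each edge's one-dimensional payoff difference for interior
roots, grid-scans the interior (barycentric lattice, density 20 by default)
with a Nelder–Mead polish, and classifies every equilibrium by central
finite-difference eigenvalues of the Jacobian projected on the simplex
(coordinates drop the dominant strategy so vertex perturbations stay
feasible; real parts within `1e-8` of zero are flagged neutral). At a
vertex, the edge eigenvalues coincide with `rare_invader_fitness()`, which
the tests assert — this is the cross-module consistency between the
replicator and invasion analyses.

## The finite-population simulator

`run_abm()` is the stochastic counterpart used to check the mean-field
predictions: `N` discriminators (default 50) in `K` equal groups play
everyone each round — including themselves, which keeps the bookkeeping
faithful to the model's definition and cancels in payoff comparisons — then
all views are re-assessed synchronously by the observers each monitoring
scale prescribes (1 public observer, `K` group-wise, `N` private). After
`rounds_per_generation` rounds, five random ordered pairs compare
per-generation payoffs under the Fermi rule with selection intensity `w`,
and with probability `u_s = 10/N` one agent's propensity is perturbed by a
Normal(0, 0.05^2) deviate, clipped to [0, 1].

Design choices where the sources are silent or ambiguous:

* The generation length is a knob. One reading of the reference conditions
  is 2500 rounds per generation; another normalizes payoffs to "100 games
  per generation". We default `rounds_per_generation = 2500` and always
  rescale cumulative payoffs to `games_per_generation = 100` games, so the
  Fermi comparison operates on the same scale under either reading.
* The selection intensity `w` is not specified; the default is 1. When
  generations are scaled down to `R` rounds for runtime, the per-generation
  payoff standard error grows like `1/sqrt(R)`, so comparisons at fixed `w`
  become noisier than at full scale. The scaled-down runs in the tests and
  the reproduction script therefore use the variance-matched
  `w = sqrt(2500/R)` (e.g. `w = 5` at `R = 100`), which preserves the
  signal-to-noise ratio of each Fermi comparison.
* Observers may observe their own interactions, and a group-wise observer
  updates her own group's stereotype by the same sampling rule as any other
  group's.
* Mutated propensities are clipped to [0, 1] because `p` is a probability.

The generation loop is implemented in compiled code (Rcpp) and consumes R's
RNG, so runs are reproducible from `set.seed()`; a pure-R reference loop
built from the exported `play_round()` / `update_reputations()` /
`imitate_and_mutate()` operations is retained (`engine = "r"`) and the test
suite checks that the two paths agree distributionally.

What the simulator does and does not emulate: it realizes the model's own
sampling assumptions (binary views, one observation per donor per observer,
synchronous updates) at finite `N`, so agreement with the mean-field
solution validates the analytical machinery, not the model's realism.
Finite-`N` corrections of order `1/N` are visible at small populations, and
the simulator evolves only the stereotype propensity among discriminators —
competition with unconditional strategies is analyzed at the mean-field
level by the replicator module.

## Problem sizes used in the shipped analyses

The test suite and the reproduction script run: selection-gradient grids of
101 points; bifurcation sweeps over `eta` in [0.25, 0.45] at step 0.005;
cooperation curves of 101 points for all nine monitoring combinations;
stochastic runs with `N = 100` (600 rounds, fixed propensity) for the
mean-field comparison and ten runs with `N = 50`, 100 rounds per generation
and 5000 generations (variance-matched `w = 5`) for the convergence of the
propensity to its predicted attractor. These sizes reproduce all qualitative
targets and keep the full suite within a coffee break on one CPU.

## Known limitations

* Scoring, Shunning and Simple Standing are fully supported by the
  machinery, but the shipped analyses focus on Stern Judging; cross-norm
  evolutionary competition and observer-heterogeneous norms are out of
  scope.
* The adaptive-dynamics module classifies singular points by convergence
  stability only; evolutionary branching is not analyzed.
* Boundary attractors at `p = 0` and `p = 1` are classified from one-sided
  gradients at the grid ends, so attractors within `1/(resolution - 1)` of a
  boundary can merge with it.
* Reputation equilibria are found by damped fixed-point iteration; in
  bistable regions the reported root depends on the initial value (0.5 by
  default), which branch sweeps must — and do — handle by warm starting.

## A worked example

```{r example, eval = FALSE}
pars <- model_params("SternJudging", "public", "public", eta = 0.35)
find_singular_points(pars)
#>      p_star attractive     kind   gradient cooperation ingroup_gap
#> 1 0.0000000       TRUE boundary -0.5806683   0.9423077           0
#> 2 0.6870528      FALSE interior  0.0000000   0.8292266           0
#> 3 0.8417571       TRUE interior  0.0000000   0.8624337           0
#> 4 1.0000000      FALSE boundary -0.1023077   0.9423077           0
```

Read: at access cost 0.35, abstaining from stereotypes (`p = 0`) is locally
stable, but so is heavy stereotyping (`p* = 0.84`), the two basins separated
by a repeller at `p = 0.69`; full stereotyping `p = 1` is not a rest point
(the gradient at 1 is negative). The cooperation column shows the price: the
high-stereotyping attractor supports lower cooperation (0.86) than either
pure information regime (0.94).
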