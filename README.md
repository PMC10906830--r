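# stereorecip

Indirect reciprocity sustains cooperation through reputations: people help
those in good standing, and helping earns good standing. But judging every
individual is cognitively costly, and people often fall back on
*stereotypes* — a single good/bad assessment attached to a whole social
group. `stereorecip` implements a game-theoretic model for studying when
such stereotyped reputations help or hurt cooperation, for researchers in
evolutionary game theory and social evolution.

The population is infinitely large and partitioned into `K` groups. In
one-shot donation games a donor pays `c` to give `b > c`. A discriminator
with stereotype-use propensity `p` consults the recipient's individual
reputation with probability `1 − p` (paying an access cost `η` per lookup)
and the recipient group's stereotype with probability `p`, cooperating iff
the consulted view is good. Observers assign standing under a second-order
social norm `(q_C, q_D)` — Stern Judging (0, 1), Simple Standing (1, 1),
Scoring (1, 0), Shunning (0, 0) — with execution errors `u_e` and assessment
errors `u_a`, and views are shared at one of three monitoring scales
(private, group-wise, public), independently for individual and stereotyped
information.

The package provides four layers of analysis:

* **Equilibrium reputations** — the self-consistent mean-field system for
  individual standings `g_i^{J,I}` (strategy i, donor group J, observer
  group I) and stereotypes `g_S^{J,I}`, under any of the nine
  monitoring-scale combinations (`solve_reputation_equilibrium`).
* **Payoffs and cooperation** — per-round fitness `Π_i^I` and
  within/between-group cooperation rates at equilibrium
  (`strategy_fitness`, `cooperation_rates`, `cooperation_curve`).
* **Strategy dynamics** — replicator dynamics
  `ḟ_i = f_i Σ_J ν_J (Π_i^J − Π̄^J)` on the simplex over {ALLC, ALLD,
  pDISC, TAG}: trajectories, flow fields, equilibrium enumeration with
  stability (`integrate_trajectory`, `classify_equilibria`), plus adaptive
  dynamics of the propensity `p`: exact rare-mutant invasion fitness
  `Σ_J ν_J (Π_Q^J − Π_R^J)|_{f_Q=0}`, selection gradients, singular points,
  bifurcation sweeps and pairwise invasibility plots (`invasion_fitness`,
  `find_singular_points`, `bifurcation_sweep`, `pip_grid`).
* **Stochastic simulation** — a seed-reproducible finite-population
  simulator (compiled core) with binary views, synchronous observer
  updates, Fermi pairwise-comparison imitation and local mutation of `p`
  (`run_abm`).

## A worked example

Where does the stereotype propensity evolve under Stern Judging when all
information is public (`b = 3`, `c = 1`, `u_e = u_a = 0.02`)?

```r
library(stereorecip)
pars <- model_params("SternJudging", "public", "public", eta = 0.35)
find_singular_points(pars)
#>      p_star attractive     kind   gradient cooperation ingroup_gap
#> 1 0.0000000       TRUE boundary -0.5806683   0.9423077           0
#> 2 0.6870528      FALSE interior  0.0000000   0.8292266           0
#> 3 0.8417571       TRUE interior  0.0000000   0.8624337           0
#> 4 1.0000000      FALSE boundary -0.1023077   0.9423077           0
```

At access cost `η = 0.35` the dynamics are bistable: no stereotyping
(`p = 0`) and heavy stereotyping (`p* ≈ 0.84`) are both attractors,
separated by a repeller at `p ≈ 0.69`. The cooperation column quantifies
the cost of the stereotyping attractor: 0.86 versus 0.94 at `p = 0`. Below
`η = 0.35` the interior attractor disappears and `p = 0` is the unique
stable outcome — so a population that stereotypes heavily snaps to `p = 0`
only once `η` drops through that fold, a hysteresis that makes established
stereotyping hard to dislodge.

The same machinery exposes the destabilizing side of stereotypes:

```r
rare_invader_fitness("DISC", "ALLD", model_params(eta = 0.1), resident_p = 0)
#> [1] -1.617262     # defectors cannot invade non-stereotyping discriminators
rare_invader_fitness("DISC", "ALLD", model_params(eta = 0.1), resident_p = 1)
#> [1] 0.9423077     # ... but they invade full stereotypers at any access cost
```

## Command-line interface

```sh
inst/cli/stereorecip coop-curve  --norm SternJudging --ind-scale public --st-scale group-wise
inst/cli/stereorecip bifurcation --eta-points 101 --alld-background 0.2
inst/cli/stereorecip pip         --eta 0.3
inst/cli/stereorecip simplex     --strategies "ALLD,0DISC,1DISC" --eta 1.0
inst/cli/stereorecip abm         --N 50 --p0 0.5 --rounds 2500 --generations 1000
inst/cli/stereorecip run         --config experiment.yaml
```

Each subcommand writes plotting-ready CSV files plus a JSON manifest of the
fully resolved configuration. See `vignettes/stereotyped-reputations.Rmd`
for the model details, numerical choices, and known limitations.
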