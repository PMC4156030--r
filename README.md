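# devhourglass

Evolutionary simulation of developmental gene networks and the hourglass
pattern.

Comparative embryology keeps finding an "hourglass": early and late
development diverge freely between species, while a mid-developmental
window — the phylotypic stage — is strongly conserved, expresses the
evolutionarily oldest transcriptome, and is where perturbations are most
lethal. `devhourglass` is for evo-devo and systems-biology researchers who
want to study *why* such a pattern can emerge from the structure of
developmental gene regulation, and to test its signatures in staged
expression data.

## The model in brief

Development is modelled as a **developmental gene execution network
(DGEN)**: a layered DAG whose layer-`l` nodes are the regulatory genes
transitioning at stage `l`, with edges only between consecutive stages.
Each stage has a regulatory specificity `s(l)`; a stage-`l` gene regulates
a given stage-`l+1` gene with probability `s'(l) = 1 − s(l)`. A population
of `N` individuals evolves Wright-Fisher-style under per-gene deletion
(DL), duplication (DP) and rewiring (RW) events. A gene that loses a
fraction `r` of its upstream regulators fails with probability

    P_RF(r) = 1 − exp(−z·r/(1−r)),   P_RF(1) = 1,

and failures cascade toward later stages; an individual whose final stage
drops below the viability threshold Γ fails development and is replaced by
a surviving individual's clone. Four presets of increasing complexity are
provided: constant specificity (model 1), linearly increasing `s(l) = l/L`
(model 2), plus duplications under a dynamic size controller (model 3),
plus deletions (model 4).

The shape of a width profile `w(1..L)` is scored by the **hourglass
score** `H = (τ_Y − τ_X)/2`, where `τ_X`, `τ_Y` are normalized
Mann-Kendall trend statistics of the widths before and after the waist
(the minimum-width stage, ties broken toward mid-development): `H = 1` for
a clean hourglass, about `0.5` for a monotonically increasing (funnel)
profile. Stage lethality, gene age `A(g) = i − t0(g)` and gene prevalence
complete the simulation observables. For staged expression matrices, the
package identifies **transitioning genes** (`|δ| > c` on normalized or
absolute expression), sweeps the threshold `c`, and computes each
stage-pair's expression-weighted **transcriptome age index (TAI)** from a
phylostratum-rank table.

## Worked example

```r
library(devhourglass)

cfg <- sim_config(model = 2, N = 10, L = 10, gamma0 = 20, z = 4,
                  P_RW = 1e-3, generations = 5000, metric_interval = 1000,
                  seed = 11)
sim <- run_simulation(cfg)
sim
#> <dgen_sim> model 2, N = 10, L = 10, gamma0 = 20, 5000 generations (seed 11)
#> final generation: median H = 0.732, median size = 181, 9590 events logged
```

After 5,000 generations under increasing specificity the population median
hourglass score has risen from ~0.5 (the score of the initial flat
profile read as increasing) to 0.732, and the networks have lost genes
preferentially in mid-development: the median DGEN carries 181 of its
initial 200 genes. `tidy(sim)` returns the checkpoint-by-individual
trajectory, `glance(sim)` the one-row summary, `autoplot(sim)` and
`plot_width_profile(sim)` the standard figures, and `sim_lethality()` /
`sim_age_by_stage()` the per-stage observables.

Scoring a width profile directly:

```r
hourglass_score(c(100, 80, 60, 40, 60, 80, 100, 120, 130, 140),
                exclude_first = FALSE)
#> # A tibble: 1 × 5
#>       H H_robust waist tau_X tau_Y
#> 1     1        1     4    -1     1
```

The profile decreases to a waist at stage 4 and increases after it, so
both trend statistics are extreme and `H = 1` — a perfect hourglass.

The transcriptome pipeline on synthetic data with known ground truth:

```r
des <- synth_design(seed = 7)           # waist planted at stage-pair 4
synth <- synth_expression(des)
threshold_sweep(synth$expression, c(1.2e-4, 2e-4, 3.9e-4),
                mode = "normalized")
#> # A tibble: 3 × 5
#>         c     H H_robust waist total
#> 1 0.00012     1        1     4   170
#> 2 0.0002      1        1     4   170
#> 3 0.00039     1        1     4   170
```

Across the design's whole threshold band the sweep recovers the planted
waist (stage-pair 4), a perfect hourglass score, and all 170 planted
transitioning genes.

A thin command-line wrapper is installed with the package
(`inst/cli/hourglass.R`) with `simulate`, `score-widths`, `analyze-expr`
and `synth` subcommands over the same functions.

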