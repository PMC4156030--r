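---
title: "An evolutionary model of the developmental hourglass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evolutionary model of the developmental hourglass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devhourglass)
```

## The question and the model

Cross-species comparisons of embryogenesis repeatedly find an "hourglass"
pattern: early and late development diverge freely between species while a
mid-developmental period — the phylotypic stage — is strongly conserved,
expresses the evolutionarily oldest transcriptome, and is the period where
perturbations are most lethal. `devhourglass` implements a population-level
evolutionary model that asks under which conditions this pattern emerges
from the structure of developmental gene regulation alone.

The model's central object is the *developmental gene execution network*
(DGEN): a layered directed acyclic graph whose layer-`l` nodes are the
regulatory genes that change functional state at developmental stage `l`,
and whose edges denote causal triggering of a state transition at the next
stage. Edges only connect consecutive stages, so development is a single
forward pass through the layers.

Each stage `l` carries a *regulatory specificity* `s(l)` in `[0, 1]`: a
gene at stage `l` regulates any given gene at stage `l + 1` independently
with the complementary probability `s'(l) = 1 - s(l)`. High specificity
means sparse, targeted downstream regulation. Three profile shapes are
provided (`specificity_profile()`): constant, linear `s(l) = l/L`, and a
logistic ramp `s(l) = 0.9 - 0.8/(1 + exp(l - gamma_mid))` rising from 0.1
to 0.9 with its 50% point at the stage `gamma_mid`. We use the increasing
orientation of the ramp throughout: the model's key assumption is that
specificity increases along development (general-purpose regulators early,
organ- and tissue-specific regulators late), and `gamma_mid` is meaningful
precisely as the stage where an increasing specificity crosses 50%.

A population of `N` individuals, each carrying a DGEN, reproduces
asexually. Per gene and generation, three structural perturbations occur
independently:

* **deletion** (probability `P_DL`) removes a gene with all incident
  edges;
* **duplication** (`P_DP`) inserts an identical copy — same stage, same
  upstream and downstream regulators, same functional label and age;
* **rewiring** (`P_RW`) redraws a gene's upstream regulators from the
  previous stage at probability `s'(l - 1)` and perturbs its downstream
  edges incrementally: with `N-` and `N+` independent
  `Binomial(|D(g)|, s'(l))` draws, `N-` existing outgoing edges are
  removed and `N+` new ones are added among unconnected targets, so the
  new out-degree stays within `[0, 2 |D(g)|]`. The gene receives a fresh
  functional label and its `t0` is reset — rewiring creates, in effect, a
  new gene in an old slot.

Losing upstream regulators can disable a gene. A gene that lost a fraction
`r` of its regulators this generation undergoes *regulatory failure* with
probability

\[ P_{RF}(r) = 1 - e^{-z r / (1 - r)}, \qquad P_{RF}(1) = 1, \]

where `z >= 0` measures the fragility of regulatory interactions
(`regulatory_failure_prob()`). Removed genes deprive their own downstream
targets, so failures cascade stage by stage toward the end of development
(`propagate_cascade()`). Because edges span exactly one boundary, a single
ascending pass over stages computes the cascade exactly — no fixed-point
iteration is needed.

The final stage represents the developed embryo: an individual whose
final-stage width falls below the viability threshold `gamma0` suffers
*developmental failure* and is replaced by a clone of a uniformly chosen
surviving individual, keeping the population size constant
(`df_policy()`, `step_generation()`). Two relaxations of the strict
threshold are provided: a tolerance `gamma_tol` (fail below
`gamma0 - gamma_tol`) and a probabilistic linear ramp
`min(1, (gamma0 - w(L))/ramp_width)`; the ramp shape is our choice — any
monotone ramp would do, and the linear one is the simplest with a single
width parameter.

## Scores and observables

**Hourglass score.** For a width profile `w(1..L)` the waist `b` is the
minimum-width stage, ties broken toward `floor(L/2)` (equidistant ties to
the earlier stage — a deterministic convention we fix once). With `X` the
widths up to the waist and `Y` from the waist on,

\[ H = \frac{\tau_Y - \tau_X}{2}, \]

where `tau` is the normalized Mann-Kendall trend statistic: the average of
`sign(x_j - x_i)` over ordered pairs, `-1` for decreasing, `+1` for
increasing, near 0 for random sequences; ties contribute zero to the sum
but count as pairs. `H = 1` for a clean hourglass, and about `0.5` for a
monotonically increasing profile, because the pre-waist segment is then a
singleton whose trend we define as 0. A robust variant excludes adjacent
pairs (`j >= i + 2`) from both trend statistics, which desensitizes the
score to single-stage jitter. We read "do not take into account adjacent
stages" as dropping adjacent comparison *pairs*; the alternative reading —
subsampling every other stage — discards half the data rather than half
the comparisons and makes the score depend on the subsampling phase, so we
did not adopt it.

For simulated populations the first stage is excluded from scoring by
default (`exclude_first = TRUE`): without deletions, stage-1 genes are
never removed (they have no upstream regulators to lose), so their width
is frozen and would bias the pre-waist trend. Transcriptome stage-pair
profiles have no such frozen element and are scored over all pairs.

**Stage lethality** is estimated from the event log as the fraction of
deletion and rewiring events at stage `l` whose individual failed
development that generation. Duplications are never counted. When an
individual fails in a generation with several DL/RW events, all of them
are flagged: at the per-gene probabilities the model is run with
(`<= 1e-3`), two or more events per individual-generation are rare enough
that the attribution bias is negligible.

**Gene age** is `A(g) = i - t0(g)`, generations since the last rewiring;
duplicates inherit their parent's `t0`. **Prevalence** of a functional
label is the fraction of individuals carrying at least one gene with that
label. Because clones preserve instance ids and labels, both quantities
are comparable across individuals.

## The transcriptome pipeline

Real expression time courses cannot reveal a DGEN's edges, but they can
estimate its stage widths. For a genes-by-stages matrix, expression is
normalized per stage (`e'_{i,l} = e_{i,l} / sum_j e_{j,l}`), and a gene is
*transitioning* at the stage-pair `(l-1, l)` when
`|delta_{i,l}| = |e'_{i,l} - e'_{i,l-1}| > c` for a threshold `c` (strict
inequality; boundary values do not transition). The per-pair counts
`n(2..L)` form the width profile that `threshold_sweep()` scores across a
grid of thresholds; `delta_cdf()` shows where a chosen `c` sits in the
distribution of expression changes. A gene transitioning `n` times counts
in `n` pairs.

With a phylostratum rank table (`read_ages()`, lower rank = older), each
pair receives a transcriptome age index: the expression-weighted mean rank
of its age-known transitioning genes, weighted by the later stage's
normalized expression,

\[ TAI(l) = \frac{\sum_i p_i\, e'_{i,l}}{\sum_i e'_{i,l}}. \]

Pairs with fewer than `min_genes` age-known transitioning genes report
`NA`; the weights default to normalized expression in both identification
modes (the formula is stated in normalized terms), with
`weights = "absolute"` as a switch. Genes of unknown age count toward
widths but not toward TAI.

## The synthetic generator

`synth_design()` / `synth_expression()` produce matrices whose ground
truth is known by construction: planted genes take one persistent step at
an assigned pair, background variation is truncated-normal noise, and the
two are separated by a guaranteed margin — every planted normalized
`|delta|` exceeds the band's upper edge `c_hi` while every background
`|delta|` stays below the lower edge `c_lo` (the generator verifies both
after construction and requires `c_lo > 6 * noise_sd`). Step signs
alternate within each pair so column sums can be rebalanced through a
negligible correction spread over background genes. Defaults (400 genes, 6
stages, planted pair counts 50/30/10/30/50 with the waist at pair 4, rank
profile 5/4/2/4/5) emulate the statistical structure the pipeline assumes:
threshold-separable transitions, hourglass-shaped widths, old genes at the
waist. What the generator deliberately does *not* emulate is real
measurement noise — no heteroskedasticity, no count noise, no
between-replicate variance — so recovering the planted structure validates
the pipeline's arithmetic, not its robustness on noisy microarray or
RNA-Seq data.

## Numerical and design choices

* **Event order.** Within a generation and individual, phases run
  duplication, then deletion, then rewiring, each as independent per-gene
  Bernoulli draws over the genes present at the phase start. The model
  itself specifies no order; a fixed order makes runs reproducible, and at
  the probabilities used multi-event interactions are negligible.
* **What counts as loss.** The RF fraction `r` counts only losses of
  *baseline* regulators (the upstream set at the generation's start);
  edges gained during the same generation never offset losses. A gene
  rewired this generation adopts its new upstream set as its baseline and
  is exempt from RF — its rewiring replaces regulators rather than losing
  them. Genes created this generation have no baseline and are likewise
  exempt. A single end-of-generation evaluation on cumulative loss is
  used rather than one evaluation per event.
* **Empty draws.** A constructed gene above stage 1 with no upstream
  regulator could never transition, so construction and the rewiring
  upstream redraw both repair an empty draw with one uniformly chosen
  regulator.
* **All-fail generations.** If every individual fails, the previous
  population is retained and a warning is issued. This happens only in
  deliberately extreme settings.
* **RNG.** One seeded stream per run with a fixed iteration order
  (individuals in index order, phases in DP/DL/RW order) makes every run
  bit-reproducible from its seed.
* **Duplication controller.** For models 3-4, `P_DP` is multiplied or
  divided by a factor (default 1.2) every 100 generations to keep the
  population-mean DGEN size inside a target band (70-80% of `L * gamma0`),
  clamped to at most 0.01. The generation loop also applies a floor of
  1e-7: during the long initial approach from above, unbounded division
  drives `P_DP` to numerical zero, from which the multiplicative recovery
  would take thousands of generations.
* **Output formatting.** Report files print floating-point values at 6
  significant digits and carry a `# run_id:` provenance comment; the JSON
  summary echoes the full configuration and seed.

## Problem sizes

The dynamics of interest — hourglass emergence, waist placement, the
lethality and age profiles — are asymptotic population properties. The
package's documented study conditions use populations of 10-30
individuals, 10 stages, 20-100 genes per stage and rewiring probabilities
of `1e-4` to `2e-3` over 15,000-50,000 generations: large enough that the
width profiles converge and the score trajectories flatten, small enough
to run on a laptop core in minutes. Raising `P_RW` compresses evolutionary
time (events per generation scale linearly) without changing which
structures are favored, which is how the long-run regimes are reached at
these scales. Because individuals within a population are strongly
correlated (every developmental failure replaces an individual with a
clone), single-run medians fluctuate considerably; summary comparisons
therefore pool small ensembles of independent runs — the model's standard
protocol — and take medians across all individuals and all runs. The test
suite pins the qualitative outcomes (score orderings, unimodal lethality
and age profiles, waist shifts with `gamma_mid` and `z`, controller
band-keeping) rather than any particular trajectory.

## Limitations

* The DGEN is an abstraction: genes may appear at several stages in real
  regulatory cascades, but each stage-slot here is a distinct gene record;
  there is no regulatory logic (activation vs repression, input
  functions), no spatial domains, and no multi-state expression.
* Selection is binary (develop or fail); there are no graded fitness
  effects, no recombination, and no explicit selection coefficients.
* The trend statistic is used descriptively; no significance testing of
  `tau` is provided.
* The transcriptome pipeline consumes precomputed phylostratum ranks; it
  does not infer orthology or gene ages, and it does not preprocess raw
  microarray or RNA-Seq measurements.
```{r session, eval = FALSE, include = FALSE}
sessionInfo()
```
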