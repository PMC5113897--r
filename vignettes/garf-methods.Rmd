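---
title: "Methods: evolving reduced gene panels with GARF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolving reduced gene panels with GARF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(garf)
```

## The model

`garf` treats panel reduction as a combinatorial search: given a pool of
$p$ candidate genes shared by all cohorts, find a subset of fixed size $k$
whose random-forest classifier reproduces a reference classification as
faithfully as possible on cohorts it was not trained on. Exhaustive search
is hopeless — already $\binom{753}{48} \approx 2.13\times 10^{76}$
(`big_choose(753, 48)` computes it exactly) — so the search is a genetic
algorithm whose individuals are gene panels and whose selection operator
acts on the *pool*, not on individual panels:

* each generation draws $p$ panels of $k$ genes uniformly without
  replacement from the current pool (one panel per pool gene, so the
  number of models shrinks with the pool);
* each panel's fitness is the pooled concordance of its forest's
  predictions with the reference labels over all evaluation-cohort
  samples;
* the top $\lceil p/k\rceil$ models survive — the dynamic survivor rule.
  This is the *minimum* number of $k$-gene panels that could jointly carry
  all $p$ genes, so if all genes performed equally, none would be forced
  out; in practice only genes that appear in more than one top model tend
  to persist. Equivalently, the top $100/k$ percent of models survives
  (2.08% at $k=48$);
* the next pool is the union of the survivors' genes. There is no
  crossover or mutation operator: recombination happens implicitly when
  the next generation resamples panels from the reduced pool. This rewards
  genes with *combined* predictive value rather than punishing genes that
  happened to land in weak company.

A generation is accepted only if its mean fitness (over **all** its
panels, not just survivors) strictly exceeds the previous accepted
generation's. The run stops on the first non-improving generation, when
the pool reaches the target size, when no gene was eliminated (the search
would loop), or at a `max_generations` safeguard — the latter two guards
are ours; without them a plateaued pool cycles forever. The best panel is
the top-fitness panel of the best-performing generation. The entire search
restarts `n_runs` times (default 10) from derived seeds, and the winner is
the best panel across runs by pooled evaluation concordance.

### Train / evaluate / holdout separation

Fitness is always computed by training on the single training cohort and
scoring on the evaluation cohorts; cross-validation inside a pooled
training set would reward cohort-specific quirks. The holdout cohort
exists to detect exactly that failure mode, so it must not influence
selection: `evaluate_subset()` never receives it, and `garf()` scores it
exactly once, after the cross-run winner is fixed. Ranking the restarts on
evaluation cohorts only (rather than evaluation + holdout) is the
no-leakage reading of an ambiguous design choice; the panel-size module
exposes `include_holdout = TRUE` for strict replication of designs that
scored every available sample.

## Choosing the panel size

`panel_size_curve()` estimates, for each candidate size $s$ (default grid
2–60), the mean pooled concordance of `n_models` (default 1000) random
$s$-gene panels. The raw means are noisy, so they are smoothed with local
polynomial regression (`stats::loess`, degree 2, span 0.75,
`surface = "direct"` so grid-point fits are exact for polynomials); the
selected $k$ is the largest grid size reached before the first smoothed
forward difference falls below `gain_threshold` (default 0.001 percentage
points of accuracy per added gene). Two interpretive choices are worth
flagging: the threshold is read as *percentage points on the smoothed
curve's forward differences* over the integer grid, not as a derivative
estimate or a relative gain; and when every gain is sub-threshold the
smallest grid size is returned with a warning rather than an error, since
a flat curve is informative (no size helps).

## Random forests

Forests use the `randomForest` implementation: `trees` per model (default
5000 — all models in a study are built identically) and the package's
classification default `mtry = ⌊√k⌋` unless overridden. 5000 trees is far
past stabilization for panels of this size; the package-level studies in
the test suite use 40–150 trees, which we found adequate for panels of
4–12 genes at these sample sizes while keeping a full multi-seed study in
the minutes range. Seeds are derived hierarchically (master seed → run
seeds → per-panel forest seeds) so that whole searches are bit-reproducible
while panels within a generation are not seed-correlated.

## Preprocessing

The harmonization stack mirrors common multi-cohort microarray practice,
in this order: brightest-probe collapse, gene intersection, quantile
normalization, batch adjustment.

* **Brightest probe** (`collapse_probes()`): for genes with several
  probes, the probe with the highest mean intensity across that dataset's
  samples is retained (configurable to median). Brightness is judged
  per-dataset, before cohorts are combined, since probe behaviour is
  platform-specific.
* **Gene intersection** (`intersect_genes()`): only symbols present in
  every cohort survive, sorted lexicographically so all downstream
  matrices align deterministically.
* **Quantile normalization** (`quantile_normalize()`, backed by
  `limma::normalizeQuantiles`): applied to the column-bound combined
  matrix, mapping every sample onto the per-rank mean distribution, ties
  receiving the mean of the tied ranks' reference values. It is idempotent
  up to floating-point noise.
* **Batch adjustment** (`batch_adjust()`): the built-in `center_scale`
  mode standardizes each gene within batch and maps it back to the gene's
  global mean and pooled within-batch standard deviation, exactly removing
  additive and multiplicative batch shifts. It is deliberately *not*
  ComBat: it performs no empirical-Bayes shrinkage across genes, which
  matters for small batches where gene-wise variance estimates are
  unstable. The pluggable `mode = "combat"` (via `sva`) is available when
  that shrinkage is wanted. Batches with a single sample are an error;
  a gene with zero variance inside a batch gets a location-only
  adjustment there, with a message.
* **Rank normalization** (`rank_normalize()`): per-sample fractional ranks
  `rank/n` in $(0, 1]$, ties averaged — the convention used when RNA-seq
  queries must be compared against microarray-trained panels, because it
  depends only on within-sample ordering and is invariant to any strictly
  monotone per-sample transform.

## The simulator and what it does (not) show

`simulate_cohorts()` generates the data structure the method targets:
several cohorts over one gene universe, a minority of class-informative
genes, and cohort-aligned batch effects. Its defaults are the package's
study conditions and are fixed: 4 classes, 40 informative + 160 noise
genes, 15 samples per class per cohort (60 per cohort, comparable to the
smaller cohorts in multi-cohort subtype studies), within-class SD 1,
effect size $\delta = 2$ SD units, additive cohort offsets
$0.5\,(i - 1)$ with unit scale, and 3 cohorts filling the
training/evaluation/holdout roles. Each informative gene is a
subtype-marker: one randomly chosen "up" class is shifted by
$\delta\,\sigma$ above a gene-specific baseline drawn from
$\mathcal{N}(7, 1)$ (a typical log2-intensity scale); full-factorial class
means can be configured instead, but single-marker structure matches how
subtype signatures actually look. `planted_recovery_score()` then measures
how strongly a selected panel concentrates the planted genes (precision,
and enrichment relative to the pool's informative fraction).

What passing on this simulator shows: the survivor rule concentrates
jointly predictive genes, the stopping rule halts at or near the signal,
and the holdout protocol detects the resulting panels' generalization.
What it does not show: robustness to correlated co-expression blocks,
heavy-tailed intensity noise, platform-specific probe effects,
class imbalance, or label noise in the reference classification — real
microarray/RNA-seq cohorts have all of these, so performance numbers on
simulated data do not transfer to real accuracy claims.

## Numerical choices and degenerate inputs

* Ranking ties (equal pooled concordance) are broken by lower panel
  sampling index, making every step deterministic.
* `survivor_percentage()` rounds half-up (100/32 = 3.125 → 3.13), the
  convention a reader applies by hand, rather than IEEE round-half-even.
* A pool already at $k$ genes yields one generation of identical panels
  and stops immediately (`target_reached`).
* Concordance requires identical sample-id sets; missing panel genes in a
  query are a hard error naming the symbols — no imputation, since a
  panel is only as portable as its complete gene list.
* Holdout concordance is `NA`, not 0, when no holdout cohort exists.
* The search-space count `big_choose()` uses exact integer arithmetic
  (multiply, then exactly divide, in base-$10^9$ chunks); doubles lose
  exactness for these counts beyond $2^{53}$.

## Problem sizes used in the packaged studies

The test suite runs the full pipeline at deliberately desk-scale settings
chosen as the smallest configurations where the statistical properties are
clearly resolved: the planted-recovery study uses the simulator defaults
with $k = 12$, 150 trees, ten seeds, and a 100-panel random baseline; the
size-curve study uses 50 random models per size over sizes 2–30. The
production-scale settings (5000 trees, 1000 models per size, sizes 2–60,
10 restarts) are the documented defaults of the corresponding functions.

## Known limitations

* Fitness evaluation retrains one forest per panel per generation; at
  production scale (pools of ~750 genes, 5000 trees) a search is hours of
  CPU, and the package makes no attempt to parallelize it.
* The survivor rule can stall on plateaus (`no_elimination`) when $k$ is
  large relative to the pool; the run guards stop it, but the returned
  pool may then sit above the target size.
* `center_scale` assumes batch effects are gene-wise location–scale
  shifts; interaction-type batch effects (batch × class) are outside its
  model and will leak into fitness.
* The reference labels are taken as ground truth; the method reproduces
  them, including their mistakes.
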