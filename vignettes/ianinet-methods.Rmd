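---
title: "Imbalance-aware network integration: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalance-aware network integration: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Genome-wide cancer driver prediction is a positive–unlabelled (PU)
classification problem with severe class imbalance: the curated positives
(COSMIC-style driver lists) cover under 5% of network genes, and the
"negatives" are merely genes not yet curated. `ianinet` models a gene's
driver propensity purely from its position in a high-confidence
protein–protein interaction network. The working assumptions are:

* interactions with combined confidence ≥ 700 (on STRING's 0–1000 scale)
  are reliable enough to define the graph; below-threshold edges carry more
  noise than signal;
* the graph can be treated as simple and undirected for centrality
  computation (self-loops dropped, duplicate edges collapsed to the maximum
  confidence), while outdegree/indegree bookkeeping retains the directed
  reading of the input file — on reciprocal-row STRING files the two
  coincide;
* driver genes are topologically distinctive: higher degree, betweenness
  and PageRank, membership in deeper k-cores. This is an assumption about
  *curated* drivers; it is also the model's main known bias (see
  Limitations).

Eight features per gene form the complete model input: degree, normalised
betweenness, PageRank, k-core number, clustering coefficient, closeness,
eigenvector centrality and triangle count. Features are exported unscaled —
a single source of truth — and each learner owns whatever standardisation
it needs (the logistic and neural learners standardise internally on
training statistics only).

## The imbalance correction, level by level

**Data level.** After a stratified 80/20 split (per-class test counts are
`round(n × 0.2)`, round-half-up; the test partition is never touched
again), the training positives are SMOTE-oversampled: each synthetic row is
`x_i + u (x_nn − x_i)` with `u ~ U(0,1)` and `x_nn` one of the `k = 5`
nearest minority neighbours (Euclidean distance in standardised space;
interpolation in raw space — the two give identical rows since the
transform is affine). The majority class is undersampled through a Latin
hypercube: every feature is rank-transformed to (0, 1], a `target_n`-point
LHS design is drawn, and each design point (visited in a seed-shuffled
order, to avoid positional bias) claims its nearest not-yet-selected row in
rank space. Rank space rather than z-space makes the strata equal-mass
under arbitrary marginals, which is the property that lets the selection
preserve the majority's distributional structure.

The default targets multiply the minority by 2.7 and retain 89% of the
majority. At the genome-wide scale that reproduces the intended resampled
composition (roughly 1,500 positives against 10,000 negatives, an achieved
prior near 0.13); a clamp pulls the majority target further down whenever
the achieved prior would fall outside ±0.02 of the `target_prior = 0.15`
default. If the training prior is already within that band, rebalancing is
a no-op. Every resampled row carries a provenance flag
(`original` / `synthetic` / `retained-majority`), which is what makes the
leak audit (`audit_leakage()`) a mechanical check rather than a promise.

**Model level.** Four base learners with these defaults:

| learner | key defaults | role |
|---|---|---|
| logistic (ridge) | C = 0.1 (inverse regularisation) | calibrated linear baseline |
| random forest | 500 trees, depth 20, min node 2, √p features | interaction-robust votes |
| gradient boosting | 300 rounds, ν = 0.05, depth 6, subsample 0.8 | sequential error correction |
| neural network | layers 128-64-32-16, dropout 0.3/0.3/0.2/0.2, Adam lr 0.001, batch 64 | focal-loss learner |

The classical three receive balanced class weights `w_c = N/(2 N_c)`. The
network minimises focal loss `−α_t (1−p_t)^γ log p_t` with `γ = 2`,
`α = 0.25`: the `(1−p_t)^γ` factor silences confidently classified
majority examples so the gradient concentrates on hard minority cases.
At `γ = 0, α = 0.5` the loss reduces exactly to half the cross-entropy — a
reduction the test suite checks to 1e−12, and the configuration the
uncorrected baseline uses.

**Decision level.** Soft-voting weights are grid-searched on the simplex in
steps of 0.05, scored by the best achievable F1 on pooled CV-validation
predictions. The decision threshold τ scans the midpoints of adjacent
sorted unique scores (plus 0 and 1) and takes the *smallest* maximiser —
the tie-break favours recall, consistent with the motivation that a default
0.5 cut systematically suppresses sensitivity under imbalance. τ is fitted
on the pooled CV predictions, never on the test set, which is evaluated
exactly once.

Cross-validation is stratified 5-fold; the rebalancing is re-applied
inside each fold's fit partition with fold-offset seeds, while validation
folds stay at the natural imbalance to mirror deployment.

## Statistical toolkit

Hubs are genes whose outdegree strictly exceeds μ + 2σ (population SD; at
genome scale the sample/population distinction is negligible, and the
strict inequality follows the "exceeding the threshold" reading).
Enrichment is quantified as OR = ad/bc with the log-scale Wald interval
`exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`; zero cells get the
Haldane–Anscombe +0.5 correction, flagged in the output. Exact Fisher
p-values come from the classical two-sided hypergeometric convention.
Group comparisons use Mann–Whitney U (exact for untied samples of combined
size ≤ 12, tie-corrected normal otherwise) with Cohen's d (pooled SD) as
the effect-size currency. Bonferroni families default to the three used in
the analysis design (hub = 45, pathway = 150, external validation = 12)
but are plain arguments. Correlations are reported with Fisher-z CIs.

The degree-matched null replaces each predicted gene with a random gene
whose degree lies within ±10% (multiplicative window, floor/ceil to
integers), sampled without replacement within a replicate and with
replacement across replicates; genes with no window partner relax the
tolerance in +0.05 steps with a warning. The z statistic uses the
empirical null SD (not a binomial approximation), because the null is
defined as the distribution of overlap proportions across the random sets.

## What the synthetic generator emulates — and what it does not

`generate_planted_network()` produces a preferential-attachment graph
(attachment parameter m = 5, mean degree ≈ 10) in which a planted minority
(default 4.4%, 5% in the acceptance study) receives extra
preferentially-attached edges. The extra-edge count is *proportional to
each positive's own degree* (an edge multiplier), calibrated by
generate-and-measure iteration until the standardised degree effect of
positives versus background reaches the target (d ≈ 1). The multiplicative
form was chosen over a uniform per-positive count deliberately: a uniform
bump concentrates planted positives just above any hub cutoff and, by the
scale-invariance of power-law tails, erases their representation in the
extreme tail — whereas scaling each positive's connectivity preserves the
tail shape, so planted drivers are genuinely over-represented among
μ + 2σ hubs, as real drivers are. Edge confidences are drawn uniformly in
[700, 1000]: downstream code only ever sees the post-filter regime. Files
are written in the exact dialects the readers parse (reciprocal-row edge
list, prefixed protein ids, two-column id map), and a round-trip test pins
generator and parser to each other.

What passing tests on this generator do **not** show: the planted signal
is purely topological and degree-driven, so (i) the synthetic benchmark
cannot separate "the model learned biology" from "the model learned
connectivity" — on synthetic data the degree-matched null correctly
reports that test-set predictions are largely explained by degree; (ii)
baseline classifiers behave degenerately (an uncorrected τ = 0.5 ensemble
predicts almost nothing at 5% prevalence, making its precision a
near-vacuous 1.0 on a handful of predictions), so precision comparisons
against that baseline are not informative here even though the recall gain
is; and (iii) real PPI data has correlated annotation biases, modular
structure and confidence-score artefacts the generator does not model.

## Numerical choices

* Betweenness: exact (via the graph library's Brandes implementation) up
  to 5,000 nodes, above that Brandes pivot sampling with seeded pivots and
  `n/k` scaling; with `k = n` the estimate equals the exact value, which
  the tests assert. Normalised by the pair count `(n−1)(n−2)/2`, endpoints
  excluded; graphs of ≤ 2 nodes score 0.
* Closeness on disconnected graphs: per-component convention scaled by
  reachable-fraction, `(r/(n−1))·(r/D)`; singletons score 0. This avoids
  infinities without inventing cross-component distances.
* PageRank: damped power iteration (damping 0.85, L1 tolerance 1e−9, cap
  200 iterations, error carrying the residual on non-convergence).
* Eigenvector centrality: shifted power iteration on `A + I` per connected
  component (primitive on a connected graph, so no period-2 oscillation),
  nonnegative, L2-normalised within each component.
* Focal loss probabilities are clipped at 1e−7 with a warning.
* The neural network is plain matrix arithmetic: He initialisation,
  inverted dropout, Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), early stopping
  on the epoch loss with patience 10, best-weights restoration, and a hard
  error on non-finite loss. Single-threaded and fully determined by one
  seed.
* Hyperparameter search: Gaussian-process regression (RBF kernel on the
  unit cube, length-scale 0.3, nugget 1e−6, Cholesky solve) with expected
  improvement over a 500-point seeded candidate pool; pure random search
  as the fallback method.
* AUPRC uses step-wise (not trapezoidal) precision–recall integration, the
  standard choice for imbalanced evaluation; a constant scorer yields
  exactly the prevalence.
* All randomness flows through a save/restore seed wrapper, so any
  documented seed fully determines results without mutating the caller's
  RNG state.

## Openly decided points

Where the procedure was under-specified, the package fixes one behaviour
and documents it: duplicate edges keep the maximum score (conservative
high-confidence reading); id-map collisions merge into one symbol-level
node with unioned edges; the test-set allocation is round-half-up per
class; SMOTE ties and LHS assignment use the declared distance metrics
(standardised-Euclidean and rank-space Euclidean respectively); voting
weights are searched on a 0.05 simplex grid; τ ties break low. The
train split keeps every gene not allocated to the test set — at the
genome-wide scale that is 12,040 background genes alongside 559 drivers,
the arithmetically forced counts. ADASYN-style density weighting is
exposed nowhere: SMOTE is the implemented oversampler, as all quantitative
statements about the procedure are SMOTE-based.

## Problem sizes used in tests

Module tests run on toy graphs (≤ 12 nodes, against exhaustive
enumeration oracles) and a 600-gene planted study; the acceptance suite
and `scripts/acceptance.R` use a 2,000-gene planted study with 5%
positives and 200-replicate null distributions. These sizes were chosen so
the full pipeline — including five-fold re-resampled cross-validation and
four learners per fold — exercises every code path in about a minute on a
single core while keeping the planted effect measurable with comfortable
margins.

## Limitations

The model sees only static, context-free network topology: tissue-specific
interactions, expression, mutation and methylation signals are out of
scope, and moderately connected drivers are systematically harder to
recover. PU labelling means reported precision/recall are lower bounds
with respect to the true (unknown) driver set. The hub statistics are
descriptive, not causal. And the synthetic benchmark, by construction,
rewards exactly the topological signal the model uses — results on it
bound what the software does, not what the biology is.
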