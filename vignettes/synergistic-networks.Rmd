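---
title: "Inferring synergistic gene-pair networks and using them for cross-study outcome prediction"
author: "synetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synergistic gene-pair networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Network-based outcome predictors (NOPs) promise better survival
classification from gene expression by grouping genes along the edges of a
gene network before training a classifier. In practice, reports conflict:
random networks often perform as well as curated interactomes. `synetr`
turns the question around: instead of feeding a given biological network
into a NOP, it *infers* the network whose links actually help — a network
of **synergistic gene pairs** derived directly from survival-labelled
expression data.

A pair of genes (i, j) is synergistic when the joint predictor beats both
single genes. For each pair we compute three quantities under a
leave-one-study-out, repeated-subsample design:

* `A_i`, `A_j`, `A_ij` — median holdout AUCs of the single genes and of
  their linear meta-gene (ordinary least squares of the 0/1 outcome on the
  two z-scored genes);
* synergy `S = A_ij / max(A_i, A_j)` — above 1 when the pair beats its
  best member;
* mean AUC `M = (A_i + A_j) / 2` — guards against the inflation of `S`
  when both genes are weak;
* co-expression `C` — absolute Spearman correlation on the training
  partition; integrating correlated genes reduces meta-gene noise.

Each measure is min–max normalized to [0, 1] over the scored pairs of a
fold, and the **fitness** of a pair is its negative Euclidean distance to
the ideal point (1, 1, 1):

$$F = -\sqrt{(1-\bar S)^2 + (1-\bar M)^2 + (1-\bar C)^2} \in [-\sqrt 3, 0].$$

Fitness is medianed per-pair across the leave-one-study-out folds
(normalize-then-median; the per-fold tables are each normalized within
themselves first). The top pairs by fitness — 50,000 at genome scale —
form the synergy network. Because fitness is non-positive while group
construction wants positive edge weights, edges carry the fitness *rank*
scaled to (0, 1]; this preserves the fitness order exactly and is
deterministic.

## Outcome labels

Survival is dichotomized at 5 years: an event before the threshold is
`poor`, follow-up past it is `good`, and censoring before it is
`excluded`. Excluded samples cannot be labelled either way, so they are
dropped from training and from every AUC — the standard treatment for
dichotomized survival. Recurrence-free survival is preferred over overall
survival when both are annotated. Expression is quantile-normalized within
each study (mapping every sample of a study onto the study's mean quantile
vector; the `ties = FALSE` convention makes the operation exactly
idempotent). Residual batch correction is treated as a pluggable
preprocessing step outside the package: the synthetic generator emulates
data after such correction, up to additive study shifts.

## Cross-study validation

All evaluation is leave-one-study-out: the held-out study's samples never
touch network inference, hyperparameter tuning, or training. Inside an
outer fold, inner leave-one-study-out folds drive a grid search; each of
the repeats redraws 70% of the outer training samples *with replacement*
and re-tunes, while the fold assignment itself is frozen in a `FoldPlan`
that is reused verbatim by every compared method — differences between
methods are then never an artifact of fold luck. The same 70% subsample,
keyed by (seed, fold, repeat), is shared by every gene and pair in the
scan, so chunked scans concatenate into a full scan bit-for-bit. A leakage
guard intersects training and test sample ids before every training call
and aborts on any overlap.

Per-gene orientation ("higher expression ⇒ poor") is fixed by the sign of
the training regression weight, never by folding test AUC upward; a
genuinely uninformative gene therefore scores near 0.5 on holdout instead
of being optimistically pushed above it.

## Classifiers

* **Lasso** (glmnet): L1-logistic on all genes — the baseline any network
  method must beat.
* **Overlapping group lasso**: every network gene seeds a group of itself
  plus its `K` strongest neighbors; overlaps are handled by variable
  duplication (latent group lasso) with penalty
  $\lambda \sum_g \sqrt{|g|}\,\lVert w_g \rVert_2$. The solver is FISTA
  with backtracking and adaptive restart, then a Newton polish restricted
  to the active groups; with singleton groups it reproduces glmnet's lasso
  to ~1e-7, which the tests assert. No group-lasso solver was available as
  a dependency, so this solver is part of the package.
* **Correlation clustering (Park-style)**: average-linkage clustering on
  `1 - |rho|`, cluster means as meta-genes, lasso on top; the cut is tuned
  by inner folds; a singleton cut reduces exactly to plain lasso.
* **Greedy subnetworks (Chuang-style)**: seeds expand by the neighbor that
  most improves the training AUC of the averaged meta-gene, halting when
  no candidate improves it (score sequences are strictly increasing by
  construction).
* **Hub dysregulation (Taylor-style)**: hubs are genes with degree > 5;
  each hub is scored by the mean absolute change of hub–neighbor Pearson
  correlation between outcome classes, and the top half of hubs (the
  fraction is configurable, as the original cutoff is not specified)
  define averaged meta-genes.

Ties in the grid search prefer the sparser model: larger `lambda`, then
smaller `K`/cluster count. Default grids span `lambda` log-spaced from
1e-3, `K` in {1, 3, 5}, and are deliberately small at desk scale; all are
overridable per task.

## The synthetic compendium

Because the package must be exercisable end-to-end without proprietary
data, the generator plants known structure in a multi-study compendium
(defaults: 4 studies × 250 samples, 300 genes, 20 marginal genes, 10
synergy pairs, 5 correlated blocks of 10, effect size 1, batch-shift SD
0.3, 20% censoring):

* a latent binary outcome per sample (balanced);
* **marginal genes**: mean shift of `effect_size` between classes;
* **synergy pairs**: both genes load a shared latent factor with weight 3;
  the outcome signal (0.6 × effect) lives only in the *contrast*
  g_i − g_j, each gene carrying half. Marginally the factor dominates
  (true single-gene AUC ≈ 0.53); the fitted pair cancels the factor
  (true pair AUC ≈ 0.77). The contrast coding was chosen over the
  sign-flipped (anti-correlated, sum-signal) variant deliberately:
  per-study quantile normalization applies a per-sample monotone map,
  which cancels in local differences of strongly correlated genes but
  corrupts sums — the contrast coding survives normalization intact. The
  flip side, documented here, is that *averaged* meta-genes of a contrast
  pair carry no signal, so the average-based predictors cannot exploit
  these pairs; their mechanics are tested on averaging-compatible
  constructions instead. An XOR mechanism (signal in the sign product) is
  available as a negative control for linear meta-genes.
* **correlated blocks**: a shared non-outcome factor (pairwise rho ≈ 0.8)
  — decoys for the correlation component of fitness;
* **batch shifts**: additive per-study, per-gene Normal(0, 0.3²) offsets —
  these shift a held-out study's scores uniformly and are also the target
  of per-study quantile normalization;
* **survival**: exponential times with rate 0.7 (poor) or 0.008 (good),
  so the 5-year dichotomization recovers the latent class for ≥95% of
  uncensored samples; censoring replaces the time by a uniform draw below
  it.

What the generator does *not* emulate: platform-specific noise, probe
effects, non-additive batch distortions, unbalanced outcome prevalence
across studies. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted structure, not clinical
performance on real cohorts.

## Network analysis

Two null models serve different purposes: **node-label shuffling**
preserves the topology as an unlabeled graph (used to destroy biological
identity while keeping structure), and **degree-preserving rewiring**
(double edge swaps via igraph, weights reshuffled onto the new edges)
randomizes wiring at fixed degrees. Overlap between networks is
standardized against 1000 rewires (fewer at desk scale) after thresholding
to a fraction of links or genes: `z = (obs − mean_null) / sd_null`, with a
degenerate null reported as NA.

For link prediction, every candidate pair is described per network by
direct-link status, degree, shortest path, neighborhood Jaccard, and
PageRank (four damping factors, default {0.1, 0.3, 0.5, 0.85} — exposed
because no canonical set exists), closeness, clustering and eigenvector
centrality, each edge-ized as mean and absolute difference. Unreachable or
absent pairs get bounded codings (largest finite shortest path + 1;
centrality 0) so the classifier never sees infinities. A 50-fold
cross-validation hides 1/50 of the positive pairs per fold and removes
every training pair sharing a gene with a test pair, so the reported AUC
cannot come from memorizing gene identity.

## Numerical choices and degenerate inputs

* AUC is the Mann–Whitney statistic with ties counted ½; an exact O(n²)
  counting oracle backs it in the tests.
* Collinear pairs in the scan (|det| below 1e-8 of its scale) fall back to
  the stronger single gene, so a duplicated gene scores like the gene
  itself.
* Constant genes get weight 0 (scan), correlation 0 (networks), and are
  never allowed to produce NaNs.
* Edge-weight and fitness ties break lexicographically by gene symbols;
  every stochastic step is keyed by an explicit integer seed, and reruns
  are bit-identical (asserted in the tests).
* Group-lasso convergence: relative objective change below `tol`
  (1e-9 default) with a Newton polish; non-convergence warns with the
  iteration budget and residual.

## Problem sizes

Desk-scale defaults keep the full pipeline fast: the default compendium
(1000 samples × 300 genes; 44,850 pairs) scans in ~15 s with the compiled
AUC kernel; the cross-study benchmark configurations used in the tests
(3 studies × 100 samples, 100 genes) run in seconds per seed. At genome
scale (11,748 genes; 69,001,878 pairs) the scan is embarrassingly parallel
over pair-index chunks via `synet scan --chunk i/n`, whose concatenation
is exactly a full scan.

## Worked example

```{r, eval = FALSE}
library(synetr)

sim <- simulate_compendium(synth_config(seed = 1))
cmp <- quantile_normalize_per_study(sim$compendium)

# infer the synergy network from all pairs
inferred <- infer_synet(cmp, n_links = 100, seed = 2)
head(rank_fitness(inferred$fitness))

# evaluate predictors under the shared fold plan
plan <- make_fold_plan(cmp, n_repeats = 2, seed = 3)
res <- run_cross_study(cmp, list(
  lasso = list(method = "lasso"),
  gl    = list(method = "gl", network = inferred$network)), plan)
sapply(res$tasks, stability_metrics)
```

## Known limitations

* The meta-gene is linear by design; interaction-only (XOR-type) synergy
  is invisible to it, which the generator's negative control makes
  explicit.
* Fitness normalization is relative to the scored pair collection, so
  fitness values are not comparable across datasets — only ranks are.
* The harness evaluates AUC per held-out study and never pools samples
  across studies; with very small studies the per-fold AUC is noisy and
  stability metrics inherit that noise.
* Batch correction beyond per-study quantile normalization is delegated to
  preprocessing.
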