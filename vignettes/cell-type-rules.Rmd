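---
title: "Interpretable cell-type classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable cell-type classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Annotating cell types in single-cell expression data is usually done either
with hand-curated marker genes or by similarity to a labeled reference. Both
approaches leave the *decision logic* implicit. `cellrules` implements a
third route: train classifiers on a labeled cells × genes matrix, select a
compact discriminative gene set, and then read the classifier's logic back
out as explicit IF–THEN rules on expression thresholds. The workflow was
designed around an adult human heart cell atlas with 11 annotated cell types
whose sizes range over two orders of magnitude (from 718 mesothelial cells
to 125,289 ventricular cardiomyocytes out of 451,513 cells), so severe class
imbalance is a first-class concern throughout.

The pipeline has five stages:

1. **Feature ranking.** A multiclass gradient-boosted tree ensemble is fit
   to the full matrix and every gene is scored by its *split count* — the
   number of internal nodes, summed over all trees, that split on it. Genes
   used more often rank higher; ties break by total split gain, then input
   column order. The statistic is defined on the ensemble's exported tree
   structures, not on any backend-specific normalization.
2. **Incremental feature selection (IFS).** Nested prefixes of the ranked
   list (sizes `step, 2·step, …` up to `cap`) are each evaluated by
   stratified 10-fold cross-validation; the optimum is the smallest prefix
   attaining the maximal weighted F1.
3. **Class balancing.** Inside every training fold, SMOTE oversamples each
   minority class up to the majority count: a synthetic sample is
   `x + u·(x_nn − x)` with `u ~ Uniform(0,1)` and `x_nn` one of the `k = 5`
   nearest same-class neighbors under exact Euclidean distance.
4. **Rule mining.** The optimal decision tree is refit on all cells and each
   root-to-leaf path becomes a rule: an ordered conjunction of
   `gene ≤ t` / `gene > t` predicates, the leaf's majority class, and the
   *passed count* — the number of training cells reaching that leaf. The
   rules partition the feature space, so passed counts sum to the number of
   training cells.
5. **Robustness.** A noise protocol perturbs a fraction of cells with
   bounded relative noise and re-evaluates the selected classifier,
   repeated with fresh noise draws.

## Models and their assumptions

**Classifiers.** The decision tree is an in-package CART: exact greedy Gini
search, midpoint thresholds, unlimited depth, `x ≤ t` to the left. It exists
in-package (rather than wrapping an external tree) because rule mining
requires the serialized predicates to reproduce the tree's routing
*bit-exactly*: the rule schema uses `≤ / >` comparators, and external CART
implementations route with `< / ≥`, which cannot be rewritten as `≤ / >`
without changing predictions on points that hit a threshold exactly. Score
ties keep the smallest feature index and threshold, and majority ties at a
leaf keep the first class in level order, so a fitted tree is a
deterministic function of its training data. The random forest is the
standard bagged-CART ensemble (100 trees, `√p` features per split, majority
vote), provided by `ranger` with a fixed seed and one thread.

**Metrics.** With strongly imbalanced classes, accuracy alone is
uninformative; the headline metric is the weighted F1 — per-class
F1 (`2·precision·recall / (precision + recall)`, defined as 0 when its
denominator vanishes) averaged with weights equal to each class's share of
the true labels. Macro F1, accuracy, and the multiclass Matthews correlation
coefficient (Gorodkin's confusion-matrix form, 0 when a denominator term is
0) are reported alongside.

**Evaluation discipline.** SMOTE is fit and applied *inside* each training
fold, never to the held-out split, so synthetic samples cannot leak into
evaluation; out-of-fold predictions are pooled over all ten folds and scored
once, which keeps the estimate stable for classes with only a handful of
cells. Balancing the whole dataset before splitting — a reading some
published descriptions permit — is available behind an explicit
`smote_before_cv` flag but is not the default, because it inflates scores.
The final rule-mining tree is trained on the *original* unbalanced data by
default (flag `balance_final`), so passed counts refer to real cells; in the
motivating atlas the largest reported passed count (95,879) is below its
class's raw size (125,289), consistent with unbalanced training.

## The synthetic benchmark

Real atlas-scale data is neither redistributable nor desk-scale, so the
package ships a generator that preserves the features the workflow actually
exercises:

* **Imbalance.** Class proportions default to the 11 heart-atlas types
  (`heart_cell_type_counts()`); cell counts come from largest-remainder
  rounding, which conserves the total exactly (ties break in table order).
  At the benchmark size of 2,000 cells the rarest class keeps 3 cells and
  the max/min ratio is ≈ 174, matching the atlas's imbalance.
* **Sparse counts.** Each value is negative binomial (mean `m`, dispersion
  `r`, variance `m + m²/r`) with independent dropout zeroing. Defaults —
  baseline mean 0.5, dispersion 10, dropout 0.1 — give ≈ 65% zeros and a
  clearly separable signal at the default `marker_effect = 8`: the regime
  the selection experiments are meant to showcase, where the limiting factor
  is the workflow, not irreducible class overlap. (A harsher regime, e.g.
  dropout 0.3 with dispersion 2, caps even an oracle classifier near
  weighted F1 0.92 at this size and is better explored via the exposed
  parameters.)
* **Planted markers.** Each class owns a disjoint set of
  `markers_per_class = 5` genes whose mean is multiplied by `marker_effect`
  within that class, with the marker map returned as ground truth so
  ranking-recovery is measurable.

What the generator deliberately does **not** emulate: gene–gene correlation,
real marker identities, batch effects, library-size variation, or ambient
contamination. A passing benchmark therefore certifies the *mechanics* of
ranking, selection, balancing, rule extraction and scoring — not performance
on real tissue.

## Numerical and design choices

* **Determinism.** Every stochastic stage takes an explicit integer seed; no
  global RNG state is consumed (seeds are applied via `withr::with_seed`).
  The pipeline fans one master seed out by fixed offsets and records all of
  them in its manifest; rerunning from the manifest reproduces every output
  file byte-for-byte.
* **Ranking backend.** The default booster is `xgboost`
  (`multi:softprob`, one tree per class per round, 100 rounds, library
  defaults otherwise, single-threaded, seeded); split counts and gains are
  read from the dumped trees, so the counts sum exactly to the ensemble's
  internal nodes. A minimal built-in one-vs-rest boosted-stump ranker
  (`method = "stump"`, exact split search, no sampling) provides a fully
  deterministic backend with the same exported statistics; backend
  parameters travel with the ranked list rather than in the TSV, which keeps
  the artifact one-header-plus-one-line-per-gene.
* **IFS grid.** Defaults are the classical step 5 with a cap of 1000
  (200 subsets). The benchmark analyses in `analysis/` and the acceptance
  checks use prefix sizes {50, 100, 150} — at 500 genes with 55 planted
  markers, finer steps only resample the plateau of the curve. Optimum ties
  resolve to the smallest subset (parsimony).
* **SMOTE edge cases.** "Almost the same size" is resolved to exact equality
  with the majority count. A class of one cannot be interpolated and raises
  an error naming the class; `k` larger than a class clamps to class size −1
  with a warning. Neighbor search is exact (ties by row index) — approximate
  search would break reproducibility.
* **Noise model.** The robustness protocol formalizes "increase or decrease
  each feature by a small number" as `s·u·δ·σ_g` per gene (random sign,
  `u ~ Uniform(0,1)`, `σ_g` the per-gene standard deviation of the input),
  applied to exactly `⌊fraction·n⌋` cells and clipped at zero to preserve
  non-negativity. `δ` defaults to 0.10 and is always reported; at `δ = 0`
  the perturbation is the identity, and the study then reproduces its
  baseline exactly because baseline and repeats share the fold seed.
* **Thresholds and serialization.** Rule thresholds are midpoints between
  adjacent observed values and are serialized at 17 significant digits, so a
  written-and-reread rule set routes identically to the tree that produced
  it. Expression values are used as given (counts or normalized — the
  workflow is agnostic); rule thresholds are therefore on the input scale.

## Problem sizes

The shipped analyses and checks run at 2,000 cells × 500 genes with 10-fold
cross-validation, chosen so the complete workflow — ranking, two IFS runs,
rule mining, and a 10-repeat robustness study — executes in minutes on a
single core while keeping every class large enough to survive stratified
10-fold splitting (every class needs at least 3 cells so each training split
retains at least 2 for interpolation). Scaling the same code to
atlas-sized inputs is a matter of compute, not of different code paths.

## Known limitations

* Rules are mined from a single tree; forests stay black boxes by design
  (no ensemble rule extraction, pruning, or merging across leaves).
* The synthetic benchmark's marker structure is far cleaner than real
  tissue; numbers obtained on it are mechanics checks, not performance
  claims about any real dataset.
* No expression preprocessing (normalization, log-transform, HVG selection)
  is provided; upstream tooling owns that.
* Very deep trees on label noise can produce thousands of rules; the
  rule-set applier is vectorized per rule and is comfortable at that scale,
  but rule *readability* degrades long before the code does.
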