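# cellrules

Interpretable cell-type classification for labeled single-cell expression
matrices: rank genes by gradient-boosted-tree split-count importance, pick a
compact discriminative gene set by incremental feature selection (IFS) under
SMOTE-balanced 10-fold cross-validation, and mine the optimal decision tree
into explicit IF–THEN rules whose "passed counts" report how many real cells
satisfy each rule. The package is aimed at computational biologists who want
the *decision logic* of a cell-type annotator — which genes, which
thresholds, for which type — rather than a black-box score.

The workflow was designed around an adult human heart cell atlas (11 cell
types, 451,513 cells, classes spanning 718 to 125,289 cells), and ships a
synthetic generator that reproduces that imbalance with planted marker genes
so the whole pipeline is testable at desk scale.

## The method

Given a cells × genes matrix `X` with per-cell type labels `y`:

1. **Ranking.** Fit a multiclass gradient-boosted tree ensemble (one tree
   per class per round). Gene `g`'s importance is its *split count*
   `I(g) = #{internal nodes splitting on g}` summed over all trees; ties
   break by total split gain, then column order. This yields the ranked
   list `F`.
2. **IFS.** For nested prefixes `f_k = F[1..k]` (`k = step, 2·step, …, cap`)
   evaluate a classifier by stratified 10-fold cross-validation and score
   the pooled out-of-fold predictions with the weighted F1
   `Σ_c (n_c / N) · F1_c` (per-class F1 = `2PR/(P+R)`, 0 when undefined),
   plus accuracy, macro F1 and multiclass MCC. The optimum is the smallest
   `k` maximizing weighted F1. Both a decision tree (DT, CART/Gini) and a
   random forest (RF, 100 bagged trees, √p features per split) are run.
3. **Balancing.** Inside each training fold SMOTE equalizes every class to
   the majority count: synthetic minority samples `x + u·(x_nn − x)`,
   `u ~ U(0,1)`, `x_nn` among the k = 5 nearest same-class neighbors.
   The held-out fold is never touched.
4. **Rules.** The optimal DT, refit on the full (unbalanced) data, is read
   out leaf by leaf: each root-to-leaf path becomes a rule
   `IF g1 ≤ t1 AND g2 > t2 … THEN type`, with the passed count = training
   cells reaching that leaf. The rules partition the feature space
   (exactly one matches any cell; passed counts sum to n).
5. **Robustness.** Perturb 10% of cells by `±u·δ·σ_g` per gene (δ = 0.1 by
   default), re-evaluate the optimal classifier by cross-validation, repeat
   ten times.

## Worked example

The numbered scripts under `analysis/` run the full study on the synthetic
heart-atlas benchmark (2,000 cells × 500 genes, 5 planted markers per type,
8-fold marker effect) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # data + ground truth
Rscript analysis/02_rank_features.R   # ranked list F
Rscript analysis/03_ifs_selection.R   # IFS curves for RF and DT
Rscript analysis/04_mine_rules.R      # rule set from the optimal DT
Rscript analysis/05_robustness.R      # noise protocol on the optimal RF
```

Output actually printed by those runs:

```
wrote 2000 cells x 500 genes to results/data
rarest type: Mesothelial (3 cells); most abundant: Ventricular cardiomyocyte (555 cells)
matrix sparsity: 64.8% zeros
planted markers in top 110 ranks: 53 / 55
RF optimum: k = 150, weighted F1 = 0.9852
DT optimum: k = 100, weighted F1 = 0.8592
133 rules from the optimal DT (k = 100); passed counts sum to 2000 cells
robustness_result (RF, k=150): baseline 0.9852; 10 repeats mean 0.9859 (sd 0.0013, range 0.9842-0.9887)
```

Reading: the booster recovers 53 of the 55 planted markers in the top 110
ranks; the forest classifies the 11 types almost perfectly (weighted
F1 0.985) while the single tree trades ~0.13 of weighted F1 for a complete,
human-readable rule set — e.g. the most populous rule covers 371 ventricular
cardiomyocytes — and perturbing 10% of cells with δ = 0.1 noise moves the
forest's score by less than 0.001. Per-type tables (rules per type, top
rules by passed count, IFS curves, confusion matrices) land in `results/`.

The same five stages run as one call with a single master seed:

```r
library(cellrules)
gd <- generate_dataset(spec_from_table1(2000, seed = 1))
run_pipeline(gd$data, "results/bundle",
             pipeline_config(step = 50, cap = 150, seed = 1))
```

which also writes `manifest.json`; rerunning from the manifest reproduces
every file byte-for-byte.

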