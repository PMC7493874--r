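# fpscreen

Ligand-based virtual screening from molecular fingerprints, for
computational chemists who need one model family to serve two screening
regimes: *early screening*, where every true active must surface in the top
fraction of the ranking even at the price of false positives, and *mature
screening* (hit expansion), where active/inactive discrimination must be
precise.

## What it does

Compounds are encoded as seven types of 1024-bit molecular fingerprints
(RDKit path-based, Morgan, AtomPair, Torsion, Layered, FeatMorgan, ECFP4),
recoded as signed vectors `v = 2b − 1 ∈ {−1, +1}^1024`, and classified by
convolutional neural networks:

* **1D CNN** per fingerprint type and **2D CNN** over a k×1024 stack of
  distinct types (2 ≤ k ≤ 7): four conv(ReLU)+maxpool blocks, a
  1024/512/256 dense ReLU head, one sigmoid unit, binary cross-entropy.
* **Voting**: the seven per-type 1D CNNs vote with hard labels; the
  majority wins.
* **Tuned-MLP-Out**: seven higher-capacity 1D CNNs (512/256/128/64
  filters) retrained from scratch feed their output probabilities into a
  one-hidden-layer MLP head, tuned per task — 3 ReLU units / Adam / 1e-3
  for discrimination, 5 units / Adamax / 1e-4 for active-only selection.
* **Baselines**: RBF-SVM and random forest at tuned hyperparameters, on the
  same signed fingerprints.

Activity labels are derived from the data: two-cluster K-means on raw IC50
values (µM) with the threshold at the centroid mean,

  t = (c_active + c_inactive) / 2,

supported by a WCSS elbow diagnostic; a compound is active iff IC50 ≤ t.
Two split schemes mirror the two regimes (stratified 80/10/10; and a
48%/52% split with the training side enriched to ~21% actives), both with
stratified 10-fold CV folds. Evaluation covers balanced accuracy
`bACC = (TP/P + TN/N)/2`, sensitivity, specificity, F1, MCC (with
|MCC| = √(χ²/n)), AUC, log-loss and the enrichment factor

  EF p% : hits in the top ⌊p·n/100⌋ of the ranking, as a percentage of
  min(window, P),

the headline early-recognition metric. A synthetic fingerprint generator
(hashed pattern sets with planted activity motifs and bimodal lognormal
IC50s) makes the whole pipeline testable without external chemistry data.

## Worked example

A complete run on the generator's default synthetic screen (500 actives /
5000 inactives, ~9 minutes on one CPU; shrink `n_active`/`n_inactive` for a
quick look):

```r
library(fpscreen)

# a synthetic screen with a planted two-motif activity signature
ds <- generate_dataset(seed = 11)

# derive the activity threshold from the IC50 distribution and label
thr <- fit_threshold(ds$compounds, seed = 11)
thr
#> IC50 activity threshold model (two-cluster K-means)
#>   active centroid:   1.07893 uM (cluster upper bound 7.367)
#>   inactive centroid: 14.11624 uM (cluster lower bound 7.851)
#>   threshold:         7.59758 uM (centroid average), n = 5500
labeled <- assign_labels(ds$compounds, thr)

# discrimination-style split, then train a 1D CNN on one fingerprint type
split <- scheme1_split(labeled, seed = 11)
y <- setNames(as.numeric(labeled$label == "active"), labeled$compound_id)
X <- fp_input(ds, "rdkit")
part <- function(p) split$compound_id[split$partition == p]
fit <- train_cnn(
  build_cnn1d(cnn_spec("1d", dropout = 0.2, batch_size = 32, seed = 11)),
  X[part("train"), ], y[part("train")],
  X[part("validation"), ], y[part("validation")],
  max_epochs = 30, patience = 6, monitor = "val_bacc", seed = 11
)
glance(fit)
#> # A tibble: 1 × 6
#>   dimensionality n_params epochs_run best_epoch best_val_loss best_val_bacc
#>   <chr>             <dbl>      <int>      <int>         <dbl>         <dbl>
#> 1 1d              1738865         15          8         0.139         0.912

# score the held-out screen and read off enrichment
p <- predict(fit, X[part("test"), ])
screen <- ranked_screen(tibble::tibble(
  compound_id = part("test"), score = p,
  label = ifelse(y[part("test")] == 1, "active", "inactive")
))
enrichment_factor(screen, p = c(1, 2, 5))
#> # A tibble: 3 × 4
#>   p_percent window  hits percent
#>       <dbl>  <dbl> <int>   <dbl>
#> 1         1      5     5   100
#> 2         2     11     9    81.8
#> 3         5     27    23    85.2
evaluate_scores(y[part("test")], p)
#> # A tibble: 1 × 9
#>    bacc sensitivity specificity    f1   mcc   auc  loss     n n_active
#>   <dbl>       <dbl>       <dbl> <dbl> <dbl> <dbl> <dbl> <int>    <int>
#> 1 0.938         0.9       0.976 0.841 0.826 0.969 0.133   550       50
```

The recovered threshold sits between the two IC50 modes (0.92 and
13.9 µM); every compound in the top 1% of the ranked screen is a true
active (`percent` divides by the best attainable count,
`min(window, 50)`); and sensitivity lands exactly at the generator's
signal rate — 90% of actives carry the planted signature, which caps what
any classifier can recall.

A command-line workbench wraps the same functions
(`exec/fpscreen <command>`): `simulate`, `fingerprint`, `label`, `split`,
`train`, `gridsearch`, `evaluate`, `screen`, each writing a JSON manifest
that makes the run reproducible.

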