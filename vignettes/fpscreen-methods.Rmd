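---
title: "Methods: fingerprint-based virtual screening with CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint-based virtual screening with CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Ligand-based virtual screening ranks candidate compounds by predicted
activity against a protein target so that experimental testing can be
concentrated on the top of the list. Two regimes matter in practice. In
*early screening* the cost of missing an active is much higher than the cost
of testing a false positive, so the model should maximize recall of actives
at the very top of the ranking; the headline metric is the enrichment
factor. In a *mature* stage (hit expansion) precise discrimination between
actives and inactives is wanted, and balanced accuracy and MCC take over.
`fpscreen` implements one architecture family that serves both regimes by
changing the training objective and ensemble head, not the network.

## Compound representation

Compounds are represented by binary molecular fingerprints: fixed-width bit
vectors in which enumerated substructure patterns are hashed to a handful of
positions each (typically 4–5) and OR-ed together. Hash collisions mean a
set bit does not prove a pattern's presence, but an all-zero pattern proves
its absence. Seven fingerprint types are supported at 1024 bits — `rdkit`,
`morgan`, `atompair`, `torsion`, `layered`, `featmorgan`, `ecfp4` — in that
canonical order wherever types are stacked. 1024 bits is the package-wide
default: narrower vectors lose too much structure to hashing, wider ones
inflate the networks. The `morgan`/`ecfp4` pair are both radius-2 circular
fingerprints and are deliberately computed with different generator settings
(`ecfp4` additionally hashes redundant atom environments) so they are
distinct descriptors; `featmorgan` replaces element-based atom invariants
with pharmacophoric feature invariants. Fingerprinting is delegated to RDKit
through the `python` interpreter; parsing failures surface as structured
errors carrying the offending SMILES, and multi-fragment inputs are reduced
to their largest fragment unless `standardize = FALSE`.

Before classification every fingerprint is recoded from {0, 1} to
{−1, +1} (`values = 2·bits − 1`). These vectors are sparse — typically under
10% of bits set — and near-zero inputs would leave most convolutional units
idle; the signed form keeps the binary information while giving every
position a nonzero signal. The recoding is a bijection and `to_bits()`
inverts it exactly.

## Activity labels from IC50 clustering

Binary labels are derived from the data rather than a literature cutoff:
one-dimensional K-means (Lloyd's algorithm, `stats::kmeans`, 25 restarts,
run to convergence) with two clusters on the raw micromolar IC50 values, the
threshold being the mean of the two centroids. The elbow diagnostic
(`wcss_curve()`) justifies the choice of two clusters. A compound is labeled
active when IC50 ≤ threshold, boundary inclusive. The threshold is a data
artifact: it is persisted as JSON next to the labeled dataset and never
hard-coded. On reference data of this kind the two centroids fall near 0.92
and 13.9 µM, putting the threshold near 7.4 µM. Records with missing IC50
are dropped (with a count); compounds known inactive by construction — for
example an off-target expansion set — can be forced inactive via
`inactive_ids`, bypassing the threshold. Clustering is done on the raw
micromolar scale, not log-transformed, because the cluster bounds that a
raw-scale clustering reports are the quantities of interest downstream.

## Training schemes

Two split regimes mirror the two screening regimes:

* **Scheme 1** (discrimination): stratified 80%:10%:10%
  train/validation/test, the global active:inactive ratio (≈1:10 on
  reference data) preserved in every partition to within one sample.
* **Scheme 2** (early screening): the dataset is split into two almost equal
  parts — by default 48% training, 52% test, with 90% of all actives
  assigned to the training side — so training is active-enriched and the
  test set is realistically scarce (≈2% actives). The training side is
  further split 90:10 into train and validation, stratified. The default
  fractions reproduce the reference quotas exactly: on 800 actives + 6360
  inactives they give a 3440-compound training side with 720 actives and a
  3720-compound test set with 80 actives.

Both schemes attach stratified 10-fold cross-validation assignments to the
training partition; folds are balanced to within one compound globally and
per class. All splits are deterministic in their seed. Class imbalance is
handled entirely by the split schemes — no class weighting is applied in the
loss.

For class-ratio stress testing, `resample_ratio()` thins the actives
(keeping every inactive) until the requested 1:r ratio holds, switching to
thinning inactives only when the inactive pool cannot support the ratio.

## The classifiers

All networks share one family: four convolutional layers with ReLU
activations, each followed by max pooling, then a dense head of
1024/512/256 ReLU units and a single sigmoid output trained with binary
cross-entropy.

* **1D CNNs** read a single signed fingerprint (1×1024). Direct classifiers
  use 128/64/32/16 filters; kernel sizes 2–4 are in the tuning grid with 3
  as the default.
* **2D CNNs** read a k×1024 stack of 2–7 distinct fingerprint types (rows in
  canonical type order). Kernels are pairs *(length along bits, extent
  across rows)* with row extents 1–2, matching the small row dimension;
  pooling is 2×2 until the row axis is exhausted, after which only the bit
  axis is pooled. A kernel whose row extent exceeds the stack height is a
  build-time shape error.

Padding may be `same` (default) or `valid`. Dropout (grid 0.2–0.9) is
applied after each dense hidden layer during training; placement in the
dense head keeps the convolutional feature extractors deterministic given
their inputs. Optimizers: Adam, Adamax and plain SGD, with framework-typical
moment constants (0.9/0.999, ε = 1e-7). Training checkpoints the weights at
the best validation epoch — by validation loss by default, or by validation
balanced accuracy with `monitor = "val_bacc"` — and early-stops after
`patience` non-improving epochs; `patience = 0` stops exactly one epoch
after the best. Maximum epochs default to 100 with patience 10.

The engine is implemented in single-precision RcppArmadillo. Convolutions
over single-row inputs run as per-sample shifted GEMMs (one GEMM per kernel
offset), true 2D layers use im2col + GEMM; workspace buffers persist across
batches. The forward pass and gradients are pinned in the test suite against
an exact double-precision R reference on a degenerate 1×1-kernel network,
where every layer can be reproduced in plain R. Weight initialization is
Glorot uniform, deterministic in the spec seed; training is deterministic
given its seed in single-threaded execution. Binary cross-entropy clips
probabilities to [1e-7, 1−1e-7]. A non-finite training loss aborts with
diagnostics rather than returning a broken model.

### Ensembles

* **Voting**: the best 1D CNN per fingerprint type votes with its hard
  label (0.5 threshold); the majority of the seven wins, and odd membership
  means the vote never abstains.
* **Tuned-MLP-Out**: seven 1D CNNs — retrained from scratch with
  512/256/128/64 filters, higher capacity than the direct classifiers — are
  connected in parallel through their output probabilities into a
  one-hidden-layer MLP head. The members are frozen while the head trains:
  the two phases stay independently reproducible and the design is exactly
  "members in parallel feeding a probability classifier". The head is tuned
  per task: 3 ReLU units, Adam, learning rate 1e-3 for discrimination;
  5 units, Adamax, 1e-4 for active-only selection. Member networks default
  to kernel size 2 (the smallest in the grid) and batch size 16: seven
  high-capacity networks are trained per ensemble, and these choices keep
  stacked training tractable on a single CPU without leaving the
  architecture family.

### Baselines

An RBF-kernel SVM (`e1071`) and a random forest (`randomForest`) consume the
identical signed fingerprint matrices. Tuned hyperparameters per scheme:
SVM C = 5, γ = 1 (scheme 1) and C = 1, γ = 0.1 (scheme 2); forest with Gini
splitting and 100 trees (scheme 1) or 2 trees (scheme 2); FeatMorgan is the
default fingerprint for both. SVM ranking scores are Platt-calibrated
probabilities (`probability = TRUE`); the forest reports vote fractions.

## Evaluation

`evaluate_scores()` reports balanced accuracy, sensitivity, specificity, F1,
MCC, AUC and log-loss. AUC uses the rank statistic (probability that a
random active outranks a random inactive, ties counting one half), making it
invariant under monotone transforms of the scores. MCC satisfies
|MCC| = √(χ²/n) on the 2×2 table; degenerate margins return 0 with a
warning rather than an error.

The enrichment factor at p% takes the top `floor(p·n/100)` compounds of the
ranking (stable sort, so tied scores keep input order — continuous CNN
outputs are effectively tie-free) and counts true actives in that window.
The reported percentage divides by `min(window, P)` where P is the total
number of actives: a perfect ranking scores 100% even when the window
exceeds the number of actives that exist. An empty window is an error
advising a larger p or screen.

## The synthetic data generator

Real bioactivity data cannot ship with the package, so `generate_dataset()`
builds datasets with the statistical structure the pipeline assumes, plus
ground truth for auditing:

* A pattern library maps each abstract pattern to exactly 4 (configurable
  to 5) positions per pseudo-type; seven independent hash maps stand in for
  the seven fingerprint types — the same pattern universe, differently
  collided, which mimics how real fingerprint types redundantly encode the
  same chemistry. Collisions are kept and queryable
  (`pattern_collisions()`), so the absence guarantee can be audited: an
  absent pattern appears fully lit only if every one of its positions
  collides with a present pattern.
* Each compound carries ~20 background patterns. The activity signal is a
  small motif set (8 patterns): an active carries a *pair* of distinct
  motifs with probability `q_signal` (default 0.9), an inactive a *single*
  stray motif with probability `noise_rate` (default 0.05). The pair-versus-
  single design is deliberate: mere motif presence occurs in both classes,
  so a classifier must weigh motif evidence, and the top of a good ranking
  is occupied by signature-bearing actives rather than noisy inactives.
  With these defaults a plain linear read-out of the motif bits reaches
  AUC ≈ 0.95, and the ceiling on sensitivity is `q_signal` itself —
  actives without the signature are statistically indistinguishable from
  inactives, which keeps the benchmark honest.
* IC50 values are lognormal per class with medians 0.92 and 13.9 µM and
  log-scale spreads 0.55 and 0.18. The spreads put well under 2% of each
  component across the ≈7.4 µM boundary *and* are tight enough that
  two-cluster K-means on the raw values recovers the component boundary —
  with much wider components the clustering prefers to split the 10×-larger
  inactive mode instead, which is a property of K-means worth knowing about
  on real data too.

What passing tests on synthetic data do **not** show: real fingerprints have
correlated bits from overlapping substructures, class-conditional pattern
frequencies are not uniform, and assay noise is not lognormal-clean. The
generator validates the machinery (representation, training, ranking,
thresholding), not chemistry.

## Problem sizes in the test suite

The end-to-end recovery test uses the generator's default study conditions —
500 actives / 5000 inactives, `q_signal` 0.9, noise 0.05, fixed seed — with
a scheme-1 split. The direct 1D classifier trains on the full training
partition (batch 32, dropout 0.2, balanced-accuracy checkpointing, at most
30 epochs). The stacked ensemble's seven members train for 4 epochs on a
class-balanced subsample of the training partition (300 actives + 600
inactives, batch 16): member networks are seven high-capacity CNNs and the
balanced subsample gives them the most informative gradient steps per unit
of compute; the ensemble is then evaluated on the untouched, imbalanced
held-out screen. Unit tests use narrower networks (16/8/8/4 filters, 64–128
bits) — the same architecture family at desk scale.

## Known limitations

* Single-threaded CPU training: practical for 1024-bit inputs and the
  reference dataset sizes, not for millions of compounds.
* The full tuning grid is provided (`grid_space()`) but is meant to be
  subset via `budget`; exhausting it is a cluster-scale undertaking.
* No scaffold- or time-based splits; stratification is by class only.
* No count-based or 3D fingerprints; no SMILES-based representation
  learning.
* SVM probability calibration (Platt) behind the EF ranking is one of
  several defensible score choices for the baselines.
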