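---
title: "Selective Class Average Voting: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective Class Average Voting: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scavote)
```

## The problem

Radiogenomic mutation prediction is a small-sample, imbalanced problem:
cohorts with segmented CT volumes and confirmed mutation status rarely
exceed a hundred patients, and the mutant class sits around 14% (EGFR-like)
to 24% (KRAS-like) of samples. Individual classifiers trained on such data
tend to be *cautious about the rare class*: their minority
pseudo-probabilities sit below 0.5 even for many true mutants, so an
ensemble that simply averages probabilities inherits the caution and scores
near-zero sensitivity, while an ensemble that trusts the single most
confident model inherits that model's noise.

## The SCAV rule

Let `p_ij` in [0, 1] be model `i`'s mutant pseudo-probability for sample
`j`, with `m` models. SCAV labels sample `j` in three steps:

1. model `i` votes mutant iff `p_ij >= 0.5`; the votes are counted,
   `v_j = #{i : p_ij >= 0.5}`;
2. if `v_j >= t` the label is mutant and the ensemble score is
   `mean{ p_ij : p_ij >= 0.5 }` — only the mutant-voting models speak;
   otherwise the label is wildtype and the score is
   `mean{ p_ij : p_ij < 0.5 }` (nonempty whenever `v_j < t <= m`);
3. the label equals thresholding the score at 0.5.

Step 3 can never contradict step 2 under these conventions: the mutant
branch averages numbers that are all at least 0.5 and the wildtype branch
numbers all below 0.5. This is a provable consequence of two choices we
made where the rule's verbal description is ambiguous:

* **"Above a threshold" is inclusive** (`v >= t`). This makes `t = m`
  (unanimity) expressible and `t = 1` the any-vote rule; a strict `>` is
  the same family shifted by one, so no generality is lost.
* **A model "votes mutant" at `p >= 0.5`** — ties go to the rare class,
  the conservative direction for a class that is easy to miss.
* **The score axis is always the mutant pseudo-probability**, in both
  branches, so a single orientation serves for AUC. Had the wildtype
  branch averaged wildtype probabilities instead, the score axis would
  flip per sample and the 0.5 re-threshold could contradict the count
  branch.

Because raising `t` can only move samples from the mutant to the wildtype
side, sensitivity is non-increasing and specificity non-decreasing in `t`;
the test suite asserts this on random matrices, along with exact agreement
between the vectorized implementation and a naive per-sample transcription
of the rule.

### Threshold tuning and member selection

`t` has no natural default; it is a fitted parameter. `scav_ensemble()`
evaluates every `t` in `1..m` on the *training* score matrix, computes the
training AUC of the resulting ensemble score, and keeps the argmax
(smallest `t` on ties, favouring sensitivity). Ensemble members are chosen
by ranking base models on training AUC and keeping the top `k`; inside the
cross-validated pipeline the per-model training AUC is the mean across
folds of the fold-training AUC, and both member ranking and threshold
tuning see training folds only.

## The experiment pipeline

`run_cv()` reproduces the tabular-branch experiment skeleton: stratified
k-fold CV (default 10) where each fold runs feature selection, then
optional SMOTE, then classifier fitting — in that order, on training rows
only — and scores the held-out rows. Stratification is not optional at 14%
prevalence: unstratified 10-fold splits of an 83-sample cohort frequently
produce mutant-free folds, in which sensitivity is undefined. Fold sizes
stay within one sample of each other and per-fold mutant counts within one.

Feature selection offers the two rankers of the study design:

* **Mann-Whitney**: two-sided rank-sum p-value per feature, ascending.
  Exact p-values when the smaller class has at most 8 samples without
  ties; the normal approximation with tie and continuity correction
  otherwise; a constant feature gets p = 1. Ties in p are broken
  lexicographically by feature name so selections are reproducible.
* **ReliefF**: a deterministic all-instances variant — every sample is
  visited, nearest hits/misses are found by Euclidean distance on
  range-normalized features (distance ties broken by sample index), and
  weights accumulate (miss diffs − hit diffs)/(n · k). The deterministic
  variant was chosen over sampled ReliefF so tests can be exact;
  `n_neighbors = 10` is the conventional default.

**SMOTE** oversamples only: synthetic mutants are convex combinations
`x_i + g (x_nn − x_i)`, `g ~ U(0, 1)`, of a minority sample and one of its
`k = 5` nearest minority neighbours, until the class ratio reaches 1
(within one sample). Neighbour search runs on features standardized by the
table's mean/sd and synthesis is de-standardized afterwards, which keeps
each synthetic row an exact featurewise convex combination of two
originals — the property the tests verify by solving for `g`. Majority
rows are never touched, undersampling variants are out of scope, and
applying SMOTE before a train/test split would leak; the pipeline applies
it inside folds only.

**Classifiers are adapters**, not reimplementations: the method under test
is everything around the classifier, so learners are bound at runtime
behind a `fit`/`score` contract (scores in [0, 1], fit sees training rows
only, deterministic under a seed). The package ships a dependency-free
nearest-centroid adapter (the default in tests: fully deterministic and
fast), plus adapters for logistic regression, random forest, SVM and a
small neural network where those packages are installed.

**The image branch** supplies plumbing only, since training CNNs is out of
scope: `select_slices()` picks the largest-area axial slice (ties to the
lowest z) and its two companions at z ± 2 — immediate neighbours are
skipped as near-duplicates — discarding a companion whose tumor area is
below 10% of the central one ("no clear piece of tumor", configurable),
and crops 128×128 ROIs centred on each slice's mask centroid with constant
padding at grid borders. `grouped_split()` assigns whole patients to
65/15/20 train/validation/test sets with label stratification
(largest-remainder rounding per class, with a rebalancing pass so every
set receives at least one patient of each class whenever counts permit).
CNN score matrices enter the ensemble through the same CSV score-matrix
interface as any other model bank.

## Radiomic features

The feature families named in the tabular branch are implemented from
their standard (IBSI-style) definitions, since the original extraction
pipeline is proprietary. All texture features quantize masked intensities
to 32 equal-width levels by default (a common radiomics default; the bins
are right-closed with the minimum mapped to level 1, and a constant region
maps to level 1).

* **GLSZM** (26-connectivity in 3D, 8 in 2D): grey-level variance,
  small-zone low-grey-level emphasis, grey-level non-uniformity. Zone
  counting is validated against an independent graph-components oracle.
* **Run-length GLN**, computed per direction (13 in 3D, 4 in 2D) and
  averaged.
* **3D Laws energies**: all 125 separable outer products of the L5, E5,
  S5, R5, W5 kernels via zero-padded cross-correlation; the energy is the
  mean absolute response over masked voxels. Every kernel except L5 sums
  to zero, so constant regions yield zero for 124 of the 125 filters.
* **3D Haar wavelet energies**: one-level separable decomposition into 8
  subbands, mean squared coefficient over the mask-covered half-resolution
  region; odd axes are extended by replicating the last sample.
* **Shape**: flatness `sqrt(lambda3/lambda1)` from the spacing-weighted
  coordinate covariance; asymmetry `1 − sqrt(mu2/mu1)` from the 2D
  covariance of the largest-area axial slice (kept two-dimensional so it
  measures in-plane eccentricity, which flatness does not); orientation as
  the angle between the principal eigenvector and the z axis in [0°, 90°];
  and surface-to-volume ratio. Asymmetry and orientation have no published
  reference formula in the original feature set, so these definitions are
  stated substitutes, not reconstructions.
* **Histogram**: mean, sd, and the 10th/50th/90th percentiles with
  linear interpolation between closest ranks.

**Surface estimation.** Counting exposed voxel faces is simple and
deterministic but systematically overestimates curved surfaces: for a
digital ball the face area converges to 1.5× the true sphere area (the
mean of |nx| + |ny| + |nz| over the sphere is 3/2). We therefore apply the
standard isotropic (Crofton-type) 2/3 normalization to the face count,
which brings a radius-10 digital sphere within ~2% of the analytic 3/r.
The price is underestimation for axis-aligned flat objects (a perfect box
would come out 33% low); for the blob-like tumors this package models the
isotropic correction is the right trade, and the estimator remains exactly deterministic.

## Synthetic study conditions

The generators define the conditions every test and the acceptance script
run under; they emulate the structure of an imbalanced radiogenomic cohort,
not its biology.

* `simulate_feature_table()`: exactly `round(n × minority_fraction)`
  mutants (defaults 0.14, the EGFR-like prevalence; 0.24 for KRAS-like
  runs), informative features as class-conditional unit-variance Gaussians
  with mean shift `effect_size`, noise features standard normal, one
  patient per sample in the tabular branch. Class-conditional Gaussians
  are the simplest model with a controllable effect size.
* `simulate_score_matrix()`: `p_ij = logistic(d·u_j + e_ij)` with a shared
  per-sample latent `u_j` (−0.5 for mutant, −2 for wildtype) and
  independent per-model noise `e_ij ~ N(0, sd²)`. The *negative* offsets
  are deliberate: they reproduce the under-calling of the rare class that
  real imbalanced-data classifiers exhibit, which is precisely the regime
  SCAV is designed for. At the default `discrimination = 0.5`,
  `model_noise_sd = 1`, a single model operates near sensitivity 0.4,
  specificity 0.85, AUC 0.7 — comparable to published base classifiers on
  this problem. Model diversity, the quantity voting exploits, is the
  single knob `model_noise_sd`.
* `simulate_tumor_volume()`: a discretized ellipsoid mask with constant
  (optionally radially decaying) base intensity plus Gaussian texture.

What these generators do **not** model: feature correlation structure,
scanner/batch effects, multi-slice patients in the tabular branch,
non-ellipsoidal tumor shapes, CT acquisition physics. Passing tests
demonstrate the *method* (voting algebra, leakage-freedom, calibration of
the harness), not clinical performance on real cohorts.

## Numerical choices and degenerate inputs

* AUC is the pairwise rank statistic with half-credit ties — identical to
  trapezoidal ROC integration (asserted exactly on 1,000 random
  instances) and invariant under strictly increasing score transforms.
* Undefined sensitivity/specificity (single-class fold) is reported as
  `NA` with a warning, never coerced to 0 or 1.
* All tie-breaks are documented and deterministic: feature ranks by name,
  member ranks by model index, SCAV threshold by smallest `t`,
  maximum-vote confidence by lowest model index, central slice by lowest z.
* Every stochastic step (generators, SMOTE, fold assignment, stochastic
  adapters) takes an explicit seed and restores the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script use: 1,000 random score
matrices (m ≤ 10, n ≤ 50) for the voting oracle; 100 random 6×6×6 grids
for the zone-count oracle; 120–200-sample tables with 20–40 features for
pipeline runs; an 800-sample table (400 train / 400 test, 24% mutant) for
the leakage guard, where a null test AUC has standard error ≈ 0.05 so the
[0.4, 0.6] band is a two-sigma check; and a 10-model bank over 200 + 200
samples for the SCAV-versus-average comparison. These sizes make the whole
suite run in about a minute while keeping each statistical assertion
adequately powered.

## Known limitations

* The SCAV sensitivity advantage over average voting at the AUC-tuned
  threshold is a strong tendency, not a per-draw guarantee: across 40
  replicate banks at the default conditions it held in 39 (with one tie),
  and the tuned ensemble's AUC stayed within 0.05 of the best single
  member in all 40. Individual draws can invert the sensitivity ordering
  when the tuned `t` lands high.
* Tuning `t` by training AUC is the stated selection rule, but AUC is a
  ranking criterion while `t` acts on labels; when sensitivity is the
  clinical priority, tuning on a sensitivity-weighted criterion would be
  more direct.
* ReliefF here is the deterministic all-instances variant; packaged
  implementations that sample instances will rank slightly differently.
* The GLSZM/GLRLM implementations are pure R and sized for ROI-scale
  masks (up to ~10^5 voxels), not whole-organ segmentations.
* SMOTE assumes features are commensurable after standardization;
  categorical features are not supported.
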