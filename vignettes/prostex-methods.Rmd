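---
title: "Texture radiomics and upstream filtering for prostate mpMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics and upstream filtering for prostate mpMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostex)
```

## The problem

Sequential lesion-detection pipelines for prostate multiparametric MRI
(mpMRI) — T2-weighted, ADC and diffusion-weighted volumes per case — tend to
be over-sensitive: they propose many lesion candidates, and the resulting
false positives depress specificity and can trigger unnecessary biopsies.
`prostex` implements and evaluates the classical machine-learning remedy: a
binary benign/malignant classifier built on 3D texture radiomics, used
either standalone or as an *upstream filter* that discards cases (or
candidate lesions) the classifier considers lesion-free, with the aim of
raising specificity while maintaining sensitivity.

Because clinical mpMRI cohorts of this kind are not publicly distributable,
every quantitative claim in this package is exercised on synthetic phantoms
whose generator is itself first-class, tested code.

## The phantom generator

A case is three co-registered sequences on a 149 x 149 x 32 voxel grid at
0.75 x 0.75 x 3 mm spacing, with nested anatomy masks:

* **gland** — an axis-aligned ellipsoid with semi-axes
  `gland_radius_mm * (1, 0.85, 0.7)` centred in the grid;
* **peripheral zone (PZ)** — the posterior (+y) part of the outer
  ellipsoidal shell of relative thickness `pz_shell_fraction` (default 0.4),
  a crescent in transverse slices;
* **lesions** — spheres rejection-sampled inside the gland. 70% of
  placements target the PZ, matching the clinical prior that roughly 70% of
  prostate cancers arise there. Sphere centres are drawn inside the gland
  ellipsoid shrunk by the lesion radius, which guarantees the nesting
  invariant (lesion inside gland) by construction rather than by clipping.

Texture is a Gaussian random field per sequence and class: white noise
smoothed by a separable Gaussian kernel (correlation length in mm),
standardised, then scaled and shifted to the class's SD and mean, plus
independent voxel noise (`noise_sd`, default 5). Malignant lesions have a
shorter correlation length (finer texture) and shifted mean — hypointense on
ADC, hyperintense on DWI, intermediate on T2W — so co-occurrence, LBP and
HOG statistics genuinely separate the classes rather than mean intensity
alone. Benign lesions deliberately share the benign texture statistics:
like clinically insignificant findings, they are only weakly conspicuous.
The default benign/malignant mean separations are moderate (2-4 noise SDs);
`phantom_texture("strong")` separates means by at least 5 noise SDs on
every sequence, the regime used for the end-to-end signal-recovery checks.
The default class composition is 718:448 benign:malignant, the composition
of the motivating clinical cohort.

What the phantom does **not** emulate: MR physics (bias fields, coil
profiles, Rician noise), inter-sequence misregistration, anatomical
variability beyond ellipsoids, or any relationship between Gleason grade
and texture. Consequently, passing tests demonstrate that the pipeline
recovers a known texture signal end to end — not that it would reach any
particular performance on clinical data.

## Preprocessing

Each sequence is z-score normalised over its nonzero voxels (the standard
MRI choice; a constant volume maps to zeros with a warning), resampled to
0.75 x 0.75 x 3 mm (linear interpolation for images, nearest-neighbour for
masks), and centred-cropped/zero-padded to 149 x 149 x 32. Normalisation
precedes resampling. Crop/pad centres on the grid, not the gland centroid,
because no segmentation is available at this position in the whole-image
pipeline mode. Conventions fixed once for all modules: axis order (x, y,
z), 0-based voxel indices, half-open boxes `[lo, hi)`.

## The 297-feature texture descriptor

Per sequence the descriptor concatenates, in fixed order:

| family | composition | count |
|---|---|---|
| Haralick | 13 statistics x 13 co-occurrence offsets | 169 |
| 3D LBP | 64-bin code histogram | 64 |
| 3D HOG | 4 cells x 16 orientation bins | 64 |

giving 297 per sequence and 891 for T2W+ADC+DWI. The 169/64/64 split is a
design choice: the canonical 13 Haralick statistics over the 13 unique
distance-1 3D offsets (antipodes merged by symmetrisation), with round
binary bin counts for LBP and HOG. Any composition meeting the 297 total
could be substituted, but it must be encoded in `feature_config()`, which
enforces the total.

Numerical choices worth knowing:

* GLCM uses 32 equal-width gray levels over each volume's own range;
  matrices are symmetrised and normalised per offset; features are computed
  per offset (averaging offsets would collapse 169 to 13). Entropies are
  log base 2; sum variance is centred on the sum average (the sum-entropy
  centring in the original formula set is a known erratum); correlation
  falls back to 0 when a marginal SD is zero.
* 3D LBP compares the 6 face-connected neighbours to the centre, ties
  (`neighbour == centre`) encode as 1, giving 2^6 = 64 codes — this is the
  variant whose code count matches the 64-bin share exactly. Codes are
  computed on interior voxels.
* 3D HOG uses spacing-aware gradients (central differences inside,
  one-sided at boundaries), 16 orientation axes from the icosahedron (6
  vertex axes + 10 face axes, antipodal directions merged), magnitude
  weighting, a 2 x 2 x 1 cell grid that respects the thin z axis, and
  per-cell L2 normalisation with an epsilon guard so constant volumes give
  a zero descriptor.
* Offsets and LBP neighbourhoods live in voxel space; physical spacing
  enters only HOG gradient scaling, since volumes are resampled to a fixed
  spacing first.

All three operators are verified against brute-force loop oracles on small
volumes in the test suite.

## Feature selection

Two reductions are provided behind a common fit/transform API that makes
test-fold leakage a type error (transforming before fitting errors):

* **PCA** with training-mean centring, default k = 95 — the packaged best
  whole-image configuration pairs these 95 components with the SVM below.
* **mRMR** (maximum relevance, minimum redundancy), greedy MID criterion:
  first pick maximises I(f; y), each next pick maximises
  `I(f; y) - mean I(f; selected)`. Continuous features are discretised into
  3 levels at mean +/- SD; features with at most 3 distinct values are used
  as-is (binning a 0/1 feature at mean +/- SD would collapse it into one
  level). Ties break to the lowest feature index for determinism. The MIQ
  quotient criterion is available as a switch; k for mRMR is an open knob
  with no canonical value.

Chaining mRMR and PCA is deliberately not implemented: the winning
configurations use one or the other.

## Classifiers

Three families behind one train/predict surface, all emitting malignancy
probabilities and all carrying a feature-name contract that rejects
misordered inputs:

* **SVM** (e1071): the score is a logistic squash of the decision value,
  which keeps prediction deterministic. "Error tolerance 60" — the packaged
  preset `svm_error_tolerance_60()` — is interpreted as the regularisation
  parameter C = 60.
* **Gradient-boosted trees** (xgboost): learning rate, maximum depth and
  maximum leaf count are all live knobs (`lossguide` growth).
* **MLP** (nnet): a single hidden layer; the layer-count dimension is
  fixed at one and only the size and weight decay are searched. This is a
  capacity limitation of the backend accepted as a design choice.

Class imbalance is handled with inverse-frequency class weights.
Hyperparameters are tuned by a seeded random search over discrete grids
scored by inner-CV AUC — a deliberately simple harness over the same
dimensions a heavier optimiser would tune, kept because model-selection
machinery is not where this package's evidence lies.

## Regions and the sliding window

Four regional settings feed the classifiers: whole image (3 sequences),
gland box (3 sequences), PZ box (ADC only — PZ lesions are assessed on
ADC), and per-lesion boxes with per-lesion labels. Mask-derived boxes get
a 2-voxel in-plane margin (none across slices) and are resized to fixed
per-kind shapes (gland 64 x 56 x 12, PZ 56 x 32 x 8, lesion 24 x 24 x 6,
chosen near the upper-quantile boxes of the default anatomy) so feature
support is consistent across cases. Raw (unmasked) boxes are the default;
background zeroing is a switch.

The localisation-free path slides a 70 x 65 x 3 window at 50% overlap
(strides 35, 32, 1; a final clamped window per axis guarantees coverage).
A window is labelled by its *lesion-relative* overlap ratio
`|window ∩ lesion| / |lesion| > 0.5` — window-relative overlap would make
any lesion smaller than half the window volume unlabelable, defeating the
purpose; "exceeds 0.5" is read strictly; malignant wins when several
lesions qualify. Window scores are averaged (not maxed; switchable) into a
voxel-wise heatmap, the image cutoff maximises Youden's J on validation
scores (midpoint between classes under perfect separation; degenerate
cutoffs are flagged), and the image label is "any supra-threshold voxel",
optionally hardened with a minimum connected-component size and a
gland-mask restriction — the documented failure mode of this approach is
lesion-like structure outside the prostate. Background windows are merged
with benign for binary training; the three-way labels are retained in the
window table.

## Evaluation and pipeline integration

Cohorts are split 85/15 (stratified by case label) with 5-fold
cross-validation inside the 85%; per-lesion instances inherit their case's
fold so lesions of one case never straddle a split. Selection and
classifier are refit per fold; held-out metrics use a model refit on the
full training portion — the standard protocol, adopted where the procedure
is otherwise silent. AUC is the Mann-Whitney pairwise statistic (ties
count half); sensitivity/specificity treat malignant as positive and are
reported as `NA`, not 0, when undefined.

The external segmentation pipeline is *emulated, not reimplemented*:
`emulated_segmenter()` corrupts ground truth with a per-case Poisson rate
of false proposals and a per-lesion drop probability. Every emitted
candidate counts as a suspicious finding, so a high false-proposal rate
reproduces the over-sensitive, low-specificity baseline regime that
motivates upstream filtering. Mode 1 places a case-level classifier before
the segmenter (predicted-negative cases skip it entirely); mode 2 scores
each proposed lesion and calls the case malignant if any proposal is.
Exact contracts — always-pass equals baseline, always-block gives
sensitivity 0 / specificity 1, an oracle filter raises specificity at
exactly baseline sensitivity — are asserted in the tests. Case-level
metrics are used throughout the pipeline modes.

## Problem sizes used in the checks

The test suite runs phantoms at a reduced 48 x 48 x 12 geometry (the
feature contracts are grid-size invariant), with cohorts of 90-120 cases
for the PCA-dimensionality and signal-recovery checks; the acceptance
script uses the full 149 x 149 x 32 geometry with 120 cases. These sizes
were chosen as the smallest at which the statistical checks are stable.

## Known limitations

* Phantom realism is deliberately minimal (see above); absolute metric
  values on phantoms say nothing about clinical performance.
* The MLP is single-hidden-layer; the sliding-window training path
  subsamples background windows for tractability.
* mRMR's k and the per-kind region shapes have no canonical values and are
  configuration knobs.
* The emulated segmenter's corruption rates are free parameters; its
  default false-proposal rate is set to produce a low-specificity baseline
  regime rather than calibrated to any external system.
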