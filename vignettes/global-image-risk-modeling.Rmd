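---
title: "Global image features for cancer risk and prognosis modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global image features for cancer risk and prognosis modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imagerisk)
```

## The modeling idea

Classical computer-aided diagnosis schemes compute features from a
segmented tumor. Segmentation is brittle — diffuse tumors, leakage into
normal tissue, inter-observer variation — so this package implements the
complementary strategy: compute **global** features from the whole imaged
organ (both breasts, the entire lung, the abdominal cross-section) and let
a case-based model do the discrimination. The package covers four feature
families (bilateral mammographic asymmetry, lung-CT emphysema, abdominal-CT
adiposity, breast-MRI kinetics), a distance-weighted KNN risk score, and
the oversampling/selection/cross-validation protocol needed to evaluate
such models honestly on small, imbalanced cohorts.

## The risk score

Cases live in an n-dimensional feature space. Features are z-score
standardized with parameters learned from the reference (training) cases
only — raw-scale Euclidean distance would be dominated by whichever feature
happens to have the largest numeric range. For a query $y_q$ and reference
$x_i$:

$$d(y_q, x_i) = \sqrt{\sum_r \left[f_r(y_q) - f_r(x_i)\right]^2},
\qquad w_i = \frac{1}{d(y_q, x_i)^2},$$

and the risk score over the $K = N + M$ nearest references ($N$ positive,
$M$ negative) is

$$P_{risk} = \frac{\sum_i w_i^{+}}{\sum_i w_i^{+} + \sum_j w_j^{-}} \in [0, 1].$$

Numerical choices:

* **Zero distance.** $w = 1/d^2$ is singular at $d = 0$. Distances at or
  below $\varepsilon = 10^{-6}$ are capped at $1/\varepsilon^2$: an exact
  feature match dominates its neighbourhood (as it should — it is the most
  similar case on record) without overflowing. This also makes the score a
  sharp leakage detector: if a case ever meets its own copy in the
  reference set, its score collapses to its own label.
* **Self-exclusion.** A reference sharing the query's `case_id` is dropped
  from the neighbourhood, so scoring training cases is automatically
  leave-one-case-out.
* **Ties.** Neighbours at equal distance are taken in stored reference
  order, which is deterministic.
* **K.** Default 15, following the short-term breast-cancer-risk model this
  score derives from; it is a config value.

Relabeling positives as negatives maps $P$ to $1-P$, and multiplying all
weights by a constant leaves $P$ unchanged; both are asserted as tests.

## Class imbalance and feature selection

**SMOTE.** Each synthetic minority case is $x + u\,(x_{nn} - x)$ with
$u \sim U(0,1)$ and $x_{nn}$ one of the $k = 5$ nearest minority
neighbours. Allocation is the canonical one: every minority case generates
an equal share of the synthetics (remainder randomized), which keeps the
oversampled set evenly spread. Original rows pass through untouched and
flagged, so dropping `synthetic` rows restores the input exactly —
evaluation statistics are always computed on original cases only.

**CFS.** Correlation-based feature selection scores a subset $S$ by
$$\mathrm{merit}(S) = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}},$$
with $\bar r_{cf}$ the mean absolute feature–class (point-biserial)
correlation and $\bar r_{ff}$ the mean absolute feature–feature
correlation: informative features are rewarded, redundant ones penalized.
The search is best-first forward with a patience of 5 non-improving
expansions, ties broken by feature order; tests verify it agrees with
exhaustive best-subset search for up to six features. Constant features get
correlation 0 and are never selected.

## The evaluation protocol

Leave-one-case-out cross-validation embeds *everything* inside the loop:
for each held-out case, SMOTE, feature selection, standardization and
training see only the remaining cases. Synthetic cases appear in training
folds only and are never scored. Two canaries guard the protocol: a
feature equal to the label must yield AUC 1 (it is legitimately learnable
from every training fold), and a pure-noise table must stay at chance — if
the held-out case leaked into SMOTE or the reference set, its zero-distance
copy (capped weight $10^{12}$) would drag the AUC towards 1.

Downstream statistics follow the field's reporting conventions: Mann–Whitney
AUC (ties counted half) with the Hanley–McNeil standard error; a confusion
matrix at the operating threshold $T = 0.5$, with `score >= T` counted as a
positive call (the tie side is a documented convention); sensitivity,
specificity, PPV, NPV and accuracy as percentages to one decimal, with
zero-denominator metrics reported as `NA`, never 0; rank-based quantile
subgroups whose sizes differ by at most one; subgroup odds ratios computed
as crude 2×2 ratios against the lowest-score subgroup with Woolf
(log-normal) 95 % intervals, Haldane–Anscombe 0.5-corrected and flagged when
a cell is empty — this reproduces the published subgroup tables this
implementation is checked against to their printed precision; and a
Cochran–Armitage trend test (integer scores $1..k$) in place of a fitted
logistic trend, since only the trend's significance is reported.

## Phantoms: what they emulate, and what they do not

All tests run on seeded generators that emit ground truth alongside data:

* `gen_feature_table()` draws two-class Gaussian features with unit
  within-class SD; `n_informative` columns get a mean shift of `d`, so a
  single informative feature has theoretical AUC $\Phi(d/\sqrt2)$.
  Within-class correlation comes from an equicorrelated one-factor model.
* `gen_bilateral_pair()` mirrors a half-elliptical breast about the
  vertical axis (chest wall at the image edge) and perturbs the right side
  with extra dense blobs and local variance inflation scaled by the
  asymmetry level.
* `gen_lung_volume()` plants a voxel-exact emphysema fraction as compact
  blobs below −955 HU inside an ellipsoidal lung held above −920 HU: a
  ≥ 30 HU guard band on each side of the −950 HU threshold makes
  density-mask recovery unambiguous.
* `gen_abdominal_slice()` plants a pixel-exact subcutaneous ring and
  visceral blobs in the −130…30 HU range, a muscle wall between them, and
  non-fat tissue at ≥ 65 HU (again a guard band around the −140…40 HU fat
  window).
* `gen_mri_pair()` adds a planted enhancement field (Gaussian or
  standardized-gamma for right skew) to a two-breast phantom.

Phantom sizes default to 40×40×28 lung voxels, 120×160 abdominal pixels,
128×96 mammogram pixels, 48×64×12 MRI voxels — small enough for fast seeded
batches, large enough that boundary effects are minor. Noise is additive
Gaussian, the simplest model that exercises every estimator. What the
phantoms deliberately do **not** emulate: anatomically realistic texture,
scanner physics, partial-volume effects, or acquisition artifacts. Passing
tests therefore demonstrate correctness of the *computations* (thresholds,
geometry, protocol, statistics), not clinical performance on real images.

## Design choices in the feature extractors

* *Dense-tissue threshold* for fibroglandular area: Otsu within the breast
  mask — parameter-free and reproducible.
* *Focal regions*: the DoG map thresholded at its within-mask 99th
  percentile, largest 8-connected component; sigmas default to (2, 8) px
  and the fluctuation window to 9 px — all configurable.
* *Density category*: percent-dense binned at 25/50/75 %, a four-level
  ordinal rating analogous to standard clinical density categories.
* *GLCM*: 32 levels quantized over the region's own range (hence invariant
  to affine intensity rescaling), one-voxel offsets along each axis,
  symmetrized, normalized, averaged over offsets. Emphysema texture is
  computed on the binary emphysema-pattern map of the lung (an HU-map
  alternative is a parameter). A brute-force pair-enumeration oracle checks
  the construction exactly on small images.
* *Blob sphericity* uses face-counted surface area divided by 3/2 — the
  stereological correction for the voxel staircase (a voxelized sphere
  otherwise reports ≈ 0.67). Axis-aligned flat shapes are consequently
  over-corrected; for the compact blobs this panel describes that bias is
  acceptable and documented.
* *SFA/VFA split*: fat components connected to the boundary shell (body
  minus its erosion by 10 mm, computed by an exact Euclidean boundary
  distance) are subcutaneous; the rest visceral. The split is an exact
  partition of the fat mask.
* *MRI registration* is integer translation by exhaustive search,
  maximizing in-mask correlation (or minimizing the variance of the
  difference image when in-mask intensities are degenerate, which is
  offset-invariant in the same way). Deformable registration is out of
  scope.
* *Chest-wall separation* is a straight per-slice line fitted to the
  anterior tissue edge of wall-only columns (those whose edge lies within
  half a row of the slice's most posterior edge); a fixed plane can be
  supplied instead.
* *Kinetic statistics*: population-moment skewness (defined as 0 at zero
  variance), sample SD, and top-k % means over the $\lceil k\% \cdot N
  \rceil$ largest values so the set is never empty; statistics are computed
  per breast (a joint-breast variant would be a one-line change).

## Problem sizes in the test suite

The heaviest check runs the full SMOTE + CFS + KNN pipeline under
leave-one-case-out on tables of 500 cases (125 positive) for 50 seeds —
about four minutes on one core; all other tests are seconds. The
acceptance script uses 12 seeds for the same quantity.

## Known limitations

* The inverse-square weight concentrates nearly all weight on the single
  nearest reference when the (selected) feature space is low-dimensional
  and continuous — nearest-neighbour distances scale like $1/n$, so
  $w \sim n^2$. Combined with the binomial noise of a 15-case
  neighbourhood, the LOCO AUC of the full pipeline on tables with one
  informative feature of theoretical AUC 0.70 is measured at ≈ 0.60
  (50 seeds), an attenuation the package reports honestly rather than
  tuning around; the corresponding acceptance check fails by design of the
  score, not by implementation error. Discrete or coarsely quantized
  features (common in practice) produce distance ties that spread the
  weight and reduce the attenuation.
* The 21-feature emphysema panel is a representative, fixed-schema panel;
  texture parameters (levels, offsets) are conventions, not fitted values.
* Automatic lung/body segmentation is out of scope: masks are inputs.
* The odds-ratio tables are crude (unadjusted) 2×2 ratios; covariate
  adjustment would require per-case covariates the case table does not
  carry.
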