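---
title: "Methods: imbalance-aware melanoma identification on tabular lesion features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware melanoma identification on tabular lesion features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dermaug)
```

## The problem and the pipeline

Melanoma classification from dermoscopy is a small-data, class-imbalanced
problem: typical public archives carry a majority/minority ratio of 3–4
benign lesions per melanoma. `dermaug` implements the tabular workflow this
motivates: (1) preprocess lesion images, (2) extract a fixed catalogue of
handcrafted features, (3) select a robust feature subset with an ensemble of
ReliefF learners, (4) oversample the training minority to a target balance
ratio, audit the synthetic rows with fidelity metrics, (5) tune and evaluate
classifiers over repeated train/test splits, and (6) interpret the result
with a bootstrap-CI class-difference test, Shapley attributions and UMAP
views. Stages are pure functions of their inputs plus an explicit seed, so
every number in the package's tests and artifacts is reproducible.

Two conventions recur. "Imbalance ratio" names two distinct quantities:
the descriptive majority/minority count of a dataset (e.g. 160/40 = 4.00),
and the *target balance ratio* `r = (n_min + n_syn) / n_maj ∈ (0, 1]` that
the oversampler sweeps (1.0 = fully balanced). The package names the second
one `r` throughout and derives the synthetic-sample count as
`n_syn = max(0, ceil(r·n_maj) − n_min)`.

## Synthetic data: what it emulates and what it does not

`generate_lesion_image()` renders a lesion as an ellipse whose polar radius
is modulated by a sinusoid (border waviness, amplitude in px and an integer
cycle count) and by a one-sided radial scaling (asymmetry coefficient in
[0, 1]); these are deliberately the A and B knobs of the ABCD screening
rule. Colour variegation is painted as palette spots, texture as in-lesion
Gaussian noise (gray levels on the 0–255 scale), and hair as dark
anti-aliased quadratic Bézier strokes 1–3 px wide — the thin curvilinear
artifact class that black-hat hair removal targets. The background is a
constant beige with σ = 0.015 sensor-like noise: the simplest background
that still exercises Otsu segmentation. Hairs are drawn last from an RNG
stream derived from `seed + 10007`, so the hair-free and hairy renderings of
one spec differ only on stroke pixels — a property the preprocessing tests
rely on.

What the generator does **not** emulate: dermoscopic microstructures
(streaks, pigment networks, blue-white veil), illumination gradients, ruler
and ink marks, and realistic colour distributions. Tests passing on these
fixtures therefore demonstrate algorithmic correctness and the stated
statistical properties — not clinical performance on real dermoscopy.

`generate_feature_table()` emulates an extracted-feature table directly:
`n_maj` label-0 and `n_min` label-1 rows, the first `n_informative` features
shifted by `effect_size` standard deviations in the minority class and
sharing an equicorrelated Gaussian block (`x_i = √ρ·z₀ + √(1−ρ)·z_i`, which
preserves unit variance), remaining features N(0, 1) in both classes. The
defaults used across the test-suite experiments mirror the small-study
setting: 160/40 rows, 30–50 features, 5–10 informative. "Strong signal"
means effect size 1.5–2 (well separated), "weak signal" 0.75 with block
correlation 0.3 — a regime where AUCROC is good but a 0.5-threshold
classifier trained on imbalanced data still misses melanomas, which is what
the balance-ratio sweep is about.

## Preprocessing

Images are resized to 224 × 224 by direct bilinear resampling (no padding;
the aspect ratio of the source is not preserved). Grayscale conversion is
ITU-R 601 luma everywhere.

Hair removal detects dark curvilinear structures as the union over
orientations {0°, 30°, …, 150°} and lengths {9, 15} px of thresholded
morphological black-hat responses with linear structuring elements, at a
threshold of 10 gray levels. Two numerical choices matter:

* the response must exceed the threshold on **both** the raw luma and a
  σ = 1 px Gaussian-smoothed copy. Single-pixel noise produces black-hat
  responses only on the raw image, while the smoothed ramp at a large dark
  lesion's boundary produces them only on the smoothed image; genuine hair
  strokes respond on both. This conjunction is what keeps the false-positive
  rate on hair-free lesions below 1% while retaining ≥ 93% stroke recall on
  the fixtures.
* detected pixels are filled by a distance-ordered inpainting: unknown
  pixels are processed in increasing distance from the known region and
  replaced by an inverse-distance-weighted average of known pixels within a
  radius-3 window, each filled pixel immediately joining the known set. This
  is the marching-front scheme of fast-marching inpainting with the simplest
  admissible weight; it is deterministic and touches only masked pixels.

The fallback segmenter (Otsu threshold, largest component, hole filling)
exists for synthetic fixtures; real masks are expected as inputs.

## The feature catalogue

`extract_all()` emits 281 named features in a fixed order: 4 ABCD, 44
colour, 233 texture. Histogram/matrix families (FOS, GLCM, GLDS, GLRLM,
GLSZM, NGTDM) operate on in-mask pixels quantized to Ng = 32 levels over the
in-mask min–max (a common radiomics default balancing matrix sparsity
against gray resolution at 224²); signal families (LBP, SFM, HOS, FDTA,
DWT, WP) operate on the lesion bounding box with out-of-mask pixels filled
by the in-mask mean, which avoids spurious edges at the lesion boundary.

Conventions worth stating explicitly:

* zero-variance inputs map skewness, kurtosis, coefficient of variation and
  the Hurst slopes to 0; no feature is ever NaN or infinite (property-tested
  across random specs).
* GLCM uses distance-1 offsets {(0,1), (1,0), (1,1), (1,−1)}, symmetric
  counting, features averaged over the four offsets; the full 14-statistic
  Haralick set is emitted. GLDS emits the canonical 5 difference-histogram
  statistics; GLRLM the 16-statistic set (11 classic emphases plus
  normalized non-uniformities, gray-level/run-length variances and run
  entropy); GLSZM the 14 zone statistics with 8-connected equal-level zones.
* asymmetry is the mean non-overlap fraction of the mask against its
  reflections across the two centroid-anchored principal axes. Under this
  convention a half-disk scores ≈ 0.18 on its asymmetric axis (the exact
  discrete value is asserted against a naive reflection oracle in the
  tests); conventions that reflect across the shape's bounding edge score
  higher, and no published formula fixes the choice.
* border is compactness P²/(4πA) with the perimeter measured along the
  traced 8-connected boundary chain (unit and √2 steps), which is within 10%
  of the ideal 1.0 on a rasterized disk. Colour counts reference occupancy
  (> 1% of lesion pixels, nearest-reference assignment in RGB) over six
  dermoscopy reference colours.
* RGB and HSV statistics are pooled over all in-mask channel values (4 each);
  CIELab, CIELuv and YCrCb are per-channel (12 each), matching the
  catalogue's per-row feature counts.
* wavelet features use a periodized filter bank (bior3.3 for the 3-level
  DWT — 18 detail + 2 approximation statistics; coif1 for the depth-3
  wavelet-packet tree — 64 nodes × 2 = 128 features, nodes named by their
  a/h/v/d path). Subband statistics are the mean and sd of absolute
  coefficients. The printed catalogue counts for these two families (34 and
  125) are not derivable from any dyadic configuration, so the counts here
  are config-derived and documented.
* HOS features are normalized bispectral phase entropies of the Radon
  projection at 135° and 140°: the projection's FFT X is accumulated as
  B(f₁, f₂) = X(f₁)X(f₂)X*(f₁+f₂) over the principal triangle and the
  entropy of the phase histogram (32 bins) is normalized to [0, 1].
* FDTA estimates one Hurst exponent per dyadic resolution (original image
  plus three 2×-downsamplings) as the log–log slope of mean absolute
  intensity increments over lags 1–4.

The embedding adapter runs a full ResNet-50 forward pass (7×7 stem,
3-4-6-3 bottleneck stages, global average pooling → 2048 values) with
He-initialised random weights from a fixed seed and identity batch-norm. It
is untrained by design: it provides the embedding *contract* (shape,
determinism) for pipeline plumbing without any weight download, and is not a
substitute for a trained backbone's representation quality.

## Ensemble feature selection

The base learner is ReliefF with k = 10 neighbours, all instances as
anchors, Manhattan distance on min–max scaled features: each anchor adds the
mean per-feature difference to its nearest misses and subtracts that to its
nearest hits, normalized by the anchor count. A feature identical to the
label therefore gains weight while independent noise hovers near zero, and a
constant feature contributes exactly 0.

The ensemble fits ReliefF on M = 100 bootstrap subsets (class-stratified by
default, preserving the class counts — plain uniform resampling is available
and occasionally drops an entire class on small minorities, which is why
stratification is the default). Aggregation is by voting: each learner votes
for its top `t = ceil(0.25·D)` features; features are ranked by descending
vote count, ties broken by ascending mean rank across learners, then by
name. Votes are conserved (Σ votes = M·t, asserted), the output is a
permutation of the features, and column permutation of the input permutes
the output identically. `k_final` defaults to 35 for image-feature tables.
Selection is always fitted on training rows only; the selected names are
then applied to the test rows (leakage control).

## Oversampling, mode-specific normalization and fidelity metrics

SMOTE generates each synthetic row as `x + u·(x_nn − x)` with
`u ~ U(0, 1)` and `x_nn` among the k = 5 nearest minority neighbours
(Euclidean distance on z-scored features, interpolation on the raw scale);
outputs therefore stay inside the minority convex hull, which is asserted.
Real rows are never modified or deleted; synthetic rows carry the minority
label and `source = "synthetic"`.

Mode-specific normalization encodes a continuous column as (mode one-hot,
within-mode scalar): a Gaussian mixture with up to 10 components is fitted
(BIC-selected, components under weight 0.005 pruned), each value is assigned
to its highest-responsibility mode (the deterministic variant of the
sampling rule used during generative training), and standardized as
`(c − μₖ)/(4σₖ)`. The 4σ scaling keeps scalars in roughly [−1, 1]; the
inverse transform is exact to floating point for values assigned to their
generating mode.

Fidelity metrics follow their printed definitions: HD ∈ [0, 1] and
MAEP ∈ [0, 2] on per-feature PMFs, PCD as the Frobenius norm of the
correlation-matrix difference, RSVR as the fraction of synthetic rows
exactly equal to an earlier synthetic row. Since no definition of the PMF
for a continuous feature is fixed anywhere, the package discretizes with 20
equal-width bins over the pooled min–max of both samples; MAEP is the
printed sum (a `mean` flag divides by the bin count for users who expect the
name literally). Constant columns take correlation 0 by convention, so PCD
is always finite.

## Evaluation harness

`ir_sweep_experiment()` runs, per repeat: a stratified 80/20 train/test
split → z-scoring with training statistics → ensemble feature selection on
the training rows → minority oversampling of the training partition to each
target ratio → a stratified 5-fold grid search maximizing validation
AUCROC → a final fit → evaluation on the untouched, all-real test rows.
Reported mean ± sd is over repeats (5 by default), not folds. Grids follow
the explored ranges — LASSO C ∈ [10^−1.5, 10^0.4] (an L1-penalized logistic
classifier scored by predicted probability, λ = 1/(nC)), KNN K ∈ 1..11, RBF
SVM γ ∈ {10^−2..10^−5} × C ∈ [10^−0.9, 10^0.9], tree depth 2..8 with
min-split 5% of the training size — with continuous ranges discretized to 10
log-spaced points and ties resolved toward the less complex setting (more
regularization, smaller K, shallower tree). Class metrics threshold
probabilities at 0.5 (decision values at 0); sensitivity is the recall of
the melanoma class. The 80/20 proportion, grid density, scaling and
threshold are the package's own choices where no published value exists.

## Interpretability

The bootstrap-CI test resamples each class separately with replacement
(M = 1000), computes Δ⁽ⁱ⁾ = μ⁽ⁱ⁾₁ − μ⁽ⁱ⁾₀ per resample, and takes the
percentile (α/2, 1−α/2) interval; the difference is significant iff 0 lies
outside. The percentile interval (rather than BCa) is chosen for
transparency and because the statistic is a smooth mean difference at
n ≥ 100 per class, where the two coincide closely; calibration is verified
empirically (type-I error 0.05 ± 0.02 over 500 null simulations at n = 200
per class). No multiple-testing correction is applied by default, matching
the per-feature CI reporting convention; a Bonferroni flag exists.

Exact Shapley values enumerate all 2^D subsets for D ≤ 15 with the
combinatorial weights |S|!(D−|S|−1)!/D!; absent features are imputed by
background column means, the simplest value function consistent with
"prediction without the feature". Efficiency, symmetry and dummy hold to
1e-9 and are tested. For wider models the summary adapter switches to a
Monte-Carlo permutation estimator of the same quantity.

## Problem sizes and numerical tolerances in the shipped tests

The test-suite experiments use 160/40- to 400-row tables with 20–50
features, M = 25–50 bootstrap subsets, 2–5 repeated splits, and 14–20
synthetic images at 96–224 px — sizes chosen so the full suite documents the
method's statistical properties (recovery, calibration, sweep direction) at
desk scale. Exact-count operators (co-occurrence, runs, zones, NGTDM) are
tested to 1e-12 against naive enumerations; wavelet subbands to 1e-9 against
frozen reference values; stochastic properties (bootstrap coverage, ensemble
recovery, the sensitivity direction of the ratio sweep) as medians over
10–20 seeds.

## Known limitations

* Synthetic lesions are geometric idealizations; none of the shipped
  evaluations speak to real dermoscopy performance.
* The CTGAN/TVAE adapter slots require an external backend; only SMOTE is
  implemented natively, so comparisons across oversamplers degrade to
  capability errors without one.
* The untrained backbone gives contract-valid but semantically meaningless
  embeddings.
* The asymmetry and colour-count conventions (centroid-PCA reflection,
  fixed reference palette with a 1% occupancy threshold) are reasonable but
  not canonical; absolute values are comparable only within this package.
* ReliefF distances degrade in very high dimension; the ensemble mitigates
  variance, not the metric itself.
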