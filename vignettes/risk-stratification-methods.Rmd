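---
title: "Methods: radiomic texture features and rank-based classifier selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic texture features and rank-based classifier selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstrat)
```

# The problem

Two-class risk stratification of tumours from paired-modality 2D regions of
interest (a T2-weighted-like structural image and an ADC-like diffusion
map), with a strongly imbalanced cohort: the clinically interesting
high-risk class is the minority. The pipeline answers three questions in
order: which of seven standard classification algorithms ranks best on this
feature space; how should the selected classifier's probabilistic output be
binarized; and does the final classifier beat an ordinal reader-score
benchmark and a label-permutation null on an independent cohort.

# Feature model

Each modality contributes 55 features, concatenated T2W-then-ADC into a
110-dimensional patient vector. The manifest is frozen (see
`feature_manifest()`; a golden copy lives in `inst/extdata/`) because every
trained model validates incoming columns against it.

* **Histogram (15)** — first-order statistics of in-mask intensities: mean,
  sd, variance, skewness, excess kurtosis, min/max/range, median,
  percentiles 10/25/75/90, plus entropy (base 2) and uniformity computed on
  a 64-bin min–max histogram. Intensities are in scanner-arbitrary units, so
  only the location features (mean, median, percentiles, min/max) depend on
  the intensity scale; this is tested via shift invariance of the texture
  families.
* **GLCM (20)** — Haralick-style statistics of the symmetric, normalized
  co-occurrence matrix of 32-level quantized intensities: energy, entropy,
  correlation, contrast, homogeneity, dissimilarity, cluster shade and
  prominence, maximum probability, sum average/variance/entropy, difference
  average/variance/entropy, autocorrelation, joint mean and variance, and
  the plain and level-normalized inverse differences. Pairs are counted at
  unit distance in the four directions 0°, 45°, 90°, 135° — both pixels must
  lie in the ROI mask — and features are averaged over directions for
  rotation robustness. Averaging (rather than concatenating directions) is a
  design choice; the alternative quadruples the feature count and breaks the
  55-per-modality structure.
* **GLDM (8)** — statistics of the distribution of absolute gray-level
  differences at the same four displacements: mean, variance, entropy,
  energy, contrast, inverse difference moment, maximum probability,
  zero-difference fraction.
* **FFT (12)** — the ROI's mask bounding box is taken, out-of-mask pixels
  are replaced by the in-mask mean (mean-fill avoids the sharp mask edge
  dominating the spectrum), the mean is subtracted and the 2D DFT power
  spectrum is formed. Features: total non-DC power (the variance of the
  filled box), spectral entropy, four equal-width radial-annulus energy
  fractions, dominant radial frequency (centre of the strongest annulus,
  cycles/pixel), power-weighted mean and sd of radial frequency, spectral
  flatness, anisotropy (strongest 45° orientation sector over the mean
  sector power), and the low-frequency power fraction at the half-Nyquist
  split. The family list is rounded out to 12 with the radial-frequency
  spread, and the low/high ratio is implemented as the bounded fraction
  `low / (low + high)` so that every feature stays finite when a band is
  empty.

**Quantization.** GLCM/GLDM use 32 gray levels, histogram entropy 64 (both
overridable). Linear min–max binning over in-mask intensities; the maximum
maps to the top bin; a constant ROI maps to bin 0. 32 levels keeps the
co-occurrence matrix well-populated on small ROIs while preserving texture
contrast; both are common radiomics practice.

**Degenerate-value conventions**, all tested: skewness, kurtosis and GLCM
correlation are 0 when the relevant variance is 0; spectral features are all
0 for a spectrally empty (constant) ROI; homogeneity and the inverse
difference moments take their maxima on a constant image. These conventions
keep all 110 features finite on any valid input, down to the minimal
16-pixel mask.

# Learners

Seven algorithms with frozen hyperparameters (`learner_spec()`): SVMs with
linear, quadratic, cubic and Gaussian kernels (box constraint 1, kernel
scale γ = 1/p, inhomogeneous polynomial offset +1 — the homogeneous form is
a config switch), ridge-penalized logistic regression (λ = 1/n, the C = 1
convention; the unpenalized fit is degenerate at p = 110 ≈ n), linear
discriminant analysis with a fixed Tikhonov covariance regularizer
(α = 10⁻³ of the mean pooled variance, so within-class-constant features of
the frozen manifest cannot make the pooled covariance singular), and a
100-tree random forest.

Every model standardizes features to zero mean / unit sd using training rows
only; zero-variance features keep scale 1 rather than being dropped, so the
110-column manifest stays stable. Margin-based SVMs get a Platt sigmoid
calibration fitted on seeded, stratified 3-fold out-of-fold decision values
(the libsvm-internal calibration is not reproducible across fits, which
breaks the package's determinism contract). Decision values are oriented so
larger means more high-risk; if the out-of-fold calibration is degenerate or
inverted — possible on very small training sets where held-out folds
anti-predict — the sigmoid is refit on the training decision values so the
probability map is always non-decreasing in the decision value. Probability
outputs are clamped to [0, 1].

# Cross-validation and rank-based selection

Stratified 5-fold CV repeated 10 times. Per run, folds are drawn fresh;
random oversampling (duplicating minority rows until counts balance) is
applied to the *training folds only* — the held-out fold is never resampled
or copied, so no sample ever appears on both sides of a split. Per
(algorithm, run) the out-of-fold predictions cover each development sample
exactly once and are scored with seven measures: AUC (rank statistic, ties
credited 0.5) and F\_max/P\_max/R\_max for each class as the positive
target. Both class-specific metric sets derive from a single thresholding of
the high-risk score (predicted high iff score ≥ t); an independently swept
lower-class threshold is a config alternative, but the single-threshold rule
matches how the final classifier is actually deployed.

Algorithms are ranked within each run (rank 1 = best, average ranks on
ties). The tie-corrected Friedman statistic is computed from the rank
matrix, with the fully-tied 0/0 case defined as statistic 0, p = 1. The
Nemenyi critical difference uses the exact studentized-range quantile
`qtukey(1 - α, k, Inf) / √2` rather than a transcribed table (printed tables
differ in the third decimal); CD(k = 7, N = 10, α = 0.05) = 2.8483. The
selected algorithm must sit in the top group (mean rank within one CD of the
best) for *all seven* measures; among qualifiers the lowest grand mean rank
wins, and if no algorithm qualifies everywhere the grand mean rank decides,
with the fallback recorded in the selection provenance.

The final classifier is refit on the oversampled full development set
(consistent with how CV training saw data; the raw set is a switch) and
thresholded at the arithmetic mean of the 10 per-run F\_max-optimal
thresholds. Ties in the threshold sweep resolve toward the lowest threshold.

# Validation benchmarks

* **Ordinal comparator** — reader scores 1–5 are used raw as a ranking score
  for AUC (ties 0.5) and binarized at score > 3 for the per-class P/R/F.
  The "> 3" reading of a threshold of 3 is adopted because typical
  class-mean spacing on the 1–5 scale (lower-risk ≈ 3.3, high-risk ≈ 4.3)
  would make "≥ 3" classify nearly every patient high-risk.
* **Permutation null** — the fixed final classifier and threshold are
  evaluated on 100 copies of the validation cohort with labels randomly
  permuted (class counts preserved); per-measure mean, sd and standard
  error sd/√100 are reported. Exchangeability makes the expected AUC 0.5.
* **Paired bootstrap comparison** — 100 bootstrap resamples of the
  validation cohort (a resample that loses a class is redrawn, since AUC
  would be undefined); both methods are evaluated on the identical
  resamples and each measure's paired difference is tested with the k = 2
  Friedman test over the 100 blocks. Friedman with k = 2 is retained rather
  than substituted with a sign test because it is the stated comparison
  procedure of the framework; for tie-free k = 2 data it is algebraically
  `(2w − n)²/n`, which the test suite uses as an oracle.

The package's own Wilcoxon signed-rank test (used for the paired
with/without-oversampling comparison) computes the exact two-sided p for up
to 25 nonzero differences by convolving the signed-rank distribution over
the (possibly tied) average ranks, and falls back to the tie- and
continuity-corrected normal approximation beyond that.

# The synthetic-cohort generator

`cohort_spec()` + `generate_cohort()` emulate the study conditions: a
development cohort of 68 patients (54 lower-risk / 14 high-risk) and an
independent validation cohort of 53 (39 / 14). Per patient, each modality is
a stationary Gaussian random field: white noise filtered in the frequency
domain with a Gaussian spectral envelope whose width is the texture
correlation length, affine-scaled to the modality's mean and sd, clipped at
zero and rounded to integers (lossless 16-bit storage), inside an elliptical
ROI mask with semi-axes uniform in 0.5–0.9 of the half-size (elliptical, not
rectangular, so masked pair-counting is genuinely exercised). Defaults:
T2W-like mean 600, sd 120, correlation length 2.5 px; ADC-like mean 1200,
sd 180, correlation length 2.0 px; image size 48 px.

Class separation is a single dimensionless `effect_size` multiplier: the
high-risk class lowers the ADC-like mean by 150 per unit effect (mimicking
restricted diffusion in aggressive tumours) and lengthens the T2W-like
correlation length by 1 px per unit (coarser texture), so all four feature
families can respond. Per-patient jitter (mean intensity sd 60/100 for
T2W/ADC; lognormal sd 0.10 on correlation length) supplies between-patient
variance — without it a within-image mean would separate the classes almost
perfectly at any effect size. `effect_size = 1` is the package's "moderate"
condition and yields out-of-fold AUCs in the high-0.8s/low-0.9s at these
cohort sizes, the regime where classifier choice and thresholding
genuinely matter; `effect_size = 0`
makes the classes generatively identical. Ordinal reader scores come from a
latent Gaussian (class means 3.3 / 4.3, noise sd 0.6, rounded and clipped to
1–5), echoing typical reader-score spacing.

One master seed expands into per-patient sub-seeds through a counter scheme,
so enlarging a cohort never perturbs earlier patients, and the identical
spec + seed reproduce every pixel, label and score bit for bit.

`generate_feature_table()` is an image-free shortcut for classifier-side
testing: 110 correlated Gaussian features (block-equicorrelated, ρ = 0.3),
with `n_informative` features carrying either a plain class-mean shift of
`effect_size` within-class sds, or an XOR structure in which two halves of
the informative set load on two latent signs whose *product* encodes the
class — no single feature has marginal signal, so only interaction-capable
learners can separate the classes. The XOR experiments use
`effect_size = 3`, the smallest value at which polynomial-kernel machines
reach near-perfect CV AUC (the "strong signal" regime) while linear
learners stay at chance.

**What the generator does not emulate:** anatomy, scanner artefacts,
partial-volume effects, inter-scanner feature non-reproducibility,
multi-reader disagreement, 3D structure, or any correlation between the two
modalities beyond the shared class label. Passing tests therefore
demonstrate that the *pipeline machinery* behaves as specified under
controlled feature–label structure, not that any particular performance
level transfers to clinical images.

# Problem sizes used by the test suite

The acceptance experiments run at the study's cohort sizes (68/53 patients,
48-px images, 10 × 5-fold CV, 100 permutation and bootstrap replicates).
Multi-seed recovery checks aggregate 10 seeds; the effect-size monotonicity
property uses 2 CV repetitions per seed, which is sufficient because only
the ordering of seed-averaged AUCs is asserted.

# Known limitations

* With only 14 minority patients and 110 correlated features, a single null
  (effect 0) dataset can carry chance feature–label structure that is
  genuinely learnable in cross-validation: individual-seed CV AUCs of the
  selected algorithm range roughly 0.45–0.8 while validation AUC stays at
  chance. Null-recovery checks therefore assert 10-seed aggregates, and the
  validation-versus-permutation gap rather than CV AUC alone.
* Random oversampling does not reliably improve the threshold-swept minority
  recall (R\_max) in this synthetic setting: the F\_max sweep already
  compensates for class imbalance, and duplicating 14 minority patients
  makes flexible kernels overfit the copies, mildly degrading out-of-fold
  ranking. The acceptance suite keeps the directional check (R\_max up in
  ≥ 7/10 paired QSVM runs) and it currently fails honestly; studies
  evaluating at a *fixed* threshold, or with different stacks and real
  data, can see the opposite direction.
* Probability calibration on 3 internal folds is noisy for training sets
  under ~20 samples; the monotone fallback guarantees validity but not
  calibration quality.
* The ordinal-score comparator shares no reader-model nuance (two readers,
  consensus); it is a single latent-Gaussian reader.
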