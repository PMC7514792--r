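---
title: "Quality assessment of fundus photographs: models and design choices"
author: "retiqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of fundus photographs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fundus photographs taken in screening programmes are frequently ungradable:
defocus, motion blur and uneven illumination hide the optic disk, the
vascular arcades and the macula. Automated pipelines (and human graders)
need a gatekeeper that decides, before any clinical analysis, whether an
image has adequate quality. `retiqa` implements such a gatekeeper as a
classical feature-based classifier: a preprocessing stage that removes the
aperture border, forty global no-reference quality features, a
correlation-based feature selector, and a small neural network with an
ROC-chosen operating point.

## Preprocessing: FOV location and iterative extension

A fundus image is a bright disk (the field of view, FOV) on a dark
surround. Filters applied naively to such an image respond violently to
the artificial aperture edge, so the package first locates the FOV and
then *extends* it until the canvas has no border at all.

* **Diameter** comes from the intensity profile along the main image
  diagonal: the profile is median-smoothed (window 15) and thresholded at
  10% of its maximum; the distance between the first and last crossings
  estimates the diameter. Estimates outside (0.3, 1.2) of the smaller
  image dimension are rejected as "fov-not-found".
* **Center** comes from a circular Hough transform on a Sobel edge map of
  the red channel, restricted to radii within ±10% of the profile
  estimate. The accumulator maximum fixes center and radius.
* **Extension** dilates the mask one step at a time with a 4-neighborhood
  diamond element; each newly covered pixel takes the mean of its
  8-neighbors already inside the previous mask, independently per RGB
  channel, until the mask covers the whole canvas. Pixels inside the
  original FOV are bit-identical to the input; the output is kept in
  floating point (no re-quantization). The ring-by-ring formulation is
  implemented as a breadth-first traversal in city-block distance order,
  which is exactly the fixed point of the iterative dilation and runs in
  linear time.

## The 40 features

All features are computed on the border-free image; the entropy,
naturalness and wavelet families use the green channel, where retinal
contrast is highest.

### Block entropies (12 features)

The image is analysed at scale factors 1, 1/2 and 1/3 (antialiased Keys
bicubic resampling; output sizes are `round(dim * factor)`, so a
1956×1934 input yields 978×967 and 652×645). At each scale the channel is
tiled into 32×32 blocks from the top-left corner (partial edge blocks are
discarded so every block statistic is computed on the same support).
Per block:

* spatial entropy: Shannon entropy (bits) of the 256-level gray
  histogram, after rounding to integer levels;
* spectral entropy: Shannon entropy of the DC-excluded, power-normalized
  orthonormal 2-D type-II DCT spectrum. A block whose AC power is at
  floating-point noise level is assigned entropy 0.

Within each scale and entropy type the block values are trimmed to the
inclusive [15%, 85%] percentile band (linear-interpolation percentiles)
and pooled by mean and by the biased Fisher–Pearson skewness
g1 = m3 / m2^(3/2) (0 when m2 = 0). Trimming is applied independently per
entropy type. Note that spatial entropy is bounded by 8 bits while
spectral entropy is bounded by log2(M²−1) ≈ 10 bits at M = 32.

### Naturalness distance (1 feature)

The naturalness model follows the natural-scene-statistics approach:
quality degradations disturb the statistics of locally normalized
luminance. The channel is normalized as
(I − μ)/(σ + 1), with μ and σ the 7×7 Gaussian-weighted (sd 7/6) local
mean and deviation. The σ field also drives block selection: 64×64 blocks
whose mean deviation reaches at least T = 0.1 of the maximum are retained
(sharp, structured regions). Each retained block is described by 36
parameters — a zero-mean generalized Gaussian (shape α, spread β) fitted
to the normalized coefficients plus four asymmetric generalized Gaussians
(shape γ, spreads βl, βr, mean η) fitted to horizontal, vertical,
main-diagonal and anti-diagonal neighbor products — at the full scale and
at a bicubic 1/2 scale (the same spatial blocks, halved). Both fits use
standard moment matching with the shape parameter inverted over a
precomputed grid α ∈ [0.2, 10] (step 0.001).

A reference model (ν, Σ) is the mean and sample covariance of the pooled
block parameters of *adequate-quality training images*; the package never
ships a fixed pristine-image model. A test image is summarized by its own
(ν, Σ), and its naturalness index is the Mahalanobis-type distance

    Q = sqrt( (ν_M − ν_I)' ((Σ_M + Σ_I)/2)^[-1] (ν_M − ν_I) ),

with a Moore–Penrose pseudo-inverse (relative cutoff 1e-10) when the
pooled covariance is singular. Identical models give Q = 0; blurrier
images drift away from a sharp reference.

### Wavelet sharpness (18 features)

Edges of vessels and of the optic disk respond strongly to an isotropic
Mexican-hat wavelet; defocus suppresses that response. The channel is
convolved (FFT, reflect padding) with

    Ψ(x, y, s) = 1/(π s⁴) (1 − r²/(2s²)) exp(−r²/(2s²)),

at scales s = 2, 4, 8, 16, 32, 64, chosen to span thin vessels through
the optic disk. Numerical choices: the kernel is sampled on a square
support of half-width ceil(3.5 s) and its (tiny) truncation-induced mean
is subtracted, so the discrete kernel sums *exactly* to zero — a constant
image provokes a strictly zero response and no DC leaks into the
features. The truncation radius keeps the largest kernel at 449² samples
and the FFT grids at ≈ 900², which is what makes a 200-image study
tractable on one CPU; the clipped rim is below ~1% of the kernel peak and
identical for every image, so comparative features are unaffected. The
overall normalization constant of the transform is set to 1 (it rescales
all coefficients uniformly and cancels in any comparison).

Per scale the package computes

* the Shannon entropy of the coefficients inside the FOV (256 equal-width
  bins spanning the observed range; a numerically constant map has
  entropy 0), and
* the mean and the sample standard deviation (divisor N − 1, N = FOV
  pixel count) of the local-deviation map obtained with a circular
  standard-deviation filter of radius s (window = pixel centers within
  distance s; windows clipped at the canvas edge use the available pixels
  only; within-window divisor n − 1).

### Luminosity (9 features)

Illumination problems live in the HSV value channel
V = max(R, G, B)/255. V is denoised with an exact 5×5 median filter, then
convolved with a wide normalized Gaussian (σ = 19 px, support truncated
at ±⌊4σ⌋ = ±76, reflect padding) that suppresses vessels and small dark
lesions, leaving the illumination field B. The features are the 1%, 5%,
10%, 15% and 20% percentiles of B over the FOV (linear interpolation,
restricted to the FOV so the extended surround cannot bias the dark
percentiles) plus the four consecutive differences, which capture how
steeply the background brightens away from its darkest zones.

## Feature selection: bootstrap-stabilised FCBF

The fast correlation-based filter scores every feature by symmetrical
uncertainty with the class label,
SU(X, Y) = 2(H(X) − H(X|Y))/(H(X) + H(Y)) (base-2 entropies), ranks the
features by relevance (zero-relevance features are dropped; ties break by
column order) and removes any feature Xm predominated by an
earlier-ranked Xn, i.e. SU(Xm, Xn) ≥ SU(Xm, C). Since SU needs discrete
variables, features are rank-binned into 10 equal-frequency levels —
deterministic and invariant to monotone rescaling.

A single FCBF run is sensitive to the particular training sample, so it
is repeated on 1000 bootstrap replicates (uniform resampling with
replacement to the original size); features selected in at least 500
replicates form the final subset. Per-replicate seeds are spawned from
one master seed with a prefix-stable stream, making the procedure
reproducible and the per-feature counts monotone in the number of
replicates.

One failure mode deserves mention. When a dataset is strongly separable
through many mutually redundant features — the regime the synthetic
generator creates, where spectral-entropy means at several scales,
wavelet responses and luminosity percentiles all track the same two
degradation axes — each replicate keeps a *different* single
representative of the redundant group, votes split, and no feature
reaches the half-of-replicates threshold. The full pipeline then falls
back to a single FCBF run on the complete training set, which returns
the canonical representative of each group. On heterogeneous real data
with weaker features (the setting the bootstrap is meant to stabilise)
the threshold behaves as intended.

## Classifier: SMOTE-balanced MLP with an ROC threshold

Adequate images dominate clinical databases (≈ 86%), so before training,
the minority class is augmented with SMOTE: each minority sample u
contributes one synthetic point w = u + c(v − u), c ~ U(0, 1), on the
segment to each of its k = 5 nearest minority neighbors — exactly 5
synthetics per sample (148 minority samples produce 740 synthetics, a
minority total of 888). Features are standardized with training-set
statistics *before* SMOTE so the nearest-neighbor distances are
meaningful.

The classifier is a three-layer perceptron: selected features → tanh
hidden layer → one logistic output, trained by BFGS on the convex blend

    E = (1 − η) · CE + η · mean(w²),

where CE is the cross-entropy and the decay term averages the squared
non-bias weights. The blend makes the regularization weight η ∈ [0, 1)
directly interpretable as the fraction of the objective spent on weight
decay, which matches the hyper-parameter grid (η = 0 … 0.9 in steps of
0.1, hidden widths 1 … 100 in the full design). Hyper-parameters are
chosen by stratified 10-fold cross-validation with SMOTE applied inside
each training fold only — applying it before splitting would leak
synthetic copies of validation points into training. Training from a
seeded initialization is deterministic; the loss is recorded at optimizer
checkpoints and is non-increasing.

The operating threshold is the point of the training ROC curve (computed
on the SMOTE-augmented training set, the same data the network was fit
on) closest to the ideal corner (0, 1); candidate thresholds are
midpoints between consecutive unique scores, so a separable training set
yields the midpoint between the class score extremes. The decision rule
is strict: adequate ⇔ score > threshold; ties count negative. Evaluation
reports sensitivity, specificity, accuracy, positive predictive value,
F-score (displayed with half-up rounding to 2 decimals) and the
trapezoidal AUC of the threshold-swept ROC.

## The synthetic generator

The package validates the pipeline end to end on synthetic fundus scenes
because clinical databases cannot be redistributed. Each scene is a
bright circular aperture (radius 205 px on a 450×450 canvas) on a
near-black surround containing: a mildly mottled retina background, a
bright Gaussian optic-disk blob displaced horizontally from the center, a
darker macular blob on the opposite side, and vessel-like random-walk
polylines radiating from the disk, 20–40% darker than their surround.
Two degradation axes define ground truth, mirroring the dominant clinical
failure modes: defocus (Gaussian blur of σ px) and vignetting
(multiplicative falloff 1 − strength · (r/R)²). An image is adequate iff
blur ≤ 2 px and vignetting ≤ 0.4. Adequate images draw mild severities
(blur U(0, 1.5), vignetting U(0, 0.3)); inadequate images are clearly
degraded along one or both axes (blur U(3, 6), vignetting U(0.55, 0.9)),
as clinically rejected captures typically are; sensor noise is additive
Gaussian (σ ∈ [1, 3] gray levels). The default class balance is 86%
adequate. All randomness flows from one master seed through per-image
seeds recorded in a manifest, so every fixture is reconstructible.

The canvas size is the package's study size: it is the smallest geometry
that accommodates the s = 64 wavelet kernel with margin, and it keeps a
200-image study (the size used by the test suite and the acceptance
script, split 50/50 into training and held-out halves, with the
hyper-parameter grid restricted to widths {5, 10, 21} × η {0, 0.1})
within a desktop-scale compute budget.

What the generator does *not* emulate — pathology (lesions, hemorrhages),
camera color profiles, JPEG artifacts, interlacing eyelashes or dust —
bounds what a passing test suite shows: the pipeline discriminates the
two modeled degradation axes on images with fundus-like geometry; it is
not evidence of clinical-grade performance on real photographs.

## Degenerate inputs and numerical conventions

* Percentiles everywhere are linear-interpolation order statistics
  (`type = 7`); trimming bounds are inclusive.
* Reflect (mirror-without-repeat) padding for every spatial filter;
  circular-window filters at the canvas edge instead shrink to the
  available pixels.
* Constant blocks: spatial and spectral entropy 0; GGD/AGGD fits on
  all-zero or single-signed samples raise degenerate-input errors rather
  than returning arbitrary parameters. During block characterization,
  retained blocks whose coefficients are too flat for the fits (e.g.
  clipped-to-black regions of a heavily vignetted image) are dropped —
  they carry no natural-scene statistics; an image errors only when no
  usable block remains.
* The naturalness distance clamps tiny negative quadratic forms (from
  finite-precision pseudo-inverses) to zero.
* Confusion metrics with empty denominators return NA, never a silent
  zero.
* Skewness of a zero-variance pool is 0 by convention.

## Limitations

* The feature set is global; a locally blurred but mostly sharp image can
  sit on either side of the boundary, which is also the dominant error
  mode reported for feature-based quality gatekeepers in the literature.
* The Hough center search assumes a mostly circular, mostly centered
  aperture; heavily cropped FOVs would need a generalized search.
* The reference naturalness model must be retrained for a new camera or
  resolution; serialized models record the block parameters (P, T) to
  make stale reuse detectable.
* Synthetic validation bounds, not establishes, clinical performance (see
  above).
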