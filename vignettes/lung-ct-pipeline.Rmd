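---
title: "Methods: the lungscreen detection and risk-screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lungscreen detection and risk-screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungscreen)
```

lungscreen implements a lightweight lung-CT early-detection chain: denoise a
slice, find the lung fields, segment bright in-lung structure, extract and
filter nodule candidates, screen patients with a logistic risk model, and
classify candidate patches with a small semi-supervised contrastive network.
Every stage is exercised offline against a seeded synthetic chest phantom
with ground truth, so the package needs no clinical data to be tested.

This vignette explains the model choices, the tunable parameters, what the
phantom does and does not emulate, and the numerical decisions a maintainer
would want written down.

## 1. RWICWM denoising

The Ricker Wavelet Iterative Center-Weighted Median filter works in an
undecimated (à-trous) band-pass domain:

* **Decomposition.** Detail band $j$ is the convolution of the image with a
  discrete Mexican-hat (Ricker) kernel realized as the difference of
  adjacent dyadic Gaussians $G_{j-1}-G_j$ (with $G_0$ the delta and
  $\sigma_j = 2^{j-1}$ pixels). The kernels are exactly zero-sum, every band
  has the image's shape, and the kernels telescope, so
  `approx + sum(details)` reconstructs the image to machine precision
  (tested at $10^{-9}$). Three scales (`n_scales = 3`) cover structure from
  1 to 4 px, which brackets vessel and small-nodule detail at typical ~1 mm
  pixel spacing.
* **Variance field.** Each band's local variance is estimated in a 5 px
  window and smoothed by an iterative center-weighted median (CWM) filter —
  a median in which the center sample is replicated `center_weight = 3`
  times, biasing the filter toward the original value and preserving
  variance ridges at edges. Iteration stops when the maximum relative change
  drops below `tol = 1e-3` or after `max_iters = 10` passes. Inter-scale
  dependence is applied by averaging each band's smoothed variance with its
  parent (next-coarser) band's, weight 0.5: true edges are present across
  scales, isolated noise spikes are not.
* **Shrinkage.** Every coefficient is scaled by the Wiener-style gain
  $v/(v+\sigma_n^2)$, where $v$ is the noise-corrected signal variance
  $\max(\hat v - \sigma_n^2, 0)$ from the smoothed field and $\sigma_n$ is a
  robust global noise scale: the median absolute deviation of the finest
  band divided by 0.6745, propagated to coarser bands through the band
  kernels' $L_2$ norms. Flat regions shrink to the coarse smooth; edges,
  whose local variance is far above $\sigma_n^2$, pass nearly unchanged.

On the phantom at 10–25 HU Gaussian noise this gains 6–7 dB of
display-window PSNR over the noisy input and beats a Gaussian filter
matched to equal flat-region smoothing by an order of magnitude in
mean absolute error near edges (both are tested properties).

Baselines (Gaussian, local Wiener, guided filter) are provided for
comparison; histogram equalization implements the classic CDF remapping on
the 8-bit rescaled image and is used for display contrast. The denoise →
equalize order is fixed: equalization amplifies noise inside large
near-uniform regions, so it must run on the already-denoised image, and all
detection arithmetic below operates on calibrated HU intensities, not on
display values. For the same reason the "inverse log" display tone curve is
off by default and display windowing (default lung window, center −600 HU,
width 1500 HU) is kept strictly out of the analysis path.

## 2. Dice K-means segmentation

The Sørensen–Dice index is implemented in its three standard forms — set
cardinalities $2|X\cap Y|/(|X|+|Y|)$, confusion counts $2TP/(2TP+FP+FN)$,
and the soft vector form $2\,a\cdot b/(\lVert a\rVert^2+\lVert b\rVert^2)$ —
which coincide on binary inputs (property-tested). The clustering uses the
soft form on per-pixel neighborhood intensity vectors (radius 1, a 3×3
patch, intensities normalized to $[0,1]$): this keeps the set-overlap
statistic literal while giving it gray-value meaning.

Design choices where the method is genuinely open:

* **Centroid update.** The mean of assigned features. The soft-Dice
  similarity has no closed-form optimal centroid; the mean is the obvious
  surrogate but is not guaranteed monotone, so an update is only accepted
  while the mean assigned similarity does not decrease — the objective
  trace is non-decreasing by construction and the algorithm stops at the
  first non-improving update.
* **Initialization.** k-means++-style seeding in similarity space with a
  seeded RNG; assignment ties break toward the lowest cluster index, making
  runs bit-reproducible.
* **k = 2** by default: foreground (bright nodule-region class) vs
  background. `foreground_mask` selects the cluster with the highest mean
  intensity inside the lung as label 1.

Within the pipeline the clustering runs on the denoised image with non-lung
pixels set to the in-lung median. Clustering the raw slice instead makes
k = 2 split air from body — correct but useless for nodule foregrounds;
restricting the intensity structure to the lung makes the bright cluster the
nodule-region class.

## 3. WDSI-LSO candidate detection

* **Parenchyma.** A sliding window (16 px, stride 8) accepts windows whose
  mean lies in (−950, −500) HU *and* at least 60% of whose pixels do
  individually; the coverage test rejects chest-wall boundary windows whose
  air/soft-tissue mix merely averages into the band. The union is cleaned to
  the two largest components, each component's convex hull is filled, and
  holes are closed. The convex fill matters: a large solid nodule is
  rejected by the window test and, near the lung border, carves a bay that
  topological hole-filling cannot close; the phantom's lung fields are
  elliptical, hence convex, so the fill is exact there. On real anatomy it
  mildly over-includes the concave medial border — a documented limitation.
* **Thresholding objective.** Otsu's between-class variance
  $\sum_c \omega_c(\mu_c-\mu)^2$ over the classes induced by the threshold
  vector, computed on a 128-bin histogram of in-lung intensities. Empty
  classes contribute zero.
* **Light Spectrum Optimizer.** A population of threshold vectors (20
  individuals, 100 iterations) evolved by three light-spectrum-style
  operators — refraction toward the incumbent best, dispersion around the
  population mean, and reflection (random restart) — with *every* stochastic
  step size multiplied by a fresh Weibull-distributed scale factor
  (inverse-transform draws $\lambda(-\ln U)^{1/k}$, defaults
  $k = 1.5, \lambda = 1$). Selection is greedy per individual with global
  elitism, so the best-objective trace is non-decreasing. Correctness is
  defined against exhaustive search: on 64-bin histograms with 2 thresholds
  the optimizer reaches within 1% of the exact optimum on at least 18 of 20
  seeds (it reached 20/20 in the shipped runs).
* **ROIs and features.** Each intensity class above the lowest threshold is
  labelled separately (8-connectivity in 2D, 26 in 3D) so vessels, nodules
  and soft tissue remain distinct regions; a 2 px-radius morphological
  opening removes vessel-width structure before labelling in the detection
  wrapper. Regions that touch the lung mask are kept at full extent and
  measured: area (mm²), volume (mm³, 0 in 2D), elongation (square root of
  the second-moment eigenvalue ratio, with the pixel-extent term $s^2/12$
  added per axis so a single pixel scores exactly 1), overlap (fraction of
  the region inside the lung — the juxtapleural filter), mean intensity and
  a solidity flag (mean ≥ −300 HU).
* **Filtering.** Defaults accept areas between the disc areas of 3 mm and
  30 mm diameters (the pulmonary-nodule size range), elongation ≤ 3, and
  overlap ≥ 0.5; survivors are ranked by the compactness score
  overlap/elongation.

Under these defaults the 50-phantom recovery study (diameters 6–20 mm,
σ = 15 HU noise) reaches sensitivity 1.0 at 0.24 false candidates per slice
in the shipped run; the tested bars are ≥ 0.9 and ≤ 2.

## 4. Risk screening

Risk is a configurable logistic model in the shape of PLCOm2012:
$\operatorname{logit}(p) = \beta_0 + \sum_j \beta_j T_j(x_j)$ with
transforms from {linear, centered, log, indicator}. Published coefficient
sets are user-supplied configuration; the shipped
`example_risk_coefficients.yaml` is synthetic and illustrative only.
Screening is triggered by the presence of at least one *solid* candidate;
untriggered patients keep their computed probability but are always
stratified low. The default cut-off 0.0151 is a conventional screening
threshold choice, configurable. The "survival" summary reported by the
pipeline is simply the cohort fraction stratified low — the package fits no
survival-time model.

The synthetic cohort draws age uniform on 55–74 years (the usual screening
window), log-normal smoking intensity (median 20 cigarettes/day, log-sd
0.4) for ever-smokers, and Bernoulli comorbidity histories; latent risks are
computed by `risk_probability` itself, so strata recovery is exact by
construction and is tested as such. The coefficient-recovery study refits
with `stats::glm` on Bernoulli outcomes at $n = 10^4$; it uses a dedicated
three-term design (age, intensity, COPD, intercept −1.8) because the full
example set is deliberately collinear (smoking indicators vs
intensity/duration) and not identifiable at that sample size — a property of
the design, not of the fitting code.

## 5. The SSCL classifier

A small, fully hand-written network: two 3×3 convolution blocks (8 channels
each) with logistic activations, 2×2 max-pooling, a residual fully-connected
layer `full = sigmoid(f W + b) + f`, a softmax head, and a linear projection
head normalized to the unit sphere. Patch intensities are centered to
$[-0.5, 0.5]$ before the first convolution — with uncentered inputs the
logistic pre-activations saturate and training stalls on a sizeable
fraction of initializations. Training minimizes
`CE + 0.5 * triplet + 0.5 * pseudo-CE` with Adam (lr 0.01), single-threaded
and fully seeded (same config + seed gives identical weights; tested).

* **Views.** Weak = flip/translate ≤ 2 px; strong = weak + rotation ≤ 15°,
  ±10% intensity jitter, one 8×8 cutout. The triplet term uses strong views
  as anchors, the same sample's weak view as positive and a
  different-class weak view as negative, with margin 0.5 on Euclidean
  distances between unit projections. The loss is
  $\max(0, d_{AP} - d_{AN} + m)$ — zero when the negative is at least the
  margin farther than the positive; the occasionally-seen opposite sign
  ordering is inconsistent with that zero-loss behaviour and is not used.
* **Pseudo-labels.** After a 5-epoch warmup, unlabeled embeddings are
  labelled by the nearest class prototype (cosine similarity, softmax
  temperature 0.1) and accepted at confidence ≥ 0.9; accepted samples
  contribute a cross-entropy term. With the contrastive weight at zero and
  no unlabeled data the loop reduces exactly to supervised training
  (tested as an identity at epoch 1).
* **Label sets.** The default 3-class scheme is
  normal / large-cell carcinoma / squamous cell carcinoma; alternative
  schemes are plain configuration. `classify` flags Abnormal whenever the
  argmax class is not the configured normal class.

The tested bar is an overfit sanity run: 60 phantom patches, 30 epochs,
train accuracy ≥ 0.95 — evidence the optimization works, *not* evidence of
clinical discrimination.

## 6. Metrics

MSE, PSNR ($10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$, infinite at zero
error; the squared form is used throughout since MAX is a pixel value, 255
for 8-bit), and mean local SSIM with the standard Gaussian 11×11, σ = 1.5
window and $C_i = (k_i\,\mathrm{MAX})^2$, $k_1 = 0.01$, $k_2 = 0.03$.
Confusion matrices and accuracy/recall/precision follow the usual
definitions with typed errors on empty denominators; percentages are
reported to one decimal. The published evaluation counts (TP = TN = 436,
FP = FN = 8 for detection; 430/430/14/14 for risk) round to 98.2% and 96.8%
under these formulas, which the acceptance script recomputes.

## 7. What the phantom emulates — and what it does not

The generator draws two elliptical lung fields (−850 HU) in a soft-tissue
body (+40 HU) on air (−1000 HU), vessel-like bright segments (−100 HU)
confined to the lungs, and rasterized disc nodules (≤ 30 mm, default
+30 HU) with exact truth masks; noise is additive Gaussian, then
multiplicative speckle, then salt-and-pepper, all seeded. 3D volumes are
stacks of such slices.

It does **not** emulate airway trees, fissures, beam hardening, sinogram
noise, ground-glass (sub-solid) nodules, or concave lung borders. Passing
tests therefore demonstrate algorithmic correctness and calibrated behaviour
under controlled contrast ordering — not clinical performance. Two
deliberate consequences: the recovery study places nodules fully inside a
lung (juxtapleural lesions merge with the chest wall under any
threshold-based scheme and are out of scope), and the convex lung fill is
exact only because the phantom lungs are convex.

## 8. Problem sizes and degenerate inputs

The shipped studies use 256×256 slices, 50 phantoms for detection, 20
histograms for the optimizer oracle, $10^4$ rows for coefficient recovery
and 60 patches for the classifier — sizes chosen so the whole suite runs on
a laptop-class single core in a few minutes while keeping every estimate's
Monte-Carlo error far from its test margin.

Degenerate inputs are handled by contract, not silently: constant images
equalize to themselves with a warning and refuse to cluster (fewer distinct
features than clusters); empty lung masks label zero ROIs with a warning;
two empty sets have Dice 1 by definition (logged) while all-zero confusion
counts are errors; readers reject empty directories and unreadable files
with typed conditions. All randomness flows through explicit seeds, and
generators save and restore the caller's RNG state.
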