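---
title: "Explainable 3-D segmentation of multi-parametric MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable 3-D segmentation of multi-parametric MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

segxai is a toolkit for studying *why* a volumetric segmentation network
makes its predictions, built around prostate multi-parametric MRI (mpMRI).
It chains five pieces: a synthetic phantom generator, the mono-exponential
diffusion signal model, a patch-based 3-D U-Net, segmentation Grad-CAM heat
maps, and two families of quantitative checks on those heat maps
(localization IOU, and randomization sanity checks scored by normalized
mutual information and SSIM). This vignette documents the models, the
tunable parameters and the design decisions; the package's tests and the
acceptance script compute every empirical number referred to here.

## The diffusion signal model

Diffusion-weighted MRI signal under mono-exponential decay is

$$S(b) = S_0 \, e^{-b \cdot \mathrm{ADC}},$$

with the b-value in s/mm² and the apparent diffusion coefficient (ADC) in
mm²/s. `fit_adc()` estimates ADC and $S_0$ per voxel by ordinary least
squares of $\log S$ on $b$ — closed-form, deterministic, and the standard
choice when only 2–4 b-values are available. Voxels with any signal at or
below `min_signal` (default `1e-6`) are excluded from the valid mask, since
their logarithm is undefined; they receive ADC = 0, $S_0$ = 0. The log-domain
fit is unweighted, which is a known limitation at low SNR: the noisiest
(high-b) points carry the same weight as the b = 0 point.

`synthesize_high_b()` extrapolates the fitted model to an unacquired
diffusion weighting; b = 1400 s/mm² is the conventional high-b target for
prostate imaging and the default. On a noiseless forward-simulated series
the fit recovers the generating ADC and $S_0$ to near machine precision
(the round-trip test asserts relative error below $10^{-8}$).

### Noise conventions

`generate_dwi_series()` adds Gaussian noise scaled either to the local
noiseless signal of each b-volume (`sigma_mode = "relative"`, the default)
or to the local $S_0$ (`"absolute"`, a constant thermal-noise floor across
b-values, which is how receiver noise actually behaves). The relative mode
is the default because it keeps a single `noise_sigma` meaningful across the
whole decay curve and matches the phantom generator's definition of noise as
a fraction of the local tissue mean. The distinction matters for accuracy
statements: with 5% relative noise at b = (0, 400, 800), the median relative
ADC error over a phantom is about 3–4%; with a constant 5%-of-$S_0$ floor the
information content of the high-b points is so much lower that no estimator
can reach a 5% median error at typical tissue ADCs (a Cramér–Rao argument
puts the floor near 7–8%). The tests therefore exercise the relative mode.

## The phantom generator

There is no public accession for co-registered mpMRI with whole-mount
histology ground truth, so every stage is exercised on synthetic phantoms.
`generate_phantom()` builds a three-channel volume:

* an ellipsoidal **gland** with randomly jittered center and axial
  orientation, semiaxes drawn from 12–18 mm;
* zero or more ellipsoidal **lesions** (default 1–2, semiaxes 3–6 mm)
  placed fully inside the gland by rejection sampling (bounded retries, an
  explicit error naming the constraint on failure);
* per-tissue parameter fields — T2-like intensity, ADC, $S_0$ — smoothed at
  tissue borders (Gaussian, $\sigma$ = 1 voxel by default) so interfaces are
  not voxel-sharp;
* channels: the T2-like map (lesion hypointense relative to gland), the ADC
  map, and a synthetic b = 1400 s/mm² image computed through the forward
  model above; Gaussian noise is added per channel as a fraction
  (`noise_sigma`, default 5%) of the local tissue mean.

The default tissue parameters (ADC 2.0/1.4/0.7 × 10⁻³ mm²/s and relative
T2 and $S_0$ levels for background/gland/lesion) are plausibility choices in
the range reported for prostate tissue, not measurements; they are fully
config-overridable. Lesion count and size distributions are likewise
arbitrary defaults, since clinical cohorts vary widely. The default grid is
64 × 64 × 16 voxels at 0.78 × 0.78 × 3 mm — one training patch — so a
phantom is the field of view a cropped, resampled clinical volume would
present to the network.

Two tumor ground truths are produced. The lesion mask itself plays the role
of a radiologist-drawn contour; a second mask is derived from it by warping
with a smooth random displacement field (Gaussian-smoothed white noise,
mean magnitude 2 mm by default), emulating the non-rigid discrepancy between
MRI contours and histology contours transferred from a resected, deformed
specimen. The two masks overlap but are not equal, which is exactly the
property needed to exercise dual-ground-truth evaluation. The deformation
emulates the *effect* of registration error, not the mechanics of
registration itself.

What the phantom deliberately does not model: zonal anatomy, bias fields,
Rician noise statistics at very low SNR, field-strength heterogeneity,
benign confounders (hyperplasia, bleeding). Passing tests on phantoms
therefore demonstrates that the machinery is correct and sensitive — not
that the network would reach clinical-grade accuracy on patients, where
reported tumor Dice values are far lower.

## Preprocessing and patch sampling

`crop_to_roi()` restricts volumes to the gland bounding box plus a margin;
`resample()` interpolates images trilinearly and labels by nearest neighbour
to a target spacing (default 0.78 × 0.78 × 3 mm; output shape is the ceiling
of physical extent over target spacing). `sample_patch()` draws the class of
the patch-center voxel from configurable probabilities — default ⅓ each for
background, gland, tumor, countering class imbalance — then picks a uniform
voxel of that class; patches are zero-padded at grid borders so shapes are
always exactly `patch_size` (default 64 × 64 × 16). Classes absent from a
volume are renormalized away. `augment_rotation()` applies, with probability
0.70, a single uniformly drawn in-plane rotation to image and labels through
the identical spatial map (image trilinear, labels nearest neighbour). The
angle distribution is uniform on [0°, 360°), a choice the data protocol
leaves open.

## The 3-D U-Net

`unet_build()` instantiates a three-level encoder–decoder: per block
`convs_per_block` (default 2) 3×3×3 convolutions with stride 1, padding 1,
each followed by batch normalization and ReLU; 2×2×2 max pooling between
encoder blocks; 2×2×2 stride-2 transposed convolutions with skip
concatenation in the decoder; and a 1×1×1 convolution head with batch
normalization whose output is the pre-softmax class score used by Grad-CAM.
The transposed convolution uses padding 0 — the only setting that yields the
exact ×2 upsampling required for skip concatenation. Desk-scale defaults are
8 base channels (doubling per level) and, in `train_config()`, 25 epochs of
12 patches; the clinical-scale setting (150 epochs) remains reachable by
configuration.

Choices the architecture description leaves open and how they are resolved
here: optimizer Adam (the protocol names only the learning rate, 0.001);
loss class-weighted cross-entropy with median-frequency weights computed
from the training labels (capped at 10); batch size 1, with batch-norm
statistics over the patch's voxels and running statistics
(exponential moving average, momentum 0.1) for inference; per-channel
z-scoring of each input volume. Inference uses running statistics, so
prediction is deterministic and independent of batch composition;
`predict()` zero-pads grids to multiples of 8 and crops back.

The network is implemented inside the package (base R plus two compiled
kernels that evaluate the 3×3×3 convolution and its adjoints as 27
offset-wise BLAS products). This keeps the full computation graph open to
the explainability modules: the forward pass caches every block's
post-activation feature maps, and reverse-mode backward returns gradients
with respect to every block output — the capture contract Grad-CAM and the
randomization tests are built on. All gradients are verified against central
finite differences in the test suite.

## Segmentation Grad-CAM

For a chosen class $c$, feature maps $A^k$ of a chosen block (default `D3`,
the last decoder convolution block), and a voxel set ʍ (the *score mask*),
the method computes the scalar score as the arithmetic mean of the
pre-softmax class score over ʍ, its gradients

$$G^{c,k} = \frac{\partial\, \overline{y^c}(ʍ)}{\partial A^k},$$

global-average-pools them over all $N$ feature-grid voxels into kernel
weights $\omega^{c,k} = \frac{1}{N}\sum_x G^{c,k}(x)$, and forms

$$H^c = \mathrm{ReLU}\Big(\sum_k \omega^{c,k} A^k\Big),$$

optionally upsampled trilinearly to the input grid and min–max normalized.
Gradients are pooled raw (no rectification before pooling): this is plain
Grad-CAM generalized to segmentation, not Grad-CAM++.

Two decisions deserve emphasis. First, the mask-averaged score: averaging
the class score over a voxel set is implemented as the plain arithmetic
mean — the natural reading of "averaging the class score for a set of voxels
in the output segmentation mask" — and is exposed directly as
`mask_averaged_score()`. Second, the default ʍ is the network's **own
predicted mask** for the class, so that an explanation does not presuppose
ground truth; a ground-truth mode exists for evaluation studies, plus
whole-volume and custom modes. A constant (all-negative-weight) heat map is
valid output, not an error; min–max normalization maps it to all zeros.
On a degenerate 1×1×1 grid with whole-volume ʍ the construction reduces to
classification Grad-CAM, which the tests verify against a closed-form
oracle.

## Heat-map evaluation

`threshold_heatmap()` binarizes a normalized heat map at δ with a strict
`>`. The strictness matters at δ = 0: a ReLU heat map is exactly zero
outside its support, and a non-strict threshold would select the entire
volume, making the δ = 0 row of any localization table a trivial volume
ratio. `localization_iou()` then scores
$\mathrm{Loc}^c(\delta) = |L^c(\delta) \cap y^c_{Gt}| \,/\, |L^c(\delta) \cup y^c_{Gt}|$,
with an empty union scoring 0; `localization_curve()` applies a δ grid,
default {0, 0.25, 0.5}. Dice is $2|A\cap B|/(|A|+|B|)$ with the
both-empty case defined as 1 (correctly predicting absence is perfect
agreement); Dice and IOU are linked by $D = 2\,\mathrm{IOU}/(1+\mathrm{IOU})$,
asserted on random masks in the tests. Gland Dice is computed against the
full gland mask with predicted classes {gland, tumor} pooled, because a
whole-gland contour contains the tumor while the softmax class map is
exclusive.

## Randomization sanity checks

A faithful saliency method must be sensitive to the learned weights. The
**model randomization test** compares heat maps from the trained network
with heat maps from a freshly initialized copy; the **cascaded
randomization test** randomizes blocks stage by stage (default order BL, D1,
D2, D3, E1, E2, E3, bracketed by TN = trained and RN = all-random stages),
in an independent (one block at a time) or cumulative variant — both are
provided because "cascading" randomization appears in both forms in the
sanity-check literature. Randomizing a block re-draws its convolution
weights from the initialization distribution, zeroes biases, and resets
batch-norm affine parameters and running statistics to the untrained
identity; a distribution test asserts that no trained weight leaks into a
randomized stage.

Comparisons are scored by symmetric normalized mutual information,
$2I(A;B)/(H(A)+H(B))$ from a 64-bin joint histogram (a constant map has zero
entropy and scores 0 by convention), and by mean local SSIM with a 3-D
Gaussian window (σ = 1.5 voxels, radius 5, stabilization constants
K1 = 0.01, K2 = 0.03, unit data range). Local SSIM statistics use normalized
convolution — border windows are renormalized over their in-grid support —
so self-comparison is exactly 1. Throughout the randomization tests the
score mask is frozen to the trained network's predicted mask, so that the
comparison isolates weight sensitivity instead of confounding it with
changes in the predicted mask itself; this is configurable.

## Problem sizes, tolerances, degenerate inputs

The package's own studies run at desk scale on one CPU: 40 training and 10
held-out phantoms of 64 × 64 × 16 voxels, base width 8, 25 epochs × 12
patches (about six minutes of training), and 5 cases for the randomization
checks. At these sizes the trained network reaches mean gland Dice around
0.9 and tumor Dice around 0.7–0.85 on held-out phantoms, tumor-class
Loc(δ = 0.5) around 0.6–0.7 versus near 0 for an untrained network, and
trained-versus-random MI/SSIM far below the self-comparison value of 1 —
the qualitative signatures expected of a working, weight-sensitive
explanation pipeline. Numerical tolerances: noiseless round trips are
asserted at 10⁻⁸ relative error, analytic gradients at 10⁻³ against central
finite differences (they agree to ~10⁻¹⁰ in double precision), metric
identities at 10⁻¹².

Degenerate inputs are first-class: zero-lesion phantoms (empty tumor mask,
two-class label map), empty score masks (an error that names the
whole-volume fallback), constant heat maps (MI 0 by convention, all-zero
normalized map), fits where every voxel is invalid (empty valid mask plus a
warning, not an exception), and grids not divisible by 8 (padded and
cropped transparently in prediction, a hard error in the raw forward pass).

## Known limitations

* The log-linear ADC fit is unweighted; a noise-aware weighted or nonlinear
  fit would be more efficient at low SNR.
* Gaussian rather than Rician noise; acceptable at moderate SNR, wrong in
  the air background of real magnitude images.
* The phantom's geometric simplicity means segmentation performance on it
  vastly overstates clinical performance; it is a correctness instrument,
  not a benchmark.
* Batch size is fixed at 1; batch-norm statistics are per-patch, which is
  closer to instance normalization during training.
* Heat maps are computed for one class and one block per call; multi-block
  aggregation is left to the caller.
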