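---
title: "Benchmarking MRI-guided synthetic CT for PET attenuation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking MRI-guided synthetic CT for PET attenuation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sctpet)
```

## The problem

PET attenuation correction (AC) needs a map of 511 keV linear attenuation
coefficients (mu, cm^-1). PET/CT derives it from the CT; PET/MRI has no CT,
so a synthetic CT (sCT) must be estimated from MR images. In-phase Dixon MR
is the usual input, and its core ambiguity drives everything that follows:
bone and air are both nearly signal-free, while they sit at opposite ends of
the attenuation scale. `sctpet` implements the three families of sCT
generation in clinical use and propagates each through a PET simulator so
that attenuation-map errors become measurable uptake (SUV) bias:

* **Segmentation (three-class)**: body contour and lung segmentation on the
  MR, then fixed class values -- soft tissue 0 HU / 0.096 cm^-1, background
  air -1000 HU / 0 cm^-1, lung -770 HU / 0.022 cm^-1. No bone class exists,
  and the lung coefficient is a population constant: those are its two
  systematic error sources.
* **Multi-atlas fusion**: co-registered MR-CT pairs are deformed onto the
  target MR; a bone map is voted voxel-wise; each atlas is weighted at each
  voxel by a product of Gaussian kernels on the signed-distance discrepancy
  to the voted bone map and on the local mean absolute phase-congruency
  difference; the sCT is the resulting convex combination of mapped CTs.
* **Deep learning**: a residual dilated CNN regresses CT from MR slice-wise
  (three blocks at dilations 1/2/4, batch normalization and ReLU, residual
  connections between equal-shape layer pairs, L2 loss, Adam).

Each candidate mu-map, plus the reference CT-derived map, feeds an
attenuated 2D parallel-beam projector and OSEM reconstruction (4 iterations,
8 subsets). Bias is `100 * (PET_sCT - PET_CT) / PET_CT` over voxels where
the reference exceeds 0.05 SUV, summarised per tissue (soft [-400, 160] HU,
bone > 160 HU, lungs from truth masks) and per lesion VOI, with paired
t-tests between arms at 0.05.

## The digital torso phantom

Everything runs on generated data, so the full pipeline is testable without
any download. A phantom is a stack of independent transaxial slices on a
64-128 voxel grid (2-4 mm in-plane) holding co-registered tissue labels, CT
(HU), in-phase-like MR, an FDG-like activity map and named organ masks.
Design choices that matter:

* **Geometry**: torso ellipse (88 x 62 mm semi-axes), two lateral arms, two
  lungs, spine with marrow core, ribs/scapulae/sternum cross-sections and a
  peripheral fat layer. Axes and lung centres jitter per subject (5
  percent SD); slices taper mildly along z.
* **MR contrast**: class means put fat (0.78) and soft tissue (0.55) bright,
  lung (0.17) dark, bone (0.10) and air (0.03) darkest -- the in-phase
  ambiguity. The MR is corrupted by a multiplicative exponentiated
  quadratic bias field (20 percent peak by default) and additive Gaussian
  noise, so the N4-style correction has something real to remove.
* **Per-subject tissue density**: each subject draws its own mean HU per
  class (lung SD 55 HU, bone 50, fat 10, soft 8). Lung density is coupled
  to lung MR signal through a proton-density slope (denser lung = brighter
  in-phase signal). This is the mechanism that separates the methods:
  image-based methods can in principle follow a patient's lung density,
  while the fixed lung coefficient of the three-class map cannot.
* **Lung volume variability**: each lung can additionally draw a size scale
  (off by default; the DL training cohort uses 0.25-1.15, and doubles the
  density jitter so dense, consolidated lungs are in-distribution). A
  network trained only on one canonical anatomy learns a positional "a
  lung lives here" prior that overrides image evidence exactly where the
  abnormal-anatomy scenarios need it to adapt; wide lung-volume and
  lung-density variability in the training cohort -- as in any clinical
  population -- forces it to follow the image instead. The
  histogram-matching reference is a canonical evaluation-anatomy subject,
  never a member of the widened training cohort, so the matched intensity
  scale is common to training and evaluation.
* **Activity**: soft 1.0, lung 0.3, bone 0.8, lesion 4.0 (arbitrary units);
  the bias metric is scale-invariant, so only contrast matters.

Four corruptions reproduce the canonical outlier cases: lateral MR
truncation (MR blanked outside a reduced transaxial FOV; CT and activity
untouched), a metal implant (3000 HU sphere) with a much larger MR
susceptibility void, pneumonectomy (one lung relabelled to soft tissue;
the remaining lung consolidated to -550 HU with correspondingly brighter
MR, reflecting the reduced aeration typical after surgery), and a small
soft-tissue lung nodule (1.0 mL by default, activity 4x soft tissue).

## Preprocessing

MR conditioning follows the standard chain: bias-field correction,
histogram matching to a cohort reference, normalization to [0, 1]
(order-statistic percentiles (0, 99.5), which makes the map exactly
idempotent and robust to implant outliers; a zero-range image maps to
zeros by convention). The bias correction fits a third-order polynomial
surface in the log domain to voxels near the dominant intensity mode,
iterating with a shrinking window (0.3, 0.2, 0.15 log units) so anatomy is
not mistaken for bias; robust trimming alone does not converge to a single
tissue class on piecewise-constant anatomy.

Registration composes an affine stage and a B-spline free-form stage, both
driven by normalized mutual information (48 bins). The affine stage is
Nelder-Mead at two resolutions, seeded by an exhaustive coarse translation
search because the metric has sub-voxel interpolation ripple that traps a
simplex started at the identity. The B-spline stage optimises a 40 mm
control grid with simultaneous-perturbation stochastic approximation (SPSA,
the same family as the adaptive stochastic gradient descent used by
standard registration toolkits): 300 iterations, Bernoulli perturbations,
gain auto-scaled from probe gradients so the first steps move control
points by about 1.2 mm. The metric is evaluated on lightly smoothed images
(3x3 box) -- without smoothing the interpolation ripple drowns the
stochastic gradient signal. The best-seen metric value is kept, so the
reported mutual information never decreases; if a slice fails to improve,
one retry with 1.5x control spacing runs. On synthetic smooth deformations
of 8 mm peak this recovers over half the misalignment on average; fields
that displace mostly homogeneous interior regions are fundamentally only
partially recoverable, since mutual information carries no signal away from
edges.

## Numerical choices

* Signed distances are exact Euclidean distances to the mask boundary
  voxels (lower-envelope transform, anisotropic spacing), negative inside.
* Phase congruency uses the canonical log-Gabor construction (4 scales from
  wavelength 3 at multiplier 2.1, 6 orientations, Rayleigh noise threshold
  at k = 2, frequency-spread weighting); the small stabilising epsilon
  scales with image amplitude so the map is exactly invariant to affine
  intensity rescaling.
* Atlas fusion kernels default to sigma_d = 5 mm, sigma_p = 0.2, patch
  radius 2; atlases without CT coverage at a voxel get zero weight; if all
  weights underflow the fusion falls back to uniform weights over covering
  atlases.
* HU to mu is piecewise linear: mu = 0.096 (HU + 1000)/1000 below 0 HU and
  a shallower bone slope above, anchored so 1000 HU maps to 0.172 cm^-1;
  the three-class anchor values are reproduced exactly (-770 HU gives
  0.02208 cm^-1).
* The projector is a sparse pixel-driven splat (each voxel deposits its
  value times its footprint into the two straddling radial bins), so the
  backprojector is the exact adjoint and attenuation factors are
  exp(-integral mu dl) along the same rays the EM update uses. 180-degree
  parallel-beam coverage; experiments use 96 angles on a 64-voxel grid.
* OSEM subsets are angle-interleaved; the multiplicative update preserves
  non-negativity; zero-sensitivity voxels stay zero.
* SUV has no dose/weight for phantoms: all arms of a subject are scaled by
  one factor that sets the reference arm's body mean to 1. The bias metric
  is invariant to this common scale.
* The paired t-test reports p = 1 for identical vectors and p = 0 (with a
  warning) for zero-variance non-zero shifts.

## The network at desk scale

The full-scale preset keeps the published architecture: 20 convolutional
layers in blocks of 7/7/6 at dilations 1/2/4, 16/32/64 channels, batch 32,
learning rate decaying 0.04 to 0.01 (realised as linear decay; the
published schedule's shape is unstated). That configuration is not
trainable in a sensible time on one CPU, so the desk preset keeps the
architectural signature -- three dilation blocks, residual pairs, BN+ReLU,
L2/Adam -- at 3/3/2 layers and 8/16/32 channels, batch 8, lr 5e-3 to 1e-3.
Convolutions run as im2col + BLAS GEMM with C-level gather/scatter. The
kernel is 3x3 (the reference describes 3x3x3 kernels but runs the model in
a 2D configuration; in 2D the in-plane footprint is what remains). CT
targets map to [0, 1] via (HU + 1000)/2000 clipped at 1000 HU (implants
clip); the inverse is applied at inference. After training, batch-norm
running statistics are recalibrated over the full training set so
inference matches training-mode behaviour. Training is deterministic given
the seed; cross-validation splits subjects, never slices.

## Experiments and what passing them shows

`run_experiment()` generates disjoint atlas, training and evaluation
cohorts from hierarchical seeds (any stage is replayable in isolation),
builds the three candidate sCTs per subject, reconstructs four arms and
reports per-region bias, RMSE, lesion VOIs and paired tests.
`run_scenario_suite()` shares one trained network and one atlas cohort
across the four outlier scenarios (5 evaluation subjects each, 64 x 64
single-slice phantoms at 4 mm, noiseless projections for determinism) and
collects the affected-region bias of each arm: the truncated-arm voxels,
the susceptibility void, the removed-lung space plus an adjacent band, or
the nodule VOI. The qualitative pattern the suite checks is: atlas fusion
most robust to truncation and metal (its inputs carry full anatomy that a
smooth deformation cannot remove); the network and especially the
three-class map follow the corrupted MR down; the network most accurate
for abnormal anatomy and small nodules (it follows the image where the
atlas prior cannot and the fixed coefficients do not).

These phantoms establish mechanism, not clinical magnitudes: 2D slices, no
scatter or randoms, geometric organs, and bias percentages that depend on
the configured contrasts. Features of real data they do not emulate
include Dixon water/fat channel physics, respiratory motion, CT beam
hardening and streaks, scanner-specific geometry, and truly 3D anatomy.

## Known limitations

* Registration recovers deformations only where image structure constrains
  them; the atlas arm inherits this.
* At 4 mm voxels the body edge is a large fraction of the volume, so
  boundary hedging by the network costs a few percent of body-mean mu that
  would be negligible at clinical resolution.
* The metal scenario models the susceptibility void and the implant
  density, not CT streak artifacts or their MAR correction.
* The SUV surrogate fixes the reference-arm body mean to 1; absolute SUVs
  are not meaningful, only ratios between arms.
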