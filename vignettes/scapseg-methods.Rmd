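---
title: "Scapula segmentation and glenoid morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scapula segmentation and glenoid morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`scapseg` implements an end-to-end workflow for automatic scapular bone
segmentation from high-resolution volumetric MRI and for computing the
clinically important glenoid measurements from the resulting 3D bone
masks: deterministic preprocessing, stochastic augmentation, trainable 2D
and 3D V-Net segmentation networks with a negative log-Dice loss,
consecutive K-fold cross-validation with early stopping, Dice-gated
probability-averaging ensembles, automatic landmark extraction with six
glenoid measurements, surface-distance maps, trial-mean comparisons
between modalities, and a normality-gated statistical protocol. A
geometric scapula phantom generator with analytically known landmarks
makes every stage testable without any patient data.

This vignette documents the models, the conventions, the tunable
parameters, and the design decisions that were genuinely open.

# Image model and preprocessing

All grids are 3D arrays in a fixed (row, column, slice) order, the slice
axis being the axial acquisition axis. Voxel indices are 0-based in
physical math: a voxel's physical position is `index * spacing` (mm).
The canonical acquisition this pipeline targets is a 512 x 512 x 248
fat-saturated T2-weighted volume at 0.375 x 0.375 mm in-plane with 0.5 mm
slice spacing, stored as NIfTI.

Three deterministic preprocessing steps reduce the memory footprint of a
3D training example without resampling:

* **Crop**: the first 112 rows and 112 columns are removed (the empty
  margin of a shoulder acquisition; literal leading-index cropping, not
  centered).
* **Interleaved split**: every other slice starting from the first or the
  second slice, yielding two stacks with doubled slice spacing
  (512 x 512 x 248 becomes two 400 x 400 x 124 stacks after the crop).
  Odd slice counts are allowed; the first stack is then one slice longer.
  `interleave_merge()` inverts the split exactly, which is how
  full-resolution predictions are reassembled at inference time.
* **Intensity normalization**, three schemes:
  * 3D training: divide by a value drawn uniformly from
    `[max - 1000, max + 1000]` (intensity units);
  * 2D training: the same with half-width 500;
  * validation/inference: divide by the exact maximum, then by the 85th
    percentile of the rescaled intensities.

The randomized training divisor makes models robust against coil-gain
intensity inflation and acts as implicit augmentation; the percentile
division tames volumes whose maximum is an outlier. The uniform law over
the stated band is our choice (only the band is given by the protocol),
as is the percentile definition (linear-interpolation quantile over all
voxels). A non-positive divisor draw — possible only when the jitter
exceeds the volume maximum — is redrawn up to ten times, then an error is
raised; in the normal regime exactly one uniform value is consumed per
volume.

# Augmentation

`augment_pair()` applies up to four transform families, each independently
with probability 0.30 per generated copy: random affine (rotation, scale,
translation), elastic deformation (coarse Gaussian displacement field,
trilinearly upsampled), Gaussian blur, and additive Gaussian noise.
Spatial transforms use identical parameters for image and mask; masks are
resampled nearest-neighbour so they stay strictly binary; intensity
transforms touch the image only. `augment_dataset()` keeps the originals
and adds eight augmented copies per original by default.

The transform magnitudes (rotation up to 15 degrees per axis, scale
0.9-1.1, translation up to 10 voxels, elastic amplitude up to 4 voxels at
8-voxel smoothness, blur sigma 0.5-1.5 voxels, noise 1-5% of the image
maximum) are package defaults chosen to deform plausibly without
destroying the thin scapular blade; the protocol we follow names the
families but not the magnitudes, and everything is overridable. We read
"a 30% chance of undergoing any of the listed augmentations" as per
family and per copy; the alternative (30% per copy overall) is a
configuration away (`per_transform_prob`).

# The V-Net

`vnet_config()` describes the networks; the published configurations are
the defaults:

| | 2D | 3D |
|---|---|---|
| channels | 16 | 12 |
| levels | 2 | 4 |
| convolutions per level | [4, 4] | [1, 3, 4, 3] |
| bottom convolutions | 2 | 4 |
| learning rate | 5e-4 | 1e-5 |

The topology is the classic V-Net reading of those numbers: an input
convolution lifts the image to the base channel count; each encoder level
applies its convolution blocks (5-voxel kernels, PReLU activations) with
a residual addition, then downsamples by a strided 2x block convolution
that doubles the channels; the decoder mirrors this with transposed block
convolutions and additive skip connections; a 1-voxel convolution and a
sigmoid produce the foreground probability (the background probability is
its complement, so per-voxel class probabilities sum to one). Dropout
(keep probability 0.95) runs after each residual block during training
only. Activation type, kernel size and the downsampling operator are not
dictated by the protocol; we use the standard V-Net choices (PReLU,
kernel 5 — configurable, small test networks use 3 — and strided rather
than pooled downsampling) and additive rather than concatenated skips to
keep the channel bookkeeping uniform.

A 2D network is the same machinery with a singleton slice axis, applied
slice-wise along its view axis (axial, sagittal or coronal) and restacked
into a volume. Inputs whose spatial size is not divisible by
`2^n_levels` are mirror-padded and un-padded after inference.

Forward and backward passes are implemented in this package (direct
vectorized convolution kernels in C++; the tape-based backward pass is
verified against finite differences in the test suite). There is no
external deep-learning runtime underneath.

# Training, early stopping, ensembling

`train_model()` runs Adam (beta1 0.9, beta2 0.999, eps 1e-8 — the
standard internal parameters) on the negative logarithmic Dice loss

$$F = -\log_{10} \frac{2\,|p \cdot \hat y| + s}{|p| + |\hat y| + s},$$

one volume per iteration (batch size one; the protocol never states a
batch size), cycling through the training pairs in order. Every 90
training steps (configurable) a validation epoch computes the mean
validation DSC of predictions binarized at 0.5; the best checkpoint is
kept. Training stops at 100 000 iterations or after 30 validation epochs
without improvement, where an improvement must exceed 1e-4 (a strict
float comparison would let noise keep training alive indefinitely). The
smoothing constant `s` (default 1e-5) keeps the logarithm finite before
the prediction first overlaps the reference. Whether the monitored DSC
was soft or binarized is not stated in the protocol; we monitor the
binarized version, matching how the gate below is applied to final
models.

Cross-validation uses `kfold_split()`: consecutive contiguous folds in
subject order, without shuffling, sizes differing by at most one (larger
folds first) — 55 subjects at k = 5 gives five folds of 11.

`build_ensemble()` keeps every trained model whose best validation DSC is
strictly above 0.70 ("above" read literally). `ensemble_predict()`
reconstructs each member's prediction on the full-resolution grid (2D
members slice-wise along their own view axis; interleaved 3D members
predict both slice stacks, which are re-interleaved) and averages the
probability maps voxel-wise without weights before thresholding. The
fusion rule is ours: averaging is the minimal symmetric choice for
combining heterogeneous members, it is permutation-invariant and bounded
voxel-wise by the member extremes, both of which are tested.

# Glenoid morphometry

Six measurements are computed from named landmarks, all in physical
millimetres/degrees:

* **glenoid height / width**: distances between the superior/inferior and
  anterior/posterior rim points;
* **retroversion**: angle between the anterior-to-posterior glenoid line
  and the line from the glenoid centre to the medial scapular border,
  referenced to perpendicular (a face perpendicular to the scapular axis
  reads 0; posterior tilt positive);
* **inclination**: angle between the inferior-to-superior glenoid line
  and the supraspinatus fossa floor line, referenced to perpendicular
  (superior inclination positive);
* **critical shoulder angle**: angle at the inferior glenoid between the
  glenoid line and the line to the lateral acromion;
* **RSA angle**: angle between the inferior-glenoid-to-lateral-fossa line
  and the perpendicular erected on the fossa floor tangent (medial tilt
  positive).

The landmark detector (`extract_landmarks()`) is entirely this package's
construction — the measurement geometry is standard, but no published
automatic procedure exists for obtaining the landmarks from a mask, so a
deterministic, intrinsic pipeline was designed and is tested on phantoms:

1. largest 6-connected component;
2. medial-lateral axis = leading principal axis of the voxel cloud,
   oriented toward the end that is thicker along the bone's thinnest
   axis (glenoid + acromion vs. the tapering blade tip);
3. glenoid face = largest connected cluster of lateral-facing surface
   voxels (outward normals from the gradient of the smoothed mask),
   refined to the surface voxels in a thin slab around the fitted plane
   that stay connected to the cluster, and validated as near-planar
   (RMS plane distance below 2 mm — a sphere fails here);
4. rim points = extremal face points along the in-plane principal axes;
   the superior sign comes from the acromion-side mass lateral of the
   face, the anterior sign from the posterior offset of the spine ridge
   relative to the fossa floor strip;
5. medial border = farthest foreground point on the medial side of the
   face centre;
6. fossa floor = the inferior-most long cluster of superior-facing
   surface voxels medial of the articular face (the floor lies below the
   spine crest), fitted with a 3D line and completed at its lateral tip
   from a thin tube around that line;
7. lateral acromion = most lateral point above the superior glenoid rim.

Because every direction is derived from the shape itself, the procedure
is equivariant under rigid motion and mirroring; left shoulders need no
special casing, and the sign conventions survive mirroring (verified in
the tests). Measurements are computed in physical coordinates, so
anisotropic voxels do not bias the angles.

`surface_distance_map()` reports directed distances (exact Euclidean
distance transform with anisotropic spacing) from each surface voxel of
one mask to the nearest surface voxel of another; call it both ways for
the two directed maps. `compare_measurements()` computes the absolute
difference of per-modality trial means, reported at two decimals rounded
half away from zero — with that convention the bundled example table
(`glenoid_trials_example()`) reproduces the published mean differences
cell for cell (one published RSA cell disagrees with its own printed
trials by 0.03, presumably computed from unrounded data; we reproduce the
value implied by the printed trials).

# The phantom generator

`generate_phantom()` voxelizes a parametric scapula: an elliptical
articular disc (height/width diameters; rotated by version about the
superior-inferior axis and by inclination about the anterior-posterior
axis), a thin tapering blade extending medially whose top edge carries
the supraspinatus fossa floor strip, a spine ridge offset posteriorly, a
connector, and a spherical lateral acromion. The acromion is placed in
closed form so the critical shoulder angle is met exactly; the fossa
strip endpoint is solved for the RSA target and clamped clear of the
articular face (at strong inferior inclination the realized, stored RSA
angle therefore exceeds the target). The sphere matters: the "most
lateral point" of a sphere is stable under the small axis-estimation
errors of the detector, where a box corner would not be.

Truth landmarks are computed in continuous coordinates before
voxelization, and the stored truth measurements are obtained by applying
the same measurement formulas to those landmarks — so truth is
self-consistent to machine precision by construction, and recovery
experiments measure only voxelization plus detection error. Junction
overlaps and the minimum blade thickness scale with the voxel size so
the union stays 6-connected on coarse grids.

`render_intensity()` emulates desk-scale fat-saturated T2-like contrast:
dark background, bright soft-tissue shell, low-intensity bone, a smooth
multiplicative bias field (coil-gain artifact surrogate) and additive
Gaussian noise. What the phantom does **not** emulate: real trabecular
texture, pathology (bone loss, fractures, osteophytes), partial-volume
fat/water mixing, or anatomical shape variability beyond its parameter
ranges. Passing the recovery and training suites therefore demonstrates
that the machinery is correct and well-conditioned, not that the network
generalizes to clinical scans.

`generate_cohort()` samples phantom parameters uniformly from plausible
clinical ranges (heights 30-50 mm, widths 22-34 mm, version -15 to +5
degrees, inclination within 15 degrees, CSA 25-38, RSA 8-18 degrees,
rigid orientations within 10 degrees), keeping height at least 2 mm above
width — anatomically sensible and required for unambiguous in-plane axis
identification. The default cohort grid is 160^3 at 0.75 mm; recovery
experiments use 0.5 mm grids; training-mechanics tests use 64^3 coarse
grids so a single CPU handles them in minutes. Problem sizes in the test
suite (20-phantom recovery grid, single-phantom overfit within 500
iterations, six-phantom two-fold pipeline with 200-iteration models) are
the package's chosen desk-scale study conditions.

# Statistics

`gated_paired_compare()` applies a Shapiro-Wilk test to the paired
differences (the t-test's normality assumption concerns the differences,
not the margins, which resolves an ambiguity in the protocol); if
normality is not rejected at 0.05 a paired Student t-test is used,
otherwise a two-sided Wilcoxon signed-rank test with zero differences
dropped and the exact null distribution for n up to 25 when the absolute
differences are tie-free (normal approximation otherwise). The exact
branch is verified against full 2^n sign-flip enumeration in the tests,
and the size of the whole gated procedure is calibrated by simulation.
All-zero (or constant) difference vectors are flagged degenerate rather
than tested. `oneway_anova()` is the classical equal-variance one-way
decomposition. Significance is p below 0.05 throughout; no
multiple-testing correction is applied, matching the protocol.

# Numerical choices and limitations

* Binarization threshold defaults to 0.5 with ties going to foreground.
* Dropout masks, normalization divisors, augmentation draws and weight
  initialization all consume R's RNG, so a seed makes any stage
  bit-reproducible.
* The landmark detector assumes a scapula-like topology: one connected
  component, a near-planar lateral articular face at least ~30 surface
  voxels large, an acromion above the superior rim, a posteriorly offset
  spine, and an extended (>= 15 mm) fossa floor. Violations raise
  descriptive `landmark extraction failed` errors instead of returning
  nonsense.
* Angle recovery degrades with voxel size; at 0.5 mm isotropic the grid
  experiment recovers all four angles with mean absolute error well
  under 2 degrees, but masks coarser than ~1.5 mm are suitable for
  segmentation experiments only.
* Training the full-size published configurations to clinical accuracy
  is out of scope on a CPU; the package demonstrates correctness of the
  training mechanics (gradient checks, overfit sanity, early stopping,
  gating) at reduced scale.
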