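# scapseg

Automatic scapular bone segmentation from high-resolution volumetric MRI,
and clinical glenoid morphometry on the resulting 3D bone masks — as one
testable R package.

Three-dimensional bone models of the shoulder are the basis for surgical
planning in instability, rotator-cuff disease and arthroplasty. CT is the
clinical gold standard for bone, but shoulder patients usually already
have an MRI; segmenting the scapula directly from MRI would give surgeons
the bone model without a second scan and without ionizing radiation. The
scapula is a hard target — a thin blade, a ridge-like spine, and a small
articular socket (the glenoid) whose orientation drives the clinically
relevant numbers.

`scapseg` implements the full workflow:

* **Preprocessing** — in-plane cropping (drop the first 112 rows/columns
  of a 512×512 acquisition), interleaved slice splitting (one 512×512×248
  volume → two 400×400×124 stacks) and its exact inverse, and three
  intensity-normalization schemes: divide by a random value in
  `[max − 1000, max + 1000]` (3D training), `[max − 500, max + 500]`
  (2D training), or divide by the maximum and then by the 85th percentile
  (validation/inference).
* **Augmentation** — random affine, elastic, blur and noise transforms,
  each applied with 30% probability, eight copies per original, applied
  jointly to image and mask (mask resampled nearest-neighbour).
* **V-Net segmentation networks** — configurable 2D (16 channels,
  2 levels, convolutions [4, 4]) and 3D (12 channels, 4 levels,
  convolutions [1, 3, 4, 3]) encoder–decoders with PReLU activations,
  residual blocks, strided down-convolutions, additive skips and a
  sigmoid output. Forward and backward passes are implemented in the
  package (C++ kernels, gradient-checked); no deep-learning runtime is
  required.
* **Training** — Adam on the negative log-Dice loss
  `F = −log10( 2|p·ŷ| / (|p| + |ŷ|) )`, validation every 90 steps, early
  stopping after 30 stagnant validation epochs, dropout keep-probability
  0.95, consecutive (unshuffled) K-fold cross-validation.
* **Ensembling** — keep all models with validation DSC strictly above
  0.70 and average their probability maps voxel-wise on the
  full-resolution grid.
* **Morphometry** — automatic landmark extraction from a binary mask and
  six measurements: glenoid height and width (mm), retroversion,
  inclination, critical shoulder angle and RSA angle (degrees), plus
  directed surface-distance maps and trial-mean comparison tables.
* **Statistics** — Shapiro–Wilk-gated paired tests (Student t vs. exact
  Wilcoxon signed-rank) and one-way ANOVA, significance at p < 0.05.
* **Phantoms** — a geometric scapula generator with analytically known
  landmarks and measurements, plus an MRI-like renderer (soft-tissue
  shell, dark bone, coil-gain bias field, noise), so everything above is
  testable without patient data.

See `vignettes/scapseg-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

Generate a phantom with known anatomy, measure its voxelized mask, and
compare against the analytic truth:

```r
library(scapseg)

ph <- generate_phantom(phantom_spec(glenoid_height = 38, glenoid_width = 28,
                                    version = -2, inclination = 5))
ph$truth$measurements
#> <scap_measurements>
#>   glenoid_height              38.00 mm
#>   glenoid_width               28.00 mm
#>   retroversion                 1.99 deg
#>   inclination_angle            5.00 deg
#>   critical_shoulder_angle     32.00 deg
#>   rsa_angle                   12.00 deg

measure_mask(ph$mask)
#> <scap_measurements>
#>   glenoid_height              37.62 mm
#>   glenoid_width               27.52 mm
#>   retroversion                 2.22 deg
#>   inclination_angle            4.53 deg
#>   critical_shoulder_angle     33.01 deg
#>   rsa_angle                   14.00 deg
```

The phantom was built retroverted by 2° (version −2), inclined 5°
superiorly, with a 32° critical shoulder angle; the automatic landmark
detector recovers the distances to within half a millimetre and the
angles to within a couple of degrees — the discretization error expected
at 0.5 mm resolution.

Comparing paired measurement trials between modalities (here the bundled
MRI-vs-CT example table):

```r
tab <- glenoid_trials_example()
s <- subset(tab, patient == "056")
compare_measurements(split(s$value[s$modality == "mri"], s$measurement[s$modality == "mri"]),
                     split(s$value[s$modality == "ct"],  s$measurement[s$modality == "ct"]))
#>               measurement  mean_a  mean_b mean_difference mean_difference_2dp
#> 1 critical_shoulder_angle  31.040  28.320           2.720                2.72
#> 2          glenoid_height  41.995  38.540           3.455                3.46
#> 3           glenoid_width  27.200  28.485           1.285                1.29
#> 4       inclination_angle  98.400  96.630           1.770                1.77
#> 5            retroversion   0.120   3.385           3.265                3.27
#> 6               rsa_angle   9.585  11.835           2.250                2.25
```

`mean_difference_2dp` is the absolute difference of the per-modality
trial means, rounded half away from zero — e.g. 1.29 mm for the glenoid
width of subject 056.

An end-to-end run (simulate → preprocess → train per fold → ensemble →
measure → compare → stats) on a small synthetic cohort:

```r
res <- run_pipeline(pipeline_config(output_dir = "run", seed = 1))
read.csv(res$paths$comparison)   # predicted-vs-truth measurement table
```

A thin command-line front end for the same operations is installed at
`inst/cli/scapseg.R` (subcommands `simulate`, `preprocess`, `measure`,
`compare`, `run`).

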