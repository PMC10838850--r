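---
title: "Centroid sampling and Multiple Instance Ensembling for maxillary-sinus anomaly classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid sampling and Multiple Instance Ensembling for maxillary-sinus anomaly classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinusmie)
```

## The problem

Polyps and retention cysts of the maxillary sinus (MS) are frequent
incidental findings on head-and-neck MRI. Classifying each sinus as normal
or anomalous with a 3D CNN faces two practical obstacles: the relevant MS
subvolume must first be localized inside a much larger scan, and labeled
cohorts are small. This package implements a pipeline that addresses both
with one mechanism, and ships a synthetic phantom cohort so every stage is
runnable and testable without clinical data.

The key observation is that after rigid registration to a common reference
scan, MS centroids occupy a narrow, side-specific band of voxel coordinates.
Localization therefore needs no learning: the per-axis centroid distribution
of each side is modeled as a Gaussian, `N(mu_a, sigma_a^2)` for axes
`a = x, y, z`, estimated once from a handful of annotated scans. The default
`centroid_model()` uses, in the 173 x 319 x 319 reference grid, left
`mu = (75, 231, 121)`, `sigma = (1.47, 1.56, 1.76)` and right
`mu = (149, 232, 118)`, `sigma = (1.90, 1.66, 6.47)` (voxels).

For each sinus, `N` candidate centroids are drawn from these distributions
and a cubic patch of side `P` is cropped around each. This serves three
purposes at once: it localizes the sinus, it multiplies the training set by
`N` (the overlapping crops differ by small translations), and at test time it
provides the instances for ensembling. Right-side patches are mirrored along
the left-right axis so both sinuses share one appearance, and every patch is
trilinearly resampled to the fixed 64^3 network input.

At inference, **Multiple Instance Ensembling (MIE)** averages the softmax
outputs of the classifier `f` over the `N` instances of a sinus:

`y_hat = (1/N) * sum_i softmax(f(x_i))`

i.e. implicit test-time augmentation over translational jitter. The
single-instance ablation (`use_mie = FALSE` in `evaluate_fold()`) scores the
first sampled instance only.

## Coordinate and unit conventions

The package treats the centroid parameters as **0-based voxel coordinates**
in the registered reference frame, with array axis 1 = left-right (x),
axis 2 = y, axis 3 = z. The left/right means (75 vs 149) straddle the
173-voxel x axis, which fixes the axis naming; a millimetre reading of the
same numbers (dividing by the 0.53/0.75 mm spacings) would place the
centroids outside any plausible anatomy, so the voxel reading is the only
consistent one. The "coronal flip" of right-side patches is implemented as
mirroring along x.

Patch centering rounds the continuous centroid half-up and spans 0-based
indices `c - floor(P/2) .. c - floor(P/2) + P - 1`. Crops that extend beyond
the volume are zero-padded (not clamped): padding preserves the geometry of
off-center sinuses, whereas clamping would silently translate the patch. A
crop lying entirely outside the volume raises a localization-failure error.
Resampling to 64^3 is trilinear on a corner-aligned grid; constants and
linear ramps are fixed points (verified in the tests), and `P = 64` is the
identity. The flip is applied to the raw crop *before* resampling, where it
is exact.

## The phantom cohort

`phantom_spec()` / `generate_phantom_cohort()` emulate the statistical
structure of a registered FLAIR cohort, not its anatomy: a mid-intensity
soft-tissue background (0.5), two dark ellipsoidal air cavities (0.1) whose
centers follow the side-specific centroid Gaussians, and, in anomalous
sinuses, a bright mass (0.9) attached to the cavity wall — the FLAIR-like
hyperintensity of fluid-filled cysts and polyps. Masses come in two shape
families chosen uniformly, a smooth dome (cyst-like) and a lobulated union
of 2-4 overlapping spheres (polyp-like), with radii drawn from a configured
range; voxelwise Gaussian noise (sd 0.05 by default) is added last. Each
sinus is anomalous independently with probability 0.32, the prevalence of
the cohort the method was developed on (299 patients, about a third of
sinuses anomalous). Cavity semi-axes default to 10-15 voxels at full scale,
matching a 2-3 cm sinus at the reference spacing; mass radii default to 4-8
voxels.

Everything is reproducible from `spec$seed`; rendering draws each patient's
noise from a derived substream, so streaming one volume at a time and batch
generation give bit-identical cohorts. Geometry placement
(`generate_phantom_truths()`) is separated from rasterization, which is what
makes population-level checks (prevalence within 2 points over thousands of
sinuses, per-axis centroid sd within 10% of sigma at n = 10,000) affordable
in the test suite.

What the phantoms deliberately do *not* model: anatomy around the sinuses,
bias fields, motion, partial-volume effects, Rician noise statistics, or
anomalies that fill the entire cavity. Consequently the phantom task is
*easier* than the clinical one — the classes are separable by design (the
suite verifies an intensity-threshold oracle exceeds 95% accuracy). Passing
the end-to-end benchmark demonstrates that the pipeline's plumbing —
localization, flipping, resampling, patient-level splitting, training,
ensembling, metrics — is correct and that MIE behaves as intended, not that
clinical-grade accuracy would be reached on real MRI.

## Datasets and cross-validation

Labels live at sinus level (anomalous = positive class); assignment to
train/validation/test is at patient level, so both sinuses and all `N`
instances of a patient land in one partition and no patient leaks across
them. Stratification groups patients by their number of anomalous sinuses
(0/1/2); each partition receives a deterministic largest-remainder share of
every stratum, and a greedy repair pass swaps patients with the training
partition until each partition's positive fraction is within a tolerance
(default 3 percentage points) of the target. Fold construction was an open
design point: the three folds are three independent stratified draws from
derived seeds rather than a rotation, which keeps every fold's partition
sizes identical to the configured fractions (defaults proportional to the
327/37/41 sinus counts of the original split).

## The classifier

The instance classifier is `tiny3d`, a compact native-R 3D CNN: a fixed 4x
average pool of the min-max-normalized 64^3 input, two 3^3 convolution
blocks (default widths 8 and 16) each followed by ReLU, a 2x average pool
between them, global average pooling, and a 2-way fully connected head.
Convolutions are evaluated as im2col gathers plus BLAS matrix products, and
gradients are hand-derived (and checked against finite differences in the
suite). Training follows the study protocol: cross-entropy, Adam, batch
size 16, default 100 epochs at learning rate 1e-4, with the rate divided by
10 after 5 epochs without validation-loss improvement
(`plateau_schedule()` exposes the policy standalone); the returned model is
the best-validation-loss checkpoint. Validation loss is computed
per-instance (whether to aggregate per sinus was unspecified; per-instance
matches the training unit). No class weighting is applied and no
augmentation beyond the sampling itself. Per-instance min-max normalization
was chosen as the intensity normalization.

The deeper `resnet3d` / `densenet3d` configurations are accepted for
bookkeeping and report labeling, but `train_classifier()` refuses to train
them: those backbones (up to ResNet200/DenseNet264) belong to cluster-scale
experiments, and every quantitative claim this package makes is computed
with `tiny3d`. Since the first pooling stage is parameter-free, dataset
assembly precomputes it once per instance, which keeps a cohort's instances
in a few tens of megabytes.

## Evaluation

With a 32% positive prevalence, accuracy is misleading; the package reports
AUPRC and F1. `auprc()` is step-wise average precision (no interpolation;
ties form one threshold; constant scores give the prevalence), verified
against an exhaustive threshold-enumeration oracle on all small datasets.
`f1()` uses the 0.5 threshold on the anomalous probability with exact ties
classified positive. Cross-fold aggregation uses the sample (n-1) standard
deviation; the cross-architecture percentage-increase report uses the
population (n) convention, which is the convention that reproduces the
published summary statistics from the published per-architecture table
(21.86 +/- 11.92 and 4.27 +/- 5.04 for sampling, 9.85 +/- 4.02 for
sampling + MIE on the DenseNets), as `percentage_increase_report()`
demonstrates.

## The benchmark and its problem sizes

`run_mie_benchmark()` is the package's end-to-end experiment: 120 phantoms
at half scale (86 x 160 x 160 voxels), 32% anomalous sinuses, `N = 5`
Gaussian samples per sinus, `P = 18` (the half-scale counterpart of the
full-resolution optimum `P = 35`), threefold patient-level
cross-validation, and a 12-epoch tiny3d schedule at learning rate 1e-3 —
the phantom task converges within a few epochs, so the full 100-epoch
protocol would add nothing. These sizes are the package's chosen benchmark
conditions; full-scale geometry and the complete `N` / `P` grids remain
available through the same functions. On this benchmark, MIE AUPRC exceeds
the 0.62 floor (chance = prevalence = 0.32) in every fold and is at least
as good as single-instance inference in the majority of folds — the
directional claim of the ensembling strategy.
`sampling_strategy_comparison()` reruns the pipeline per sampling variant
(seven equidistant combinations plus Gaussian) with shared folds and seeds,
mirroring the published ablation's table shape.

## Numerical notes and limitations

* Gaussian draws with `N = 1` are still random (one draw), matching uniform
  treatment of all `N`; deterministic mu-centered extraction is available
  via the equidistant mode with `n = 1`.
* `extract_patch()` errors only when the crop misses the volume entirely;
  partial overlap zero-pads silently, since border sinuses are legitimate.
* The repair pass in `make_folds()` can fail on pathological label tables
  (e.g. all-normal cohorts with a positive target); it errors rather than
  returning an off-target split.
* Checkpoints serialize with `dput()` — plain text, diffable, and
  bit-faithful for the small tiny3d weight set; large backbones would need a
  binary format.
* The phantom cohort's easiness means benchmark AUPRCs saturate near 1;
  the acceptance checks are therefore floors and directional comparisons,
  never point reproductions of the clinical-cohort values.
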