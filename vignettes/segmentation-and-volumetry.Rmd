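---
title: "Automatic tumor segmentation and volumetry: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic tumor segmentation and volumetry: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Measuring the size and volume of a mass-enhancing breast tumor on
dynamic contrast-enhanced MRI (DCE-MRI) is clinically important — T
staging by the longest tumor dimension drives treatment planning — but
manual 3D delineation is slow and shows inter- and intra-observer
variability. `segvol` implements an automatic pipeline: a residual U-Net
("Res-UNet") segments the lesion on a subtraction-like 3D volume, and a
quantification stage derives radiomics-style shape features, an
Otsu-based cystic/necrotic decomposition, and the T stage, with
agreement statistics (DSC, IOU, ICC) against reference masks.

Real DCE-MRI cohorts of this kind are private, so the package ships a
first-class phantom module: synthetic lesions with *closed-form*
geometry that let every stage be validated against analytic truth. What
passes on phantoms demonstrates the correctness of the machinery, not
clinical performance — see "What the phantoms do and do not show".

# The segmentation model

## Architecture

The network is an encoder–decoder U-Net whose encoder blocks are
residual units: two convolution → instance-norm → ReLU stages whose
input joins the output through an addition. When the unit changes
channel count or resolution, the identity path is projected with a 1×1×1
convolution followed by instance norm. Downsampling is a stride-2
convolution, upsampling a stride-2 transposed convolution, and each
decoder level concatenates the same-level encoder output (the U-Net skip
connection) before its own residual unit. A 1×1×1 head produces
two-class score maps at input resolution; a softmax converts them to
background/lesion probabilities.

Channel counts are `base_channels * 2^(level-1)`. `depth` (resolution
levels) and `base_channels` are configurable; patch sizes must be
divisible by `2^(depth-1)`. Normalization is instance-style (per-channel,
per-patch) and the nonlinearity is the rectifier — common 3D-segmentation
choices where a schematic leaves them open.

Because no deep-learning framework is available to R in this stack, the
forward pass, backpropagation and the Adam optimizer are implemented in
the package itself on compiled kernels. Stride-1 convolutions use a
shift-and-GEMM scheme on one-voxel zero-padded grids (one BLAS `sgemm`
per kernel offset, no im2col buffer); strided convolutions use im2col,
whose buffer scales with the 8× smaller output grid. Convolution
arithmetic is single precision — the conventional CNN precision — while
losses, normalization statistics and all quantification run in double.
Every layer's gradient is verified against central finite differences in
the test suite.

## Objective

Training minimizes the equally weighted combination

    loss = 0.5 * DSC_loss + 0.5 * cross_entropy_loss

where `DSC_loss = 1 - (2 Σ p y + s) / (Σ p + Σ y + s)` is the soft Dice
loss on the foreground softmax probability `p` with target `y`, pooled
over the patch, and the cross-entropy term is the per-voxel mean of
`-log softmax` of the true class. The smoothing term `s = 1e-5` keeps
empty-target patches finite; for hard 0/1 predictions `1 - DSC_loss`
equals the evaluation DSC as `s → 0`. Weights are configurable through
`loss_config()`.

## Pre-processing and sampling

* **Respacing.** The per-axis arithmetic mean of the training cohort's
  voxel spacings defines the target grid; images are resampled
  trilinearly, masks by nearest neighbour (kept binary). Output shape is
  `round(shape * spacing / target)`, preserving world extent to within a
  voxel.
* **Normalization.** Per case, *after* respacing: clamp to the volume's
  0.5–99.5 percentile range, then z-score with the mean/SD of the
  clamped volume. Statistics use the whole volume, not only foreground.
  A constant volume maps to zeros (`sd` guarded by `epsilon = 1e-8`).
* **Patch sampling.** Patches (default 96³; every dimension must be a
  multiple of 2) are centred on a uniformly drawn foreground voxel with
  probability `fg_center_prob` (default 0.5, i.e. half-to-half; 2/3
  reproduces a 2:1 positive:negative mix) and on a background voxel
  otherwise. Volumes smaller than the patch are symmetrically
  zero-padded; centres are clipped so patches fit, which jitters
  effective centres near borders.
* **Augmentation.** Random zoom, intensity scale, intensity shift,
  Gaussian noise, in-plane 90° rotation, and elastic deformation (a
  coarse Gaussian control-point field upsampled trilinearly). Geometric
  transforms hit image and label (labels warped with nearest neighbour,
  so they stay binary); intensity transforms touch the image only.
  Magnitudes default to conservative ranges in normalized units (zoom
  and scale 0.9–1.1, shift ±0.1, noise SD up to 0.1, elastic SD 2
  voxels on a 4³ grid) since only the transform list, not magnitudes, is
  prescribed; all are configurable.

## Training

Adam (default learning rate 1e-3, batch 2) over a fixed number of patch
iterations — patch-based sampling has no natural dataset epoch, so an
"epoch" is simply a checkpoint interval. Checkpoints are
self-describing (parameters + architecture + training config + target
spacing). Training aborts with diagnostics on a non-finite loss and is
fully reproducible under `train_config(seed=)`.

# Inference

Whole volumes are predicted by sliding windows with fractional overlap
(default 0.5), averaging class probabilities uniformly over covering
windows; volumes smaller than the window are padded and cropped back.
Rotation test-time augmentation (TTA) averages the identity pass with
90°/180°/270° passes in the axial plane, each un-rotated before
averaging; non-square in-plane grids are padded to square and cropped.
Checkpoint ensembles average member probability maps (TTA composes with
ensembling). Averaging at the probability level is the simplest
reproducible combination rule. The final mask is the per-voxel argmax
(ties resolve to background) with every 26-connected foreground
component of fewer than 30 voxels removed — strictly fewer, so a
30-voxel component survives. The filter is idempotent, and an empty
output mask is legal.

# Quantification

All measurements run on the largest 26-connected component (ties broken
toward the smallest linear seed index), in millimetres via
`world = origin + index * spacing`:

* **Maximum 3D diameter** — the largest pairwise Euclidean distance
  between foreground voxel centres. The maximizing pair always has both
  endpoints on the surface, so only surface voxels (those with a
  6-neighbour outside the mask) are enumerated; tests compare against
  the all-pairs brute force.
* **Maximal/minimal diameter** — `4*sqrt(λ1)` and `4*sqrt(λ2)` from the
  eigenvalues `λ1 ≥ λ2 ≥ λ3` of the sample covariance of foreground
  coordinates: the radiomics major/minor axis lengths of the
  moment-matched ellipsoid. For a uniform solid ellipsoid with semi-axes
  `a ≥ b ≥ c` the moments give `4a/√5` (≈ 0.894·2a), *not* `2a` — the
  phantoms' closed forms account for this.
* **Mesh volume** — the volume enclosed by the 0.5 iso-surface of the
  binary mask: each grid cell (padded by one background layer so the
  surface closes) is split into six tetrahedra sharing the main
  diagonal; within a tetrahedron the interpolated field is linear, so
  the sub-volume above the level has a closed form. This equals the
  volume bounded by a marching-tetrahedra mesh.
* **Voxel volume** — foreground count × voxel volume, exactly.
* **Cystic/necrotic decomposition** — Otsu's threshold on the in-lesion
  intensity histogram (128 equal-width bins by default; bin count is a
  reproducibility convention, configurable). In-lesion voxels below the
  threshold form the candidate region; components under 30 voxels are
  removed as outliers. When several cuts tie — exactly flat criterion
  across the empty bins between well-separated modes — the plateau
  midpoint is taken, so the threshold falls centrally in the gap; a
  degenerate (constant) histogram reports "no cystic component".
* **T staging** — T1 ≤ 20 mm < T2 ≤ 50 mm < T3 by the configured staging
  diameter. The clinical convention is by the longest tumor dimension,
  but both reported diameters are candidates; the default stages by the
  covariance-based maximal diameter with a switch to the maximum 3D
  diameter (`stage_by = "max3d"`). Upper bounds are inclusive, the
  AJCC-consistent reading of size categories whose verbal definitions
  overlap at the boundaries.

# Evaluation

Per case: `DSC = 2|X∩Y|/(|X|+|Y|)` and `IOU = |X∩Y|/|X∪Y|` on foreground
voxel sets (linked by `DSC = 2·IOU/(1+IOU)`). If exactly one mask is
empty both metrics are 0; if both are empty they are defined as 1 with a
warning (the defensible convention for a correctly predicted absence).
Stage classification is summarized by a 3×3 confusion matrix with
one-vs-rest precision, recall (sensitivity), specificity and F1 per
class, macro and support-weighted averages, and overall accuracy;
weighted recall equals accuracy by construction. Classes absent from the
truth yield `NA` metrics, disclosed rather than dropped silently.
Measurement agreement uses the two-way random-effects,
absolute-agreement, single-measure ICC — ICC(2,1) — computed from the
mean-squares decomposition; absolute agreement is the defensible variant
for method-vs-reference comparison because it penalizes systematic
offsets. Bands: excellent above 0.95, good above 0.80.

# The phantom module

Phantoms emulate the one statistical structure the pipeline assumes: a
hyperintense lesion on a darker noisy background, optionally with a
hypointense core standing in for cystic/necrotic change.

* Geometry: a rotated ellipsoid (semi-axes `a ≥ b ≥ c`), digitized by
  the voxel-centre-inside rule — matching the discrete mask semantics of
  every downstream feature. Optional lobulation perturbs the radius by
  `1 + amplitude * P(direction)` with `P` a random degree-2/3 real
  spherical-harmonic combination normalized to sup-norm 1; amplitude is
  capped at 0.3. Lobulated shapes have no closed-form truth, so their
  analytic fields are `NA` and cohort generation defaults to amplitude 0.
* Intensities: background 50, lesion 300, core 100, additive Gaussian
  noise SD 20, on an arbitrary scanner-like scale in the hundreds (real
  lesion means sit in the hundreds on subtraction images; the background
  level is a convention since no background statistics are published).
* Spacing defaults to anisotropic (0.7, 0.7, 1.1) mm — the coarse axis
  matches a typical 1.1 mm slice thickness.
* Cohorts: stage mix defaults to 23/72/5 percent (a clinically
  imbalanced distribution); per-stage staging diameters are drawn with a
  2 mm interior margin from the 20/50 mm boundaries so the digitized
  masks have a well-defined true stage; cores appear with probability
  `core_fraction` at 25–40% of the lesion axes.

**What the phantoms do and do not show.** They exercise every contract —
geometry recovery, loss arithmetic, stitching, filtering, staging,
agreement statistics — against analytic truth, and they let a small
network be trained to convergence in minutes. They do not contain breast
anatomy, coil inhomogeneity, DCE time dynamics, non-mass enhancement, or
multifocal disease; passing on them says the machinery is correct, not
that the printed clinical accuracies transfer.

# Scaled-down validation experiment

The self-contained recovery experiment (in the acceptance tests and
`scripts/acceptance.R`) uses 40 training and 10 held-out phantoms at
1 mm isotropic spacing, a depth-3/base-8 network, 48³ patches, 300 Adam
iterations at batch 1, and checkpoints every 100 iterations — the three
snapshots double as the ensemble members. These sizes are the package's
chosen desk-scale study: large enough that the network must genuinely
learn the lesion appearance (held-out Dice above 0.98 in practice, with
TTA and the ensemble within a hair of the single best member), small
enough to re-run anywhere. The full-scale defaults (96³ patches, depth
4, base 16, batch 2) remain the configuration surface for real data.

# Numerical choices and degenerate inputs

* Dice smoothing 1e-5; normalization epsilon 1e-8; instance-norm epsilon
  1e-5.
* Argmax ties at exactly 0.5/0.5 go to background.
* Empty predicted masks are legal everywhere downstream: geometry
  reports zeros with a warning, DSC/IOU report 0 against a non-empty
  reference.
* Single-voxel masks report zero diameters.
* Component labelling order (and hence tie-breaks) is the linear scan
  order of the array, which is deterministic.
* One master seed fans out to per-stage/per-case seeds through a fixed
  integer derivation, so stages are individually reproducible.

# Known limitations

* No DICOM ingestion, bias-field correction, breast cropping or
  registration: inputs are already-subtracted, NIfTI-format volumes.
* One residual unit per level; deeper per-level stacks are not
  implemented.
* CPU-only: full-scale training (96³ patches, thousand-case cohorts) is
  out of reach; the architecture is validated at desk scale.
* No multifocal lesion accounting — measurements describe the largest
  connected component only.
* The false-positive suppression step suggested as future work in the
  source literature is not implemented.
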