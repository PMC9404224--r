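# segvol

Automatic segmentation and volumetric measurement of mass-enhancing
tumors on 3D contrast-enhanced MRI, in R.

Preoperative tumor size drives T staging and treatment planning, but
manual 3D delineation on DCE-MRI is slow and observer-dependent.
`segvol` implements the full automatic pipeline for radiologists'
measurement tasks:

* a **residual U-Net** (Res-UNet: encoder of residual units, U-Net skip
  connections, instance norm, stride-2 down/transposed-conv up) trained
  with the combined objective
  `loss = 0.5 · DSC_loss + 0.5 · cross_entropy_loss`, where
  `DSC_loss = 1 − (2Σpy + s)/(Σp + Σy + s)` is the soft Dice loss on
  the foreground softmax probability;
* **pre-processing** exactly as a segmentation cohort needs it:
  respacing to the cohort mean spacing, per-case percentile-clamped
  z-score normalization (`clamp to [P0.5, P99.5]`, then `(x − mean)/SD`),
  balanced foreground/background patch sampling, and training-time
  augmentation (zoom, intensity scale/shift, Gaussian noise, 90°
  rotation, elastic deformation);
* **inference** by overlapping sliding windows, rotation test-time
  augmentation (90°/180°/270°, averaged after un-rotation), checkpoint
  ensembling, and removal of predicted components with fewer than 30
  voxels;
* **quantification** of the largest connected component: maximum 3D
  diameter (max pairwise distance of voxel centres, mm), maximal/minimal
  diameter (4·√λ of the coordinate-covariance eigenvalues — the
  radiomics axis lengths), iso-surface mesh volume, exact voxel volume,
  Otsu-threshold decomposition of hypointense cystic/necrotic cores, and
  T staging (T1 ≤ 20 mm < T2 ≤ 50 mm < T3);
* **evaluation**: per-case DSC = 2|X∩Y|/(|X|+|Y|) and IOU = |X∩Y|/|X∪Y|,
  one-vs-rest stage classification metrics, and two-way random-effects
  absolute-agreement ICC(2,1) for volume and diameters.

Because clinical DCE-MRI cohorts are private, the package also ships a
**phantom module**: lobulated, rotated ellipsoid lesions with known
closed-form geometry (optionally with hypointense cores), written as
NIfTI cohorts with CSV manifests, so that every stage — from the loss
arithmetic to the ICC — is validated against analytic ground truth. The
network, backpropagation and Adam optimizer are implemented inside the
package on compiled (Rcpp/RcppArmadillo + BLAS) kernels; no external
deep-learning framework is required.

## Worked example

Simulate one noisy cored lesion and quantify it:

```r
library(segvol)

spec <- phantom_spec(grid_shape = c(64, 64, 48), spacing_mm = c(0.7, 0.7, 1.1),
                     semi_axes_mm = c(15, 12, 10), rotation = c(0.4, 0.2, 0.1),
                     noise_sd = 20, seed = 7,
                     core = list(core_semi_axes_mm = c(6, 5, 4),
                                 core_intensity = 100))
ph <- generate_phantom(spec)
q <- quantify_case(ph$volume, ph$mask, cystic = TRUE)
q$geometry
#> <lesion_geometry> max 3D diameter 29.79 mm | mesh volume 7506.3 mm3 |
#>   maximal/minimal diameter 26.80/21.48 mm | voxel volume 7516.9 mm3 (13946 voxels)
as.character(q$t_stage)
#> "T2"      # staging diameter 26.80 mm
q$cystic
#> Otsu threshold 194.0 | cystic volume 504.5 mm3 |
#>   lesion mean 286.4 | cyst mean 100.1
```

Against the closed forms: the ellipsoid volume is 7539.8 mm³ (voxel
volume off by 0.3%, mesh volume by 0.4%), the analytic maximal diameter
is 26.83 mm (measured 26.80), and the analytic core volume is 502.7 mm³
(Otsu recovers 504.5 despite noise at 10% of the rim–core contrast). A
26.8 mm lesion is T2 (20 mm < d ≤ 50 mm).

Train and evaluate a small model end to end on a simulated cohort:

```r
cfg <- load_config(system.file("extdata", "smoke_config.yaml", package = "segvol"))
run_pipeline("end-to-end", cfg)   # simulate -> train -> predict -> quantify -> evaluate
```

which leaves cohorts, checkpoints, a training log, predicted masks,
per-case geometry, and `segmetrics.csv` / `classification.json` /
`agreement.json` reports under `cfg$output_root`. The same stages are
available from a shell via the thin wrapper:

```sh
Rscript inst/cli/segvol.R end-to-end --config my_config.yaml --seed 7 --out runs/
```

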