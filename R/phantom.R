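#' Specification of a synthetic lesion phantom
#'
#' A phantom emulates the appearance of a mass-enhancing tumor on a
#' subtraction DCE-MRI volume: a hyperintense (optionally lobulated,
#' rotated) ellipsoid on a darker noisy background, with an optional
#' hypointense core standing in for cystic/necrotic change. The geometry is
#' analytic, so every downstream measurement can be checked in closed form.
#'
#' Default intensities (background 50, lesion 300, core 100, additive
#' Gaussian noise SD 20) are on an arbitrary scanner-like scale in the
#' hundreds; default spacing is anisotropic `(0.7, 0.7, 1.1)` mm with the
#' coarse axis matching a typical 1.1 mm slice thickness.
#'
#' @param grid_shape Integer vector of 3, voxels per axis.
#' @param spacing_mm Positive voxel size per axis (mm).
#' @param center_mm Lesion centre in mm (default: grid centre).
#' @param semi_axes_mm Ellipsoid semi-axes `(a, b, c)` in mm; sorted to
#'   `a >= b >= c`.
#' @param rotation Euler angles (radians) applied as `Rz(a) Ry(b) Rx(c)`.
#' @param lesion_intensity,background_intensity Mean signal of lesion and
#'   background; lesion must be brighter.
#' @param noise_sd SD of additive Gaussian noise.
#' @param lobulation_amplitude Radial perturbation fraction in `[0, 0.3]`;
#'   0 gives a pure ellipsoid with closed-form geometry.
#' @param core Optional `list(core_semi_axes_mm =, core_intensity =)` for a
#'   hypointense central core (same centre and orientation as the lesion).
#' @param seed RNG seed controlling noise and lobulation shape.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 64),
                         spacing_mm = c(0.7, 0.7, 1.1),
                         center_mm = NULL,
                         semi_axes_mm = c(15, 12, 10),
                         rotation = c(0, 0, 0),
                         lesion_intensity = 300,
                         background_intensity = 50,
                         noise_sd = 20,
                         lobulation_amplitude = 0,
                         core = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("phantom_spec: grid_shape must be 3 integers >= 4")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("phantom_spec: non-positive spacing")
  if (is.null(center_mm)) center_mm <- (grid_shape - 1) * spacing_mm / 2
  semi_axes_mm <- sort(as.numeric(semi_axes_mm), decreasing = TRUE)
  if (length(semi_axes_mm) != 3L || any(semi_axes_mm <= 0))
    stop("phantom_spec: semi_axes_mm must be 3 positive values")
  if (lobulation_amplitude < 0 || lobulation_amplitude > 0.3)
    stop("phantom_spec: lobulation_amplitude must lie in [0, 0.3]")
  if (lesion_intensity <= background_intensity)
    stop("phantom_spec: lesion_intensity must exceed background_intensity")
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  # the lesion (any rotation, any lobulation) is bounded by this radius
  r_bound <- semi_axes_mm[1] * (1 + lobulation_amplitude)
  extent_lo <- rep(0, 3)
  extent_hi <- (grid_shape - 1) * spacing_mm
  if (any(center_mm - r_bound < extent_lo + spacing_mm) ||
      any(center_mm + r_bound > extent_hi - spacing_mm))
    stop("phantom_spec: lesion exceeds grid bounds (needs >= 1 voxel margin); ",
         "enlarge grid_shape or shrink semi_axes_mm")
  if (!is.null(core)) {
    if (!all(c("core_semi_axes_mm", "core_intensity") %in% names(core)))
      stop("phantom_spec: core needs core_semi_axes_mm and core_intensity")
    core$core_semi_axes_mm <- sort(as.numeric(core$core_semi_axes_mm), decreasing = TRUE)
    if (any(core$core_semi_axes_mm >= semi_axes_mm))
      stop("phantom_spec: core must lie strictly inside the lesion")
    if (core$core_intensity >= lesion_intensity)
      stop("phantom_spec: core_intensity must be below lesion_intensity")
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 center_mm = as.numeric(center_mm), semi_axes_mm = semi_axes_mm,
                 rotation = as.numeric(rotation),
                 lesion_intensity = lesion_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 lobulation_amplitude = lobulation_amplitude,
                 core = core, seed = as.integer(seed)),
            class = "phantom_spec")
}

euler_matrix <- function(angles) {
  ca <- cos(angles[1]); sa <- sin(angles[1])
  cb <- cos(angles[2]); sb <- sin(angles[2])
  cc <- cos(angles[3]); sc <- sin(angles[3])
  rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cc, sc, 0, -sc, cc), 3, 3)
  rz %*% ry %*% rx
}

# Low-order (degree 2 and 3) real spherical-harmonic style polynomial basis
# evaluated on unit directions; used for the lobulation perturbation.
sph_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(3 * z^2 - 1, x * z, y * z, x^2 - y^2, x * y,
        z * (5 * z^2 - 3), x * (5 * z^2 - 1), y * (5 * z^2 - 1),
        z * (x^2 - y^2), x * y * z, x * (x^2 - 3 * y^2), y * (3 * x^2 - y^2))
}

# Deterministic direction-dependent radial perturbation with sup-norm 1.
make_lobulation_fn <- function(seed) {
  coef <- with_seed(seed + 104729L, rnorm(12))
  # normalize against a fixed quasi-uniform direction sample
  ref <- with_seed(20221L, {
    m <- matrix(rnorm(3000), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  scale <- max(abs(sph_basis(ref) %*% coef))
  function(u) as.numeric(sph_basis(u) %*% coef) / scale
}

# Digitize an (optionally lobulated) rotated ellipsoid: a voxel belongs to
# the mask iff its centre lies inside the surface (no partial volume).
digitize_ellipsoid <- function(grid_shape, spacing, center, semi_axes, rot,
                               lob_amp = 0, lob_fn = NULL) {
  mask <- array(0L, grid_shape)
  r_bound <- semi_axes[1] * (1 + lob_amp)
  lo <- pmax(1L, floor((center - r_bound) / spacing) + 1L)
  hi <- pmin(grid_shape, ceiling((center + r_bound) / spacing) + 1L)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  xs <- (ix - 1) * spacing[1] - center[1]
  ys <- (iy - 1) * spacing[2] - center[2]
  zs <- (iz - 1) * spacing[3] - center[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  u <- g %*% rot  # = t(R) %*% offset, in lesion frame
  q <- sweep(u, 2, semi_axes, "/")
  rho <- sqrt(rowSums(q^2))
  if (lob_amp > 0) {
    dirs <- q / pmax(rho, .Machine$double.eps)
    inside <- rho <= 1 + lob_amp * lob_fn(dirs)
  } else {
    inside <- rho <= 1
  }
  sub <- array(0L, c(length(ix), length(iy), length(iz)))
  sub[inside] <- 1L
  mask[ix, iy, iz] <- sub
  mask
}

#' Closed-form geometry of an unlobulated phantom
#'
#' For a pure ellipsoid the ground truth is analytic: volume
#' `(4/3) pi a b c`, maximum 3D diameter `2a`, covariance-based
#' maximal/minimal axis lengths `4a/sqrt(5)` and `4b/sqrt(5)` (the second
#' moment of a uniform solid ellipsoid along a semi-axis `s` is `s^2/5`),
#' and the core volume if a core is present. Refuses lobulated specs,
#' which have no closed form.
#'
#' @param spec A [phantom_spec()] with `lobulation_amplitude = 0`.
#' @param rules Staging thresholds, see [staging_rules()].
#' @param stage_by Which diameter drives staging: `"maximal"` (covariance
#'   major-axis length, default) or `"max3d"` (maximum 3D diameter).
#' @return A list of class `ground_truth` with the analytic quantities and
#'   the true T stage.
#' @export
analytic_geometry <- function(spec, rules = staging_rules(), stage_by = c("maximal", "max3d")) {
  stopifnot(inherits(spec, "phantom_spec"))
  stage_by <- match.arg(stage_by)
  if (spec$lobulation_amplitude > 0)
    stop("analytic_geometry: no closed form for lobulated phantoms")
  ax <- spec$semi_axes_mm
  vol <- 4 / 3 * pi * prod(ax)
  core_vol <- if (is.null(spec$core)) 0 else 4 / 3 * pi * prod(spec$core$core_semi_axes_mm)
  maximal <- 4 * ax[1] / sqrt(5)
  minimal <- 4 * ax[2] / sqrt(5)
  d_stage <- if (stage_by == "maximal") maximal else 2 * ax[1]
  structure(list(analytic_volume_mm3 = vol,
                 analytic_max_diameter_mm = 2 * ax[1],
                 analytic_maximal_diameter_mm = maximal,
                 analytic_minimal_diameter_mm = minimal,
                 staging_diameter_mm = d_stage,
                 t_stage_true = as.character(classify_t_stage(d_stage, rules)),
                 core_volume_mm3 = core_vol),
            class = "ground_truth")
}

#' Generate one phantom volume + ground-truth mask
#'
#' Digitizes the lesion by the voxel-centre-inside rule, paints intensities
#' (background, lesion, optional core), and adds Gaussian noise. Fully
#' deterministic for a fixed `spec$seed`.
#'
#' @inheritParams analytic_geometry
#' @return A list with elements `volume` ([volume3d()]), `mask`
#'   ([mask3d()]), `core_mask` (or `NULL`) and `truth` (a `ground_truth`
#'   record; analytic fields are `NA` for lobulated phantoms).
#' @export
generate_phantom <- function(spec, rules = staging_rules(), stage_by = c("maximal", "max3d")) {
  stopifnot(inherits(spec, "phantom_spec"))
  stage_by <- match.arg(stage_by)
  rot <- euler_matrix(spec$rotation)
  lob_fn <- if (spec$lobulation_amplitude > 0) make_lobulation_fn(spec$seed) else NULL
  mask <- digitize_ellipsoid(spec$grid_shape, spec$spacing_mm, spec$center_mm,
                             spec$semi_axes_mm, rot,
                             spec$lobulation_amplitude, lob_fn)
  core_mask <- NULL
  dat <- array(spec$background_intensity, spec$grid_shape)
  dat[mask == 1L] <- spec$lesion_intensity
  if (!is.null(spec$core)) {
    core_mask <- digitize_ellipsoid(spec$grid_shape, spec$spacing_mm, spec$center_mm,
                                    spec$core$core_semi_axes_mm, rot)
    core_mask <- core_mask * mask  # core is part of the lesion by construction
    dat[core_mask == 1L] <- spec$core$core_intensity
  }
  if (spec$noise_sd > 0)
    dat <- dat + with_seed(spec$seed, array(rnorm(length(dat), 0, spec$noise_sd),
                                            spec$grid_shape))
  truth <- if (spec$lobulation_amplitude == 0) {
    analytic_geometry(spec, rules, stage_by)
  } else {
    structure(list(analytic_volume_mm3 = NA_real_,
                   analytic_max_diameter_mm = NA_real_,
                   analytic_maximal_diameter_mm = NA_real_,
                   analytic_minimal_diameter_mm = NA_real_,
                   staging_diameter_mm = NA_real_,
                   t_stage_true = NA_character_,
                   core_volume_mm3 = if (is.null(spec$core)) 0 else NA_real_),
              class = "ground_truth")
  }
  truth$mask <- mask3d(mask, spec$spacing_mm)
  list(volume = volume3d(dat, spec$spacing_mm),
       mask = truth$mask,
       core_mask = if (is.null(core_mask)) NULL else mask3d(core_mask, spec$spacing_mm),
       truth = truth)
}

# Integer stage counts from proportions: floor + largest remainder.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    idx <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[idx] <- k[idx] + 1
  }
  as.integer(k)
}

#' Generate a simulated cohort on disk
#'
#' Writes `n` phantom image/mask NIfTI pairs plus a CSV manifest holding
#' the file paths and the closed-form ground truth (semi-axes, volume,
#' staging diameter, T stage, core volume, per-case seed). Stage counts
#' follow `stage_mix` up to largest-remainder rounding; per-stage lesion
#' sizes are drawn with a 2 mm interior margin from the stage boundaries so
#' the true stage is well defined for the digitized masks. Lobulated
#' cohorts (`lobulation_amplitude > 0`) have no closed-form truth; their
#' analytic columns are `NA` except the voxel-counted `volume_mm3`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Number of cases.
#' @param stage_mix Proportions over `(T1, T2, T3)`; must sum to 1. The
#'   default mirrors a clinically imbalanced 23/72/5 percent mix.
#' @param core_fraction Probability that a case has a hypointense core.
#' @param seed Master seed; per-case seeds are derived from it.
#' @param spacing_mm Voxel spacing for all cases.
#' @param lobulation_amplitude Radial perturbation fraction for all cases.
#' @param noise_sd,lesion_intensity,background_intensity,core_intensity
#'   Intensity model, see [phantom_spec()].
#' @param rules,stage_by Staging configuration, see [analytic_geometry()].
#' @return The manifest as a `cohort_manifest` data.frame (invisibly the
#'   same CSV is at `file.path(out_dir, "manifest.csv")`).
#' @export
generate_cohort <- function(out_dir, n,
                            stage_mix = c(T1 = 0.23, T2 = 0.72, T3 = 0.05),
                            core_fraction = 0.15,
                            seed = 1L,
                            spacing_mm = c(0.7, 0.7, 1.1),
                            lobulation_amplitude = 0,
                            noise_sd = 20,
                            lesion_intensity = 300,
                            background_intensity = 50,
                            core_intensity = 100,
                            rules = staging_rules(),
                            stage_by = c("maximal", "max3d")) {
  stage_by <- match.arg(stage_by)
  if (n < 1) stop("generate_cohort: n must be >= 1")
  if (abs(sum(stage_mix) - 1) > 1e-8)
    stop("generate_cohort: stage_mix must sum to 1")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("generate_cohort: cannot create output directory: ", out_dir)
  }
  counts <- apportion(n, stage_mix)
  stages <- rep(c("T1", "T2", "T3"), counts)
  case_seeds <- derive_seeds(seed, n)
  # staging-diameter sampling windows, 2 mm inside each stage's range
  win <- list(T1 = c(8, rules$t1_max_mm - 2),
              T2 = c(rules$t1_max_mm + 2, rules$t2_max_mm - 2),
              T3 = c(rules$t2_max_mm + 2, rules$t2_max_mm + 20))
  stage_factor <- if (stage_by == "maximal") 4 / sqrt(5) else 2
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- with_seed(case_seeds[i], {
      d <- runif(1, win[[stages[i]]][1], win[[stages[i]]][2])
      a <- d / stage_factor
      b <- a * runif(1, 0.6, 0.95)
      cc <- b * runif(1, 0.7, 1.0)
      rotation <- runif(3, 0, 2 * pi)
      has_core <- runif(1) < core_fraction
      core_f <- runif(1, 0.25, 0.4)
      jitter <- runif(3, -2, 2)
      list(d = d, axes = c(a, b, cc), rotation = rotation,
           has_core = has_core, core_f = core_f, jitter = jitter)
    })
    r_bound <- ci$axes[1] * (1 + lobulation_amplitude)
    grid <- as.integer(ceiling((2 * r_bound + 10) / spacing_mm)) + 1L
    center <- (grid - 1) * spacing_mm / 2 + ci$jitter
    core <- if (ci$has_core)
      list(core_semi_axes_mm = ci$axes * ci$core_f, core_intensity = core_intensity)
    spec <- phantom_spec(grid_shape = grid, spacing_mm = spacing_mm,
                         center_mm = center, semi_axes_mm = ci$axes,
                         rotation = ci$rotation,
                         lesion_intensity = lesion_intensity,
                         background_intensity = background_intensity,
                         noise_sd = noise_sd,
                         lobulation_amplitude = lobulation_amplitude,
                         core = core, seed = case_seeds[i])
    ph <- generate_phantom(spec, rules, stage_by)
    case_id <- sprintf("case_%03d", i)
    img_name <- paste0(case_id, "_image.nii.gz")
    msk_name <- paste0(case_id, "_mask.nii.gz")
    write_volume(ph$volume, file.path(out_dir, img_name))
    write_volume(ph$mask, file.path(out_dir, msk_name))
    vol_mm3 <- if (lobulation_amplitude == 0) ph$truth$analytic_volume_mm3 else
      sum(ph$mask$data) * prod(spacing_mm)
    rows[[i]] <- data.frame(case_id = case_id,
                            image_path = img_name, mask_path = msk_name,
                            a_mm = ci$axes[1], b_mm = ci$axes[2], c_mm = ci$axes[3],
                            volume_mm3 = vol_mm3,
                            t_stage = if (lobulation_amplitude == 0) ph$truth$t_stage_true else stages[i],
                            staging_diameter_mm = ph$truth$staging_diameter_mm,
                            core_volume_mm3 = ph$truth$core_volume_mm3,
                            seed = case_seeds[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  read_manifest(file.path(out_dir, "manifest.csv"))
}
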