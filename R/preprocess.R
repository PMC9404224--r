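#' Percentile-clamped z-score normalization
#'
#' Clips voxels to the `[lower_pct, upper_pct]` percentile range of the
#' volume, then standardizes with the mean and SD of the clipped volume:
#' `(x - mean) / max(sd, epsilon)`. Statistics are per case and computed
#' over the whole clipped volume. A constant volume returns all zeros with
#' a warning (the epsilon guard).
#'
#' @param vol A [volume3d()].
#' @param lower_pct,upper_pct Clamping percentiles (defaults 0.5 / 99.5).
#' @param epsilon Guard for near-zero SD.
#' @return `list(volume = <normalized volume3d>, params = <list>)` where
#'   `params` records the clip bounds, mean and SD actually used.
#' @export
clamp_normalize <- function(vol, lower_pct = 0.5, upper_pct = 99.5, epsilon = 1e-8) {
  stopifnot(inherits(vol, "volume3d"))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("clamp_normalize: need 0 <= lower_pct < upper_pct <= 100")
  x <- vol$data
  q <- stats::quantile(x, c(lower_pct, upper_pct) / 100, names = FALSE)
  x <- pmin(pmax(x, q[1]), q[2])
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < epsilon) {
    warning("clamp_normalize: (near-)constant volume; returning zeros")
    x[] <- 0
    s_used <- epsilon
  } else {
    s_used <- s
    x <- (x - m) / s_used
  }
  list(volume = volume3d(x, vol$spacing, vol$origin),
       params = list(lower_pct = lower_pct, upper_pct = upper_pct,
                     clip = q, mean = m, sd = s_used, epsilon = epsilon))
}

#' Mean spacing of a cohort
#'
#' The per-axis arithmetic mean of the case spacings defines the standard
#' target grid that all cases are resampled to before training and
#' inference.
#'
#' @param manifest A `cohort_manifest` (see [read_manifest()]).
#' @return Numeric length-3 spacing in mm.
#' @export
compute_target_spacing <- function(manifest) {
  if (!is.data.frame(manifest) || nrow(manifest) < 1)
    stop("compute_target_spacing: empty manifest")
  sp <- vapply(manifest$image_path, function(p) {
    abs(RNifti::pixdim(RNifti::niftiHeader(p)))[1:3]
  }, numeric(3))
  rowMeans(sp)
}

#' Resample a volume or mask to a target spacing
#'
#' The new grid has `round(old_shape * old_spacing / target_spacing)`
#' voxels per axis (world extent preserved to within one voxel) and shares
#' the origin. Images use trilinear interpolation (`mode = "continuous"`),
#' masks nearest-neighbour (`mode = "nearest"`), which keeps them binary.
#'
#' @param vol A [volume3d()] or [mask3d()].
#' @param target_spacing Positive numeric length 3 (mm).
#' @param mode `"continuous"` or `"nearest"`; defaults to `"nearest"` for
#'   masks and `"continuous"` for volumes.
#' @return The resampled object, same class as the input.
#' @export
resample_volume <- function(vol, target_spacing,
                            mode = if (inherits(vol, "mask3d")) "nearest" else "continuous") {
  stopifnot(inherits(vol, "volume3d") || inherits(vol, "mask3d"))
  mode <- match.arg(mode, c("continuous", "nearest"))
  if (any(target_spacing <= 0)) stop("resample_volume: non-positive target spacing")
  dims <- dim(vol$data)
  odims <- as.integer(round(dims * vol$spacing / target_spacing))
  if (any(odims < 1))
    stop("resample_volume: degenerate output shape ", paste(odims, collapse = "x"))
  out <- resample3_cpp(as.double(vol$data), dims, vol$spacing,
                       odims, as.double(target_spacing), mode == "nearest")
  dim(out) <- odims
  if (inherits(vol, "mask3d")) mask3d(out, target_spacing, vol$origin)
  else volume3d(out, target_spacing, vol$origin)
}

#' Patch sampling configuration
#'
#' @param patch_size Integer length 3; each dimension must be even.
#' @param fg_center_prob Probability that a patch is centred on a
#'   foreground voxel (0.5 = the half-to-half default; 2/3 gives the 2:1
#'   positive:negative alternative).
#' @param samples_per_volume Patches drawn per call to [sample_patches()].
#' @return An object of class `patch_config`.
#' @export
patch_config <- function(patch_size = c(96, 96, 96), fg_center_prob = 0.5,
                         samples_per_volume = 1L) {
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3L || any(patch_size < 2L))
    stop("patch_config: patch_size must be 3 integers >= 2")
  if (any(patch_size %% 2L != 0L))
    stop("patch_config: each patch dimension must be a multiple of 2")
  if (fg_center_prob < 0 || fg_center_prob > 1)
    stop("patch_config: fg_center_prob must lie in [0, 1]")
  structure(list(patch_size = patch_size, fg_center_prob = fg_center_prob,
                 samples_per_volume = as.integer(samples_per_volume)),
            class = "patch_config")
}

# Symmetric zero-padding to at least `size`; returns padded arrays.
pad_to_size <- function(arr, size, value = 0) {
  dims <- dim(arr)
  if (all(dims >= size)) return(arr)
  newd <- pmax(dims, size)
  out <- array(value, newd)
  lo <- (newd - dims) %/% 2 + 1
  out[lo[1]:(lo[1] + dims[1] - 1),
      lo[2]:(lo[2] + dims[2] - 1),
      lo[3]:(lo[3] + dims[3] - 1)] <- arr
  out
}

#' Draw balanced foreground/background patches
#'
#' With probability `fg_center_prob` the patch centre is a uniformly drawn
#' lesion voxel, otherwise a background voxel; centres are then clipped so
#' the patch lies fully inside the (zero-padded) volume. If the mask has no
#' foreground, background centres are used with a warning. Uses the current
#' RNG stream; seed externally for reproducibility.
#'
#' @param vol A (normalized) [volume3d()].
#' @param mask The aligned [mask3d()].
#' @param cfg A [patch_config()].
#' @return List of patch samples, each
#'   `list(image, label, center_index, case_id)`.
#' @param case_id Carried through to the samples for bookkeeping.
#' @export
sample_patches <- function(vol, mask, cfg = patch_config(), case_id = NA_character_) {
  stopifnot(inherits(cfg, "patch_config"))
  validate_pair(vol, mask)
  ps <- cfg$patch_size
  img <- pad_to_size(vol$data, ps)
  lab <- pad_to_size(mask$data, ps)
  dims <- dim(img)
  fg <- which(lab == 1L)
  bg <- which(lab == 0L)
  use_fg_possible <- length(fg) > 0
  if (!use_fg_possible && cfg$fg_center_prob > 0)
    warning("sample_patches: empty foreground; falling back to background centers")
  half <- ps %/% 2
  out <- vector("list", cfg$samples_per_volume)
  for (s in seq_len(cfg$samples_per_volume)) {
    take_fg <- use_fg_possible && runif(1) < cfg$fg_center_prob
    pool <- if (take_fg) fg else bg
    lin <- pool[sample.int(length(pool), 1L)] - 1L
    ctr <- c(lin %% dims[1],
             (lin %/% dims[1]) %% dims[2],
             lin %/% (dims[1] * dims[2])) + 1L
    lo <- pmin(pmax(ctr - half, 1L), dims - ps + 1L)
    hi <- lo + ps - 1L
    out[[s]] <- structure(list(
      image = img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
      label = lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
      center_index = ctr, fg_centered = take_fg, case_id = case_id),
      class = "patch_sample")
  }
  out
}

#' Augmentation configuration
#'
#' Training-time transforms mirroring the usual 3D-segmentation menu:
#' random zoom, random intensity scale, random intensity shift, random
#' Gaussian noise, random in-plane 90-degree rotation, and random elastic
#' deformation (the foreground/background crop choice lives in
#' [patch_config()]). Geometric transforms hit image and label (nearest
#' interpolation for the label); intensity transforms touch the image only.
#' Magnitudes are conservative defaults in normalized-intensity units and
#' are fully configurable; disabling everything yields the identity.
#'
#' @param enable_zoom,enable_intensity_scale,enable_intensity_shift,enable_noise,enable_rot90,enable_elastic
#'   Per-transform switches.
#' @param zoom_range Multiplicative zoom range; must bracket 1.
#' @param scale_range Intensity scale factor range; shift_range additive
#'   shift range; noise_sd_range range of the Gaussian noise SD.
#' @param prob Probability that each enabled transform fires.
#' @param elastic_grid Control points per axis of the coarse displacement
#'   field; elastic_sd its SD in voxels.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(enable_zoom = TRUE, enable_intensity_scale = TRUE,
                           enable_intensity_shift = TRUE, enable_noise = TRUE,
                           enable_rot90 = TRUE, enable_elastic = TRUE,
                           zoom_range = c(0.9, 1.1),
                           scale_range = c(0.9, 1.1),
                           shift_range = c(-0.1, 0.1),
                           noise_sd_range = c(0, 0.1),
                           prob = 0.5,
                           elastic_grid = 4L, elastic_sd = 2) {
  if (zoom_range[1] > 1 || zoom_range[2] < 1)
    stop("augment_config: zoom_range must bracket 1.0")
  if (prob < 0 || prob > 1) stop("augment_config: prob must lie in [0, 1]")
  structure(list(enable_zoom = enable_zoom,
                 enable_intensity_scale = enable_intensity_scale,
                 enable_intensity_shift = enable_intensity_shift,
                 enable_noise = enable_noise,
                 enable_rot90 = enable_rot90,
                 enable_elastic = enable_elastic,
                 zoom_range = zoom_range, scale_range = scale_range,
                 shift_range = shift_range, noise_sd_range = noise_sd_range,
                 prob = prob, elastic_grid = as.integer(elastic_grid),
                 elastic_sd = elastic_sd),
            class = "augment_config")
}

# Rotate a 3D array by k*90 degrees in the (axis1, axis2) plane.
rot90_3d <- function(arr, k, axes = c(1, 2)) {
  k <- k %% 4
  if (k == 0) return(arr)
  perm <- seq_along(dim(arr))
  perm[axes] <- axes[c(2, 1)]
  for (i in seq_len(k)) {
    arr <- aperm(arr, perm)
    idx <- rep(list(quote(expr = )), 3)
    idx[[axes[1]]] <- dim(arr)[axes[1]]:1
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  arr
}

# Warp by a dense displacement (voxel units); nearest keeps labels binary.
apply_warp <- function(arr, disp, nearest) {
  out <- warp3_cpp(as.double(arr), dim(arr),
                   as.double(disp[[1]]), as.double(disp[[2]]), as.double(disp[[3]]),
                   nearest)
  dim(out) <- dim(arr)
  out
}

# Zoom about the patch centre: displacement is linear in the offset.
zoom_disp <- function(dims, factor) {
  ctr <- (dims - 1) / 2
  f <- 1 / factor - 1
  list(array(f * (seq_len(dims[1]) - 1 - ctr[1]), dims),
       aperm(array(f * (seq_len(dims[2]) - 1 - ctr[2]), dims[c(2, 1, 3)]), c(2, 1, 3)),
       aperm(array(f * (seq_len(dims[3]) - 1 - ctr[3]), dims[c(3, 2, 1)]), c(3, 2, 1)))
}

# Coarse random field upsampled to the patch grid.
elastic_disp <- function(dims, grid, sd) {
  lapply(1:3, function(a) {
    coarse <- array(rnorm(grid^3, 0, sd), rep(grid, 3))
    up <- resample3_cpp(as.double(coarse), rep(grid, 3L),
                        (dims - 1) / (grid - 1), dims, c(1, 1, 1), FALSE)
    dim(up) <- dims
    up
  })
}

#' Apply training-time augmentation to a patch
#'
#' Transform order: zoom, in-plane 90-degree rotation, elastic deformation
#' (all geometric, label warped with nearest interpolation), then intensity
#' scale, shift and Gaussian noise on the image only. Draws from the
#' current RNG stream.
#'
#' @param sample A patch sample from [sample_patches()].
#' @param cfg An [augment_config()].
#' @return The augmented patch sample; the label stays binary.
#' @export
augment_patch <- function(sample, cfg = augment_config()) {
  stopifnot(inherits(sample, "patch_sample"), inherits(cfg, "augment_config"))
  img <- sample$image
  lab <- sample$label
  dims <- dim(img)
  if (cfg$enable_zoom && runif(1) < cfg$prob) {
    f <- runif(1, cfg$zoom_range[1], cfg$zoom_range[2])
    d <- zoom_disp(dims, f)
    img <- apply_warp(img, d, FALSE)
    lab <- round(apply_warp(lab, d, TRUE))
  }
  if (cfg$enable_rot90 && runif(1) < cfg$prob) {
    k <- sample.int(4L, 1L) - 1L
    if (dims[1] != dims[2] && k %% 2L == 1L) k <- 2L  # keep non-square patches shaped
    img <- rot90_3d(img, k)
    lab <- rot90_3d(lab, k)
  }
  if (cfg$enable_elastic && runif(1) < cfg$prob) {
    d <- elastic_disp(dims, cfg$elastic_grid, cfg$elastic_sd)
    img <- apply_warp(img, d, FALSE)
    lab <- round(apply_warp(lab, d, TRUE))
  }
  if (cfg$enable_intensity_scale && runif(1) < cfg$prob)
    img <- img * runif(1, cfg$scale_range[1], cfg$scale_range[2])
  if (cfg$enable_intensity_shift && runif(1) < cfg$prob)
    img <- img + runif(1, cfg$shift_range[1], cfg$shift_range[2])
  if (cfg$enable_noise && runif(1) < cfg$prob) {
    nsd <- runif(1, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
    if (nsd > 0) img <- img + array(rnorm(length(img), 0, nsd), dims)
  }
  storage.mode(lab) <- "integer"
  structure(list(image = img, label = lab, center_index = sample$center_index,
                 fg_centered = sample$fg_centered, case_id = sample$case_id),
            class = "patch_sample")
}
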