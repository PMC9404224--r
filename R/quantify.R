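#' Connected-component labelling of a binary mask
#'
#' @param mask A [mask3d()] (or plain 3D binary array).
#' @param connectivity 26 (default) or 6.
#' @return Integer 3D array of labels (0 = background), components numbered
#'   in order of their seed voxel (smallest linear index).
#' @export
label_components <- function(mask, connectivity = 26) {
  arr <- if (inherits(mask, "mask3d")) mask$data else mask
  if (!connectivity %in% c(6, 26))
    stop("label_components: connectivity must be 6 or 26")
  lab <- label_components_cpp(as.integer(arr), dim(arr), as.integer(connectivity))
  n <- attr(lab, "n_components")
  dim(lab) <- dim(arr)
  attr(lab, "n_components") <- n
  lab
}

#' Keep only the largest connected component
#'
#' Tumors are agglomerate regions, so all measurements run on the maximum
#' connected component of the predicted mask. Ties are broken
#' deterministically in favour of the component whose seed voxel has the
#' smallest linear index. An empty mask is returned unchanged with a
#' warning.
#'
#' @inheritParams label_components
#' @return A [mask3d()] containing exactly one component (or empty).
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "mask3d"))
  lab <- label_components(mask, connectivity)
  k <- attr(lab, "n_components")
  if (k == 0L) {
    warning("largest_component: empty mask")
    return(mask)
  }
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which.max(sizes)  # first max = smallest seed index
  out <- array(0L, dim(mask$data))
  out[lab == keep] <- 1L
  mask3d(out, mask$spacing, mask$origin)
}

#' Remove small connected components
#'
#' Deletes every foreground component with strictly fewer than
#' `min_voxels` voxels (a 30-voxel component survives the default).
#'
#' @inheritParams label_components
#' @param min_voxels Components with fewer voxels than this are removed.
#' @return A filtered [mask3d()].
#' @export
filter_small_components <- function(mask, min_voxels = 30, connectivity = 26) {
  stopifnot(inherits(mask, "mask3d"))
  if (min_voxels <= 0) return(mask)
  lab <- label_components(mask, connectivity)
  k <- attr(lab, "n_components")
  if (k == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  drop <- which(sizes < min_voxels)
  if (length(drop)) {
    out <- mask$data
    out[array(lab %in% drop, dim(out))] <- 0L
    return(mask3d(out, mask$spacing, mask$origin))
  }
  mask
}

# Voxel-centre world coordinates (mm) of foreground voxels, as an n x 3 matrix.
mask_coords_mm <- function(mask, which_idx = NULL) {
  dims <- dim(mask$data)
  idx <- if (is.null(which_idx)) which(mask$data == 1L) else which_idx
  idx0 <- idx - 1L
  cbind((idx0 %% dims[1]) * mask$spacing[1],
        ((idx0 %/% dims[1]) %% dims[2]) * mask$spacing[2],
        (idx0 %/% (dims[1] * dims[2])) * mask$spacing[3])
}

#' Shape and volume features of a lesion mask
#'
#' Computes the standard radiomics shape set for a single lesion (run
#' [largest_component()] first):
#' * `max_3d_diameter_mm` - maximum pairwise Euclidean distance between
#'   foreground voxel centres (attained on surface voxels);
#' * `mesh_volume_mm3` - volume enclosed by the iso-surface of the binary
#'   mask at level 0.5 (marching-tetrahedra decomposition);
#' * `maximal_diameter_mm` / `minimal_diameter_mm` - major and minor axis
#'   lengths `4*sqrt(lambda_1)`, `4*sqrt(lambda_2)` from the eigenvalues
#'   `lambda_1 >= lambda_2 >= lambda_3` of the sample covariance of the
#'   foreground voxel-centre coordinates in mm (the moment-matched
#'   ellipsoid fit; for a uniform solid ellipsoid this is `4a/sqrt(5)`,
#'   not `2a`);
#' * `voxel_volume_mm3` - foreground count times the voxel volume, exactly.
#'
#' A single-voxel mask reports zero diameters with a warning; an empty
#' mask reports all zeros with a warning.
#'
#' @param mask A [mask3d()].
#' @return An object of class `lesion_geometry` (a named list).
#' @export
compute_geometry <- function(mask) {
  stopifnot(inherits(mask, "mask3d"))
  n <- sum(mask$data)
  voxvol <- prod(mask$spacing)
  if (n == 0L) {
    warning("compute_geometry: empty mask; all features are zero")
    return(structure(list(max_3d_diameter_mm = 0, mesh_volume_mm3 = 0,
                          maximal_diameter_mm = 0, minimal_diameter_mm = 0,
                          voxel_volume_mm3 = 0, n_voxels = 0L),
                     class = "lesion_geometry"))
  }
  if (n == 1L)
    warning("compute_geometry: single-voxel mask; diameters are zero")
  surf <- surface_voxels_cpp(as.integer(mask$data), dim(mask$data))
  max3d <- if (n >= 2) max_pairwise_dist_cpp(mask_coords_mm(mask, surf)) else 0
  if (n >= 2) {
    cm <- mask_coords_mm(mask)
    ev <- sort(eigen(stats::cov(cm), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    maximal <- 4 * sqrt(ev[1])
    minimal <- 4 * sqrt(ev[2])
  } else {
    maximal <- minimal <- 0
  }
  meshvol <- tetra_mesh_volume_cpp(as.integer(mask$data), dim(mask$data),
                                   mask$spacing, 0.5)
  structure(list(max_3d_diameter_mm = max3d,
                 mesh_volume_mm3 = meshvol,
                 maximal_diameter_mm = maximal,
                 minimal_diameter_mm = minimal,
                 voxel_volume_mm3 = n * voxvol,
                 n_voxels = as.integer(n)),
            class = "lesion_geometry")
}

#' @export
print.lesion_geometry <- function(x, ...) {
  cat(sprintf(paste0("<lesion_geometry> max 3D diameter %.2f mm | mesh volume %.1f mm3 | ",
                     "maximal/minimal diameter %.2f/%.2f mm | voxel volume %.1f mm3 (%d voxels)\n"),
              x$max_3d_diameter_mm, x$mesh_volume_mm3, x$maximal_diameter_mm,
              x$minimal_diameter_mm, x$voxel_volume_mm3, x$n_voxels))
  invisible(x)
}

#' Otsu histogram threshold
#'
#' Bins the intensities into `n_bins` equal-width bins and exhaustively
#' searches the bin edges for the cut that minimizes the within-class
#' variance (equivalently maximizes the between-class variance) of the
#' histogram. When several cuts tie (a flat stretch of empty bins between
#' two well-separated modes), the middle of the tying plateau is taken, so
#' the threshold falls centrally in the gap. The returned threshold is the
#' upper edge of the last class-0 bin and lies strictly between the
#' minimum and maximum intensity.
#'
#' @param intensities Numeric vector (at least two distinct values).
#' @param n_bins Number of histogram bins (default 128).
#' @return The scalar threshold; values `< threshold` form the lower class.
#' @export
otsu_threshold <- function(intensities, n_bins = 128) {
  x <- intensities[is.finite(intensities)]
  if (length(unique(x)) < 2)
    stop("otsu_threshold: degenerate histogram (fewer than 2 distinct values)")
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  mu <- mids
  w0 <- cumsum(w)[-n_bins]
  m0 <- cumsum(w * mu)[-n_bins]
  mT <- sum(w * mu)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  # between-class variance for a cut after bin k
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mT * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  mx <- max(sigma_b)
  ties <- which(sigma_b >= mx - 1e-9 * max(1, abs(mx)))
  k <- ties[ceiling(length(ties) / 2)]  # plateau midpoint
  edges[k + 1]
}

#' Otsu-based cystic/necrotic decomposition of a lesion
#'
#' Thresholds the in-lesion intensity histogram with [otsu_threshold()];
#' in-lesion voxels below the threshold form the candidate cystic/necrotic
#' region, from which connected components with fewer than
#' `min_component_voxels` voxels are removed as outliers. When the
#' histogram is degenerate no cystic component is reported.
#'
#' @param vol The intensity [volume3d()].
#' @param lesion The lesion [mask3d()] (non-empty).
#' @param min_component_voxels Small-component threshold (default 30).
#' @param n_bins Histogram bins for the Otsu search.
#' @param connectivity Component connectivity (26 or 6).
#' @return `list(cyst_mask = <mask3d>, report = <cystic_report>)`; the
#'   report carries the threshold, cystic volume (mm3), mean intensities
#'   of lesion and cyst, and the surviving component count.
#' @export
segment_cystic <- function(vol, lesion, min_component_voxels = 30,
                           n_bins = 128, connectivity = 26) {
  validate_pair(vol, lesion)
  inlesion <- vol$data[lesion$data == 1L]
  if (length(inlesion) == 0) stop("segment_cystic: empty lesion mask")
  lesion_mean <- mean(inlesion)
  empty_report <- function(thr) {
    structure(list(otsu_threshold = thr, cyst_volume_mm3 = 0,
                   cyst_mean_intensity = NA_real_,
                   lesion_mean_intensity = lesion_mean,
                   n_cyst_components = 0L),
              class = "cystic_report")
  }
  empty_mask <- mask3d(array(0L, dim(lesion$data)), lesion$spacing, lesion$origin)
  thr <- tryCatch(otsu_threshold(inlesion, n_bins), error = function(e) NULL)
  if (is.null(thr))
    return(list(cyst_mask = empty_mask, report = empty_report(NA_real_)))
  cyst <- array(0L, dim(lesion$data))
  cyst[lesion$data == 1L & vol$data < thr] <- 1L
  cyst <- filter_small_components(mask3d(cyst, lesion$spacing, lesion$origin),
                                  min_component_voxels, connectivity)
  ncomp <- attr(label_components(cyst, connectivity), "n_components")
  nvox <- sum(cyst$data)
  report <- if (nvox == 0) empty_report(thr) else
    structure(list(otsu_threshold = thr,
                   cyst_volume_mm3 = nvox * prod(lesion$spacing),
                   cyst_mean_intensity = mean(vol$data[cyst$data == 1L]),
                   lesion_mean_intensity = lesion_mean,
                   n_cyst_components = as.integer(ncomp)),
              class = "cystic_report")
  list(cyst_mask = cyst, report = report)
}

#' T-staging thresholds
#'
#' AJCC-consistent size categories by the longest tumor dimension:
#' T1 up to `t1_max_mm`, T2 above that and up to `t2_max_mm`, T3 beyond.
#' Upper bounds are inclusive (`d = 20` is T1, `d = 50` is T2).
#'
#' @param t1_max_mm,t2_max_mm Stage upper bounds in mm.
#' @return An object of class `staging_rules`.
#' @export
staging_rules <- function(t1_max_mm = 20, t2_max_mm = 50) {
  if (!(t1_max_mm > 0 && t2_max_mm > t1_max_mm))
    stop("staging_rules: need 0 < t1_max_mm < t2_max_mm")
  structure(list(t1_max_mm = t1_max_mm, t2_max_mm = t2_max_mm),
            class = "staging_rules")
}

#' Classify tumor T stage from a diameter
#'
#' @param diameter_mm Non-negative diameter(s) in mm.
#' @param rules A [staging_rules()].
#' @return Factor with levels `T1`, `T2`, `T3` (vectorized).
#' @export
classify_t_stage <- function(diameter_mm, rules = staging_rules()) {
  stopifnot(inherits(rules, "staging_rules"))
  if (any(!is.finite(diameter_mm)) || any(diameter_mm < 0))
    stop("classify_t_stage: diameters must be finite and >= 0")
  out <- ifelse(diameter_mm <= rules$t1_max_mm, "T1",
                ifelse(diameter_mm <= rules$t2_max_mm, "T2", "T3"))
  factor(out, levels = c("T1", "T2", "T3"))
}

#' Quantify one case end to end
#'
#' Convenience wrapper: keep the largest component, compute its geometry,
#' stage it, and optionally decompose cystic/necrotic change.
#'
#' @param vol Intensity [volume3d()].
#' @param mask Segmentation [mask3d()].
#' @param cystic Run the Otsu decomposition as well?
#' @param rules Staging thresholds.
#' @param stage_by `"maximal"` (covariance major axis, default) or
#'   `"max3d"` (maximum 3D diameter) as the staging diameter.
#' @param connectivity Component connectivity.
#' @return List with `geometry`, `t_stage`, and (if requested) `cystic`.
#' @export
quantify_case <- function(vol, mask, cystic = FALSE, rules = staging_rules(),
                          stage_by = c("maximal", "max3d"), connectivity = 26) {
  stage_by <- match.arg(stage_by)
  main <- largest_component(mask, connectivity)
  geom <- compute_geometry(main)
  d <- if (stage_by == "maximal") geom$maximal_diameter_mm else geom$max_3d_diameter_mm
  out <- list(geometry = geom,
              t_stage = classify_t_stage(d, rules),
              staging_diameter_mm = d)
  if (cystic && sum(main$data) > 0)
    out$cystic <- segment_cystic(vol, main)$report
  out
}
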