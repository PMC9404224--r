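#' Inference configuration
#'
#' @param patch_size Sliding-window size (voxels).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @param tta Enable rotation test-time augmentation.
#' @param tta_angles Subset of `c(90, 180, 270)` degrees.
#' @param tta_plane Axis pair for the in-plane rotations (default axial,
#'   axes 1-2).
#' @param min_component_voxels Post-filter threshold: predicted foreground
#'   components with strictly fewer voxels are removed (default 30).
#' @param connectivity 26 (default) or 6.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(patch_size = c(96, 96, 96), overlap = 0.5,
                             tta = FALSE, tta_angles = c(90, 180, 270),
                             tta_plane = c(1, 2),
                             min_component_voxels = 30, connectivity = 26) {
  if (overlap < 0 || overlap >= 1) stop("inference_config: overlap must lie in [0, 1)")
  if (!all(tta_angles %in% c(90, 180, 270)))
    stop("inference_config: tta_angles must be a subset of {90, 180, 270}")
  if (min_component_voxels < 0) stop("inference_config: min_component_voxels must be >= 0")
  structure(list(patch_size = as.integer(patch_size), overlap = overlap,
                 tta = isTRUE(tta), tta_angles = as.integer(tta_angles),
                 tta_plane = as.integer(tta_plane),
                 min_component_voxels = as.integer(min_component_voxels),
                 connectivity = as.integer(connectivity)),
            class = "inference_config")
}

prob_map <- function(probs, spacing, origin) {
  structure(list(probs = probs, spacing = spacing, origin = origin),
            class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<prob_map> %d classes, %s voxels\n", d[1],
              paste(d[-1], collapse = "x")))
  invisible(x)
}

# Probabilities for one patch: a trained model (softmax over the network
# scores) or a user-supplied operator function(patch_3d) -> K x dims array.
predict_patch_probs <- function(model, patch) {
  if (is.function(model)) {
    out <- model(patch)
    stopifnot(length(dim(out)) == 4L)
    return(out)
  }
  m <- as_segvol_model(model)
  fwd <- forward_network(m, patch)
  p <- softmax_probs(fwd$scores)
  array(p, c(nrow(p), dim(patch)))
}

window_starts <- function(n, p, overlap) {
  if (n <= p) return(1L)
  stride <- max(1L, as.integer(round(p * (1 - overlap))))
  s <- seq(1L, n - p + 1L, by = stride)
  if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
  unique(s)
}

#' Sliding-window whole-volume prediction
#'
#' Tiles the (padded) volume with overlapping windows, averages the
#' per-window class probabilities uniformly over covering windows, and
#' crops back to the input grid. Every voxel is covered at least once.
#' The volume must already be respaced and normalized as in training.
#'
#' @param model A `segvol_model`, `segvol_checkpoint`, checkpoint path, or
#'   a function mapping a 3D patch array to a `K x dims` probability
#'   array.
#' @param vol A (preprocessed) [volume3d()].
#' @param cfg An [inference_config()].
#' @return A `prob_map` (per-class probabilities, summing to 1 per voxel).
#' @export
sliding_window_predict <- function(model, vol, cfg = inference_config()) {
  stopifnot(inherits(vol, "volume3d"))
  ps <- cfg$patch_size
  if (!is.function(model)) {
    m <- as_segvol_model(model)
    check_patch_divisibility(m$spec, ps)
  }
  orig_dims <- dim(vol$data)
  img <- pad_to_size(vol$data, ps)
  dims <- dim(img)
  sx <- window_starts(dims[1], ps[1], cfg$overlap)
  sy <- window_starts(dims[2], ps[2], cfg$overlap)
  sz <- window_starts(dims[3], ps[3], cfg$overlap)
  k <- NULL
  psum <- NULL
  wsum <- array(0, dims)
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    xi <- x0:(x0 + ps[1] - 1); yi <- y0:(y0 + ps[2] - 1); zi <- z0:(z0 + ps[3] - 1)
    pr <- predict_patch_probs(model, img[xi, yi, zi])
    if (is.null(psum)) {
      k <- dim(pr)[1]
      psum <- array(0, c(k, dims))
    }
    psum[, xi, yi, zi] <- psum[, xi, yi, zi] + pr
    wsum[xi, yi, zi] <- wsum[xi, yi, zi] + 1
  }
  for (ki in seq_len(k)) psum[ki, , , ] <- psum[ki, , , ] / wsum
  lo <- (dims - orig_dims) %/% 2 + 1
  probs <- psum[, lo[1]:(lo[1] + orig_dims[1] - 1),
                lo[2]:(lo[2] + orig_dims[2] - 1),
                lo[3]:(lo[3] + orig_dims[3] - 1), drop = FALSE]
  prob_map(probs, vol$spacing, vol$origin)
}

# Rotate every class channel of a K x nx x ny x nz probability array.
rotate_probs <- function(probs, k, axes) {
  d <- dim(probs)
  out <- NULL
  for (ki in seq_len(d[1])) {
    r <- rot90_3d(array(probs[ki, , , ], d[-1]), k, axes)
    if (is.null(out)) out <- array(0, c(d[1], dim(r)))
    out[ki, , , ] <- r
  }
  out
}

#' Rotation test-time augmentation
#'
#' Averages the identity sliding-window pass with passes on the volume
#' rotated by each configured angle (90/180/270 degrees in the axial
#' plane), each un-rotated back to native orientation before averaging.
#' Non-square in-plane grids are padded to square for the odd rotations
#' and cropped back. With `cfg$tta = FALSE` this reduces exactly to
#' [sliding_window_predict()].
#'
#' @inheritParams sliding_window_predict
#' @return A `prob_map`.
#' @export
tta_predict <- function(model, vol, cfg = inference_config(tta = TRUE)) {
  if (!cfg$tta) return(sliding_window_predict(model, vol, cfg))
  axes <- cfg$tta_plane
  dims <- dim(vol$data)
  need_square <- dims[axes[1]] != dims[axes[2]]
  side <- max(dims[axes])
  pad_dims <- dims
  pad_dims[axes] <- side
  embed <- function(arr) {
    if (!need_square) return(arr)
    out <- array(0, pad_dims)
    out[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- arr
    out
  }
  maps <- list(sliding_window_predict(model, vol, cfg)$probs)
  base <- embed(vol$data)
  for (ang in cfg$tta_angles) {
    k <- ang %/% 90L
    rotated <- rot90_3d(base, k, axes)
    pm <- sliding_window_predict(model, volume3d(rotated, vol$spacing, vol$origin), cfg)
    back <- rotate_probs(pm$probs, 4L - k, axes)
    if (need_square)
      back <- back[, seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
    maps[[length(maps) + 1L]] <- back
  }
  avg <- Reduce(`+`, maps) / length(maps)
  prob_map(avg, vol$spacing, vol$origin)
}

#' Ensemble prediction over multiple checkpoints
#'
#' Unweighted mean of the member probability maps (each computed with
#' [tta_predict()], so TTA composes with ensembling when enabled). A
#' single member returns that member's map.
#'
#' @param models List of models / checkpoints / checkpoint paths (or
#'   operator functions).
#' @inheritParams sliding_window_predict
#' @return A `prob_map`.
#' @export
ensemble_predict <- function(models, vol, cfg = inference_config()) {
  if (!is.list(models) || length(models) < 1)
    stop("ensemble_predict: need a non-empty list of models")
  nclasses <- vapply(models, function(m) {
    if (is.function(m)) NA_integer_ else as_segvol_model(m)$spec$num_classes
  }, integer(1))
  nc <- unique(nclasses[!is.na(nclasses)])
  if (length(nc) > 1)
    stop("ensemble_predict: members disagree on num_classes: ",
         paste(nc, collapse = ", "))
  maps <- lapply(models, function(m) tta_predict(m, vol, cfg)$probs)
  prob_map(Reduce(`+`, maps) / length(maps), vol$spacing, vol$origin)
}

#' Binarize a probability map and remove small components
#'
#' Voxel label = argmax class (ties resolve to the lower class index, i.e.
#' background); foreground connected components with strictly fewer than
#' `cfg$min_component_voxels` voxels are then deleted (a 30-voxel
#' component survives the default threshold). An empty output mask is
#' legal.
#'
#' @param prob A `prob_map`.
#' @param cfg An [inference_config()].
#' @return A [mask3d()].
#' @export
binarize_and_filter <- function(prob, cfg = inference_config()) {
  stopifnot(inherits(prob, "prob_map"))
  d <- dim(prob$probs)
  k <- d[1]
  flat <- matrix(prob$probs, nrow = k)
  cls <- rep(1L, ncol(flat))
  best <- flat[1, ]
  for (ki in seq_len(k)[-1]) {
    upd <- flat[ki, ] > best
    cls[upd] <- ki
    best[upd] <- flat[ki, upd]
  }
  fg <- array(as.integer(cls == k), d[-1])
  mask <- mask3d(fg, prob$spacing, prob$origin)
  filter_small_components(mask, cfg$min_component_voxels, cfg$connectivity)
}

#' Predict a segmentation mask for a raw volume
#'
#' End-to-end inference for one case: resample to the checkpoint's target
#' spacing, clamp-normalize, run (ensembled, optionally TTA) sliding
#' window prediction, binarize, filter small components, and resample the
#' mask back to the input grid.
#'
#' @param models A model/checkpoint or list of them (ensembled).
#' @param vol The raw intensity [volume3d()].
#' @param cfg An [inference_config()].
#' @return `list(mask = <mask3d on the input grid>, prob = <prob_map on
#'   the inference grid>)`.
#' @export
predict_mask <- function(models, vol, cfg = inference_config()) {
  if (!is.list(models) ||
      inherits(models, c("segvol_model", "segvol_checkpoint")) ||
      is.function(models))
    models <- list(models)
  first <- models[[1]]
  target <- if (!is.function(first)) {
    ck <- if (is.character(first)) load_checkpoint(first) else first
    if (inherits(ck, "segvol_checkpoint")) ck$target_spacing else NULL
  }
  work <- vol
  resampled <- FALSE
  if (!is.null(target) && any(abs(vol$spacing - target) / target > 1e-4)) {
    work <- resample_volume(vol, target, "continuous")
    resampled <- TRUE
  }
  work <- clamp_normalize(work)$volume
  pm <- ensemble_predict(models, work, cfg)
  mask <- binarize_and_filter(pm, cfg)
  if (resampled) {
    back <- resample3_cpp(as.double(mask$data), dim(mask$data), mask$spacing,
                          dim(vol$data), vol$spacing, TRUE)
    dim(back) <- dim(vol$data)
    mask <- mask3d(back, vol$spacing, vol$origin)
  }
  list(mask = mask, prob = pm)
}
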