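#' 3D scalar volume with voxel geometry
#'
#' A `volume3d` couples a 3D numeric array with its voxel spacing (mm) and
#' the world position of voxel `(1,1,1)`'s centre. World coordinates follow
#' `origin + (index - 1) * spacing` on each axis, with axes in the canonical
#' RAS order; every geometric feature downstream is defined in mm through
#' this mapping.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing Positive numeric vector of length 3, voxel size in mm.
#' @param origin Numeric vector of length 3, world position (mm) of the
#'   centre of the first voxel.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array, got ", length(dim(data)), " dimensions")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: `spacing` must be 3 strictly positive values")
  if (any(!is.finite(data)))
    stop("volume3d: `data` contains non-finite voxels")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' Binary label volume aligned to a [volume3d()]
#'
#' @param data 3D array with values in \{0, 1\}.
#' @inheritParams volume3d
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("mask3d: `data` must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("mask3d: `spacing` must be 3 strictly positive values")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask3d: non-binary values found: ", paste(utils::head(setdiff(vals, c(0, 1)), 5), collapse = ", "))
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "mask3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing (%s) mm, intensity [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> %s voxels, spacing (%s) mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              sum(x$data)))
  invisible(x)
}

#' Read a 3D volume or mask from NIfTI
#'
#' Loads a NIfTI-1 file, canonicalizes its axes to the RAS orientation, and
#' returns a [volume3d()] (or [mask3d()] with `as_mask = TRUE`). Rejects
#' non-3D images and non-finite voxel data.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param as_mask Logical; validate and return as a binary [mask3d()].
#' @return A `volume3d` or `mask3d`.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  ndim <- hdr$dim[1]
  if (ndim != 3L)
    stop("read_volume: expected a 3D image, got ", ndim, "D: ", path)
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))  # plain array, no NIfTI baggage
  if (any(!is.finite(dat)))
    stop("read_volume: non-finite voxels in ", path)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  if (as_mask) mask3d(dat, spacing, origin) else volume3d(dat, spacing, origin)
}

#' Read a binary mask from NIfTI
#' @inheritParams read_volume
#' @return A `mask3d`.
#' @export
read_mask <- function(path) read_volume(path, as_mask = TRUE)

#' Write a volume or mask to NIfTI
#'
#' Images are stored as float32, masks as unsigned 8-bit, with the spacing
#' and origin written to the qform/sform (RAS).
#'
#' @param vol A [volume3d()] or [mask3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d") || inherits(vol, "mask3d"))
  img <- RNifti::asNifti(vol$data * 1.0)
  RNifti::pixdim(img) <- vol$spacing
  q <- diag(c(vol$spacing, 1))
  q[1:3, 4] <- vol$origin
  q <- structure(q, code = 2L)
  RNifti::qform(img) <- q
  RNifti::sform(img) <- q
  dtype <- if (inherits(vol, "mask3d")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Check that a volume and a mask share one voxel grid
#'
#' Passes iff shapes match, spacings agree within a relative 1e-4, origins
#' agree within 1e-3 mm, and the mask is binary. Each violated condition is
#' named in the error.
#'
#' @param vol A [volume3d()].
#' @param mask A [mask3d()].
#' @return Invisibly, `list(vol, mask)` when consistent.
#' @export
validate_pair <- function(vol, mask) {
  problems <- character()
  if (!identical(dim(vol$data), dim(mask$data)))
    problems <- c(problems, sprintf("shape mismatch (%s vs %s)",
                                    paste(dim(vol$data), collapse = "x"),
                                    paste(dim(mask$data), collapse = "x")))
  rel <- abs(vol$spacing - mask$spacing) / pmax(vol$spacing, .Machine$double.eps)
  if (any(rel > 1e-4))
    problems <- c(problems, "spacing mismatch")
  if (any(abs(vol$origin - mask$origin) > 1e-3))
    problems <- c(problems, "origin mismatch")
  if (!all(mask$data %in% c(0L, 1L)))
    problems <- c(problems, "non-binary mask")
  if (length(problems))
    stop("validate_pair: ", paste(problems, collapse = "; "))
  invisible(list(vol = vol, mask = mask))
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with one row per case holding at least `case_id`,
#' `image_path` and `mask_path` (relative paths are resolved against the
#' manifest's directory), plus optional ground-truth geometry columns
#' written by [generate_cohort()].
#'
#' @param path CSV path.
#' @param check_files Verify that the referenced image/mask files exist.
#' @return A `data.frame` with class `cohort_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("read_manifest: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "image_path", "mask_path")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_manifest: missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$case_id))
    stop("read_manifest: duplicate case_id values")
  base <- dirname(normalizePath(path))
  for (col in c("image_path", "mask_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  if (check_files) {
    gone <- c(df$image_path[!file.exists(df$image_path)],
              df$mask_path[!file.exists(df$mask_path)])
    if (length(gone))
      stop("read_manifest: missing files: ", paste(utils::head(gone, 3), collapse = ", "))
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}
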