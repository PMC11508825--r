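#' 3D image volume
#'
#' Light container for a 3D scalar grid together with its voxel-to-world
#' affine and voxel spacing. PET volumes carry uptake in Bq/ml, MRI volumes
#' arbitrary units. The affine maps 0-based voxel indices (i, j, k, 1) to
#' world coordinates in millimetres, following the NIfTI convention.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)`.
#' @param spacing voxel size in mm per axis; derived from `affine` when that
#'   is given.
#' @return An object of class `image_volume` with fields `data`, `affine`,
#'   `spacing`.
#' @export
image_volume <- function(data, affine = NULL, spacing = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3D array")
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("image_volume: 'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("image_volume: affine is not invertible")
  if (is.null(spacing))
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be positive and finite")
  if (any(!is.finite(data)))
    stop("image_volume: data contains non-finite values")
  structure(list(data = data, affine = unname(affine), spacing = unname(spacing)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A binary mask on a named grid, carrying the provenance of the delineation
#' (`"flair-drawn"`, `"auto-threshold"` or `"refined"`) and the space it was
#' drawn in.
#'
#' @param data logical (or 0/1) 3D array.
#' @param affine,spacing grid geometry, as for [image_volume()].
#' @param provenance one of `"flair-drawn"`, `"auto-threshold"`, `"refined"`.
#' @param space one of `"mri"`, `"pet"`.
#' @param allow_empty permit an all-`FALSE` mask (used for negative scans).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, affine = NULL, spacing = NULL,
                     provenance = c("flair-drawn", "auto-threshold", "refined"),
                     space = c("pet", "mri"), allow_empty = FALSE) {
  provenance <- match.arg(provenance)
  space <- match.arg(space)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("roi_mask: data values must be binary")
    data <- array(data > 0, dim = dim(data))
  }
  if (!is.logical(data) || length(dim(data)) != 3L)
    stop("roi_mask: 'data' must be a logical 3D array")
  vol <- image_volume(array(0, dim = dim(data)), affine = affine, spacing = spacing)
  if (!any(data) && !allow_empty)
    stop("roi_mask: mask is empty")
  structure(list(data = data, affine = vol$affine, spacing = vol$spacing,
                 provenance = provenance, space = space),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, provenance '%s', space '%s'\n",
              sum(x$data), x$provenance, x$space))
  invisible(x)
}

#' Labeled anatomical atlas
#'
#' Integer-labeled volume plus a lookup table mapping label IDs to structure
#' name, hemisphere and tentorial tier, in the style of a Desikan-Killiany
#' parcellation restricted to the structures the pipeline needs (white
#' matter, caudate, putamen, pallidum, thalamus per hemisphere, pons).
#'
#' @param data integer 3D array; 0 is unlabeled.
#' @param lookup data.frame with columns `label`, `name`, `hemisphere`
#'   (`"left"`, `"right"` or `"midline"`) and `tier` (`"supratentorial"` or
#'   `"subtentorial"`).
#' @param affine,spacing grid geometry, as for [image_volume()].
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(data, lookup, affine = NULL, spacing = NULL) {
  vol <- image_volume(array(0, dim = dim(data)), affine = affine, spacing = spacing)
  storage.mode(data) <- "integer"
  need <- c("label", "name", "hemisphere", "tier")
  if (!is.data.frame(lookup) || !all(need %in% names(lookup)))
    stop("label_atlas: lookup must have columns label, name, hemisphere, tier")
  present <- setdiff(unique(as.vector(data)), 0L)
  missing <- setdiff(present, lookup$label)
  if (length(missing))
    stop("label_atlas: labels present in image but absent from lookup: ",
         paste(missing, collapse = ", "))
  structure(list(data = data, affine = vol$affine, spacing = vol$spacing,
                 lookup = as.data.frame(lookup)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %d labels on a %s grid\n",
              nrow(x$lookup), paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Dynamic (4D) PET series
#'
#' A stack of 3D frames sharing one grid, plus the frame timing parsed from
#' the BIDS sidecar.
#'
#' @param data numeric 4D array (x, y, z, frame).
#' @param timing a [frame_timing()] whose length equals the 4th extent.
#' @param affine,spacing grid geometry, as for [image_volume()].
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, timing, affine = NULL, spacing = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("dynamic_series: 'data' must be a 4D array")
  if (!inherits(timing, "frame_timing"))
    stop("dynamic_series: 'timing' must be a frame_timing object")
  if (length(timing$start) != dim(data)[4])
    stop(sprintf("dynamic_series: sidecar lists %d frames but image has %d",
                 length(timing$start), dim(data)[4]))
  vol <- image_volume(array(0, dim = dim(data)[1:3]), affine = affine, spacing = spacing)
  structure(list(data = data, affine = vol$affine, spacing = vol$spacing,
                 timing = timing),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %d frames of %d x %d x %d, %.0f-%.0f s\n",
              d[4], d[1], d[2], d[3], min(x$timing$start),
              max(x$timing$start + x$timing$duration)))
  invisible(x)
}

#' Extract one frame of a dynamic series as an image volume
#' @param dyn a [dynamic_series()].
#' @param frame frame index (1-based).
#' @return An [image_volume()].
#' @export
get_frame <- function(dyn, frame) {
  stopifnot(inherits(dyn, "dynamic_series"))
  if (frame < 1 || frame > dim(dyn$data)[4]) stop("get_frame: frame out of range")
  image_volume(dyn$data[, , , frame, drop = TRUE], affine = dyn$affine)
}

# Shared-grid check: same dims and affine (within tolerance).
same_grid <- function(a, b, tol = 1e-6) {
  da <- dim(a$data)[1:3]; db <- dim(b$data)[1:3]
  all(da == db) && max(abs(a$affine - b$affine)) < tol
}

stop_grid_mismatch <- function(what) {
  stop(sprintf("grid mismatch: %s must share the same grid (dims and affine)", what))
}

# Map 1-based voxel indices (n x 3) to world mm coordinates.
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

# Map world mm coordinates (n x 3) to continuous 1-based voxel indices.
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE] + 1
}

#' Read a NIfTI file as an image volume or dynamic series
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param timing optional [frame_timing()]; required when the image is 4D.
#' @return An [image_volume()] for 3D images, a [dynamic_series()] for 4D.
#' @export
read_volume <- function(path, timing = NULL) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti header attributes
  nd <- length(dim(arr))
  if (nd == 3L) {
    image_volume(arr, affine = aff)
  } else if (nd == 4L) {
    if (is.null(timing))
      stop("read_volume: 4D image requires frame timing (see read_frame_timing)")
    dynamic_series(arr, timing = timing, affine = aff)
  } else stop("read_volume: expected a 3D or 4D image, got ", nd, "D")
}

#' Write an image volume, mask, atlas or dynamic series to NIfTI
#'
#' Masks and atlases are written with an integer datatype.
#'
#' @param x an [image_volume()], [roi_mask()], [label_atlas()] or
#'   [dynamic_series()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  arr <- x$data
  dt <- "double"
  if (inherits(x, "roi_mask")) { arr <- array(as.integer(arr), dim = dim(arr)); dt <- "int16" }
  if (inherits(x, "label_atlas")) { dt <- "int16" }
  img <- RNifti::asNifti(arr, datatype = dt)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# population standard deviation (divisor n), used for TACs and sub-regions
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a temporary RNG seed, restoring caller RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
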