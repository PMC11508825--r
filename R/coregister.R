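# Spatial transforms and resampling.
#
# A spatial_transform stores the *pull-back* map used for resampling: the
# 4x4 matrix `fixed_to_moving` sends world coordinates of the fixed (target)
# grid to world coordinates of the moving (source) image. Registration
# (estimate_rigid / estimate_nonlinear) returns the transform that, applied
# by resample_image(moving, transform, fixed), best aligns the moving image
# onto the fixed one.

new_transform <- function(kind, matrix, params = NULL, center = c(0, 0, 0)) {
  structure(list(kind = kind, fixed_to_moving = matrix, params = params,
                 center = center),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform> kind '%s'\n", x$kind))
  if (!is.null(x$params)) {
    cat("  params:", paste(signif(x$params, 5), collapse = ", "), "\n")
  }
  invisible(x)
}

rot3 <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Construct a rigid (6 degree-of-freedom) transform
#'
#' Parameterized as three rotations (radians, applied about `center`) and
#' three translations (mm): a fixed-space world point w maps to
#' `R (w - center) + center + translation` in moving space.
#'
#' @param rotation numeric(3), radians about x, y, z.
#' @param translation numeric(3), mm.
#' @param center rotation center in world mm.
#' @param scale optional isotropic scale (used by the low-DOF template
#'   alignment); 1 for a true rigid transform.
#' @return A `spatial_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0), scale = 1) {
  R <- rot3(rotation[1], rotation[2], rotation[3]) * scale
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + translation - R %*% center
  new_transform(if (scale == 1) "rigid" else "nonlinear", m,
                params = c(rotation, translation,
                           if (scale != 1) scale else NULL),
                center = center)
}

#' Identity transform
#' @return A `spatial_transform` with an identity map.
#' @export
identity_transform <- function() {
  new_transform("rigid", diag(4), params = rep(0, 6))
}

#' Invert a spatial transform
#' @param transform a `spatial_transform`.
#' @return The inverse `spatial_transform`.
#' @export
invert_transform <- function(transform) {
  new_transform(transform$kind, solve(transform$fixed_to_moving),
                center = transform$center)
}

#' Compose two transforms
#'
#' `compose_transforms(a, b)` returns the pull-back "through a, then b": the
#' composite maps fixed-space coordinates through `a$fixed_to_moving` and
#' then `b$fixed_to_moving`. Used to carry template-space labels to PET
#' space in a single resampling (template -> MRI composed with MRI -> PET).
#'
#' @param a,b `spatial_transform`s; `a` is applied first.
#' @return A composite `spatial_transform`.
#' @export
compose_transforms <- function(a, b) {
  new_transform("composite", b$fixed_to_moving %*% a$fixed_to_moving)
}

# mapping from 0-based target voxel indices to 0-based moving voxel indices
voxel_map <- function(moving, transform, target) {
  solve(moving$affine) %*% transform$fixed_to_moving %*% target$affine
}

target_voxel_grid <- function(d) {
  n <- prod(d)
  lin <- 0:(n - 1)
  i <- lin %% d[1]
  j <- (lin %/% d[1]) %% d[2]
  k <- lin %/% (d[1] * d[2])
  rbind(i, j, k, 1)
}

#' Resample an image onto a target grid
#'
#' @param image the moving [image_volume()].
#' @param transform a `spatial_transform` whose pull-back maps target world
#'   coordinates to `image` world coordinates.
#' @param target an [image_volume()] (or any object with a grid) defining
#'   the output grid.
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @return An [image_volume()] on the target grid; out-of-field voxels are 0.
#' @export
resample_image <- function(image, transform, target,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  arr <- resample_array(image$data, voxel_map(image, transform, target),
                        dim(target$data)[1:3], interpolation)
  image_volume(arr, affine = target$affine)
}

resample_array <- function(src, M, dout, interpolation) {
  d <- dim(src)
  vox <- target_voxel_grid(dout)
  s <- M %*% vox
  x <- s[1, ]; y <- s[2, ]; z <- s[3, ]
  out <- numeric(prod(dout))
  if (interpolation == "nearest") {
    xi <- round(x) + 1; yi <- round(y) + 1; zi <- round(z) + 1
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out[ok] <- src[cbind(xi[ok], yi[ok], zi[ok])]
  } else {
    eps <- 1e-7
    x <- pmin(pmax(x, -eps), d[1] - 1 + eps)
    y <- pmin(pmax(y, -eps), d[2] - 1 + eps)
    z <- pmin(pmax(z, -eps), d[3] - 1 + eps)
    inside <- s[1, ] >= -eps & s[1, ] <= d[1] - 1 + eps &
      s[2, ] >= -eps & s[2, ] <= d[2] - 1 + eps &
      s[3, ] >= -eps & s[3, ] <= d[3] - 1 + eps
    x0 <- pmin(pmax(floor(x), 0), d[1] - 2)
    y0 <- pmin(pmax(floor(y), 0), d[2] - 2)
    z0 <- pmin(pmax(floor(z), 0), d[3] - 2)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    i0 <- x0 + 1; j0 <- y0 + 1; k0 <- z0 + 1
    v <- function(di, dj, dk) src[cbind(i0 + di, j0 + dj, k0 + dk)]
    val <-
      v(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
      v(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
      v(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
      v(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
      v(1, 1, 0) * fx * fy * (1 - fz) +
      v(1, 0, 1) * fx * (1 - fy) * fz +
      v(0, 1, 1) * (1 - fx) * fy * fz +
      v(1, 1, 1) * fx * fy * fz
    out[inside] <- val[inside]
  }
  array(out, dout)
}

#' Resample labels or a mask with nearest-neighbor interpolation
#'
#' Every output voxel carries the label of its nearest pre-image, so the
#' output label set is always a subset of the input's — interpolation never
#' invents labels.
#'
#' @param labels a [label_atlas()] or [roi_mask()].
#' @param transform a `spatial_transform` (pull-back, as in
#'   [resample_image()]).
#' @param target grid-defining object.
#' @return The same type as `labels`, on the target grid.
#' @export
resample_labels <- function(labels, transform, target) {
  if (inherits(labels, "label_atlas")) {
    arr <- resample_array(labels$data, voxel_map(labels, transform, target),
                          dim(target$data)[1:3], "nearest")
    storage.mode(arr) <- "integer"
    label_atlas(arr, labels$lookup, affine = target$affine)
  } else if (inherits(labels, "roi_mask")) {
    arr <- resample_array(array(as.numeric(labels$data), dim(labels$data)),
                          voxel_map(labels, transform, target),
                          dim(target$data)[1:3], "nearest")
    roi_mask(arr > 0.5, affine = target$affine, provenance = labels$provenance,
             space = labels$space, allow_empty = TRUE)
  } else stop("resample_labels: expected a label_atlas or roi_mask")
}

# Histogram-based mutual information between two equal-length vectors.
mutual_information <- function(a, b, bins = 32) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1, 1), bins)
  joint <- tabulate(ia + bins * (ib - 1), nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
}

# intensity-weighted world centroid
world_centroid <- function(vol) {
  w <- pmax(vol$data, 0)
  if (sum(w) == 0) stop("cannot compute centroid of a nonpositive image")
  idx <- which(w > 0)
  pos <- arrayInd(idx, dim(vol$data))
  wt <- w[idx] / sum(w[idx])
  colSums(voxel_to_world(vol, pos) * wt)
}

# strided copy of a volume (for fast metric evaluation)
subsample_volume <- function(vol, stride) {
  d <- dim(vol$data)
  ix <- seq(1, d[1], by = stride); iy <- seq(1, d[2], by = stride)
  iz <- seq(1, d[3], by = stride)
  aff <- vol$affine %*% diag(c(stride, stride, stride, 1))
  image_volume(vol$data[ix, iy, iz, drop = FALSE], affine = aff)
}

smoothed_copy <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  image_volume(gaussian_smooth3(vol$data, sigma_vox * vol$spacing[1],
                                vol$spacing),
               affine = vol$affine)
}

#' Rigid MRI-to-PET registration
#'
#' Estimates the 6-DOF rigid transform aligning `moving` onto `fixed` by
#' maximizing histogram mutual information (suitable across modalities).
#' Both images are lightly smoothed, the translation is initialized from
#' intensity centroids, and the six parameters are refined by two rounds of
#' Nelder-Mead simplex search on a strided voxel subset.
#'
#' @param moving,fixed [image_volume()]s with valid affines and nonconstant
#'   intensities.
#' @param bins joint-histogram bins for the metric.
#' @param stride voxel stride for metric evaluation.
#' @param smooth_sigma_vox pre-smoothing in voxels.
#' @param maxit Nelder-Mead iteration cap per round.
#' @return A rigid `spatial_transform`; its `params` are
#'   `(rx, ry, rz, tx, ty, tz)` (radians, mm) about the fixed image's
#'   intensity centroid.
#' @export
estimate_rigid <- function(moving, fixed, bins = 32, stride = 2,
                           smooth_sigma_vox = 1, maxit = 400) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  fit <- register_params(moving, fixed, dof = 6, bins = bins, stride = stride,
                         smooth_sigma_vox = smooth_sigma_vox, maxit = maxit)
  rigid_transform(rotation = fit$par[1:3], translation = fit$par[4:6],
                  center = fit$center)
}

#' Template-to-MRI alignment
#'
#' Contract-level stand-in for deformable template registration: estimates a
#' low-DOF global shape alignment (rigid plus isotropic scale, 7 parameters)
#' with the same mutual-information machinery as [estimate_rigid()]. The
#' returned transform plugs into [resample_labels()] /
#' [compose_transforms()] exactly like any other backend's output would.
#'
#' @inheritParams estimate_rigid
#' @param template the moving template volume.
#' @param mri the fixed subject MRI.
#' @return A `spatial_transform` of kind `"nonlinear"` with params
#'   `(rx, ry, rz, tx, ty, tz, scale)`.
#' @export
estimate_nonlinear <- function(template, mri, bins = 32, stride = 2,
                               smooth_sigma_vox = 1, maxit = 400) {
  stopifnot(inherits(template, "image_volume"), inherits(mri, "image_volume"))
  fit <- register_params(template, mri, dof = 7, bins = bins, stride = stride,
                         smooth_sigma_vox = smooth_sigma_vox, maxit = maxit)
  rigid_transform(rotation = fit$par[1:3], translation = fit$par[4:6],
                  center = fit$center, scale = exp(fit$par[7]))
}

register_params <- function(moving, fixed, dof, bins, stride,
                            smooth_sigma_vox, maxit) {
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("registration: degenerate (constant) image")
  mv <- smoothed_copy(moving, smooth_sigma_vox)
  fx <- smoothed_copy(fixed, smooth_sigma_vox)
  fx_sub <- subsample_volume(fx, stride)
  center <- world_centroid(fx)
  t0 <- world_centroid(mv) - center
  par0 <- c(0, 0, 0, t0, if (dof == 7) 0 else NULL)
  fvec <- as.vector(fx_sub$data)
  obj <- function(p) {
    tr <- rigid_transform(rotation = p[1:3], translation = p[4:6],
                          center = center,
                          scale = if (dof == 7) exp(p[7]) else 1)
    res <- resample_image(mv, tr, fx_sub)
    -mutual_information(fvec, as.vector(res$data), bins = bins)
  }
  ps <- c(0.02, 0.02, 0.02, 1, 1, 1, if (dof == 7) 0.02 else NULL)
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, parscale = ps,
                                     reltol = 1e-10))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, parscale = ps / 10,
                                     reltol = 1e-12))
  if (!is.finite(fit$value) || fit$value >= 0)
    stop("registration: optimizer failed to find informative alignment ",
         "(metric ", signif(-fit$value, 4), ")")
  list(par = fit$par, center = center, metric = -fit$value)
}

#' Mean voxel displacement of a transform over a grid
#'
#' Diagnostic used to verify near-identity self-registration.
#'
#' @param transform a `spatial_transform`.
#' @param vol grid-defining [image_volume()].
#' @return Mean displacement magnitude in mm over all voxels.
#' @export
mean_displacement <- function(transform, vol) {
  d <- dim(vol$data)
  vox <- target_voxel_grid(d)
  w <- vol$affine %*% vox
  wm <- transform$fixed_to_moving %*% w
  mean(sqrt(colSums((wm[1:3, , drop = FALSE] - w[1:3, , drop = FALSE])^2)))
}
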