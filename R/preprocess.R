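#' Region growing on a FLAIR volume
#'
#' Grows a connected lesion mask from a seed voxel, mimicking the
#' semi-automatic drawing tool used to delineate FLAIR signal abnormality:
#' a voxel joins the region if it is connected to the seed through voxels
#' that all lie within `max_radius` (world mm) of the seed and differ from
#' the seed intensity by at most `max_diff`. The result is the maximal such
#' connected set.
#'
#' @param flair an [image_volume()].
#' @param seed_voxel integer triple (1-based voxel index).
#' @param max_radius maximum distance from the seed in world mm.
#' @param max_diff maximum absolute intensity difference from the seed value.
#' @param connectivity 6 or 26.
#' @return A [roi_mask()] with provenance `"flair-drawn"`.
#' @export
region_grow <- function(flair, seed_voxel, max_radius, max_diff,
                        connectivity = 6) {
  stopifnot(inherits(flair, "image_volume"))
  d <- dim(flair$data)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1) || any(seed_voxel > d))
    stop("region_grow: seed voxel outside the volume")
  seed_val <- flair$data[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  seed_w <- voxel_to_world(flair, matrix(seed_voxel, 1))
  # eligibility field: intensity window and world-distance ball
  ok_int <- abs(flair$data - seed_val) <= max_diff
  idx <- which(ok_int)
  if (length(idx)) {
    pos <- arrayInd(idx, d)
    w <- voxel_to_world(flair, pos)
    dist <- sqrt(rowSums(sweep(w, 2, as.numeric(seed_w))^2))
    ok <- array(FALSE, d)
    ok[idx[dist <= max_radius + 1e-9]] <- TRUE
  } else ok <- array(FALSE, d)
  ok[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
  lab <- label_components(ok, connectivity)
  seed_lab <- lab[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  grown <- array(lab == seed_lab & lab > 0, dim = d)
  if (sum(grown) == 1L && max_radius > 0 && max_diff > 0)
    warning("region_grow: growth produced a single-voxel mask")
  roi_mask(grown, affine = flair$affine, provenance = "flair-drawn",
           space = "mri")
}

#' Apply a brain mask to a PET volume
#'
#' Zeroes every voxel outside the mask, removing extracerebral (skull)
#' signal before tumor thresholding. The mask must already be on the PET
#' grid.
#'
#' @param pet an [image_volume()].
#' @param brain a [roi_mask()] on the same grid.
#' @return The masked [image_volume()].
#' @export
apply_brain_mask <- function(pet, brain) {
  stopifnot(inherits(pet, "image_volume"), inherits(brain, "roi_mask"))
  if (!same_grid(pet, brain)) stop_grid_mismatch("PET and brain mask")
  out <- pet
  out$data[!brain$data] <- 0
  out
}
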