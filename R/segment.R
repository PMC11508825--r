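#' Compute the SUVr volume
#'
#' Normalizes the brain-masked PET volume to N, the maximum uptake within
#' the eroded contralateral white-matter reference: `SUVr = PET / N`.
#'
#' @param pet brain-masked PET [image_volume()].
#' @param reference reference-region [roi_mask()] on the PET grid.
#' @return An object of class `suvr_volume`: an [image_volume()] with an
#'   extra field `n_value` (the reference maximum, Bq/ml).
#' @export
compute_suvr <- function(pet, reference) {
  stopifnot(inherits(pet, "image_volume"), inherits(reference, "roi_mask"))
  if (!same_grid(pet, reference)) stop_grid_mismatch("PET and reference mask")
  if (!any(reference$data)) stop("compute_suvr: reference mask is empty")
  n_value <- max(pet$data[reference$data])
  if (n_value <= 0)
    stop("compute_suvr: invalid reference (maximum uptake ", n_value, " <= 0)")
  out <- image_volume(pet$data / n_value, affine = pet$affine)
  out$n_value <- n_value
  class(out) <- c("suvr_volume", class(out))
  out
}

#' Threshold the SUVr volume at 1
#'
#' Voxels with uptake strictly above the reference maximum (SUVr > 1) define
#' the raw tumor candidate. The raw set also contains physiologic high-uptake
#' anatomy (striatum, venous sinus); [choose_tumor_voi()] restricts it to the
#' lesion neighborhood before the validity gate.
#'
#' @param suvr a `suvr_volume` from [compute_suvr()].
#' @return A [roi_mask()] with provenance `"auto-threshold"` (possibly
#'   empty).
#' @export
threshold_tumor <- function(suvr) {
  stopifnot(inherits(suvr, "suvr_volume"))
  roi_mask(suvr$data > 1, affine = suvr$affine, provenance = "auto-threshold",
           space = "pet", allow_empty = TRUE)
}

ratio_pair <- function(pet, mask, striatum, reference) {
  if (!any(mask$data)) return(list(t_s = NA_real_, t_n = NA_real_,
                                   tumor_max = NA_real_))
  tmax <- max(pet$data[mask$data])
  smax <- max(pet$data[striatum$data])
  nmax <- max(pet$data[reference$data])
  list(t_s = tmax / smax, t_n = tmax / nmax, tumor_max = tmax)
}

#' Choose the tumor VOI: automatic threshold vs FLAIR-drawn fallback
#'
#' The raw SUVr > 1 candidate is restricted to its connected components that
#' intersect the dilated FLAIR lesion mask (a pure global threshold also
#' picks up striatum and sinus anywhere in the brain). T/S and T/N are then
#' computed for both the restricted automatic candidate and the FLAIR-drawn
#' VOI; the automatic mask is adopted only if all four ratios are strictly
#' greater than 1 and the restricted candidate is nonempty — otherwise the
#' FLAIR-drawn VOI is used. When the two candidates disagree on the gate a
#' note is attached for the pipeline log.
#'
#' @param auto raw auto-threshold [roi_mask()] (from [threshold_tumor()]).
#' @param flair_voi FLAIR-drawn lesion [roi_mask()] in PET space (mandatory).
#' @param pet brain-masked PET [image_volume()].
#' @param striatum assembled striatum [roi_mask()].
#' @param reference eroded reference [roi_mask()].
#' @param flair_dilate_vox dilation radius (voxels) defining the lesion
#'   neighborhood for the component restriction.
#' @param connectivity 6 or 26, for the component analysis.
#' @return An object of class `segmentation_result`: fields `tumor_mask`
#'   (with provenance `"auto-threshold"` iff the gate passed), `t_s`, `t_n`,
#'   `gate_passed`, `candidates` (ratio table for both candidates) and
#'   `notes`.
#' @export
choose_tumor_voi <- function(auto, flair_voi, pet, striatum, reference,
                             flair_dilate_vox = 2, connectivity = 6) {
  stopifnot(inherits(auto, "roi_mask"), inherits(flair_voi, "roi_mask"),
            inherits(pet, "image_volume"))
  if (!same_grid(auto, pet) || !same_grid(flair_voi, pet))
    stop_grid_mismatch("candidate masks and PET")
  if (!any(auto$data) && !any(flair_voi$data))
    stop("choose_tumor_voi: both candidate masks are empty (negative scan)")
  # restrict the raw threshold mask to the lesion neighborhood
  restricted <- auto
  if (any(auto$data) && any(flair_voi$data)) {
    neigh <- dilate_mask_array(flair_voi$data,
                               ball_offsets(max(1, flair_dilate_vox)))
    lab <- label_components(auto$data, connectivity)
    keep <- setdiff(unique(lab[neigh]), 0L)
    restricted$data <- array(lab %in% keep, dim = dim(lab))
  }
  auto_r <- ratio_pair(pet, restricted, striatum, reference)
  flair_r <- ratio_pair(pet, flair_voi, striatum, reference)
  candidates <- data.frame(
    candidate = c("auto-threshold", "flair-drawn"),
    t_s = c(auto_r$t_s, flair_r$t_s),
    t_n = c(auto_r$t_n, flair_r$t_n),
    n_vox = c(sum(restricted$data), sum(flair_voi$data))
  )
  ratios <- c(auto_r$t_s, auto_r$t_n, flair_r$t_s, flair_r$t_n)
  gate <- any(restricted$data) && all(is.finite(ratios)) && all(ratios > 1)
  notes <- character(0)
  auto_ok <- all(is.finite(c(auto_r$t_s, auto_r$t_n))) &&
    all(c(auto_r$t_s, auto_r$t_n) > 1)
  flair_ok <- all(c(flair_r$t_s, flair_r$t_n) > 1)
  if (auto_ok != flair_ok)
    notes <- c(notes, sprintf(
      "gate disagreement: auto candidate %s, FLAIR candidate %s",
      if (auto_ok) "passes" else "fails",
      if (flair_ok) "passes" else "fails"))
  if (gate) {
    chosen <- restricted
    chosen$provenance <- "auto-threshold"
    rat <- auto_r
  } else {
    if (!any(flair_voi$data))
      stop("choose_tumor_voi: gate failed and FLAIR VOI is empty ",
           "(negative scan)")
    chosen <- flair_voi
    chosen$provenance <- "flair-drawn"
    chosen$space <- "pet"
    rat <- flair_r
  }
  structure(list(tumor_mask = chosen, t_s = rat$t_s, t_n = rat$t_n,
                 gate_passed = gate, candidates = candidates, notes = notes),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> gate %s, provenance '%s', T/S = %.4g, T/N = %.4g\n",
    if (x$gate_passed) "passed" else "failed", x$tumor_mask$provenance,
    x$t_s, x$t_n))
  invisible(x)
}
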