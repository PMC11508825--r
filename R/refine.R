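#' Early-frame sinus pseudo-probability map
#'
#' The superior sagittal sinus carries a high blood-pool signal in the first
#' frames of a dynamic acquisition that decays afterwards. A weighted sum of
#' the first two frames, normalized to its maximum, therefore acts as a
#' pseudo-probability map of venous sinus signal.
#'
#' @param dyn a [dynamic_series()] with at least 2 frames.
#' @param w1,w2 weights of the first and second frame.
#' @return An [image_volume()] with values in \[0, 1\] and maximum exactly 1.
#' @export
sinus_probability_map <- function(dyn, w1 = 0.5, w2 = 0.5) {
  stopifnot(inherits(dyn, "dynamic_series"))
  if (dim(dyn$data)[4] < 2L)
    stop("sinus_probability_map: need at least 2 frames")
  m <- w1 * dyn$data[, , , 1] + w2 * dyn$data[, , , 2]
  mx <- max(m)
  if (mx <= 0)
    stop("sinus_probability_map: early frames carry no signal")
  image_volume(pmax(m, 0) / mx, affine = dyn$affine)
}

#' Lesion probability distance map
#'
#' Removes small connected components from the automatic tumor mask,
#' integrates the result with the FLAIR-drawn lesion by logical OR, and
#' smooths the combined indicator with a Gaussian of the given FWHM,
#' renormalized to maximum 1 — a soft map of how close a voxel is to the
#' lesion.
#'
#' @param tumor_auto automatic tumor [roi_mask()].
#' @param flair_voi FLAIR-drawn lesion [roi_mask()] on the same grid.
#' @param min_component_vox components smaller than this are removed.
#' @param fwhm_mm Gaussian full width at half maximum in mm.
#' @param connectivity 6 or 26.
#' @return An [image_volume()] with values in \[0, 1\].
#' @export
lesion_distance_map <- function(tumor_auto, flair_voi, min_component_vox = 10,
                                fwhm_mm = 5, connectivity = 6) {
  stopifnot(inherits(tumor_auto, "roi_mask"), inherits(flair_voi, "roi_mask"))
  if (!same_grid(tumor_auto, flair_voi))
    stop_grid_mismatch("tumor and FLAIR masks")
  filtered <- filter_small_components(tumor_auto, min_component_vox,
                                      connectivity)
  combined <- filtered$data | flair_voi$data
  if (!any(combined))
    stop("lesion_distance_map: combined lesion mask is empty")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sm <- gaussian_smooth3(array(as.numeric(combined), dim(combined)),
                         sigma, tumor_auto$spacing)
  image_volume(sm / max(sm), affine = tumor_auto$affine)
}

#' Remove sinus contamination from the tumor mask
#'
#' For each voxel of the unrefined tumor mask, two features are extracted:
#' the sinus pseudo-probability and the lesion distance probability. A
#' 2-means clustering on these features separates tumor from sinus voxels —
#' the cluster whose centroid has the higher sinus probability is labeled
#' sinus. A linear-kernel SVM is then fitted on the K-means labels and its
#' predictions give the final labels; the returned mask keeps the
#' tumor-labeled voxels. Run only for lesions that passed the T/S and T/N
#' gate and only when dynamic data exist.
#'
#' @param tumor_auto unrefined tumor [roi_mask()] (nonempty).
#' @param sinus_map [sinus_probability_map()] output.
#' @param distance_map [lesion_distance_map()] output.
#' @param seed RNG seed for the K-means initialization.
#' @param svm use the SVM relabeling step (`TRUE`) or the raw K-means labels.
#' @param min_separation minimum distance between the two cluster centroids
#'   along the sinus-probability axis for the split to count as a
#'   tumor-vs-sinus separation; below it the mask is sinus-free and returned
#'   unchanged (blood-pool signal sits near the top of the \[0, 1\] scale,
#'   tumor early uptake far below, so a genuine sinus cluster separates
#'   widely).
#' @return A [roi_mask()] with provenance `"refined"`, plus attributes
#'   `n_removed` (voxels dropped as sinus). If the feature clouds are
#'   degenerate (a single cluster) the input mask is returned unchanged with
#'   a warning.
#' @export
classify_tumor_sinus <- function(tumor_auto, sinus_map, distance_map,
                                 seed = 17L, svm = TRUE,
                                 min_separation = 0.2) {
  stopifnot(inherits(tumor_auto, "roi_mask"))
  if (!same_grid(tumor_auto, sinus_map) || !same_grid(tumor_auto, distance_map))
    stop_grid_mismatch("tumor mask and feature maps")
  if (!any(tumor_auto$data)) stop("classify_tumor_sinus: empty tumor mask")
  idx <- which(tumor_auto$data)
  feats <- cbind(sinus_prob = sinus_map$data[idx],
                 lesion_prob = distance_map$data[idx])
  if (length(idx) < 3L || stats::sd(feats[, 1]) + stats::sd(feats[, 2]) == 0) {
    warning("classify_tumor_sinus: degenerate features; mask unchanged")
    return(tumor_auto)
  }
  km <- with_seed(seed, stats::kmeans(feats, centers = 2, nstart = 5))
  if (any(km$size == 0)) {
    warning("classify_tumor_sinus: clustering collapsed; mask unchanged")
    return(tumor_auto)
  }
  if (abs(diff(km$centers[, "sinus_prob"])) < min_separation) {
    warning("classify_tumor_sinus: clusters do not separate on the sinus ",
            "feature; mask treated as sinus-free and returned unchanged")
    return(tumor_auto)
  }
  sinus_cluster <- which.max(km$centers[, "sinus_prob"])
  labels <- factor(ifelse(km$cluster == sinus_cluster, "sinus", "tumor"),
                   levels = c("tumor", "sinus"))
  if (length(unique(labels)) < 2L) {
    warning("classify_tumor_sinus: all voxels in one cluster; mask unchanged")
    return(tumor_auto)
  }
  final <- labels
  if (svm) {
    fit <- e1071::svm(feats, labels, kernel = "linear", scale = TRUE)
    pred <- stats::predict(fit, feats)
    # the SVM refines the boundary; if it degenerates to one class, keep the
    # K-means labels
    if (length(unique(pred)) == 2L) final <- pred
  }
  keep <- idx[final == "tumor"]
  out <- tumor_auto
  out$data <- array(FALSE, dim(tumor_auto$data))
  out$data[keep] <- TRUE
  out$provenance <- "refined"
  attr(out, "n_removed") <- length(idx) - length(keep)
  out
}
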