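wm_labels <- function(atlas, hemisphere) {
  lut <- atlas$lookup
  lut$label[lut$name == "wm" & lut$hemisphere == hemisphere]
}

#' Determine the tumor hemisphere from atlas overlap
#'
#' Counts tumor-mask voxels overlapping labeled structures: if overlap with
#' subtentorial labels (pons, cerebellum) exceeds all supratentorial overlap
#' the tumor is called subtentorial; otherwise the supratentorial hemisphere
#' with the larger overlap wins. A tie, or a tumor overlapping no labels at
#' all, raises an error asking for a manual `hemisphere` override.
#'
#' @param tumor a [roi_mask()] in atlas/PET space.
#' @param atlas a [label_atlas()] on the same grid.
#' @return One of `"left"`, `"right"`, `"subtentorial"`.
#' @export
determine_hemisphere <- function(tumor, atlas) {
  stopifnot(inherits(tumor, "roi_mask"), inherits(atlas, "label_atlas"))
  if (!same_grid(tumor, atlas)) stop_grid_mismatch("tumor mask and atlas")
  labs <- atlas$data[tumor$data]
  labs <- labs[labs > 0]
  if (length(labs) == 0L)
    stop("determine_hemisphere: tumor overlaps no labeled structure; ",
         "pass an explicit hemisphere override")
  lut <- atlas$lookup
  counts <- table(labs)
  ov <- function(sel) sum(counts[as.character(lut$label[sel])], na.rm = TRUE)
  sub_ov <- ov(lut$tier == "subtentorial")
  left_ov <- ov(lut$tier == "supratentorial" & lut$hemisphere == "left")
  right_ov <- ov(lut$tier == "supratentorial" & lut$hemisphere == "right")
  if (sub_ov > left_ov + right_ov) return("subtentorial")
  if (left_ov == right_ov)
    stop("determine_hemisphere: left/right overlap tie (", left_ov,
         " voxels each); pass an explicit hemisphere override")
  if (left_ov > right_ov) "left" else "right"
}

#' Select the eroded white-matter reference region
#'
#' For hemispheric tumors the white matter of the opposite hemisphere is the
#' reference; for subtentorial tumors the left hemisphere is used by
#' convention. The label union is eroded to mitigate spillover, and the
#' selection is verified against the tumor mask: a nonempty intersection
#' means the reference is contaminated and is an error.
#'
#' @param atlas a [label_atlas()] in PET space.
#' @param tumor_hemisphere `"left"`, `"right"` or `"subtentorial"`.
#' @param erosion_iterations passes of binary erosion (see [erode_labels()]).
#' @param tumor optional [roi_mask()] used for the contamination check.
#' @return A [roi_mask()] of eroded reference white matter.
#' @export
select_reference <- function(atlas, tumor_hemisphere, erosion_iterations = 1,
                             tumor = NULL) {
  stopifnot(inherits(atlas, "label_atlas"))
  ref_hemi <- switch(tumor_hemisphere,
                     left = "right", right = "left",
                     subtentorial = "left",
                     stop("select_reference: unknown hemisphere '",
                          tumor_hemisphere, "'"))
  labs <- wm_labels(atlas, ref_hemi)
  if (length(labs) == 0L)
    stop("select_reference: no white-matter label for hemisphere ", ref_hemi)
  ref <- erode_labels(atlas, labs, iterations = erosion_iterations)
  if (!is.null(tumor)) {
    if (!same_grid(tumor, atlas)) stop_grid_mismatch("tumor mask and atlas")
    if (any(ref$data & tumor$data))
      stop("select_reference: reference region contaminated - tumor mask ",
           "intersects the ", ref_hemi, " white matter (",
           sum(ref$data & tumor$data), " voxels)")
  }
  ref
}

#' Assemble the corpus striatum from atlas labels
#'
#' Union (logical OR) of the caudate, putamen and pallidum labels of the
#' requested side(s). Assembly is idempotent and order-independent.
#'
#' @param atlas a [label_atlas()].
#' @param sides `"both"` (default), `"left"` or `"right"`.
#' @return A [roi_mask()].
#' @export
assemble_striatum <- function(atlas, sides = c("both", "left", "right")) {
  sides <- match.arg(sides)
  lut <- atlas$lookup
  hemis <- if (sides == "both") c("left", "right") else sides
  parts <- c("caudate", "putamen", "pallidum")
  m <- array(FALSE, dim(atlas$data))
  for (h in hemis) for (p in parts) {
    lab <- lut$label[lut$name == p & lut$hemisphere == h]
    if (length(lab) == 0L)
      stop("assemble_striatum: missing label for ", p, " (", h, ")")
    m <- m | array(atlas$data %in% lab, dim = dim(atlas$data))
  }
  roi_mask(m, affine = atlas$affine, provenance = "auto-threshold",
           space = "pet")
}
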