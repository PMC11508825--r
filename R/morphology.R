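# Binary 3D morphology on logical arrays. Implemented directly (shift-based)
# because the oracle-equivalence contract is on the exact set-arithmetic
# definitions: dilation = union of shifted copies, erosion = voxels whose
# whole structuring element lies inside the mask (outside the grid counts as
# background, so erosion shrinks masks at the image border).

# offsets (n x 3) of a digital ball of the given radius; radius 1 is the
# 6-connected cross
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  keep <- sqrt(g$i^2 + g$j^2 + g$k^2) <= radius + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

connectivity_offsets <- function(connectivity = 6) {
  if (connectivity == 6) {
    matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
           ncol = 3, byrow = TRUE)
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

# zero-filled shift of a logical array by an integer offset
shift3 <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_mask_array <- function(m, offsets) {
  out <- array(FALSE, dim(m))
  has_origin <- FALSE
  for (r in seq_len(nrow(offsets))) {
    if (all(offsets[r, ] == 0)) { has_origin <- TRUE; next }
    out <- out | shift3(m, offsets[r, ])
  }
  if (has_origin) out <- out | m
  out
}

erode_mask_array <- function(m, offsets) {
  out <- array(TRUE, dim(m))
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    if (all(o == 0)) { out <- out & m; next }
    out <- out & shift3(m, -o)  # shift fills FALSE: outside the grid is background
  }
  out
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a digital ball structuring element
#' (radius 1 = 6-connected cross). Used to homogenize hand-drawn FLAIR
#' lesion masks. The output always contains the input.
#'
#' @param mask a [roi_mask()].
#' @param radius_vox structuring-element radius in voxels.
#' @return A closed [roi_mask()] with the same provenance.
#' @export
close_mask <- function(mask, radius_vox = 1) {
  stopifnot(inherits(mask, "roi_mask"))
  if (radius_vox <= 0) return(mask)
  se <- ball_offsets(radius_vox)
  closed <- erode_mask_array(dilate_mask_array(mask$data, se), se)
  closed <- closed | mask$data  # guard border clipping: closing is extensive
  out <- mask
  out$data <- closed
  out
}

#' Binary erosion of an atlas label union
#'
#' Erodes the union mask of the given labels to mitigate spillover from
#' adjacent hot structures into the reference region. If erosion would empty
#' the mask the uneroded mask is returned with a warning.
#'
#' @param atlas a [label_atlas()].
#' @param target_labels integer label IDs to unite and erode.
#' @param iterations erosion passes with the 6-connected cross element;
#'   0 = identity.
#' @return A [roi_mask()] in atlas space.
#' @export
erode_labels <- function(atlas, target_labels, iterations = 1) {
  stopifnot(inherits(atlas, "label_atlas"))
  unknown <- setdiff(target_labels, atlas$lookup$label)
  if (length(unknown))
    stop("erode_labels: unknown label(s): ", paste(unknown, collapse = ", "))
  m <- array(atlas$data %in% target_labels, dim = dim(atlas$data))
  if (!any(m)) stop("erode_labels: target labels cover no voxels")
  se <- ball_offsets(1)
  out <- m
  if (iterations > 0) {
    for (it in seq_len(iterations)) out <- erode_mask_array(out, se)
    if (!any(out)) {
      warning("erode_labels: erosion emptied the mask; using uneroded mask")
      out <- m
    }
  }
  roi_mask(out, affine = atlas$affine, provenance = "auto-threshold",
           space = "pet")
}

#' Connected components of a binary mask
#'
#' @param mask logical 3D array or [roi_mask()].
#' @param connectivity 6 or 26.
#' @return Integer array of component labels (0 = background), with an
#'   attribute `sizes` giving voxel counts per component.
#' @export
label_components <- function(mask, connectivity = 6) {
  m <- if (inherits(mask, "roi_mask")) mask$data else mask
  d <- dim(m)
  idx <- which(m)
  lab <- array(0L, d)
  if (length(idx) == 0L) { attr(lab, "sizes") <- integer(0); return(lab) }
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * d[1] * d[2] + (pos[, 2] - 1) * d[1] + pos[, 1]
  lookup <- integer(0)
  offs <- connectivity_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (o[1] < 0 || (o[1] == 0 && (o[2] < 0 || (o[2] == 0 && o[3] < 0)))) next
    np <- sweep(pos, 2, o, "+")
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    nk <- (np[ok, 3] - 1) * d[1] * d[2] + (np[ok, 2] - 1) * d[1] + np[ok, 1]
    j <- match(nk, key)
    keep <- !is.na(j)
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[keep], j[keep])
  }
  n <- length(idx)
  if (length(edges)) {
    el <- do.call(rbind, edges)
    gr <- igraph::graph_from_edgelist(el, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership[seq_len(n)]
  } else comp <- seq_len(n)
  comp <- match(comp, unique(comp))  # compact, deterministic numbering
  lab[idx] <- comp
  attr(lab, "sizes") <- as.integer(table(comp))
  lab
}

#' Remove connected components smaller than a voxel-count threshold
#'
#' @param mask a [roi_mask()].
#' @param min_vox minimum component size (voxels) to keep.
#' @param connectivity 6 or 26.
#' @return A filtered [roi_mask()] (possibly empty).
#' @export
filter_small_components <- function(mask, min_vox, connectivity = 6) {
  stopifnot(inherits(mask, "roi_mask"))
  lab <- label_components(mask$data, connectivity)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes >= min_vox)
  out <- mask
  out$data <- array(lab %in% keep, dim = dim(lab))
  if (!any(out$data))
    return(roi_mask(out$data, affine = mask$affine, provenance = mask$provenance,
                    space = mask$space, allow_empty = TRUE))
  out
}

# Separable Gaussian smoothing of a 3D array; sigma in mm per axis,
# zero padding at the borders (kernel truncated at 4 sigma).
gaussian_smooth3 <- function(arr, sigma_mm, spacing) {
  out <- arr
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    if (sig <= 0) next
    n <- dim(out)[ax]
    half <- max(1L, ceiling(4 * sig))
    x <- -half:half
    ker <- exp(-x^2 / (2 * sig^2)); ker <- ker / sum(ker)
    band <- matrix(0, n, n)
    for (ii in seq_len(n)) {
      jj <- ii + x
      ok <- jj >= 1 & jj <= n
      band[ii, jj[ok]] <- ker[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- band %*% matrix(a, da[1], da[2] * da[3])
    out <- aperm(array(a, da), order(perm))
  }
  out
}
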