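#' Static parameters: T/S and T/N
#'
#' Ratios of in-mask maxima: `T/S = tumor_max / striatum_max` and
#' `T/N = tumor_max / reference_max`.
#'
#' @param pet brain-masked PET [image_volume()].
#' @param tumor,striatum,reference nonempty [roi_mask()]s on the PET grid.
#' @return An object of class `static_params` with fields `tumor_max`,
#'   `striatum_max`, `reference_max`, `t_s`, `t_n` and `provenance` (of the
#'   tumor mask).
#' @export
static_params <- function(pet, tumor, striatum, reference) {
  stopifnot(inherits(pet, "image_volume"))
  for (nm in c("tumor", "striatum", "reference")) {
    m <- get(nm)
    if (!inherits(m, "roi_mask") || !any(m$data))
      stop("static_params: empty or invalid mask: ", nm)
    if (!same_grid(pet, m)) stop_grid_mismatch(paste("PET and", nm, "mask"))
  }
  tumor_max <- max(pet$data[tumor$data])
  striatum_max <- max(pet$data[striatum$data])
  reference_max <- max(pet$data[reference$data])
  structure(list(tumor_max = tumor_max, striatum_max = striatum_max,
                 reference_max = reference_max,
                 t_s = tumor_max / striatum_max,
                 t_n = tumor_max / reference_max,
                 provenance = tumor$provenance),
            class = "static_params")
}

#' @export
print.static_params <- function(x, ...) {
  cat(sprintf("<static_params> T/S = %.4g, T/N = %.4g (tumor %s)\n",
              x$t_s, x$t_n, x$provenance))
  invisible(x)
}

#' Extract a time-activity curve
#'
#' Per-frame mean and population standard deviation of the uptake within a
#' VOI, against frame midpoint times.
#'
#' @param dyn a [dynamic_series()].
#' @param roi a nonempty [roi_mask()] on the dynamic grid.
#' @param roi_name label recorded in the output.
#' @return A data.frame of class `tac` with columns `roi`, `frame`,
#'   `midpoint_s`, `mean`, `std`.
#' @export
extract_tac <- function(dyn, roi, roi_name = "roi") {
  stopifnot(inherits(dyn, "dynamic_series"), inherits(roi, "roi_mask"))
  d3 <- dim(dyn$data)[1:3]
  if (!all(dim(roi$data) == d3) ||
      max(abs(roi$affine - dyn$affine)) > 1e-6)
    stop_grid_mismatch("dynamic series and ROI")
  if (!any(roi$data)) stop("extract_tac: empty ROI '", roi_name, "'")
  idx <- which(roi$data)
  nfr <- dim(dyn$data)[4]
  flat <- matrix(dyn$data, prod(d3), nfr)
  vals <- flat[idx, , drop = FALSE]
  out <- data.frame(
    roi = roi_name,
    frame = seq_len(nfr),
    midpoint_s = dyn$timing$midpoint,
    mean = colMeans(vals),
    std = apply(vals, 2, pop_sd)
  )
  class(out) <- c("tac", "data.frame")
  out
}

#' Time-to-peak of a TAC
#'
#' Midpoint time of the frame with the maximal mean uptake; ties break to
#' the earliest such frame.
#'
#' @param tac an [extract_tac()] result.
#' @return Time in seconds.
#' @export
time_to_peak <- function(tac) {
  if (!nrow(tac)) stop("time_to_peak: empty TAC")
  tac$midpoint_s[which.max(tac$mean)]
}

#' Late-phase slope of a TAC
#'
#' Ordinary least-squares slope of mean uptake against time over the frames
#' whose midpoint falls at or after `window_start_s` (the interval between
#' the second minute and the end of the acquisition), reported per minute.
#'
#' @param tac an [extract_tac()] result.
#' @param window_start_s start of the fitting window in seconds.
#' @return Slope in uptake units per minute, with attribute `se` (the OLS
#'   standard error, also per minute) and `n` (frames used).
#' @export
fit_slope <- function(tac, window_start_s = 120) {
  sel <- tac$midpoint_s >= window_start_s
  if (sum(sel) < 2L)
    stop("fit_slope: fewer than 2 frames with midpoint >= ", window_start_s,
         " s")
  t_min <- tac$midpoint_s[sel] / 60
  fit <- stats::lm(tac$mean[sel] ~ t_min)
  slope <- unname(stats::coef(fit)[2])
  # summary.lm warns on zero-residual (noiseless) fits; the SE is then 0
  se <- if (sum(sel) > 2L)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else NA_real_
  structure(slope, se = se, n = sum(sel))
}

#' Dynamic parameters: TTP, slopes and DSR
#'
#' TTP comes from the tumor TAC; tumor and striatum slopes from
#' [fit_slope()]; the dynamic slope ratio is the tumor slope normalized to
#' the striatum slope. The tumor ROI must be the same VOI defined in the
#' segmentation step.
#'
#' @param dyn a [dynamic_series()].
#' @param tumor_roi,striatum_roi nonempty [roi_mask()]s.
#' @param window_start_s slope-fitting window start (seconds).
#' @return An object of class `dynamic_params` with fields `ttp` (s),
#'   `tumor_slope`, `striatum_slope` (per minute), `dsr`, and the two TACs.
#' @export
dynamic_params <- function(dyn, tumor_roi, striatum_roi, window_start_s = 120) {
  tumor_tac <- extract_tac(dyn, tumor_roi, "tumor")
  striatum_tac <- extract_tac(dyn, striatum_roi, "striatum")
  ts <- fit_slope(tumor_tac, window_start_s)
  ss <- fit_slope(striatum_tac, window_start_s)
  dsr <- if (abs(as.numeric(ss)) > 1e-12) as.numeric(ts) / as.numeric(ss) else {
    warning("dynamic_params: striatum slope is zero; DSR undefined")
    NA_real_
  }
  structure(list(ttp = time_to_peak(tumor_tac),
                 tumor_slope = as.numeric(ts),
                 striatum_slope = as.numeric(ss),
                 tumor_slope_se = attr(ts, "se"),
                 striatum_slope_se = attr(ss, "se"),
                 dsr = dsr,
                 tumor_tac = tumor_tac, striatum_tac = striatum_tac),
            class = "dynamic_params")
}

#' @export
print.dynamic_params <- function(x, ...) {
  cat(sprintf(
    "<dynamic_params> TTP = %.0f s, slopes %.4g / %.4g per min, DSR = %.4g\n",
    x$ttp, x$tumor_slope, x$striatum_slope, x$dsr))
  invisible(x)
}

#' Intra-tumor uptake sub-regions
#'
#' Partitions the tumor voxels by uptake into three intervals around the
#' in-mask mean and population standard deviation:
#' maximum `v > mean + 2 sd`, mean `mean < v < mean + 2 sd`, minimum
#' `mean - 2 sd < v < mean`. The inequalities are strict, so voxels exactly
#' equal to a boundary (or at or below `mean - 2 sd`) belong to no
#' sub-region.
#'
#' @param pet static PET (or SUVr) [image_volume()]; the masks are identical
#'   either way since SUVr is an affine rescaling.
#' @param tumor nonempty tumor [roi_mask()].
#' @return An object of class `subregion_set`: `masks` (list of `maximum`,
#'   `mean`, `minimum` [roi_mask()]s, possibly empty), `mean_tumor`,
#'   `std_tumor`.
#' @export
subregions <- function(pet, tumor) {
  stopifnot(inherits(pet, "image_volume"), inherits(tumor, "roi_mask"))
  if (!same_grid(pet, tumor)) stop_grid_mismatch("PET and tumor mask")
  if (!any(tumor$data)) stop("subregions: empty tumor mask")
  vals <- pet$data[tumor$data]
  m <- mean(vals); s <- pop_sd(vals)
  if (s == 0)
    warning("subregions: constant tumor uptake; all voxels unassigned")
  mk <- function(cond) {
    arr <- array(FALSE, dim(pet$data))
    arr[tumor$data] <- cond
    roi_mask(arr, affine = pet$affine, provenance = tumor$provenance,
             space = "pet", allow_empty = TRUE)
  }
  masks <- list(
    maximum = mk(s > 0 & vals > m + 2 * s),
    mean = mk(s > 0 & vals > m & vals < m + 2 * s),
    minimum = mk(s > 0 & vals > m - 2 * s & vals < m)
  )
  structure(list(masks = masks, mean_tumor = m, std_tumor = s),
            class = "subregion_set")
}

#' @export
print.subregion_set <- function(x, ...) {
  cat(sprintf(
    "<subregion_set> mean %.4g, sd %.4g; voxels max/mean/min = %d/%d/%d\n",
    x$mean_tumor, x$std_tumor, sum(x$masks$maximum$data),
    sum(x$masks$mean$data), sum(x$masks$minimum$data)))
  invisible(x)
}

#' TACs of the intra-tumor sub-regions
#'
#' @param dyn a [dynamic_series()].
#' @param subs a [subregions()] result.
#' @return Named list of [extract_tac()] results for the nonempty
#'   sub-regions (`subregion_max`, `subregion_mean`, `subregion_min`);
#'   empty sub-regions are skipped with a warning.
#' @export
subregion_tacs <- function(dyn, subs) {
  stopifnot(inherits(subs, "subregion_set"))
  roi_names <- c(maximum = "subregion_max", mean = "subregion_mean",
                 minimum = "subregion_min")
  out <- list()
  for (nm in names(roi_names)) {
    m <- subs$masks[[nm]]
    if (!any(m$data)) {
      warning("subregion_tacs: sub-region '", nm, "' is empty; skipped")
      next
    }
    out[[roi_names[[nm]]]] <- extract_tac(dyn, m, roi_names[[nm]])
  }
  if (!length(out)) stop("subregion_tacs: all sub-regions are empty")
  out
}
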