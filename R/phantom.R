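#' Specification of the synthetic brain phantom
#'
#' The phantom emulates the inputs of the quantification pipeline on a
#' 64 x 64 x 64 grid with 2 mm isotropic voxels: a brain shell, hemispheric
#' white-matter blocks, caudate/putamen/pallidum and thalamus per hemisphere,
#' a pons, a tumor in one hemisphere (or in the pons), and a thin superior
#' midline sinus structure touching the tumor. Static uptake is piecewise
#' constant per region plus optional Gaussian noise; dynamic uptake follows
#' one of four trajectory models per region:
#' \describe{
#'   \item{accumulation}{linear wash-in to `baseline + slope * 120` over the
#'     first two minutes, then `baseline + slope * t` (t in seconds);}
#'   \item{plateau}{linear rise to `level` over `rise_s` seconds, constant
#'     after;}
#'   \item{downward}{rise to `peak` over `rise_s` seconds then linear decline
#'     `decline` per second (floored at zero);}
#'   \item{sinus}{`amp * exp(-t / tau_s)` — high in the first two frames,
#'     decaying after, as venous blood-pool signal does.}
#' }
#'
#' @param shape grid dimensions.
#' @param spacing voxel size in mm.
#' @param tumor_site `"left"`, `"right"` or `"pons"`.
#' @param levels named list of static uptake levels (arbitrary Bq/ml-scale
#'   units) for `tumor`, `striatum`, `wm`, `thalamus`, `pons`, `brain`,
#'   `sinus`.
#' @param tac named list of per-region trajectory models (see Details);
#'   regions without an entry reuse the static level as a plateau.
#' @param frame_start,frame_duration dynamic frame schedule in seconds;
#'   default 12 x 10 s then 14 x 60 s.
#' @param noise_sd additive Gaussian noise sd for PET volumes (0 = noiseless).
#' @param flair_noise_sd additive Gaussian noise sd for the FLAIR volume.
#' @param tumor_gradient radial uptake gradient inside the tumor: voxel
#'   values are multiplied by `1 + tumor_gradient * (1 - r)` where r is the
#'   normalized ellipsoid radius (0 = uniform tumor).
#' @param seed RNG seed for all noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2, 2, 2),
                         tumor_site = c("left", "right", "pons"),
                         levels = list(),
                         tac = list(),
                         frame_start = c(seq(0, 110, by = 10), seq(120, 900, by = 60)),
                         frame_duration = c(rep(10, 12), rep(60, 14)),
                         noise_sd = 0,
                         flair_noise_sd = 0,
                         tumor_gradient = 0,
                         seed = 42L) {
  tumor_site <- match.arg(tumor_site)
  default_levels <- list(tumor = 10, striatum = 6, wm = 2, thalamus = 2.5,
                         pons = 2, brain = 1, sinus = 8)
  levels <- utils::modifyList(default_levels, levels)
  if (any(unlist(levels) < 0)) stop("phantom_spec: uptake levels must be >= 0")
  default_tac <- list(
    tumor = list(pattern = "accumulation", baseline = 2, slope = 0.05),
    striatum = list(pattern = "accumulation", baseline = 3, slope = 0.025),
    wm = list(pattern = "plateau", level = 2, rise_s = 120),
    thalamus = list(pattern = "plateau", level = 2.5, rise_s = 120),
    pons = list(pattern = "downward", peak = 3, rise_s = 120, decline = 0.002),
    brain = list(pattern = "plateau", level = 1, rise_s = 120),
    sinus = list(pattern = "sinus", amp = 30, tau_s = 25)
  )
  tac <- utils::modifyList(default_tac, tac)
  ft <- frame_timing(frame_start, frame_duration)
  if (noise_sd < 0 || flair_noise_sd < 0) stop("phantom_spec: noise sd must be >= 0")
  structure(list(shape = shape, spacing = spacing, tumor_site = tumor_site,
                 levels = levels, tac = tac, timing = ft,
                 noise_sd = noise_sd, flair_noise_sd = flair_noise_sd,
                 tumor_gradient = tumor_gradient, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Logical array of an axis-aligned ellipsoid in voxel coordinates.
ellipsoid_mask <- function(shape, center, radii) {
  i <- slice.index(array(0, shape), 1)
  j <- slice.index(array(0, shape), 2)
  k <- slice.index(array(0, shape), 3)
  ((i - center[1]) / radii[1])^2 + ((j - center[2]) / radii[2])^2 +
    ((k - center[3]) / radii[3])^2 <= 1
}

box_mask <- function(shape, xr, yr, zr) {
  m <- array(FALSE, shape)
  m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  m
}

# All phantom geometry as logical arrays, plus tumor radial coordinate.
# Atlas structures are pairwise disjoint by construction; the sinus is carved
# so it touches but never overlaps the tumor.
phantom_geometry <- function(spec) {
  sh <- spec$shape
  g <- list()
  g$brain <- ellipsoid_mask(sh, c(32.5, 32.5, 32.5), c(26, 30, 24))
  g$wm_left <- box_mask(sh, c(8, 28), c(14, 44), c(24, 46))
  g$wm_right <- box_mask(sh, c(37, 57), c(14, 44), c(24, 46))
  g$caudate_left <- box_mask(sh, c(12, 16), c(48, 54), c(30, 38))
  g$caudate_right <- box_mask(sh, c(49, 53), c(48, 54), c(30, 38))
  g$putamen_left <- box_mask(sh, c(18, 22), c(48, 54), c(30, 38))
  g$putamen_right <- box_mask(sh, c(43, 47), c(48, 54), c(30, 38))
  g$pallidum_left <- box_mask(sh, c(24, 27), c(48, 54), c(30, 38))
  g$pallidum_right <- box_mask(sh, c(38, 41), c(48, 54), c(30, 38))
  g$thalamus_left <- box_mask(sh, c(20, 28), c(4, 12), c(28, 36))
  g$thalamus_right <- box_mask(sh, c(37, 45), c(4, 12), c(28, 36))
  g$pons <- box_mask(sh, c(28, 37), c(28, 37), c(6, 14))
  tumor_center <- switch(spec$tumor_site,
                         left = c(24, 24, 44),
                         right = c(41, 24, 44),
                         pons = c(32.5, 32.5, 10))
  tumor_radii <- if (spec$tumor_site == "pons") c(4, 4, 3.5) else c(6, 6, 5)
  g$tumor <- ellipsoid_mask(sh, tumor_center, tumor_radii)
  i <- slice.index(array(0, sh), 1); j <- slice.index(array(0, sh), 2)
  k <- slice.index(array(0, sh), 3)
  g$tumor_r <- sqrt(((i - tumor_center[1]) / tumor_radii[1])^2 +
                    ((j - tumor_center[2]) / tumor_radii[2])^2 +
                    ((k - tumor_center[3]) / tumor_radii[3])^2)
  sinus <- box_mask(sh, c(31, 34), c(16, 48), c(48, 54)) |
    box_mask(sh, c(25, 34), c(20, 28), c(46, 50))
  g$sinus <- sinus & !g$tumor
  g$atlas_names <- c("wm_left", "wm_right", "caudate_left", "caudate_right",
                     "putamen_left", "putamen_right", "pallidum_left",
                     "pallidum_right", "thalamus_left", "thalamus_right",
                     "pons")
  g
}

#' Build the phantom label atlas
#'
#' Stands in for a Desikan-Killiany-style parcellation: white matter,
#' caudate, putamen, pallidum, thalamus per hemisphere, and pons, each with a
#' hemisphere tag and a tentorial tier in the lookup table.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_atlas()].
#' @export
build_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  nm <- g$atlas_names
  lab <- array(0L, spec$shape)
  covered <- array(FALSE, spec$shape)
  for (idx in seq_along(nm)) {
    m <- g[[nm[idx]]]
    if (any(covered & m))
      stop("build_atlas: overlapping region definitions: ", nm[idx])
    lab[m] <- idx
    covered <- covered | m
  }
  hemi <- ifelse(grepl("_left$", nm), "left",
                 ifelse(grepl("_right$", nm), "right", "midline"))
  lookup <- data.frame(
    label = seq_along(nm),
    name = sub("_(left|right)$", "", nm),
    hemisphere = hemi,
    tier = ifelse(nm == "pons", "subtentorial", "supratentorial"),
    stringsAsFactors = FALSE
  )
  label_atlas(lab, lookup, spacing = spec$spacing)
}

# static uptake field without noise (also reused frame-wise scaling for the
# tumor gradient)
phantom_static_field <- function(spec, g) {
  lv <- spec$levels
  vol <- array(0, spec$shape)
  vol[g$brain] <- lv$brain
  vol[g$wm_left | g$wm_right] <- lv$wm
  str_m <- g$caudate_left | g$caudate_right | g$putamen_left |
    g$putamen_right | g$pallidum_left | g$pallidum_right
  vol[str_m] <- lv$striatum
  vol[g$thalamus_left | g$thalamus_right] <- lv$thalamus
  vol[g$pons] <- lv$pons
  vol[g$sinus] <- lv$sinus
  tf <- 1 + spec$tumor_gradient * pmax(0, 1 - g$tumor_r)
  vol[g$tumor] <- (lv$tumor * tf)[g$tumor]
  vol
}

#' Build the static 3D PET phantom
#'
#' Voxel value = region level (+ radial gradient inside the tumor)
#' + N(0, `noise_sd`) noise; background outside the brain shell is 0.
#'
#' @param spec a [phantom_spec()].
#' @return An [image_volume()].
#' @export
build_static_pet <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  vol <- phantom_static_field(spec, g)
  if (spec$noise_sd > 0)
    vol <- with_seed(spec$seed + 1L, vol + array(
      stats::rnorm(length(vol), sd = spec$noise_sd), dim = dim(vol)))
  image_volume(vol, spacing = spec$spacing)
}

# evaluate a trajectory model at times t (seconds)
tac_model_value <- function(model, t) {
  switch(model$pattern,
    accumulation = {
      v120 <- model$baseline + model$slope * 120
      ifelse(t < 120, v120 * t / 120, model$baseline + model$slope * t)
    },
    plateau = {
      rise <- model$rise_s %||% 120
      model$level * pmin(t / rise, 1)
    },
    downward = {
      rise <- model$rise_s %||% 120
      ifelse(t < rise, model$peak * t / rise,
             pmax(0, model$peak - model$decline * (t - rise)))
    },
    sinus = model$amp * exp(-t / model$tau_s),
    constant = rep(model$level, length(t)),
    stop("tac_model_value: unknown pattern '", model$pattern, "'")
  )
}

#' Build the dynamic 4D PET phantom
#'
#' Each region follows its trajectory model from the spec evaluated at frame
#' midpoints; the tumor's radial gradient multiplies its trajectory so that
#' core and rim have proportionally different curves. Noise is seeded.
#'
#' @param spec a [phantom_spec()].
#' @return A [dynamic_series()].
#' @export
build_dynamic_pet <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  t_mid <- spec$timing$midpoint
  nfr <- length(t_mid)
  region_masks <- list(
    brain = g$brain,
    wm = g$wm_left | g$wm_right,
    striatum = g$caudate_left | g$caudate_right | g$putamen_left |
      g$putamen_right | g$pallidum_left | g$pallidum_right,
    thalamus = g$thalamus_left | g$thalamus_right,
    pons = g$pons,
    sinus = g$sinus,
    tumor = g$tumor
  )
  vals <- lapply(names(region_masks), function(nm) {
    model <- spec$tac[[nm]] %||% list(pattern = "constant",
                                      level = spec$levels[[nm]] %||% 0)
    tac_model_value(model, t_mid)
  })
  names(vals) <- names(region_masks)
  tf <- 1 + spec$tumor_gradient * pmax(0, 1 - g$tumor_r)
  arr <- array(0, c(spec$shape, nfr))
  for (f in seq_len(nfr)) {
    frame <- array(0, spec$shape)
    for (nm in names(region_masks)) {
      m <- region_masks[[nm]]
      if (nm == "tumor") frame[m] <- (vals[[nm]][f] * tf)[m]
      else frame[m] <- vals[[nm]][f]
    }
    arr[, , , f] <- frame
  }
  if (spec$noise_sd > 0)
    arr <- with_seed(spec$seed + 2L, arr + array(
      stats::rnorm(length(arr), sd = spec$noise_sd), dim = dim(arr)))
  dynamic_series(arr, timing = spec$timing, spacing = spec$spacing)
}

#' Build the phantom FLAIR volume and its hand-drawn-style lesion mask
#'
#' The lesion is hyperintense against brain tissue; the returned mask equals
#' the tumor geometry exactly, standing in for an operator's region-growing
#' delineation.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `flair` ([image_volume()]) and `lesion`
#'   ([roi_mask()], provenance `"flair-drawn"`).
#' @export
build_flair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  vol <- array(0, spec$shape)
  vol[g$brain] <- 100
  vol[g$wm_left | g$wm_right] <- 90
  vol[g$tumor] <- 200
  if (spec$flair_noise_sd > 0)
    vol <- with_seed(spec$seed + 3L, vol + array(
      stats::rnorm(length(vol), sd = spec$flair_noise_sd), dim = dim(vol)))
  list(flair = image_volume(vol, spacing = spec$spacing),
       lesion = roi_mask(g$tumor, spacing = spec$spacing,
                         provenance = "flair-drawn", space = "mri"))
}

#' Analytic ground truth of the phantom
#'
#' The quantities the pipeline should recover in the noiseless case,
#' computed directly from the spec's levels and trajectory models.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `t_s`, `t_n`, `tumor_slope`, `striatum_slope`, `dsr`
#'   (slopes per minute, over frames with midpoint >= 120 s) and `ttp_s`.
#' @export
phantom_ground_truth <- function(spec) {
  lv <- spec$levels
  gmax <- 1 + max(0, spec$tumor_gradient)
  t_mid <- spec$timing$midpoint
  late <- t_mid[t_mid >= 120]
  slope_of <- function(model, scale = 1) {
    v <- tac_model_value(model, late) * scale
    unname(stats::coef(stats::lm(v ~ late))[2]) * 60
  }
  ts_slope <- slope_of(spec$tac$tumor, gmax)
  st_slope <- slope_of(spec$tac$striatum)
  tumor_tac <- tac_model_value(spec$tac$tumor, t_mid) * gmax
  list(
    t_s = lv$tumor * gmax / lv$striatum,
    t_n = lv$tumor * gmax / lv$wm,
    tumor_slope = ts_slope,
    striatum_slope = st_slope,
    dsr = if (st_slope != 0) ts_slope / st_slope else NA_real_,
    ttp_s = t_mid[which.max(tumor_tac)]
  )
}

minimal_json <- function(path, x) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a complete phantom BIDS tree
#'
#' Emits everything [load_subject()] discovers: FLAIR, static (and optionally
#' dynamic) PET with JSON sidecars, the brain and lesion masks and the label
#' atlas with its lookup table under `derivatives/`.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir BIDS root to create.
#' @param subject_id subject label without the `sub-` prefix.
#' @param dynamic write the 4D acquisition too?
#' @return `out_dir`, invisibly.
#' @export
write_phantom_bids <- function(spec, out_dir, subject_id = "01", dynamic = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  sub <- paste0("sub-", subject_id)
  anat <- file.path(out_dir, sub, "anat")
  pet <- file.path(out_dir, sub, "pet")
  mdir <- file.path(out_dir, "derivatives", "masks", sub)
  adir <- file.path(out_dir, "derivatives", "atlas", sub)
  for (d in c(anat, pet, mdir, adir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)

  fl <- build_flair(spec)
  write_volume(fl$flair, file.path(anat, paste0(sub, "_FLAIR.nii.gz")))
  minimal_json(file.path(anat, paste0(sub, "_FLAIR.json")),
               list(Modality = "MR", PulseSequenceType = "FLAIR"))
  write_volume(fl$lesion, file.path(mdir, paste0(sub, "_desc-lesion_mask.nii.gz")))

  g <- phantom_geometry(spec)
  brain_all <- g$brain | g$sinus  # sinus sits at the brain margin; keep it in-mask
  write_volume(roi_mask(brain_all, spacing = spec$spacing,
                        provenance = "flair-drawn", space = "mri"),
               file.path(mdir, paste0(sub, "_desc-brain_mask.nii.gz")))

  pet3d <- build_static_pet(spec)
  write_volume(pet3d, file.path(pet, paste0(sub, "_acq-static_pet.nii.gz")))
  minimal_json(file.path(pet, paste0(sub, "_acq-static_pet.json")),
               list(Modality = "PT", Units = "Bq/mL", TracerName = "FDOPA"))

  if (dynamic) {
    dyn <- build_dynamic_pet(spec)
    write_volume(dyn, file.path(pet, paste0(sub, "_acq-dynamic_pet.nii.gz")))
    minimal_json(file.path(pet, paste0(sub, "_acq-dynamic_pet.json")),
                 list(Modality = "PT", Units = "Bq/mL", TracerName = "FDOPA",
                      FrameTimesStart = spec$timing$start,
                      FrameDuration = spec$timing$duration))
  }

  atl <- build_atlas(spec)
  write_volume(atl, file.path(adir, paste0(sub, "_desc-dka_dseg.nii.gz")))
  utils::write.table(atl$lookup,
                     file.path(adir, paste0(sub, "_desc-dka_dseg.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
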