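#' Default pipeline configuration
#'
#' A single nested list is the source of truth for every tunable parameter.
#' Unknown keys are rejected on load so that typos never silently fall back
#' to defaults.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      closing_radius_vox = 1,
      erosion_iterations = 1,
      connectivity = 6
    ),
    coregister = list(
      registration_backend = "internal",
      skip_when_aligned = TRUE
    ),
    regions = list(
      hemisphere = "auto",     # auto | left | right | subtentorial
      striatum_sides = "both"
    ),
    segment = list(
      flair_dilate_vox = 2,
      save_suvr = FALSE
    ),
    refine = list(
      enabled = TRUE,
      w1 = 0.5,
      w2 = 0.5,
      fwhm_mm = 5,
      min_component_vox = 10,
      svm_kernel = "linear",
      seed = 17,
      save_maps = FALSE
    ),
    quantify = list(
      slope_window_start_s = 120
    )
  )
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("config: unknown key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_config_keys(as.list(cfg[[nm]]), ref[[nm]], paste0(path, nm, "."))
  }
}

#' Load and validate a pipeline configuration
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  ref <- default_config()
  if (is.null(path)) return(ref)
  cfg <- yaml::read_yaml(path)
  check_config_keys(cfg, ref)
  utils::modifyList(ref, cfg)
}

#' Write the full default configuration to a YAML file
#'
#' @param path output file.
#' @return `path`, invisibly.
#' @export
init_config <- function(path = "fdopaquant-config.yaml") {
  yaml::write_yaml(default_config(), path)
  invisible(path)
}

#' Run the full pipeline for one subject
#'
#' Executes preprocessing (brain-mask application), coregistration of FLAIR,
#' masks and atlas into PET space, region selection (reference white matter
#' and striatum), SUVr tumor segmentation with the FLAIR fallback gate,
#' sinus refinement (for gated-in lesions with dynamic data), and static and
#' dynamic parameter extraction. Writes the CSV outputs and a log recording
#' every gate decision, provenance and fallback.
#'
#' @param layout a [load_subject()] result.
#' @param config a [load_config()] result.
#' @param out_dir output directory for CSVs and the log; `NULL` writes
#'   nothing.
#' @return A list of class `subject_result`: `static`, `dynamic` (or NULL),
#'   `subregions`, `tacs`, `segmentation`, `hemisphere`, `log`, `files`.
#' @export
run_subject <- function(layout, config = default_config(), out_dir = NULL) {
  stopifnot(inherits(layout, "subject_layout"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[sub-", layout$subject_id, "] ", msg)
  }

  # --- load inputs -------------------------------------------------------
  pet <- read_volume(layout$pet_static_path)
  flair <- read_volume(layout$anat_path)
  brain <- as_mask(read_volume(layout$mask_paths$brain), "flair-drawn", "mri")
  lesion <- as_mask(read_volume(layout$mask_paths$lesion), "flair-drawn", "mri")
  atlas_vol <- read_volume(layout$atlas_path)
  atlas <- label_atlas(array(as.integer(round(atlas_vol$data)),
                             dim = dim(atlas_vol$data)),
                       read_atlas_lookup(layout$atlas_lookup_path),
                       affine = atlas_vol$affine)
  dyn <- NULL
  if (!is.null(layout$pet_dynamic_path)) {
    timing <- read_frame_timing(layout$sidecar_paths$pet_dynamic)
    dyn <- read_volume(layout$pet_dynamic_path, timing = timing)
  }

  # --- coregistration ----------------------------------------------------
  aligned <- same_grid(flair, pet) &&
    isTRUE(config$coregister$skip_when_aligned)
  if (aligned) {
    note("coregistration: FLAIR already on the PET grid; identity transform")
    transform <- identity_transform()
  } else {
    note("coregistration: estimating rigid FLAIR->PET transform")
    transform <- estimate_rigid(flair, pet)
    note("coregistration: rigid params (%s)",
         paste(signif(transform$params, 4), collapse = ", "))
  }
  if (!aligned) {
    flair <- resample_image(flair, transform, pet)
    brain <- resample_labels(brain, transform, pet)
    lesion <- resample_labels(lesion, transform, pet)
    atlas <- resample_labels(atlas, transform, pet)
  }
  lesion$space <- "pet"
  if (!any(lesion$data))
    stop("run_subject: FLAIR lesion mask is empty after resampling")
  lesion <- close_mask(lesion, config$preprocess$closing_radius_vox)

  # --- preprocessing -----------------------------------------------------
  pet_masked <- apply_brain_mask(pet, brain)
  note("preprocess: brain mask applied (%d voxels retained)",
       sum(brain$data))

  # --- region selection --------------------------------------------------
  hemi <- config$regions$hemisphere
  if (identical(hemi, "auto")) {
    hemi <- determine_hemisphere(lesion, atlas)
    note("regions: tumor hemisphere determined as '%s'", hemi)
  } else note("regions: hemisphere overridden to '%s'", hemi)
  reference <- select_reference(atlas, hemi,
                                config$preprocess$erosion_iterations,
                                tumor = lesion)
  note("regions: reference = eroded %s white matter (%d voxels)",
       if (hemi == "subtentorial") "left" else
         ifelse(hemi == "left", "right", "left"),
       sum(reference$data))
  striatum <- assemble_striatum(atlas, config$regions$striatum_sides)

  # --- segmentation ------------------------------------------------------
  suvr <- compute_suvr(pet_masked, reference)
  note("segment: reference maximum N = %.6g", suvr$n_value)
  auto <- threshold_tumor(suvr)
  seg <- choose_tumor_voi(auto, lesion, pet_masked, striatum, reference,
                          flair_dilate_vox = config$segment$flair_dilate_vox,
                          connectivity = config$preprocess$connectivity)
  for (nt in seg$notes) note("segment: %s", nt)
  note("segment: gate %s; tumor VOI provenance '%s' (%d voxels)",
       if (seg$gate_passed) "passed (all ratios > 1)" else "failed",
       seg$tumor_mask$provenance, sum(seg$tumor_mask$data))
  tumor <- seg$tumor_mask

  # --- refinement --------------------------------------------------------
  refine_cfg <- config$refine
  if (seg$gate_passed && !is.null(dyn) && isTRUE(refine_cfg$enabled)) {
    smap <- sinus_probability_map(dyn, refine_cfg$w1, refine_cfg$w2)
    dmap <- lesion_distance_map(tumor, lesion,
                                min_component_vox = refine_cfg$min_component_vox,
                                fwhm_mm = refine_cfg$fwhm_mm,
                                connectivity = config$preprocess$connectivity)
    tumor <- classify_tumor_sinus(tumor, smap, dmap,
                                  seed = refine_cfg$seed,
                                  svm = identical(refine_cfg$svm_kernel,
                                                  "linear"))
    note("refine: %d voxels removed as sinus; provenance '%s'",
         attr(tumor, "n_removed") %||% 0L, tumor$provenance)
  } else if (!seg$gate_passed) {
    note("refine: skipped (gate failed; FLAIR-drawn VOI in use)")
  } else if (is.null(dyn)) {
    note("refine: skipped (no dynamic acquisition)")
  }

  # --- quantification ----------------------------------------------------
  stat <- static_params(pet_masked, tumor, striatum, reference)
  note("quantify: T/S = %.6g, T/N = %.6g", stat$t_s, stat$t_n)
  log_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      note("quantify: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  subs <- log_warnings(subregions(pet_masked, tumor))
  dynp <- NULL
  tacs <- list()
  if (!is.null(dyn)) {
    dynp <- log_warnings(
      dynamic_params(dyn, tumor, striatum,
                     window_start_s = config$quantify$slope_window_start_s))
    note("quantify: TTP = %.0f s, tumor slope = %.6g/min, DSR = %.6g",
         dynp$ttp, dynp$tumor_slope, dynp$dsr)
    sub_tacs <- tryCatch(log_warnings(subregion_tacs(dyn, subs)),
                         error = function(e) {
                           note("quantify: sub-region TACs unavailable (%s)",
                                conditionMessage(e))
                           list()
                         })
    tacs <- c(list(tumor = dynp$tumor_tac, striatum = dynp$striatum_tac),
              sub_tacs)
  }

  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_results(out_dir, layout$subject_id, stat, dynp, tacs)
    if (isTRUE(config$segment$save_suvr))
      write_volume(suvr, file.path(out_dir,
                                   paste0("sub-", layout$subject_id,
                                          "_suvr.nii.gz")))
    writeLines(log, file.path(out_dir,
                              paste0("sub-", layout$subject_id, "_log.txt")))
  }

  structure(list(subject_id = layout$subject_id, static = stat,
                 dynamic = dynp, subregions = subs, tacs = tacs,
                 segmentation = seg, hemisphere = hemi, suvr_n = suvr$n_value,
                 log = log, files = files),
            class = "subject_result")
}

as_mask <- function(vol, provenance, space) {
  roi_mask(vol$data > 0.5, affine = vol$affine, provenance = provenance,
           space = space, allow_empty = TRUE)
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> sub-%s: T/S = %.4g, T/N = %.4g (%s)\n",
              x$subject_id, x$static$t_s, x$static$t_n, x$static$provenance))
  if (!is.null(x$dynamic))
    cat(sprintf("  TTP = %.0f s, DSR = %.4g\n", x$dynamic$ttp, x$dynamic$dsr))
  invisible(x)
}

#' Run the pipeline over every subject of a BIDS tree
#'
#' Iterates over `sub-*` folders, continuing past per-subject failures, and
#' writes a combined summary CSV.
#'
#' @param root BIDS root directory.
#' @param config a [load_config()] result.
#' @param out_dir output directory; defaults to `<root>/derivatives/fdopaquant`.
#' @param subjects optional character vector of subject labels (without
#'   `sub-`); default is every subject folder found.
#' @return A list of class `cohort_result`: `results` (per-subject results or
#'   error conditions), `summary` (data.frame), `n_failed`.
#' @export
run_cohort <- function(root, config = default_config(), out_dir = NULL,
                       subjects = NULL) {
  if (is.null(subjects)) {
    subjects <- sub("^sub-", "",
                    basename(Filter(dir.exists,
                                    list.files(root, pattern = "^sub-",
                                               full.names = TRUE))))
  }
  out_dir <- out_dir %||% file.path(root, "derivatives", "fdopaquant")
  if (length(subjects) == 0L)
    warning("run_cohort: no subjects found under ", root)
  results <- list()
  rows <- list()
  for (s in subjects) {
    res <- tryCatch({
      lay <- load_subject(root, s)
      run_subject(lay, config, out_dir = file.path(out_dir, paste0("sub-", s)))
    }, error = function(e) e)
    results[[s]] <- res
    if (inherits(res, "error")) {
      rows[[s]] <- data.frame(subject = paste0("sub-", s), status = "failed",
                              provenance = NA, t_s = NA, t_n = NA, ttp_s = NA,
                              tumor_slope = NA, striatum_slope = NA, dsr = NA,
                              message = conditionMessage(res))
    } else {
      rows[[s]] <- data.frame(
        subject = paste0("sub-", s), status = "ok",
        provenance = res$static$provenance,
        t_s = res$static$t_s, t_n = res$static$t_n,
        ttp_s = res$dynamic$ttp %||% NA_real_,
        tumor_slope = res$dynamic$tumor_slope %||% NA_real_,
        striatum_slope = res$dynamic$striatum_slope %||% NA_real_,
        dsr = res$dynamic$dsr %||% NA_real_,
        message = "")
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), status = character(0))
  rownames(summary) <- NULL
  if (length(rows)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, summary = summary,
                 n_failed = sum(summary$status == "failed")),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects, %d failed\n",
              nrow(x$summary), x$n_failed))
  invisible(x)
}
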