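#' Frame timing of a dynamic PET acquisition
#'
#' Houses the time axis used by time-to-peak and slope fitting. Times are in
#' seconds post-injection; the midpoint of frame i is
#' `start[i] + duration[i] / 2`.
#'
#' @param start frame start times in seconds, strictly increasing.
#' @param duration frame durations in seconds, all positive.
#' @return An object of class `frame_timing` with fields `start`, `duration`
#'   and derived `midpoint`.
#' @export
frame_timing <- function(start, duration) {
  start <- as.numeric(start); duration <- as.numeric(duration)
  if (length(start) == 0L || length(start) != length(duration))
    stop("frame_timing: start and duration must be nonempty and equal length")
  if (any(!is.finite(start)) || any(!is.finite(duration)))
    stop("frame_timing: non-finite frame times")
  if (any(diff(start) <= 0))
    stop("frame_timing: frame starts must be strictly increasing")
  if (any(duration <= 0))
    stop("frame_timing: frame durations must be positive")
  structure(list(start = start, duration = duration,
                 midpoint = start + duration / 2),
            class = "frame_timing")
}

#' @export
print.frame_timing <- function(x, ...) {
  cat(sprintf("<frame_timing> %d frames, %.0f-%.0f s\n",
              length(x$start), x$start[1], x$start[length(x$start)] +
                x$duration[length(x$duration)]))
  invisible(x)
}

#' Parse PET frame timing from a BIDS JSON sidecar
#'
#' Uses the BIDS PET sidecar keys `FrameTimesStart` and `FrameDuration`.
#'
#' @param path JSON sidecar path.
#' @param n_frames if given, the number of frames in the companion 4D image;
#'   a mismatch raises an error.
#' @return A [frame_timing()].
#' @export
read_frame_timing <- function(path, n_frames = NULL) {
  if (!file.exists(path)) stop("read_frame_timing: no such file: ", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$FrameTimesStart) || is.null(meta$FrameDuration))
    stop("read_frame_timing: sidecar ", path,
         " lacks FrameTimesStart/FrameDuration")
  ft <- frame_timing(meta$FrameTimesStart, meta$FrameDuration)
  if (!is.null(n_frames) && length(ft$start) != n_frames)
    stop(sprintf(
      "read_frame_timing: sidecar %s lists %d frames but image has %d",
      path, length(ft$start), n_frames))
  ft
}

find_one <- function(dir, pattern, what, required = TRUE) {
  hits <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(hits) == 0L) {
    if (required)
      stop(sprintf("missing %s: expected a file matching '%s' under %s",
                   what, pattern, dir))
    return(NULL)
  }
  hits[[1L]]
}

#' Discover a subject's files in a BIDS-style tree
#'
#' The expected layout, as written by [write_phantom_bids()], is
#' \preformatted{
#'   <root>/sub-<ID>/anat/sub-<ID>_FLAIR.nii[.gz]
#'   <root>/sub-<ID>/pet/sub-<ID>_acq-static_pet.nii[.gz]  (+ .json)
#'   <root>/sub-<ID>/pet/sub-<ID>_acq-dynamic_pet.nii[.gz] (+ .json, optional)
#'   <root>/derivatives/masks/sub-<ID>/sub-<ID>_desc-brain_mask.nii[.gz]
#'   <root>/derivatives/masks/sub-<ID>/sub-<ID>_desc-lesion_mask.nii[.gz]
#'   <root>/derivatives/atlas/sub-<ID>/sub-<ID>_desc-dka_dseg.nii[.gz] (+ .tsv)
#' }
#' The brain mask and FLAIR-drawn lesion mask are inputs produced upstream by
#' interactive tools (skull stripping, FLAIR lesion drawing) and are consumed
#' from the derivatives folder.
#'
#' @param root_dir BIDS root directory.
#' @param subject_id subject label without the `sub-` prefix.
#' @return A validated `subject_layout` list of paths; dynamic entries are
#'   `NULL` when no dynamic acquisition exists.
#' @export
load_subject <- function(root_dir, subject_id) {
  sub <- paste0("sub-", subject_id)
  sdir <- file.path(root_dir, sub)
  if (!dir.exists(sdir))
    stop("load_subject: no subject folder at ", sdir)
  anat <- file.path(sdir, "anat"); pet <- file.path(sdir, "pet")
  if (!dir.exists(anat))
    stop("load_subject: missing modality folder ", anat)
  if (!dir.exists(pet))
    stop("load_subject: missing modality folder ", pet)
  flair <- find_one(anat, paste0("^", sub, ".*_FLAIR\\.nii(\\.gz)?$"),
                    "FLAIR MRI", required = TRUE)
  pstat <- find_one(pet, paste0("^", sub, ".*acq-static_pet\\.nii(\\.gz)?$"),
                    "static PET", required = TRUE)
  pdyn <- find_one(pet, paste0("^", sub, ".*acq-dynamic_pet\\.nii(\\.gz)?$"),
                   "dynamic PET", required = FALSE)
  sidecar_of <- function(p) {
    if (is.null(p)) return(NULL)
    j <- sub("\\.nii(\\.gz)?$", ".json", p)
    if (file.exists(j)) j else NULL
  }
  mdir <- file.path(root_dir, "derivatives", "masks", sub)
  brain <- find_one(mdir, paste0("^", sub, ".*desc-brain_mask\\.nii(\\.gz)?$"),
                    "brain mask (derivatives)", required = TRUE)
  lesion <- find_one(mdir, paste0("^", sub, ".*desc-lesion_mask\\.nii(\\.gz)?$"),
                     "FLAIR lesion mask (derivatives)", required = TRUE)
  adir <- file.path(root_dir, "derivatives", "atlas", sub)
  atlas <- find_one(adir, paste0("^", sub, ".*_dseg\\.nii(\\.gz)?$"),
                    "label atlas (derivatives)", required = TRUE)
  lut <- find_one(adir, paste0("^", sub, ".*_dseg\\.tsv$"),
                  "atlas lookup table (derivatives)", required = TRUE)
  dyn_sidecar <- sidecar_of(pdyn)
  if (!is.null(pdyn) && is.null(dyn_sidecar))
    stop("load_subject: dynamic PET ", pdyn, " has no JSON sidecar")
  # validate dimensionality and, for dynamic, sidecar/image agreement
  hdr_ndim <- function(p) {
    d <- dim(as.array(RNifti::readNifti(p)))
    length(d)
  }
  if (hdr_ndim(pstat) != 3L)
    stop("load_subject: static PET must be 3D: ", pstat)
  if (!is.null(pdyn)) {
    img <- RNifti::readNifti(pdyn)
    d <- dim(as.array(img))
    if (length(d) != 4L)
      stop("load_subject: dynamic PET must be 4D: ", pdyn)
    read_frame_timing(dyn_sidecar, n_frames = d[4])
  }
  structure(list(
    subject_id = subject_id,
    anat_path = flair,
    pet_static_path = pstat,
    pet_dynamic_path = pdyn,
    sidecar_paths = list(pet_static = sidecar_of(pstat), pet_dynamic = dyn_sidecar),
    mask_paths = list(brain = brain, lesion = lesion),
    atlas_path = atlas,
    atlas_lookup_path = lut
  ), class = "subject_layout")
}

#' @export
print.subject_layout <- function(x, ...) {
  cat(sprintf("<subject_layout> sub-%s (dynamic: %s)\n", x$subject_id,
              if (is.null(x$pet_dynamic_path)) "no" else "yes"))
  invisible(x)
}

#' Read the atlas lookup table
#'
#' TSV with columns `label`, `name`, `hemisphere`, `tier`.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_atlas_lookup <- function(path) {
  lut <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "name", "hemisphere", "tier")
  if (!all(need %in% names(lut)))
    stop("read_atlas_lookup: ", path, " must have columns ",
         paste(need, collapse = ", "))
  lut
}

fmt_num <- function(x, digits = 12) {
  ifelse(is.na(x), NA_character_, sprintf(paste0("%.", digits, "g"), x))
}

#' Write per-subject results as CSV
#'
#' Writes `<sub>_static_params.csv` (one row of scalar parameters: the static
#' ratios plus, when dynamic data were analyzed, TTP, slopes and DSR) and,
#' when TACs are present, `<sub>_tac.csv` with one row per frame per ROI.
#' Numbers are formatted with 12 significant digits so that re-reading
#' reproduces the written values.
#'
#' @param out_dir output directory (created if needed).
#' @param subject_id subject label without the `sub-` prefix.
#' @param static_params a `static_params` object (or a list with the same
#'   fields, possibly `NA` for a negative scan).
#' @param dynamic_params optional `dynamic_params` object.
#' @param tacs optional named list of [extract_tac()] results.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(out_dir, subject_id, static_params,
                          dynamic_params = NULL, tacs = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("write_results: cannot create output directory ", out_dir)
  }
  sub <- paste0("sub-", subject_id)
  row <- data.frame(
    subject = sub,
    provenance = static_params$provenance %||% NA_character_,
    tumor_max = fmt_num(static_params$tumor_max %||% NA_real_),
    striatum_max = fmt_num(static_params$striatum_max %||% NA_real_),
    reference_max = fmt_num(static_params$reference_max %||% NA_real_),
    t_s = fmt_num(static_params$t_s %||% NA_real_),
    t_n = fmt_num(static_params$t_n %||% NA_real_),
    ttp_s = fmt_num(dynamic_params$ttp %||% NA_real_),
    tumor_slope = fmt_num(dynamic_params$tumor_slope %||% NA_real_),
    striatum_slope = fmt_num(dynamic_params$striatum_slope %||% NA_real_),
    dsr = fmt_num(dynamic_params$dsr %||% NA_real_),
    stringsAsFactors = FALSE
  )
  static_file <- file.path(out_dir, paste0(sub, "_static_params.csv"))
  utils::write.csv(row, static_file, row.names = FALSE, quote = FALSE)
  files <- c(static_params = static_file)
  if (!is.null(tacs) && length(tacs)) {
    tac_df <- do.call(rbind, lapply(tacs, function(tc) {
      data.frame(roi = tc$roi, frame_index = seq_len(nrow(tc)),
                 midpoint_s = fmt_num(tc$midpoint_s), mean = fmt_num(tc$mean),
                 std = fmt_num(tc$std), stringsAsFactors = FALSE)
    }))
    tac_file <- file.path(out_dir, paste0(sub, "_tac.csv"))
    utils::write.csv(tac_df, tac_file, row.names = FALSE, quote = FALSE)
    files <- c(files, tac = tac_file)
  }
  invisible(files)
}
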