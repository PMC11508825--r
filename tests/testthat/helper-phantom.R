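# Shared phantom fixtures, built once per test session.

default_spec <- phantom_spec()
default_geom <- fdopaquant:::phantom_geometry(default_spec)

# segmentation stage run on a phantom spec, without touching disk
phantom_segmentation <- function(spec) {
  g <- fdopaquant:::phantom_geometry(spec)
  pet <- apply_brain_mask(build_static_pet(spec),
                          roi_mask(g$brain | g$sinus, spacing = c(2, 2, 2)))
  atl <- build_atlas(spec)
  ref <- select_reference(atl, "left", 1)
  stri <- assemble_striatum(atl)
  lesion <- roi_mask(g$tumor, spacing = c(2, 2, 2), provenance = "flair-drawn")
  suvr <- compute_suvr(pet, ref)
  list(seg = choose_tumor_voi(threshold_tumor(suvr), lesion, pet, stri, ref),
       suvr = suvr, g = g, pet = pet)
}

# a written BIDS tree for the default (noiseless, dynamic) phantom
phantom_bids_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "phantom-bids-default")
      if (!dir.exists(dir)) write_phantom_bids(default_spec, dir)
    }
    dir
  }
})
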