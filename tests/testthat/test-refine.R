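test_that("the sinus map is a normalized weighted early-frame sum", {
  ft <- frame_timing(c(0, 10, 20), c(10, 10, 10))
  arr <- array(0, c(4, 4, 4, 3))
  arr[2, 3, 2, 1] <- 8; arr[2, 3, 2, 2] <- 4  # single hot voxel
  dyn <- dynamic_series(arr, ft)
  m <- sinus_probability_map(dyn)
  expect_equal(max(m$data), 1)
  expect_equal(which.max(m$data), which(arr[, , , 1] == 8))
  expect_true(all(m$data >= 0 & m$data <= 1))
  # equal frames with w1 = w2 = 0.5 reduce to frame1 / max(frame1)
  arr2 <- array(stats::runif(64), c(4, 4, 4))
  dyn2 <- dynamic_series(array(rep(arr2, 3), c(4, 4, 4, 3)), ft)
  expect_equal(sinus_probability_map(dyn2)$data, arr2 / max(arr2),
               tolerance = 1e-12)
  # all-zero early frames are an error
  dyn0 <- dynamic_series(array(0, c(4, 4, 4, 3)), ft)
  expect_error(sinus_probability_map(dyn0), "no signal")
  expect_error(sinus_probability_map(
    dynamic_series(array(1, c(4, 4, 4, 1)), frame_timing(0, 10))),
    "2 frames")
})

test_that("the phantom sinus dominates the early-frame map", {
  dyn <- build_dynamic_pet(default_spec)
  m <- sinus_probability_map(dyn)
  g <- default_geom
  expect_gt(mean(m$data[g$sinus]), 5 * mean(m$data[g$tumor]))
})

test_that("the lesion distance map peaks inside the lesion at 1", {
  lesion <- array(FALSE, c(16, 16, 16)); lesion[6:11, 6:11, 6:11] <- TRUE
  lm <- roi_mask(lesion, spacing = c(2, 2, 2))
  map <- lesion_distance_map(lm, lm, min_component_vox = 5, fwhm_mm = 5)
  expect_equal(max(map$data), 1)
  expect_equal(which.max(map$data) %in% which(lesion), TRUE)
  expect_error(
    lesion_distance_map(roi_mask(array(FALSE, c(8, 8, 8)), allow_empty = TRUE),
                        roi_mask(array(FALSE, c(8, 8, 8)), allow_empty = TRUE)),
    "empty")
})

test_that("small disconnected specks contribute nothing to the distance map", {
  d <- c(16, 16, 16)
  lesion <- array(FALSE, d); lesion[6:11, 6:11, 6:11] <- TRUE
  speck <- lesion; speck[2, 2, 2] <- TRUE; speck[2, 2, 3] <- TRUE
  # oracle check: components below the threshold really are removed
  expect_identical(oracle_filter_small(speck, 5), lesion)
  flair_voi <- roi_mask(lesion, spacing = c(2, 2, 2))
  with_speck <- lesion_distance_map(roi_mask(speck, spacing = c(2, 2, 2)),
                                    flair_voi, min_component_vox = 5)
  without <- lesion_distance_map(roi_mask(lesion, spacing = c(2, 2, 2)),
                                 flair_voi, min_component_vox = 5)
  expect_equal(with_speck$data, without$data, tolerance = 1e-12)
})

test_that("the distance map decays monotonically away from a convex lesion", {
  d <- c(24, 24, 24)
  lesion <- array(FALSE, d); lesion[10:15, 10:15, 10:15] <- TRUE
  lm <- roi_mask(lesion, spacing = c(2, 2, 2))
  map <- lesion_distance_map(lm, lm, fwhm_mm = 5)
  # strictly decreasing until the truncated kernel reaches zero, then flat
  check_ray <- function(vals) {
    pos <- vals > 1e-12
    expect_true(all(diff(vals[pos]) < 0))
    expect_true(all(diff(vals) <= 0))
  }
  check_ray(map$data[15:24, 12, 12])  # ray leaving the lesion along +x
  check_ray(map$data[12, 12, 15:24])
})

feature_phantom <- function(sinus_idx, tumor_idx, d = c(6, 6, 6)) {
  # helper: masks + feature maps with the given voxel linear indices
  tum <- array(FALSE, d); tum[c(sinus_idx, tumor_idx)] <- TRUE
  smap <- array(0, d); smap[sinus_idx] <- stats::runif(length(sinus_idx), 0.85, 1)
  smap[tumor_idx] <- stats::runif(length(tumor_idx), 0, 0.1)
  dmap <- array(0, d); dmap[sinus_idx] <- stats::runif(length(sinus_idx), 0, 0.2)
  dmap[tumor_idx] <- stats::runif(length(tumor_idx), 0.8, 1)
  list(mask = roi_mask(tum), smap = image_volume(smap),
       dmap = image_volume(dmap))
}

test_that("well-separated feature clouds split exactly at the optimal 2-partition", {
  set.seed(408)
  sinus_idx <- 1:5; tumor_idx <- 30:36
  fx <- feature_phantom(sinus_idx, tumor_idx)
  refined <- classify_tumor_sinus(fx$mask, fx$smap, fx$dmap, seed = 1)
  expect_equal(sort(which(refined$data)), sort(tumor_idx))
  expect_equal(refined$provenance, "refined")
  # oracle: exhaustive best 2-partition by within-cluster sum of squares
  idx <- which(fx$mask$data)
  feats <- cbind(fx$smap$data[idx], fx$dmap$data[idx])
  n <- length(idx)
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    ss <- sum(scale(feats[grp, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(feats[!grp, , drop = FALSE], scale = FALSE)^2)
    if (ss < best_ss) { best_ss <- ss; best <- grp }
  }
  sinus_side <- if (mean(feats[best, 1]) > mean(feats[!best, 1])) best else !best
  expect_equal(sort(idx[!sinus_side]), sort(which(refined$data)))
})

test_that("refinement is deterministic, subset-bounded, and order-symmetric", {
  set.seed(409)
  fx <- feature_phantom(1:6, c(40, 45, 50, 55, 60, 65, 70))
  a <- classify_tumor_sinus(fx$mask, fx$smap, fx$dmap, seed = 99)
  b <- classify_tumor_sinus(fx$mask, fx$smap, fx$dmap, seed = 99)
  expect_identical(a$data, b$data)
  expect_true(all(!a$data | fx$mask$data))  # refined subset of input
  # swapping the two feature maps flips the labels but induces the same
  # partition of the mask voxels
  sw <- classify_tumor_sinus(fx$mask, fx$dmap, fx$smap, seed = 99)
  kept_a <- which(a$data); kept_sw <- which(sw$data)
  removed_a <- setdiff(which(fx$mask$data), kept_a)
  expect_true(setequal(kept_sw, removed_a) || setequal(kept_sw, kept_a))
})

test_that("degenerate feature clouds leave the mask unchanged with a warning", {
  d <- c(5, 5, 5)
  tum <- array(FALSE, d); tum[1:10] <- TRUE
  flat <- image_volume(array(0.5, d))
  expect_warning(out <- classify_tumor_sinus(roi_mask(tum), flat, flat),
                 "degenerate|one cluster")
  expect_identical(out$data, tum)
  expect_equal(out$provenance, "flair-drawn")  # unchanged provenance
})

test_that("a sinus-free tumor mask is essentially unchanged by refinement", {
  spec <- default_spec
  g <- default_geom
  dyn <- build_dynamic_pet(spec)
  tum <- roi_mask(g$tumor, spacing = c(2, 2, 2), provenance = "auto-threshold")
  smap <- sinus_probability_map(dyn)
  dmap <- lesion_distance_map(tum, tum)
  refined <- suppressWarnings(classify_tumor_sinus(tum, smap, dmap, seed = 3))
  flips <- sum(xor(refined$data, tum$data))
  expect_lte(flips / sum(tum$data), 0.01)
})

test_that("the phantom sinus is removed and the tumor preserved", {
  g <- default_geom
  dyn <- build_dynamic_pet(default_spec)
  res <- phantom_segmentation(default_spec)
  auto <- res$seg$tumor_mask
  lesion <- roi_mask(g$tumor, spacing = c(2, 2, 2), provenance = "flair-drawn")
  smap <- sinus_probability_map(dyn)
  dmap <- lesion_distance_map(auto, lesion)
  refined <- classify_tumor_sinus(auto, smap, dmap, seed = 17)
  sinus_in <- auto$data & g$sinus
  tumor_in <- auto$data & g$tumor
  expect_gte(sum(sinus_in & !refined$data) / sum(sinus_in), 0.95)
  expect_lte(sum(tumor_in & !refined$data) / sum(tumor_in), 0.05)
  # refinement never adds voxels outside the input mask
  expect_true(all(!refined$data | auto$data))
})
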