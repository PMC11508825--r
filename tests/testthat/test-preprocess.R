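test_that("region growing degenerates correctly at the boundaries", {
  vol <- image_volume(array(5, c(8, 8, 8)))
  seed <- c(4, 4, 4)
  m0 <- region_grow(vol, seed, max_radius = 0, max_diff = 10)
  expect_equal(which(m0$data), which(array(seq_len(512), c(8, 8, 8)) ==
                                       ((4 - 1) * 64 + (4 - 1) * 8 + 4)))
  expect_equal(sum(m0$data), 1)
  expect_error(region_grow(vol, c(0, 4, 4), 5, 1), "outside")
  expect_error(region_grow(vol, c(4, 4, 9), 5, 1), "outside")
})

test_that("growth in a uniform image is the world-distance ball", {
  vol <- image_volume(array(1, c(8, 8, 8)), spacing = c(1, 1, 1))
  seed <- c(4, 5, 4)
  grown <- region_grow(vol, seed, max_radius = 2.5, max_diff = 0)
  # oracle: flood fill over the eligibility ball
  d <- dim(vol$data)
  eligible <- array(FALSE, d)
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    eligible[i, j, k] <- sqrt(sum((c(i, j, k) - seed)^2)) <= 2.5
  expect_identical(grown$data, oracle_flood(eligible, seed))
})

test_that("region growing honours world-mm distance under anisotropic spacing", {
  vol <- image_volume(array(1, c(9, 9, 9)), spacing = c(1, 2, 4))
  seed <- c(5, 5, 5)
  grown <- region_grow(vol, seed, max_radius = 4, max_diff = 0)
  pos <- arrayInd(which(grown$data), dim(vol$data))
  dmm <- sqrt(colSums((t(sweep(pos, 2, seed)) * c(1, 2, 4))^2))
  expect_true(all(dmm <= 4 + 1e-9))
  expect_true(any(abs(pos[, 3] - 5) == 1))  # 4 mm reaches 1 voxel in z
  expect_false(any(abs(pos[, 3] - 5) > 1))
})

test_that("region growth is connected, contains the seed, and is intensity-bounded", {
  set.seed(401)
  for (rep in 1:20) {
    vol <- image_volume(array(stats::runif(512), c(8, 8, 8)))
    seed <- sample(2:7, 3, replace = TRUE)
    md <- stats::runif(1, 0.05, 0.5)
    grown <- suppressWarnings(region_grow(vol, seed, max_radius = 6,
                                          max_diff = md))
    expect_true(grown$data[seed[1], seed[2], seed[3]])
    seed_val <- vol$data[seed[1], seed[2], seed[3]]
    expect_true(all(abs(vol$data[grown$data] - seed_val) <= md))
    lab <- label_components(grown$data)
    expect_equal(max(lab), 1)
  }
})

test_that("closing fills interior holes and is idempotent on convex solids", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  holed <- cube; holed[5, 5, 5] <- FALSE
  closed <- close_mask(roi_mask(holed), radius_vox = 1)
  expect_true(closed$data[5, 5, 5])
  expect_identical(closed$data, cube)
  ball <- fdopaquant:::ellipsoid_mask(c(11, 11, 11), c(6, 6, 6), c(3, 3, 3))
  expect_identical(close_mask(roi_mask(ball), 1)$data, ball)
})

test_that("closing matches the brute-force dilate-erode oracle on random masks", {
  set.seed(402)
  se <- fdopaquant:::ball_offsets(1)
  for (rep in 1:10) {
    m <- random_mask(c(10, 10, 10), p = 0.3)
    if (!any(m)) next
    got <- close_mask(roi_mask(m, allow_empty = TRUE), 1)$data
    expect_identical(got, oracle_close(m, se))
    expect_true(all(m[!got] == FALSE))  # extensivity: output contains input
  }
})

test_that("brain masking zeroes outside and preserves inside", {
  pet <- image_volume(array(stats::runif(8^3), c(8, 8, 8)))
  ones <- roi_mask(array(TRUE, c(8, 8, 8)))
  expect_identical(apply_brain_mask(pet, ones)$data, pet$data)
  zeros <- roi_mask(array(FALSE, c(8, 8, 8)), allow_empty = TRUE)
  expect_true(all(apply_brain_mask(pet, zeros)$data == 0))
  other <- roi_mask(array(TRUE, c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_error(apply_brain_mask(pet, other), "grid mismatch")
})

test_that("skull-shell signal is removed while the brain maximum survives", {
  g <- default_geom
  pet <- build_static_pet(default_spec)
  shell <- fdopaquant:::ellipsoid_mask(dim(pet$data), c(32.5, 32.5, 32.5),
                                       c(30, 31.5, 27)) & !g$brain & !g$sinus
  hot <- pet
  hot$data[shell] <- 50
  brain <- roi_mask(g$brain | g$sinus, spacing = c(2, 2, 2))
  masked <- apply_brain_mask(hot, brain)
  expect_true(all(masked$data[shell] == 0))
  expect_equal(max(masked$data), max(pet$data[g$brain | g$sinus]))
})

test_that("label erosion matches its set-arithmetic definition", {
  arr <- array(0L, c(9, 9, 9)); arr[4:6, 4:6, 4:6] <- 1L
  lut <- data.frame(label = 1L, name = "wm", hemisphere = "left",
                    tier = "supratentorial")
  atl <- label_atlas(arr, lut)
  ero <- erode_labels(atl, 1L, iterations = 1)
  expect_equal(which(ero$data), which(array(seq_len(729), c(9, 9, 9)) ==
                                        (4 * 81 + 4 * 9 + 5)))
  expect_equal(sum(ero$data), 1)  # 3x3x3 cube erodes to its center
  expect_identical(erode_labels(atl, 1L, iterations = 0)$data, arr == 1L)
  expect_error(erode_labels(atl, 2L), "unknown label")
})

test_that("erosion that would empty the mask falls back with a warning", {
  arr <- array(0L, c(9, 9, 9)); arr[4:6, 4:6, 5] <- 1L  # 1-voxel-thick sheet
  lut <- data.frame(label = 1L, name = "wm", hemisphere = "left",
                    tier = "supratentorial")
  atl <- label_atlas(arr, lut)
  expect_warning(ero <- erode_labels(atl, 1L, iterations = 1), "uneroded")
  expect_identical(ero$data, arr == 1L)
})

test_that("erosion and dilation agree with oracles and nest correctly", {
  set.seed(403)
  se <- fdopaquant:::ball_offsets(1)
  for (rep in 1:10) {
    m <- random_mask(c(8, 8, 8), p = 0.5)
    ero <- fdopaquant:::erode_mask_array(m, se)
    dil <- fdopaquant:::dilate_mask_array(m, se)
    expect_identical(ero, oracle_erode(m, se))
    expect_identical(dil, oracle_dilate(m, se))
    expect_true(all(!ero | m))   # erode(m) subset of m
    expect_true(all(!m | dil))   # m subset of dilate(m)
  }
})

test_that("connected components match repeated flood fill", {
  set.seed(404)
  for (rep in 1:10) {
    m <- random_mask(c(8, 8, 8), p = 0.25)
    lab <- label_components(m)
    expect_setequal(as.integer(attr(lab, "sizes")), oracle_component_sizes(m))
    expect_equal(sum(attr(lab, "sizes")), sum(m))
    # filtering agrees with the oracle
    filt <- filter_small_components(roi_mask(m, allow_empty = TRUE), 4)
    expect_identical(filt$data, oracle_filter_small(m, 4))
  }
})
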