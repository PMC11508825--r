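test_that("static ratios are ratios of in-mask maxima", {
  d <- c(6, 6, 6)
  arr <- array(1, d)
  arr[1:4] <- c(7, 10, 9, 8)    # tumor voxels
  arr[10:12] <- c(5, 4, 3)      # striatum voxels
  arr[20:24] <- 2               # reference voxels
  pet <- image_volume(arr)
  mk <- function(ix) { m <- array(FALSE, d); m[ix] <- TRUE; roi_mask(m) }
  sp <- static_params(pet, mk(1:4), mk(10:12), mk(20:24))
  expect_equal(sp$tumor_max, 10)
  expect_equal(sp$t_s, 2.0)
  expect_equal(sp$t_n, 5.0)
  # tumor mask equal to striatum mask gives T/S = 1
  sp2 <- static_params(pet, mk(10:12), mk(10:12), mk(20:24))
  expect_equal(sp2$t_s, 1.0)
  expect_error(static_params(pet, mk(1:4),
                             roi_mask(array(FALSE, d), allow_empty = TRUE),
                             mk(20:24)),
               "striatum")
})

test_that("TACs reduce to voxel series and constants correctly", {
  ft <- frame_timing(c(0, 10, 20, 30), rep(10, 4))
  arr <- array(stats::runif(4 * 64), c(4, 4, 4, 4))
  dyn <- dynamic_series(arr, ft)
  single <- array(FALSE, c(4, 4, 4)); single[2, 3, 1] <- TRUE
  tac <- extract_tac(dyn, roi_mask(single), "one")
  expect_equal(tac$mean, arr[2, 3, 1, ])
  expect_true(all(tac$std == 0))
  expect_equal(tac$midpoint_s, c(5, 15, 25, 35))
  # spatially constant frames: mean = constant, std = 0
  carr <- array(rep(1:4, each = 64), c(4, 4, 4, 4))
  ctac <- extract_tac(dynamic_series(carr, ft),
                      roi_mask(array(TRUE, c(4, 4, 4))), "all")
  expect_equal(ctac$mean, 1:4)
  expect_true(all(ctac$std == 0))
  expect_error(extract_tac(dyn, roi_mask(array(FALSE, c(4, 4, 4)),
                                         allow_empty = TRUE)),
               "empty ROI")
})

test_that("the phantom tumor TAC equals its closed-form trajectory", {
  dyn <- build_dynamic_pet(default_spec)
  tum <- roi_mask(default_geom$tumor, spacing = c(2, 2, 2))
  tac <- extract_tac(dyn, tum, "tumor")
  t_mid <- default_spec$timing$midpoint
  expected <- ifelse(t_mid < 120, 8 * t_mid / 120, 2 + 0.05 * t_mid)
  expect_equal(tac$mean, expected, tolerance = 1e-9)
  expect_true(all(tac$std < 1e-12))
})

test_that("time-to-peak takes the earliest maximal frame", {
  tac <- data.frame(roi = "t", frame = 1:5, midpoint_s = c(30, 90, 150, 210, 270),
                    mean = c(1, 3, 5, 4, 2), std = 0)
  expect_equal(time_to_peak(tac), 150)
  tac$mean <- 1:5
  expect_equal(time_to_peak(tac), 270)   # monotone: last midpoint
  tac$mean <- c(1, 5, 5, 4, 2)
  expect_equal(time_to_peak(tac), 90)    # tie: earliest
})

test_that("slope fitting matches the closed-form OLS solution", {
  set.seed(410)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    t_s <- sort(stats::runif(n, 0, 960))
    tac <- data.frame(roi = "t", frame = seq_len(n), midpoint_s = t_s,
                      mean = stats::rnorm(n), std = 0)
    sel <- t_s >= 120
    if (sum(sel) < 2) next
    got <- fit_slope(tac, 120)
    x <- t_s[sel] / 60; y <- tac$mean[sel]
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(as.numeric(got), beta, tolerance = 1e-10)
  }
  # exact line: slope 0.05/s = 3/min
  tac <- data.frame(roi = "t", frame = 1:10,
                    midpoint_s = seq(120, 930, length.out = 10))
  tac$mean <- 2 + 0.05 * tac$midpoint_s; tac$std <- 0
  expect_equal(as.numeric(fit_slope(tac)), 3, tolerance = 1e-9)
  tac$mean <- 7
  expect_equal(as.numeric(fit_slope(tac)), 0)
  expect_error(fit_slope(tac[1, ]), "fewer than 2")
})

test_that("DSR is the slope ratio with guarded degenerate cases", {
  ft <- frame_timing(seq(0, 900, 60), rep(60, 16))
  mk_dyn <- function(tum_fun, str_fun) {
    arr <- array(0, c(4, 4, 4, 16))
    for (f in 1:16) {
      arr[1:2, , , f] <- tum_fun(ft$midpoint[f])
      arr[3:4, , , f] <- str_fun(ft$midpoint[f])
    }
    dynamic_series(arr, ft)
  }
  tum <- roi_mask(array(rep(c(TRUE, FALSE), c(2, 2)), c(4, 4, 4)))
  str <- roi_mask(array(rep(c(FALSE, TRUE), c(2, 2)), c(4, 4, 4)))
  dp <- dynamic_params(mk_dyn(function(t) 0.05 * t, function(t) 0.025 * t),
                       tum, str)
  expect_equal(dp$dsr, 2.0, tolerance = 1e-9)
  expect_equal(dp$tumor_slope, 3, tolerance = 1e-9)
  # flat tumor: DSR = 0
  dp0 <- dynamic_params(mk_dyn(function(t) 5, function(t) 0.025 * t), tum, str)
  expect_equal(dp0$dsr, 0, tolerance = 1e-12)
  # flat striatum: DSR undefined with warning
  expect_warning(
    dpu <- dynamic_params(mk_dyn(function(t) 0.05 * t, function(t) 5),
                          tum, str),
    "undefined")
  expect_true(is.na(dpu$dsr))
  # TTP and ratios are invariant to a positive affine intensity rescale
  sc <- mk_dyn(function(t) 2 + 0.1 * t, function(t) 1 + 0.05 * t)
  sc2 <- sc; sc2$data <- 3.2 * sc$data + 0.7
  a <- dynamic_params(sc, tum, str); b <- dynamic_params(sc2, tum, str)
  expect_equal(a$ttp, b$ttp)
  expect_equal(b$dsr, a$dsr, tolerance = 1e-9)
})

test_that("sub-region intervals follow the strict two-sigma partition", {
  d <- c(3, 3, 1)
  pet <- image_volume(array(1:9, d))
  tum <- roi_mask(array(TRUE, d))
  subs <- subregions(pet, tum)
  expect_equal(subs$mean_tumor, 5)
  expect_equal(subs$std_tumor, sqrt(mean((1:9 - 5)^2)))
  # brute-force interval check over all 9 values
  vals <- 1:9; m <- 5; s <- subs$std_tumor
  expect_equal(which(subs$masks$maximum$data), which(vals > m + 2 * s))
  expect_equal(which(subs$masks$mean$data), which(vals > m & vals < m + 2 * s))
  expect_equal(which(subs$masks$minimum$data),
               which(vals > m - 2 * s & vals < m))
  expect_length(which(subs$masks$maximum$data), 0)  # no value exceeds 10.16
  expect_equal(which(subs$masks$minimum$data), 1:4)
  expect_equal(which(subs$masks$mean$data), 6:9)
  # the mean-valued voxel (5) is boundary-equal and unassigned
  assigned <- subs$masks$maximum$data | subs$masks$mean$data |
    subs$masks$minimum$data
  expect_false(assigned[5])
})

test_that("constant tumors leave all sub-regions empty with a warning", {
  pet <- image_volume(array(4, c(3, 3, 3)))
  expect_warning(subs <- subregions(pet, roi_mask(array(TRUE, c(3, 3, 3)))),
                 "constant")
  expect_true(all(!subs$masks$maximum$data))
  expect_true(all(!subs$masks$mean$data))
  expect_true(all(!subs$masks$minimum$data))
})

test_that("sub-region masks are disjoint, tumor-bound and interval-exact", {
  set.seed(411)
  for (rep in 1:200) {
    d <- c(6, 6, 6)
    tum_arr <- random_mask(d, p = 0.4)
    if (sum(tum_arr) < 2) next
    pet <- image_volume(array(stats::rnorm(prod(d), 5, 2), d))
    subs <- suppressWarnings(subregions(pet, roi_mask(tum_arr)))
    mx <- subs$masks$maximum$data; mn <- subs$masks$mean$data
    mi <- subs$masks$minimum$data
    expect_false(any(mx & mn) || any(mx & mi) || any(mn & mi))
    expect_true(all(!(mx | mn | mi) | tum_arr))
    # union = voxels above mean - 2 sd, minus boundary-equal voxels
    v <- pet$data; m <- subs$mean_tumor; s <- subs$std_tumor
    expected_union <- tum_arr & v > m - 2 * s &
      v != m & v != m + 2 * s
    expect_identical(mx | mn | mi, expected_union)
  }
})

test_that("graded tumors yield three ordered sub-region TACs", {
  spec <- phantom_spec(tumor_gradient = 0.6)
  g <- fdopaquant:::phantom_geometry(spec)
  pet <- build_static_pet(spec)
  dyn <- build_dynamic_pet(spec)
  tum <- roi_mask(g$tumor, spacing = c(2, 2, 2))
  subs <- subregions(pet, tum)
  tacs <- subregion_tacs(dyn, subs)
  expect_setequal(names(tacs),
                  c("subregion_max", "subregion_mean", "subregion_min"))
  # spatial uptake ordering carries through every frame
  expect_true(all(tacs$subregion_max$mean >= tacs$subregion_mean$mean))
  expect_true(all(tacs$subregion_mean$mean >= tacs$subregion_min$mean))
  expect_false(isTRUE(all.equal(tacs$subregion_max$mean,
                                tacs$subregion_min$mean)))
  # one empty sub-region: skipped with a warning, others returned
  pet2 <- image_volume(array(1:27, c(3, 3, 3)))
  tum2 <- roi_mask(array(TRUE, c(3, 3, 3)))
  subs2 <- subregions(pet2, tum2)   # maximum region empty for a uniform ramp
  ft <- frame_timing(c(0, 10), c(10, 10))
  dyn2 <- dynamic_series(array(rep(1:27, 2), c(3, 3, 3, 2)), ft)
  expect_warning(t2 <- subregion_tacs(dyn2, subs2), "empty")
  expect_lt(length(t2), 3)
})
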