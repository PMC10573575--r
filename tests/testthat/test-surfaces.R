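test_that("dynamic program equals exhaustive path enumeration on small grids", {
  set.seed(21)
  for (rep in 1:20) {
    nx <- sample(3:6, 1); nz <- sample(3:5, 1)
    ms <- sample(1:2, 1)
    cost <- matrix(stats::rnorm(nx * nz), nx, nz)
    got <- dp_min_path(cost, max_step = ms)
    expect_equal(got$cost, brute_force_min_path(cost, ms), tolerance = 1e-12)
    ## the reported path realizes the reported cost and respects the step cap
    expect_equal(sum(cost[cbind(seq_len(nx), got$path)]), got$cost,
                 tolerance = 1e-12)
    if (nx > 1) expect_true(all(abs(diff(got$path)) <= ms))
  }
})

test_that("dp ties break toward smaller depths", {
  cost <- matrix(0, 4, 5)
  expect_true(all(dp_min_path(cost, 2)$path == 1L))
})

test_that("a perfect step edge is localized at the edge midpoint everywhere", {
  k <- 30L
  arr <- array(0, dim = c(8, 16, 64))
  arr[, , 1:(k - 1)] <- 100
  s <- segment_surface(arr, "bright_above")
  expect_lt(max(abs(s - (k - 0.5))), 0.2)
  ## max_step = 0 must reproduce the same flat surface
  s0 <- segment_surface(arr, "bright_above", max_step = 0)
  expect_equal(s, s0, tolerance = 1e-9)
  ## dark-above polarity finds the opposite transition
  arr2 <- array(100, dim = c(8, 16, 64)) - arr
  s2 <- segment_surface(arr2, "dark_above")
  expect_lt(max(abs(s2 - (k - 0.5))), 0.2)
})

test_that("empty or out-of-range bands are rejected", {
  arr <- array(1, dim = c(4, 4, 16))
  expect_error(segment_surface(arr, band = c(10, 5)), "band")
  expect_error(segment_surface(arr, band = c(1, 40)), "band")
})

test_that("noise-free phantom BM is recovered within a voxel nearly everywhere", {
  ph <- test_phantom_clean()
  corrected <- compensate_attenuation(ph$volume)
  ss <- segment_choroid(ph$volume, corrected = corrected)
  bm_err <- ss$bm - ph$truth$true_bm
  expect_gte(mean(abs(bm_err) <= 1), 0.99)
})

test_that("constant 150-um choroid is recovered in the median", {
  ph <- test_phantom_clean()
  corrected <- compensate_attenuation(ph$volume)
  ss <- segment_choroid(ph$volume, corrected = corrected)
  med <- stats::median((ss$csi - ss$bm) * ph$volume$axial_spacing_um)
  expect_gte(med, 145)
  expect_lte(med, 155)
})

test_that("zero-thickness choroid yields near-zero thickness without error", {
  ph <- generate_phantom(phantom_params(
    seed = 13, speckle = FALSE, vessel_fraction_target = 0,
    thickness_um = c(mean = 0, amplitude = 0)))
  ss <- segment_choroid(ph$volume, min_thickness_um = 0)
  expect_lt(mean((ss$csi - ss$bm) * ph$volume$axial_spacing_um), 5)
})

test_that("attenuation compensation does not hurt CSI accuracy under a shadow", {
  p <- phantom_params(
    seed = 14,
    shadow_artifacts = list(list(center_px = c(32, 32), radius_px = 12,
                                 factor = 0.35, from_um = 100)))
  ph <- generate_phantom(p)
  ss_cor <- segment_choroid(ph$volume)
  ss_raw <- segment_choroid(ph$volume, compensate = FALSE)
  g <- choroquant:::grid_coords(64, 64)
  disc <- (g$x - 32)^2 + (g$y - 32)^2 <= 12^2
  err_cor <- abs(ss_cor$csi - ph$truth$true_csi)[disc]
  err_raw <- abs(ss_raw$csi - ph$truth$true_csi)[disc]
  expect_lte(mean(err_cor), mean(err_raw) + 1e-9)
})

test_that("surface-set invariants are enforced", {
  bm <- matrix(10, 4, 4); csi <- matrix(20, 4, 4)
  expect_silent(surface_set(bm, csi))
  bad <- csi; bad[2, 2] <- 5; bad[3, 3] <- 5
  expect_error(surface_set(bm, bad), "2 A-scan")
  expect_error(surface_set(matrix(0.2, 4, 4), csi), ">= 1")
})

test_that("manual corrections are applied sparsely and validated", {
  ss <- surface_set(matrix(10, 6, 6), matrix(40, 6, 6))
  expect_identical(
    apply_corrections(ss, data.frame(surface = character(0), y = integer(0),
                                     x = integer(0), z = numeric(0))),
    ss)
  fix <- data.frame(surface = "bm", y = 3, x = 5, z = 12)
  out <- apply_corrections(ss, fix)
  expect_equal(out$bm[3, 5], 12)
  expect_equal(sum(out$bm != 10), 1L)
  expect_identical(out$provenance[3, 5], "corrected")
  expect_identical(out$provenance[1, 1], "auto")
  bad <- data.frame(surface = "csi", y = 2, x = 2, z = 5)
  expect_error(apply_corrections(ss, bad), "y=2, x=2")
})
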