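test_that("circle pixel count matches the analytic area at native resolution", {
  m <- circle_mask(c(500, 500), c(250.5, 250.5), diameter_mm = 5,
                   spacing_um = 24)
  r_px <- 5000 / 2 / 24
  expect_lt(abs(sum(m) - pi * r_px^2) / (pi * r_px^2), 0.01)
})

test_that("degenerate and oversized circles behave as specified", {
  expect_lte(sum(circle_mask(c(21, 21), c(11, 11), 0, 100)), 1)
  expect_error(circle_mask(c(64, 64), c(5, 32), diameter_mm = 11,
                           spacing_um = 187.5),
               "exceeds the grid by")
})

test_that("rim and circles satisfy the exact set identities", {
  spec <- region_spec(c(32.5, 32.5), 187.5)
  rm <- region_masks(spec, c(64, 64))
  expect_identical(rm$rim, rm$circle11 & !rm$circle5)
  expect_identical(rm$rim | rm$circle5, rm$circle11)
  expect_false(any(rm$rim & rm$circle5))
})

test_that("combine_exclusions removes the ONH and artifact areas only", {
  region <- matrix(TRUE, 8, 8)
  expect_identical(combine_exclusions(region), region)
  onh <- matrix(FALSE, 8, 8); onh[1:2, 1:2] <- TRUE
  excl <- matrix(FALSE, 8, 8); excl[5, 5] <- TRUE
  out <- combine_exclusions(region, onh, excl)
  expect_false(any(out & (onh | excl)))
  expect_equal(sum(out), 64 - 5)
  expect_error(combine_exclusions(region, matrix(FALSE, 4, 4)),
               "shape mismatch")
})

test_that("an exclusion covering the whole region empties the analysis", {
  region <- matrix(TRUE, 6, 6)
  out <- combine_exclusions(region, combined_exclusion = region)
  expect_false(any(out))
  rm <- regional_mean(matrix(1, 6, 6), out)
  expect_true(is.na(rm$mean))
  expect_equal(rm$n_pixels, 0L)
})

test_that("the 10% CVI eligibility rule is a strict 'more than'", {
  c5 <- matrix(FALSE, 40, 40); c5[1:25, 1:40] <- TRUE   # 1000 pixels
  excl <- matrix(FALSE, 40, 40)
  excl[1, 1:100 %% 41] <- FALSE
  excl[1:25, 1:4] <- TRUE                                # 100 pixels = 10.0%
  e <- cvi_eligibility(excl, c5)
  expect_true(e$eligible)
  expect_equal(e$excluded_fraction, 0.1)
  excl[1, 5] <- TRUE                                     # 101 pixels = 10.1%
  e2 <- cvi_eligibility(excl, c5)
  expect_false(e2$eligible)
  expect_equal(e2$excluded_fraction, 0.101)
  e0 <- cvi_eligibility(matrix(FALSE, 40, 40), c5)
  expect_true(e0$eligible)
  expect_equal(e0$excluded_fraction, 0)
  expect_error(cvi_eligibility(excl, matrix(FALSE, 40, 40)), "empty")
})

test_that("shrinking an exclusion mask never revokes eligibility", {
  set.seed(50)
  c5 <- circle_mask(c(64, 64), c(32.5, 32.5), 5, 187.5)
  for (rep in 1:20) {
    excl <- matrix(stats::runif(64 * 64) < 0.12, 64, 64)
    sub <- excl & (matrix(stats::runif(64 * 64), 64, 64) < 0.7)
    e_big <- cvi_eligibility(excl, c5)
    e_small <- cvi_eligibility(sub, c5)
    if (e_big$eligible) expect_true(e_small$eligible)
    expect_lte(e_small$excluded_fraction, e_big$excluded_fraction)
  }
})

test_that("regional means are unweighted over included non-missing pixels", {
  m <- matrix(100, 10, 10)
  m[, 6:10] <- 200
  mask <- matrix(TRUE, 10, 10)
  expect_equal(regional_mean(m, mask)$mean, 150)
  expect_equal(regional_mean(matrix(7, 4, 4), matrix(c(TRUE, FALSE), 4, 4))$mean, 7)
  withna <- m; withna[1, 1] <- NA
  rm <- regional_mean(withna, mask)
  expect_equal(rm$n_pixels, 99L)
})

test_that("area-weighted identity ties the 5-mm, rim and 11-mm means together", {
  seg <- test_segmentation()
  tm <- thickness_map(seg$surfaces, seg$phantom$volume$axial_spacing_um)
  spec <- region_spec(seg$phantom$volume$fovea_center,
                      seg$phantom$volume$lateral_spacing_um)
  rm <- region_masks(spec, dim(tm$values))
  m5 <- regional_mean(tm, rm$circle5)
  mr <- regional_mean(tm, rm$rim)
  m11 <- regional_mean(tm, rm$circle11)
  expect_equal(m5$n_pixels + mr$n_pixels, m11$n_pixels)
  expect_equal((m5$mean * m5$n_pixels + mr$mean * mr$n_pixels) /
                 (m5$n_pixels + mr$n_pixels),
               m11$mean, tolerance = 1e-12)
})

test_that("phantom regional thickness matches the truth within 2 um", {
  seg <- test_segmentation()
  ph <- seg$phantom
  tm <- thickness_map(seg$surfaces, ph$volume$axial_spacing_um)
  spec <- region_spec(ph$volume$fovea_center, ph$volume$lateral_spacing_um)
  rm <- region_masks(spec, dim(tm$values))
  for (reg in names(rm)) {
    got <- regional_mean(tm, rm[[reg]])$mean
    want <- mean(ph$truth$true_thickness_map[rm[[reg]]])
    expect_lt(abs(got - want), 2)
  }
})
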