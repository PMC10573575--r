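test_that("TIFF + JSON round trip is exact for integer volumes", {
  set.seed(2)
  arr <- array(as.double(sample(0:4000, 12 * 10 * 8, replace = TRUE)),
               dim = c(12, 10, 8))
  vol <- oct_volume(arr, axial_spacing_um = 1.95, lateral_spacing_um = 24,
                    signal_strength = 8L, visit_label = "pretreatment",
                    laterality = "OS", mnv_type = 2L,
                    patient_id = "P9", eye_id = "P9_OS",
                    onh_mask = matrix(c(TRUE, rep(FALSE, 119)), 12, 10))
  path <- tempfile(fileext = ".tiff")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$intensity, vol$intensity, ignore_attr = FALSE,
               tolerance = 0)
  expect_equal(back$axial_spacing_um, vol$axial_spacing_um)
  expect_equal(back$fovea_center, vol$fovea_center)
  expect_identical(back$laterality, "OS")
  expect_identical(back$visit_label, "pretreatment")
  expect_identical(back$signal_strength, 8L)
  expect_identical(back$mnv_type, 2L)
  expect_identical(back$onh_mask, vol$onh_mask)
})

test_that("missing metadata fields are reported by name", {
  arr <- array(1, dim = c(4, 4, 3))
  vol <- oct_volume(arr, axial_spacing_um = 2)
  path <- tempfile(fileext = ".tiff")
  write_volume(vol, path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  meta$axial_spacing_um <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_volume(path), "axial_spacing_um")
})

test_that("page-count mismatch is detected", {
  arr <- array(1, dim = c(4, 4, 3))
  vol <- oct_volume(arr, axial_spacing_um = 2)
  path <- tempfile(fileext = ".tiff")
  write_volume(vol, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$nz <- 5
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_volume(path), "page count")
})

test_that("grid CSV round-trips values including missing entries", {
  m <- matrix(stats::rnorm(30), 5, 6)
  m[2, 3] <- NA
  path <- tempfile(fileext = ".csv")
  write_grid_csv(m, path)
  expect_equal(read_grid_csv(path), unname(m), tolerance = 1e-12)
})

test_that("quality gate follows the strict 'less than 7' rule", {
  arr <- array(1, dim = c(4, 4, 3))
  v6 <- oct_volume(arr, axial_spacing_um = 2, signal_strength = 6L)
  v7 <- oct_volume(arr, axial_spacing_um = 2, signal_strength = 7L)
  v10 <- oct_volume(arr, axial_spacing_um = 2, signal_strength = 10L)
  expect_false(quality_gate(v6)$pass)
  expect_match(quality_gate(v6)$reason, "6 < 7")
  expect_true(quality_gate(v7)$pass)
  expect_true(quality_gate(v10)$pass)
})

test_that("the native scan geometry implies 24-um A-scan spacing", {
  p <- phantom_params(grid_nx = 500, grid_ny = 500, grid_nz = 1536)
  expect_equal(p$lateral_spacing_um, 24)
  expect_equal(p$grid_nx * p$lateral_spacing_um, 12000)
})

test_that("project_slab matches a per-A-scan loop and handles empty slabs", {
  set.seed(8)
  arr <- array(sample(0:50, 6 * 5 * 20, replace = TRUE), dim = c(6, 5, 20))
  top <- matrix(sample(2:8, 30, replace = TRUE), 6, 5)
  bottom <- top + matrix(sample(0:9, 30, replace = TRUE), 6, 5)
  for (red in c("mean", "max", "sum")) {
    got <- project_slab(arr, top, bottom, red)$values
    for (y in 1:6) for (x in 1:5) {
      zs <- seq_len(20)
      zs <- zs[zs >= top[y, x] & zs < bottom[y, x]]
      if (!length(zs)) {
        expect_true(is.na(got[y, x]))
      } else {
        expected <- switch(red, mean = mean(arr[y, x, zs]),
                           max = max(arr[y, x, zs]),
                           sum = sum(arr[y, x, zs]))
        expect_identical(got[y, x], as.numeric(expected))
      }
    }
  }
})

test_that("project_slab of a constant volume is constant; crossings error", {
  arr <- array(7, dim = c(4, 4, 10))
  top <- matrix(2, 4, 4); bottom <- matrix(9, 4, 4)
  expect_true(all(project_slab(arr, top, bottom, "mean")$values == 7))
  expect_true(all(is.na(project_slab(arr, top, top, "mean")$values)))
  bad_top <- top; bad_top[1, 1] <- 9.5; bad_top[2, 2] <- 9.5
  expect_error(project_slab(arr, bad_top, bottom), "2 A-scan")
})

test_that("enface ratio maps reject out-of-range values", {
  expect_error(enface_map(matrix(1.5, 2, 2), units = "ratio"), "\\[0, 1\\]")
  expect_silent(enface_map(matrix(c(0, NA, 0.5, 1), 2, 2), units = "ratio"))
})
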