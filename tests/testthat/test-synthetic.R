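test_that("zero vessel target yields an all-zero fraction map", {
  ph <- generate_phantom(phantom_params(seed = 1, vessel_fraction_target = 0,
                                        speckle = FALSE))
  expect_true(all(ph$truth$true_vessel_fraction_map == 0))
  expect_false(any(ph$truth$true_vessel_mask))
})

test_that("zero-amplitude thickness field gives an exactly constant truth map", {
  ph <- generate_phantom(phantom_params(
    seed = 2, vessel_fraction_target = 0, speckle = FALSE,
    thickness_um = c(mean = 150, amplitude = 0)))
  expect_true(all(ph$truth$true_thickness_map == 150))
})

test_that("vessel fraction recount from the emitted mask hits the target band", {
  ph <- test_phantom()
  tr <- ph$truth
  zt <- round(tr$true_bm + 0.0)
  zt <- floor(tr$true_bm + 0.5); zb <- floor(tr$true_csi + 0.5)
  slab <- pmax(zb - zt, 0)
  cnt <- matrix(0L, nrow(zt), ncol(zt))
  for (z in seq_len(dim(tr$true_vessel_mask)[3]))
    cnt <- cnt + tr$true_vessel_mask[, , z]
  ## integer identity between mask and fraction map
  expect_equal(ifelse(slab > 0, cnt / slab, NA_real_),
               tr$true_vessel_fraction_map)
  ## recounted global fraction within +/- 0.01 of the 0.6 target
  global <- sum(cnt) / sum(slab)
  expect_gte(global, 0.59)
  expect_lte(global, 0.61)
  expect_equal(global, tr$fraction, tolerance = 1e-12)
})

test_that("without attenuation and speckle, voxels carry the assigned levels", {
  lv <- c(vitreous = 10, retina = 120, rpe = 250, stroma = 180,
          vessel = 60, sclera = 40)
  zero_mu <- setNames(rep(0, 6), names(lv))
  ph <- generate_phantom(phantom_params(
    seed = 3, speckle = FALSE, attenuation_um1 = zero_mu, levels = lv,
    bm_depth_um = c(mean = 230, amplitude = 0),
    thickness_um = c(mean = 150, amplitude = 0)))
  arr <- ph$volume$intensity
  zt <- floor(ph$truth$true_bm[1, 1] + 0.5)
  zb <- floor(ph$truth$true_csi[1, 1] + 0.5)
  expect_equal(unname(arr[1, 1, 1]), 10)              # vitreous
  slab_vals <- unique(as.vector(arr[, , zt:(zb - 1)]))
  expect_true(all(slab_vals %in% c(60, 180)))          # vessel / stroma only
  expect_equal(unname(arr[1, 1, zt - 2]), 250)         # RPE band
  expect_equal(unname(arr[1, 1, zb]), 40)              # sclera at the CSI
  expect_true(any(arr == 120))                         # retina present
})

test_that("unreachable vessel fractions raise an informative error", {
  expect_error(
    generate_phantom(phantom_params(seed = 4, vessel_fraction_target = 0.995,
                                    speckle = FALSE)),
    "unreachable|achieved")
})

test_that("longitudinal series with zero deltas reproduces the baseline", {
  p <- phantom_params(seed = 5, speckle = FALSE)
  ser <- generate_longitudinal_phantoms(
    p, delta_thickness_um = c(0, 0), delta_vessel_fraction = c(0, 0),
    transforms = list(c(0, 0, 0), c(0, 0, 0)),
    visit_labels = c("pretreatment", "exudation"))
  expect_equal(ser[[1]]$truth$true_thickness_map,
               ser[[2]]$truth$true_thickness_map)
  expect_identical(ser[[1]]$volume$intensity, ser[[2]]$volume$intensity)
})

test_that("programmed thickness deltas appear exactly in the truth maps", {
  p <- phantom_params(seed = 6, speckle = FALSE)
  ser <- generate_longitudinal_phantoms(
    p, delta_thickness_um = c(0, 12.7), delta_vessel_fraction = c(0, 0),
    transforms = list(c(0, 0, 0), c(0, 0, 0)),
    visit_labels = c("pretreatment", "exudation"))
  d <- mean(ser[[2]]$truth$true_thickness_map) -
    mean(ser[[1]]$truth$true_thickness_map)
  expect_equal(d, 12.7, tolerance = 0.5)
})

test_that("applied rigid transforms are recorded exactly and gate the fovea", {
  p <- phantom_params(seed = 8, speckle = FALSE)
  ser <- generate_longitudinal_phantoms(
    p, delta_thickness_um = c(0, 0), delta_vessel_fraction = c(0, 0),
    transforms = list(c(0, 0, 0), c(5, -3, 0)),
    visit_labels = c("pretreatment", "exudation"))
  expect_equal(unname(ser[[2]]$truth$applied_transform), c(5, -3, 0))
  expect_error(
    generate_longitudinal_phantoms(
      p, delta_thickness_um = c(0, 0), delta_vessel_fraction = c(0, 0),
      transforms = list(c(0, 0, 0), c(200, 0, 0)),
      visit_labels = c("pretreatment", "exudation")),
    "fovea")
  expect_error(
    generate_longitudinal_phantoms(p, delta_thickness_um = 0,
                                   delta_vessel_fraction = 0,
                                   transforms = list(c(0, 0, 0))),
    "at least 2 visits")
})

test_that("noise-free cohort reproduces the programmed visit deltas exactly", {
  cp <- cohort_params(
    n_patients = 5,
    thickness = list(baseline_mean = 200, between_patient_sd = 0,
                     between_eye_sd = 0, residual_sd = 0,
                     delta_exudation = 10, delta_treatment = -10),
    cvi = list(baseline_mean = 0.6, between_patient_sd = 0,
               between_eye_sd = 0, residual_sd = 0,
               delta_exudation = 0.05, delta_treatment = -0.05),
    seed = 9)
  coh <- generate_cohort(cp)
  w <- reshape(coh[, c("eye_id", "visit", "thickness")],
               idvar = "eye_id", timevar = "visit", direction = "wide")
  expect_true(all(w$thickness.exudation - w$thickness.pretreatment == 10))
  expect_true(all(w$thickness.post_treatment - w$thickness.exudation == -10))
})

test_that("fellow-eye probability drives the eye count", {
  coh <- generate_cohort(cohort_params(n_patients = 20, p_fellow_eye = 0,
                                       seed = 10))
  expect_equal(length(unique(coh$eye_id)), length(unique(coh$patient_id)))
  ## expectation 37 * (1 + 4/37) = 41 eyes at the study conditions
  ne <- vapply(1:400, function(s)
    length(unique(generate_cohort(cohort_params(seed = s))$eye_id)), 0)
  se <- sqrt(37 * (4 / 37) * (1 - 4 / 37)) / sqrt(400)
  expect_lt(abs(mean(ne) - 41), 3 * se + 1e-9)
})

test_that("mean per-eye change converges to the programmed delta", {
  coh <- generate_cohort(cohort_params(n_patients = 600, seed = 12))
  rec <- cohort_to_records(coh)
  ch <- suppressMessages(change_scores(rec, "pretreatment", "exudation",
                                       metric = "thickness_um"))
  se <- stats::sd(ch$change) / sqrt(nrow(ch))
  expect_lt(abs(mean(ch$change) - 12.7), 3 * se)
})

test_that("cohort parameter validation catches bad inputs", {
  expect_error(cohort_params(n_patients = 1), ">= 2")
  expect_error(cohort_params(mnv_type_probs = c(0.5, 0.5, 0.5)), "sum to 1")
})
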