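## End-to-end per-eye quantification and cohort analysis.

#' Pipeline configuration
#'
#' @param out_dir Optional output directory; when set, measurements, maps,
#'   transforms and logs are written there.
#' @param attenuation List: `exponent_n`, `epsilon`, `rescale`.
#' @param segmentation List of [segment_choroid()] arguments.
#' @param despeckle List of [despeckle_volume()] arguments for the
#'   binarization input.
#' @param mask_clean_k Window of the [clean_vessel_mask()] majority vote
#'   (default 9).
#' @param registration List: `rotation_bound_deg`, `rotation_step_deg`,
#'   `upsample`.
#' @param region_diameters_mm Circle diameters (default `c(5, 11)`).
#' @param eligibility_threshold CVI exclusion-area threshold (default 0.10).
#' @param min_signal_strength Quality-gate threshold (default 7).
#' @param correction Sandwich correction for the statistics (default
#'   `"CR1"`).
#' @param reference_visit Visit defining the common frame; the day of
#'   exudation, since every eye has it.
#' @param seed Seed recorded in the config (the quantification itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL,
                            attenuation = list(),
                            segmentation = list(),
                            despeckle = list(),
                            mask_clean_k = 9L,
                            registration = list(),
                            region_diameters_mm = c(5, 11),
                            eligibility_threshold = 0.10,
                            min_signal_strength = 7,
                            correction = "CR1",
                            reference_visit = "exudation",
                            seed = 1L) {
  atten <- utils::modifyList(
    list(exponent_n = 2, epsilon = NULL, rescale = "none"), attenuation)
  reg <- utils::modifyList(
    list(rotation_bound_deg = 5, rotation_step_deg = 0.25, upsample = 10),
    registration)
  stopifnot(eligibility_threshold >= 0, eligibility_threshold <= 1,
            min_signal_strength >= 0, min_signal_strength <= 10,
            reference_visit %in% VISIT_LABELS,
            correction %in% c("CR0", "CR1"))
  dsp <- utils::modifyList(
    list(median_k = 7L, sigma_z = 2, log_scale = TRUE), despeckle)
  structure(list(out_dir = out_dir, attenuation = atten,
                 segmentation = segmentation,
                 despeckle = dsp, mask_clean_k = as.integer(mask_clean_k),
                 registration = reg,
                 region_diameters_mm = region_diameters_mm,
                 eligibility_threshold = eligibility_threshold,
                 min_signal_strength = min_signal_strength,
                 correction = correction, reference_visit = reference_visit,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_entry <- function(stage, eye, visit, message) {
  list(stage = stage, eye = eye, visit = visit, message = message)
}

#' Quantify one eye across its visits
#'
#' Runs the full measurement chain for one eye: quality gate, attenuation
#' compensation, BM/CSI segmentation, thickness and CVI maps, rigid
#' registration of every visit to the reference (day-of-exudation) visit on
#' mean choroidal-slab projections, warping of maps and per-visit exclusion
#' masks into the reference frame, construction of the fovea-centered
#' regions, the combined exclusion mask, the CVI eligibility flag, and
#' regional means.  Deterministic for fixed inputs and configuration.
#'
#' @param visits Named list of [oct_volume]s (names = visit labels), or a
#'   list of `c(tiff, json)` paths to read.
#' @param config A [pipeline_config].
#' @param exclusion_masks Optional named list (per visit) of logical matrices
#'   outlining areas where the choroid could not be measured at that visit,
#'   in that visit's own frame.
#' @param corrections Optional named list (per visit) of manual surface
#'   corrections for [apply_corrections()].
#' @return A list of class `choroid_quantification`: `records` (measurement
#'   data frame), `maps`, `surfaces`, `transforms`, `thresholds`,
#'   `masks`, `log`.
#' @export
run_quantify <- function(visits, config = pipeline_config(),
                         exclusion_masks = NULL, corrections = NULL) {
  if (!length(visits)) stop("no visits supplied")
  if (is.null(names(visits)) || any(names(visits) == ""))
    stop("visits must be a named list (names = visit labels)")
  visits <- lapply(visits, function(v) {
    if (inherits(v, "oct_volume")) v else read_volume(v[[1]],
      if (length(v) > 1) v[[2]] else NULL)
  })
  logs <- list()
  ## quality gate
  keep <- character(0)
  for (nm in names(visits)) {
    qg <- quality_gate(visits[[nm]], config$min_signal_strength)
    if (qg$pass) keep <- c(keep, nm)
    else logs[[length(logs) + 1L]] <-
      log_entry("quality_gate", visits[[nm]]$eye_id, nm, qg$reason)
  }
  if (!length(keep)) stop("no visit passed the quality gate")
  if (!(config$reference_visit %in% keep))
    stop(sprintf("reference visit '%s' missing or rejected",
                 config$reference_visit))
  visits <- visits[keep]
  ref_name <- config$reference_visit
  ref_vol <- visits[[ref_name]]
  d <- dim(ref_vol)

  per_visit <- list()
  for (nm in names(visits)) {
    vol <- visits[[nm]]
    corrected <- do.call(compensate_attenuation,
                         c(list(vol), config$attenuation))
    ss <- do.call(segment_choroid,
                  c(list(vol, corrected = corrected), config$segmentation))
    if (!is.null(corrections[[nm]]))
      ss <- apply_corrections(ss, corrections[[nm]])
    thick <- thickness_map(ss, vol$axial_spacing_um)
    denoised <- do.call(despeckle_volume,
                        c(list(corrected$intensity), config$despeckle))
    thr <- otsu_threshold(slab_values(denoised, ss))
    vmask <- binarize_vessels(denoised, ss, thr)
    vmask <- clean_vessel_mask(vmask, ss, k = config$mask_clean_k)
    cvi <- cvi_map(vmask, ss)
    feat <- project_slab(corrected, ss$bm, ss$csi, "mean")
    per_visit[[nm]] <- list(volume = vol, surfaces = ss, thickness = thick,
                            cvi = cvi, threshold = thr, feature = feat)
    logs[[length(logs) + 1L]] <-
      log_entry("quantify", vol$eye_id, nm,
                sprintf("otsu threshold %.6g", thr))
  }

  ## registration to the reference visit, then warp maps and exclusions
  transforms <- list()
  for (nm in names(per_visit)) {
    if (nm == ref_name) {
      transforms[[nm]] <- rigid_transform_2d(0, 0, 0, fixed_id = ref_name,
                                             moving_id = nm, score = 1)
      next
    }
    tf <- do.call(register_enface,
                  c(list(moving = per_visit[[nm]]$feature,
                         fixed = per_visit[[ref_name]]$feature),
                    config$registration))
    tf$fixed_id <- ref_name; tf$moving_id <- nm
    transforms[[nm]] <- tf
    logs[[length(logs) + 1L]] <-
      log_entry("register", ref_vol$eye_id, nm,
                sprintf("dx %.2f dy %.2f dtheta %.2f (score %.3f)",
                        tf$dx_px, tf$dy_px, tf$dtheta_deg, tf$score))
  }
  warped <- list()
  excl_warped <- list()
  for (nm in names(per_visit)) {
    tf <- transforms[[nm]]
    warped[[nm]] <- list(
      thickness = warp_enface(per_visit[[nm]]$thickness, tf),
      cvi = warp_enface(per_visit[[nm]]$cvi, tf))
    if (!is.null(exclusion_masks[[nm]]))
      excl_warped[[nm]] <- warp_enface(exclusion_masks[[nm]], tf)
  }
  combined_excl <- union_masks(excl_warped, shape = d[1:2])

  ## regions in the reference frame
  spec <- region_spec(ref_vol$fovea_center, ref_vol$lateral_spacing_um,
                      config$region_diameters_mm)
  rmasks <- region_masks(spec, d[1:2])
  elig <- cvi_eligibility(combined_excl, rmasks$circle5,
                          config$eligibility_threshold)
  analysis <- lapply(rmasks, combine_exclusions, onh_mask = ref_vol$onh_mask,
                     combined_exclusion = combined_excl)

  rows <- list()
  for (nm in names(per_visit)) {
    vol <- per_visit[[nm]]$volume
    for (reg in names(analysis)) {
      for (met in c("thickness_um", "cvi")) {
        mp <- if (met == "cvi") warped[[nm]]$cvi else warped[[nm]]$thickness
        rm <- regional_mean(mp, analysis[[reg]])
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = vol$patient_id, eye_id = vol$eye_id,
          mnv_type = vol$mnv_type, visit = nm, region = reg, metric = met,
          value = rm$mean, n_pixels = rm$n_pixels,
          eligible = if (met == "cvi") elig$eligible else TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  out <- structure(list(records = records, maps = warped,
                        surfaces = lapply(per_visit, `[[`, "surfaces"),
                        transforms = transforms,
                        thresholds = vapply(per_visit, `[[`, 0, "threshold"),
                        masks = list(regions = rmasks, analysis = analysis,
                                     combined_exclusion = combined_excl,
                                     eligibility = elig),
                        log = logs),
                   class = "choroid_quantification")
  if (!is.null(config$out_dir)) write_quantification(out, config$out_dir)
  out
}

write_quantification <- function(q, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(q$records, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  for (nm in names(q$maps)) {
    write_grid_csv(q$maps[[nm]]$thickness,
                   file.path(out_dir, sprintf("thickness_%s.csv", nm)))
    write_grid_csv(q$maps[[nm]]$cvi,
                   file.path(out_dir, sprintf("cvi_%s.csv", nm)))
    write_transform(q$transforms[[nm]],
                    file.path(out_dir, sprintf("transform_%s.json", nm)))
  }
  log_lines <- vapply(q$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), "")
  writeLines(log_lines, file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}

#' Cohort-level longitudinal analysis
#'
#' Produces the six-table longitudinal report: for each of the three visit
#' pairs (pretreatment to day of exudation, day of exudation to
#' post-treatment, pretreatment to post-treatment), the all-eyes summary and
#' the by-MNV-type comparison (type 1 or 2 vs type 3), with cluster-robust
#' p-values.
#'
#' @param records Measurement records (data frame or CSV path), e.g. from
#'   [run_quantify()] or [cohort_to_records()].
#' @param config A [pipeline_config].
#' @return The [summarize_tables()] list; written as CSVs when
#'   `config$out_dir` is set.
#' @export
run_analyze <- function(records, config = pipeline_config()) {
  if (is.character(records)) records <- utils::read.csv(records)
  if (is.null(records) || !nrow(records))
    stop("no measurement records to analyze")
  if (length(unique(records$eye_id)) < 2L)
    stop("need at least 2 eyes")
  tables <- summarize_tables(records, correction = config$correction)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]]$all_eyes,
                       file.path(config$out_dir, sprintf("table_%s_all.csv", nm)),
                       row.names = FALSE)
      if (!is.null(tables[[nm]]$by_type))
        utils::write.csv(tables[[nm]]$by_type,
                         file.path(config$out_dir, sprintf("table_%s_by_type.csv", nm)),
                         row.names = FALSE)
    }
  }
  tables
}
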