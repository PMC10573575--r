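## Synthetic longitudinal cohorts with fellow-eye clustering.
##
## Measurement model per eye and visit:
##   value = baseline + patient effect + eye effect + visit delta + residual,
## all Gaussian.  Fellow eyes of one patient share the patient effect, which
## is what makes naive (independence) standard errors anticonservative and
## motivates the cluster-robust variance downstream.

#' Cohort simulation parameters
#'
#' Defaults emulate the study population: 37 patients contributing 41 eyes
#' (fellow-eye probability 4/37), MNV type mix 24/4/13 for types 1/2/3, a
#' 5-mm-circle baseline thickness of 200.7 um rising by 12.7 um at the day
#' of exudation and falling by 19.5 um after treatment, and CVI 0.617 with
#' changes +0.014 and -0.017.  Residual SDs are set so the SD of per-eye
#' changes (`sqrt(2) * residual_sd`) matches the observed change SDs
#' (22.8 um and 0.023); between-patient/between-eye SDs partition the
#' remaining cross-sectional variance (69.5 um, 0.039 total SD).
#'
#' @param n_patients Number of patients (>= 2).
#' @param p_fellow_eye Probability a patient contributes both eyes.
#' @param mnv_type_probs Probabilities of MNV type 1, 2, 3 per eye.
#' @param thickness,cvi Lists with `baseline_mean`, `between_patient_sd`,
#'   `between_eye_sd`, `residual_sd`, `delta_exudation` (pretreatment to day
#'   of exudation) and `delta_treatment` (day of exudation to
#'   post-treatment).
#' @param seed Integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 37, p_fellow_eye = 4 / 37,
                          mnv_type_probs = c(24, 4, 13) / 41,
                          thickness = list(baseline_mean = 200.7,
                                           between_patient_sd = 64.6,
                                           between_eye_sd = 20,
                                           residual_sd = 22.8 / sqrt(2),
                                           delta_exudation = 12.7,
                                           delta_treatment = -19.5),
                          cvi = list(baseline_mean = 0.617,
                                     between_patient_sd = 0.034,
                                     between_eye_sd = 0.010,
                                     residual_sd = 0.023 / sqrt(2),
                                     delta_exudation = 0.014,
                                     delta_treatment = -0.017),
                          seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (p_fellow_eye < 0 || p_fellow_eye > 1)
    stop("p_fellow_eye must be in [0, 1]")
  if (abs(sum(mnv_type_probs) - 1) > 1e-8)
    stop("mnv_type_probs must sum to 1")
  for (m in list(thickness, cvi)) {
    sds <- unlist(m[c("between_patient_sd", "between_eye_sd", "residual_sd")])
    if (any(sds < 0)) stop("standard deviations must be >= 0")
  }
  structure(list(n_patients = as.integer(n_patients),
                 p_fellow_eye = p_fellow_eye,
                 mnv_type_probs = mnv_type_probs,
                 thickness = thickness, cvi = cvi,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Simulate a longitudinal cohort
#'
#' @param params A [cohort_params] object.
#' @return A long-format data frame with one row per eye and visit:
#'   `patient_id`, `eye_id`, `mnv_type`, `visit` (one of
#'   `r paste(VISIT_LABELS, collapse = ", ")`), `thickness`, `cvi`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  p <- params
  set.seed(p$seed)
  rows <- vector("list", p$n_patients * 2L)
  n_row <- 0L
  for (i in seq_len(p$n_patients)) {
    pid <- sprintf("P%03d", i)
    pat_th <- stats::rnorm(1, 0, p$thickness$between_patient_sd)
    pat_cv <- stats::rnorm(1, 0, p$cvi$between_patient_sd)
    n_eyes <- 1L + stats::rbinom(1, 1, p$p_fellow_eye)
    lats <- c("OD", "OS")[seq_len(n_eyes)]
    for (lat in lats) {
      eye_th <- stats::rnorm(1, 0, p$thickness$between_eye_sd)
      eye_cv <- stats::rnorm(1, 0, p$cvi$between_eye_sd)
      mnv <- sample.int(3L, 1L, prob = p$mnv_type_probs)
      mu_th <- p$thickness$baseline_mean + pat_th + eye_th +
        cumsum(c(0, p$thickness$delta_exudation, p$thickness$delta_treatment))
      mu_cv <- p$cvi$baseline_mean + pat_cv + eye_cv +
        cumsum(c(0, p$cvi$delta_exudation, p$cvi$delta_treatment))
      th <- mu_th + stats::rnorm(3, 0, p$thickness$residual_sd)
      cv <- mu_cv + stats::rnorm(3, 0, p$cvi$residual_sd)
      n_row <- n_row + 1L
      rows[[n_row]] <- data.frame(
        patient_id = pid, eye_id = paste0(pid, "_", lat),
        mnv_type = mnv, visit = VISIT_LABELS,
        thickness = th, cvi = cv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(n_row)])
  rownames(out) <- NULL
  out
}

#' Reshape a simulated cohort into measurement records
#'
#' @param cohort Output of [generate_cohort()].
#' @param region Region label to attach (default `"circle5"`).
#' @return A measurement-record data frame with columns `patient_id`,
#'   `eye_id`, `mnv_type`, `visit`, `region`, `metric`
#'   (`"thickness_um"` / `"cvi"`), `value`, `eligible`.
#' @export
cohort_to_records <- function(cohort, region = "circle5") {
  long <- rbind(
    data.frame(cohort[c("patient_id", "eye_id", "mnv_type", "visit")],
               region = region, metric = "thickness_um",
               value = cohort$thickness, stringsAsFactors = FALSE),
    data.frame(cohort[c("patient_id", "eye_id", "mnv_type", "visit")],
               region = region, metric = "cvi",
               value = cohort$cvi, stringsAsFactors = FALSE))
  long$eligible <- TRUE
  long
}
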