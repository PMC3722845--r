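#' Configuration for the synthetic cohort generator
#'
#' Distributional choices for the covariates. The study design only fixes
#' ranges (age 4 months to 13 years, weight 6--46 kg, four drug groups,
#' binary sex/disease/test/complication, three monitored vitals), so the
#' generator defaults to neutral distributions that respect those ranges:
#' uniform for age and weight, Bernoulli(0.5) for binaries, and truncated
#' normals for the vitals. Vitals are re-drawn at every wave with a
#' within-patient correlation (compound-symmetric, default 0.7); the other
#' covariates are baseline-constant.
#'
#' @param age_range age bounds in months (default 4 to 156).
#' @param weight_range weight bounds in kg (default 6 to 46).
#' @param p_sex,p_disease,p_test,p_comp Bernoulli probabilities for the
#'   binary covariates.
#' @param vitals named list of `c(mean, sd, min, max)` for `sbp` (systolic
#'   blood pressure, mmHg), `pul` (pulse, beats/min) and `osat` (oxygen
#'   saturation, %).
#' @param vitals_rho within-patient correlation of a vital across waves.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(age_range = c(4, 156),
                          weight_range = c(6, 46),
                          p_sex = 0.5, p_disease = 0.5,
                          p_test = 0.5, p_comp = 0.5,
                          vitals = list(
                            sbp  = c(mean = 105, sd = 12,  min = 70, max = 150),
                            pul  = c(mean = 100, sd = 14,  min = 60, max = 160),
                            osat = c(mean = 97,  sd = 1.5, min = 85, max = 100)),
                          vitals_rho = 0.7) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            length(weight_range) == 2, weight_range[1] < weight_range[2],
            vitals_rho >= 0, vitals_rho < 1)
  cfg <- list(age_range = age_range, weight_range = weight_range,
              p_sex = p_sex, p_disease = p_disease, p_test = p_test,
              p_comp = p_comp, vitals = vitals, vitals_rho = vitals_rho)
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort with the design of the sedation study: patients assigned to
#' the four drug groups M (Midazolam), D (Diazepam), L (Luminal) and C
#' (Cardiac Cocktail), baseline covariates, and per-wave vital signs. The
#' default sizes reproduce the study's 30/31/32/34 split over 127 children.
#'
#' @param n_patients number of patients.
#' @param group_sizes integer vector of length 4, sizes of groups M, D, L, C
#'   (must sum to `n_patients`).
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @param config a [cohort_config()].
#' @param n_waves number of measurement occasions (default 3: 15/30/60 min).
#' @return a `data.frame` of class `sed_cohort` in long format, one row per
#'   patient x wave, with columns `patient_id`, `wave`, `group`, `age_months`,
#'   `weight_kg`, `sex`, `disease`, `test`, `comp`, `sbp`, `pul`, `osat`.
#'   Baseline covariates repeat across a patient's waves; vitals vary.
#' @export
#' @examples
#' coh <- generate_cohort(127, c(30, 31, 32, 34), seed = 1)
#' table(coh$group[coh$wave == 1])
generate_cohort <- function(n_patients = 127L,
                            group_sizes = c(M = 30L, D = 31L, L = 32L, C = 34L),
                            seed = 1L,
                            config = cohort_config(),
                            n_waves = 3L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (length(group_sizes) != 4L)
    stop("group_sizes must have length 4 (groups M, D, L, C)")
  if (sum(group_sizes) != n_patients)
    stop(sprintf("group_sizes sum to %d but n_patients is %d",
                 sum(group_sizes), n_patients))
  stopifnot(inherits(config, "cohort_config"), n_waves >= 1L)

  set.seed(as.integer(seed))
  group <- factor(rep(c("M", "D", "L", "C"), times = group_sizes),
                  levels = c("M", "D", "L", "C"))
  age    <- stats::runif(n_patients, config$age_range[1], config$age_range[2])
  weight <- stats::runif(n_patients, config$weight_range[1], config$weight_range[2])
  sex     <- stats::rbinom(n_patients, 1L, config$p_sex)
  disease <- stats::rbinom(n_patients, 1L, config$p_disease)
  test    <- stats::rbinom(n_patients, 1L, config$p_test)
  comp    <- stats::rbinom(n_patients, 1L, config$p_comp)

  # Compound-symmetric vitals: shared patient component + wave noise, then
  # clamped to the physiological bounds (clamping is rare at the default
  # parameters; documented in the methods vignette).
  rho <- config$vitals_rho
  draw_vital <- function(v) {
    base <- stats::rnorm(n_patients)
    out <- matrix(0, n_patients, n_waves)
    for (w in seq_len(n_waves)) {
      e <- stats::rnorm(n_patients)
      z <- sqrt(rho) * base + sqrt(1 - rho) * e
      out[, w] <- pmin(pmax(v[["mean"]] + v[["sd"]] * z, v[["min"]]), v[["max"]])
    }
    out
  }
  sbp  <- draw_vital(config$vitals$sbp)
  pul  <- draw_vital(config$vitals$pul)
  osat <- draw_vital(config$vitals$osat)

  idx <- rep(seq_len(n_patients), each = n_waves)
  wv  <- rep(seq_len(n_waves), times = n_patients)
  out <- data.frame(
    patient_id = idx,
    wave       = wv,
    group      = group[idx],
    age_months = age[idx],
    weight_kg  = weight[idx],
    sex        = sex[idx],
    disease    = disease[idx],
    test       = test[idx],
    comp       = comp[idx],
    sbp        = sbp[cbind(idx, wv)],
    pul        = pul[cbind(idx, wv)],
    osat       = osat[cbind(idx, wv)],
    stringsAsFactors = FALSE)
  class(out) <- c("sed_cohort", "data.frame")
  attr(out, "n_waves") <- n_waves
  out
}

validate_cohort <- function(cohort) {
  need <- c("patient_id", "wave", "group", "age_months", "weight_kg",
            "sex", "disease", "test", "comp", "sbp", "pul", "osat")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  key <- paste(cohort$patient_id, cohort$wave)
  if (anyDuplicated(key))
    stop("cohort has duplicate (patient_id, wave) rows")
  invisible(cohort)
}
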