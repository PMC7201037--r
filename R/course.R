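# PatientCourse container: covariate timeline, dose events, TDM
# observations, all on an hours-from-first-dose time base.

#' Construct a vancomycin treatment course
#'
#' @param patient_id Pseudonymous identifier.
#' @param model_id Population model id, or `NULL` to select by age
#'   ([select_model()]).
#' @param age_days Chronological age at course start, days.
#' @param gestational_age Gestational age at birth, weeks (optional).
#' @param postmenstrual_age PMA at course start, weeks; derived from
#'   gestational age + age when omitted.
#' @param sex Optional, `"F"`/`"M"`.
#' @param covariates Data frame `time_h`, `weight` (kg), optionally
#'   `height` (cm), `serum_creatinine` (mg/dL).  Time-varying values are
#'   carried forward (LOCF) at each dose/prediction time.
#' @param doses Dose-event data frame ([dose_events()]).
#' @param observations Optional TDM data frame `time_h`, `conc` (mg/L),
#'   optional `flag` (`"used"`/`"excluded"`).
#' @param true_eta Simulated-truth random effects (synthetic courses only).
#' @param pediatric_model Pediatric-tier model when `model_id` is `NULL`.
#' @return A `vanc_course` object.
#' @export
patient_course <- function(patient_id, model_id = NULL, age_days,
                           gestational_age = NULL, postmenstrual_age = NULL,
                           sex = NULL, covariates, doses,
                           observations = NULL, true_eta = NULL,
                           pediatric_model = "le_pediatric") {
  stopifnot(is.data.frame(covariates), "time_h" %in% names(covariates),
            "weight" %in% names(covariates))
  doses <- dose_events(doses$start_time, doses$amount, doses$duration)
  if (is.null(observations)) {
    observations <- data.frame(time_h = numeric(0), conc = numeric(0),
                               flag = character(0))
  } else {
    stopifnot(all(c("time_h", "conc") %in% names(observations)))
    if (is.null(observations$flag)) observations$flag <- "used"
    stopifnot(all(observations$conc > 0), all(observations$time_h >= 0),
              all(observations$flag %in% c("used", "excluded")))
  }
  ga_known <- !is.null(gestational_age) && !is.na(gestational_age)
  if (is.null(postmenstrual_age) && ga_known) {
    postmenstrual_age <- gestational_age + age_days / 7
  }
  if (is.null(model_id)) {
    model_id <- select_model(gestational_age, postmenstrual_age, age_days,
                             pediatric_model)
  }
  structure(
    list(patient_id = patient_id, model_id = model_id,
         age_days = age_days,
         gestational_age = if (ga_known) gestational_age,
         postmenstrual_age = postmenstrual_age,
         sex = sex, covariates = covariates, doses = doses,
         observations = observations, true_eta = true_eta),
    class = "vanc_course"
  )
}

#' @export
print.vanc_course <- function(x, ...) {
  cat(sprintf("<vanc_course> %s  model: %s\n", x$patient_id, x$model_id))
  cat(sprintf("  %d dose(s), %d TDM observation(s), age %.0f d\n",
              nrow(x$doses), nrow(x$observations), x$age_days))
  invisible(x)
}

#' Model covariates in effect at a course time
#'
#' Combines the LOCF covariate timeline with ages advanced to `time` and,
#' when height is available, a creatinine clearance from the bedside
#' Schwartz eGFR (normalized ml/min/1.73 m2 used directly as ml/min by
#' default; Mosteller BSA de-normalization by option).
#'
#' @param course `vanc_course`.
#' @param time Hours from course start.
#' @param denormalize_crcl Rescale eGFR by BSA/1.73 before use as CrCl.
#' @return Named list of covariates for [typical_parameters()].
#' @export
course_covariates <- function(course, time, denormalize_crcl = FALSE) {
  cov <- covariates_at(course$covariates, time)
  cov$age_days <- course$age_days + time / 24
  if (!is.null(course$postmenstrual_age)) {
    cov$postmenstrual_age <- course$postmenstrual_age + time / (24 * 7)
  }
  if (!is.null(cov$height) && !is.null(cov$serum_creatinine)) {
    egfr <- schwartz_egfr(cov$height, cov$serum_creatinine)
    cov$crcl <- if (denormalize_crcl && !is.null(cov$weight)) {
      egfr * sqrt(cov$height * cov$weight / 3600) / 1.73
    } else {
      egfr
    }
  }
  cov
}

#' Typical parameters along a course
#'
#' Evaluates the population covariate equations at each dose start time
#' (LOCF covariates) and at a reference "current" time (the last dose).
#'
#' @param model Model id or `vanc_model`.
#' @param course `vanc_course`.
#' @return List with `per_dose` (list of `vanc_params`, one per dose
#'   event) and `current` (`vanc_params` at the last dose).
#' @export
course_typical <- function(model, course) {
  m <- get_model(model)
  per_dose <- lapply(course$doses$start_time, function(t) {
    typical_parameters(m, course_covariates(course, t))
  })
  t_last <- max(course$doses$start_time)
  list(per_dose = per_dose,
       current = typical_parameters(m, course_covariates(course, t_last)))
}
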