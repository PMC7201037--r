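# Decision-support layer: reference table, custom-regimen evaluation,
# target-seeking dose search, guideline empiric dosing, Schwartz eGFR,
# and TDM timing advice.

#' Bedside (modified) Schwartz estimated GFR
#'
#' eGFR = 0.413 x height(cm) / serum creatinine (mg/dL), in
#' ml/min/1.73 m2.
#'
#' @param height_cm Height, cm (> 0).
#' @param serum_creatinine Serum creatinine, mg/dL (> 0).
#' @return eGFR in ml/min/1.73 m2.
#' @examples
#' schwartz_egfr(105, 0.4)  # 108.4
#' @export
schwartz_egfr <- function(height_cm, serum_creatinine) {
  if (is.null(height_cm) || any(is.na(height_cm))) {
    stop("height is required to compute the Schwartz eGFR")
  }
  stopifnot(all(height_cm > 0), all(serum_creatinine > 0))
  0.413 * height_cm / serum_creatinine
}

#' Target exposure specification
#'
#' @param metric `"auc24_over_mic"` (steady-state AUC24/MIC) or
#'   `"trough"` (steady-state trough, mg/L).
#' @param lower,upper Target band (lower < upper).  Guideline defaults:
#'   AUC24/MIC > 400 (band 400-600 used for dose seeking); trough 10-15
#'   mg/L, or 15-20 mg/L for deep-seated infections.
#' @param mic Minimum inhibitory concentration, mg/L (default 1, updated
#'   per isolate).
#' @return `vanc_target` list.
#' @export
target_spec <- function(metric = c("auc24_over_mic", "trough"),
                        lower = 400, upper = 600, mic = 1) {
  metric <- match.arg(metric)
  stopifnot(lower < upper, mic > 0)
  structure(list(metric = metric, lower = lower, upper = upper, mic = mic),
            class = "vanc_target")
}

# Point-estimate value of the target metric under a posterior.
.target_metric <- function(posterior, reg, target) {
  m <- get_model(posterior$model_id)
  ind <- realize_individual(m, posterior$typical, posterior$eta_mode)
  ss <- steady_state_metrics(ind, reg)
  if (target$metric == "auc24_over_mic") ss$auc24_ss / target$mic
  else ss$trough_ss
}

#' Reference table at +/-15% and +/-30% of the current dose
#'
#' Five rows at dose multipliers 0.70, 0.85, 1.00, 1.15, 1.30 of the
#' current regimen (interval unchanged), each with point steady-state
#' metrics at the posterior mode and Monte-Carlo attainment
#' probabilities.
#'
#' @inheritParams attainment_probability
#' @param current Current [regimen()].
#' @return Data frame: `multiplier`, `dose_mg`, `interval_h`, `auc24_ss`,
#'   `trough_ss`, `p_auc24_gt_400`, `p_trough_gt_20`.
#' @export
reference_table <- function(posterior, current,
                            thresholds = c(auc24 = 400, trough = 20),
                            n = 10000, seed = 20200429) {
  mult <- c(0.70, 0.85, 1.00, 1.15, 1.30)
  rows <- lapply(mult, function(f) {
    reg <- regimen(current$dose * f, current$interval,
                   current$infusion_duration)
    s <- exposure_summary(posterior, reg, thresholds, n, seed)
    data.frame(multiplier = f, dose_mg = reg$dose,
               interval_h = reg$interval, auc24_ss = s$auc24_ss,
               trough_ss = s$trough_ss, p_auc24_gt_400 = s$p_auc24_gt_400,
               p_trough_gt_20 = s$p_trough_gt_20)
  })
  do.call(rbind, rows)
}

#' Evaluate a user-entered ("custom") regimen
#'
#' Same computation path as the reference-table rows, for any regimen.
#'
#' @inheritParams attainment_probability
#' @return Exposure summary list (see [exposure_summary()]).
#' @export
evaluate_custom_regimen <- function(posterior, reg,
                                    thresholds = c(auc24 = 400, trough = 20),
                                    n = 10000, seed = 20200429) {
  stopifnot(inherits(reg, "vanc_regimen"))
  exposure_summary(posterior, reg, thresholds, n, seed)
}

#' Dose-rounding increment by body weight
#'
#' 1 mg for neonates, 25 mg for children under 40 kg, 50 mg at >= 40 kg.
#'
#' @param weight Body weight, kg.
#' @param neonate Is the patient a neonate (neonatal model tier)?
#' @return Rounding increment, mg.
#' @export
dose_increment <- function(weight, neonate = FALSE) {
  if (neonate) 1 else if (weight < 40) 25 else 50
}

#' Search for the regimen most likely to hit a target band
#'
#' Over a grid of intervals (default 6, 8, 12, 24 h) and doses rounded to
#' the given increment, returns the regimen whose predicted metric (at
#' the posterior mode) is closest to the midpoint of the target band.
#' Ties are broken towards the longer interval, then the smaller dose.
#' Regimens whose predicted metric falls outside the band are infeasible;
#' if none qualifies, `NULL` is returned with attribute
#' `reason = "no feasible regimen"`.
#'
#' @param posterior `vanc_posterior`.
#' @param target [target_spec()].
#' @param intervals Allowed dosing intervals, h.
#' @param increment Dose rounding increment, mg.
#' @param infusion_duration Infusion duration, h.
#' @param max_dose Largest dose per administration considered, mg.
#' @return The selected [regimen()], with attribute `predicted_metric`,
#'   or `NULL` if no grid point lands inside the band.
#' @export
find_regimen <- function(posterior, target, intervals = c(6, 8, 12, 24),
                         increment = 25, infusion_duration = 1,
                         max_dose = 4000) {
  stopifnot(inherits(target, "vanc_target"))
  mid <- (target$lower + target$upper) / 2
  best <- NULL
  best_key <- c(Inf, -Inf, Inf)  # distance, -interval, dose
  for (tau in sort(intervals)) {
    if (infusion_duration > tau) next
    # linear PK: metric(dose) = dose * metric(increment)/increment, so only
    # the two grid doses bracketing the band midpoint can be optimal
    mu <- .target_metric(posterior, regimen(increment, tau,
                                            infusion_duration),
                         target) / increment
    d_star <- mid / mu
    cand <- unique(pmin(pmax(
      increment * c(floor(d_star / increment), ceiling(d_star / increment)),
      increment), floor(max_dose / increment) * increment))
    for (d in cand) {
      val <- d * mu
      if (val < target$lower || val > target$upper) next
      key <- c(abs(val - mid), -tau, d)
      better <- key[1] < best_key[1] - 1e-12 ||
        (abs(key[1] - best_key[1]) <= 1e-12 &&
           (key[2] < best_key[2] - 1e-12 ||
              (abs(key[2] - best_key[2]) <= 1e-12 && key[3] < best_key[3])))
      if (better) {
        best <- regimen(d, tau, infusion_duration)
        attr(best, "predicted_metric") <- val
        best_key <- key
      }
    }
  }
  if (is.null(best)) {
    message("no feasible regimen within the given constraints")
    return(NULL)
  }
  best
}

#' Guideline empiric starting dose
#'
#' Children: 15 mg/kg per dose, every 6 h under 12 years of age or every
#' 8 h at 12 years and older, rounded to the weight-based increment.
#' With reduced kidney function (modified Schwartz eGFR below
#' 75 ml/min/1.73 m2) the 15 mg/kg dose is kept but the interval is
#' extended to 12 h and the regimen is flagged for clinician review.
#' Neonates (neonatal model tier): model-based start, i.e.
#' [find_regimen()] on the prior-only posterior built from the neonatal
#' typical parameters (weight, PMA, serum creatinine) against `target`.
#'
#' @param weight Body weight, kg.
#' @param age_days Chronological age, days.
#' @param serum_creatinine Serum creatinine, mg/dL.
#' @param height Height, cm (children; needed for eGFR).
#' @param gestational_age,postmenstrual_age Weeks (neonates).
#' @param target [target_spec()] for the neonatal model-based start.
#' @param infusion_duration Infusion duration, h.
#' @return List: `regimen`, `model_id`, `flags` (character vector, e.g.
#'   `"reduced renal function"`, `"renal function unverified"`), `egfr`
#'   (children, when computable).
#' @export
empiric_starting_dose <- function(weight, age_days, serum_creatinine,
                                  height = NULL, gestational_age = NULL,
                                  postmenstrual_age = NULL,
                                  target = target_spec(),
                                  infusion_duration = 1) {
  model_id <- select_model(gestational_age, postmenstrual_age, age_days)
  flags <- character(0)

  if (model_id == "frymoyer_neonatal") {
    post <- prior_posterior(
      "frymoyer_neonatal",
      list(weight = weight, serum_creatinine = serum_creatinine,
           postmenstrual_age = if (!is.null(postmenstrual_age))
             postmenstrual_age else gestational_age + age_days / 7))
    reg <- find_regimen(post, target, intervals = c(6, 8, 12, 24),
                        increment = dose_increment(weight, neonate = TRUE),
                        infusion_duration = infusion_duration)
    if (is.null(reg)) flags <- c(flags, "no feasible regimen")
    return(list(regimen = reg, model_id = model_id, flags = flags,
                egfr = NULL))
  }

  egfr <- NULL
  if (!is.null(height) && !is.na(height)) {
    egfr <- schwartz_egfr(height, serum_creatinine)
  } else {
    flags <- c(flags, "renal function unverified")
  }
  inc <- dose_increment(weight)
  dose <- round(15 * weight / inc) * inc
  dose <- max(dose, inc)
  if (!is.null(egfr) && egfr < 75) {
    interval <- 12
    flags <- c(flags, "reduced renal function")
  } else {
    interval <- if (age_days < 12 * 365.25) 6 else 8
  }
  list(regimen = regimen(dose, interval, infusion_duration),
       model_id = model_id, flags = flags, egfr = egfr)
}

#' TDM sampling advice
#'
#' Recommends a trough before the fourth dose, or earlier when renal
#' function is impaired or unstable, operationalized as eGFR below
#' 75 ml/min/1.73 m2 or a serum-creatinine rise above 0.3 mg/dL between
#' consecutive measurements.
#'
#' @param egfr eGFR, ml/min/1.73 m2 (or `NA` if unknown).
#' @param creatinine_series Chronological serum creatinine values, mg/dL.
#' @return List: `when` (`"before 4th dose"` or `"early"`), `message`.
#' @export
tdm_advice <- function(egfr = NA, creatinine_series = numeric(0)) {
  unstable <- length(creatinine_series) >= 2 &&
    any(diff(creatinine_series) > 0.3)
  impaired <- !is.na(egfr) && egfr < 75
  if (impaired || unstable) {
    why <- c(if (impaired) "eGFR < 75 ml/min/1.73 m2",
             if (unstable) "creatinine rise > 0.3 mg/dL")
    list(when = "early",
         message = paste0("Obtain a trough earlier than the 4th dose (",
                          paste(why, collapse = "; "), ")."))
  } else {
    list(when = "before 4th dose",
         message = "Obtain a trough concentration before the 4th dose.")
  }
}
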