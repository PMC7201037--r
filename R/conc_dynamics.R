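# Closed-form concentration-time solutions for intermittent IV infusions,
# exposure integrals, and steady-state metrics.  All quantitative outputs
# use the analytic forms; plotting grids are cosmetic only.

#' Construct a dosing regimen
#'
#' @param dose Dose per administration, mg (> 0).
#' @param interval Dosing interval tau, h.
#' @param infusion_duration Infusion duration, h; must not exceed the
#'   interval.  Default 1 h, the usual vancomycin infusion time.
#' @return A `vanc_regimen` list.
#' @export
regimen <- function(dose, interval, infusion_duration = 1) {
  stopifnot(dose > 0, interval > 0, infusion_duration > 0,
            infusion_duration <= interval)
  structure(list(dose = dose, interval = interval,
                 infusion_duration = infusion_duration),
            class = "vanc_regimen")
}

#' @export
print.vanc_regimen <- function(x, ...) {
  cat(sprintf("<vanc_regimen> %g mg q%gh (%g h infusion)\n",
              x$dose, x$interval, x$infusion_duration))
  invisible(x)
}

#' Build a dose-event table
#'
#' @param start_time Start times of each infusion, h from course start.
#' @param amount Dose amounts, mg.
#' @param duration Infusion durations, h (default 1 h, recycled).
#' @return Data frame of dose events sorted by start time.
#' @export
dose_events <- function(start_time, amount, duration = 1) {
  n <- length(start_time)
  d <- data.frame(start_time = as.numeric(start_time),
                  amount = rep_len(as.numeric(amount), n),
                  duration = rep_len(as.numeric(duration), n))
  stopifnot(all(d$amount > 0), all(d$duration > 0))
  d[order(d$start_time), , drop = FALSE]
}

#' Expand a regimen into a dose-event table
#'
#' @param reg A [regimen()].
#' @param n_doses Number of administrations.
#' @param start First dose start time, h.
#' @return Data frame of dose events.
#' @export
regimen_doses <- function(reg, n_doses, start = 0) {
  dose_events(start + reg$interval * (seq_len(n_doses) - 1),
              reg$dose, reg$infusion_duration)
}

# Disposition of a model as a sum of exponentials: a unit IV bolus gives
# C(t) = (1/V1) * sum(coef_i * exp(-lambda_i * t)) with sum(coef) = 1.
# 1-cmt: lambda = CL/V, coef = 1.  2-cmt macro-constants from the
# micro-constants k10 = CL/V1, k12 = Q/V1, k21 = Q/V2:
#   alpha + beta = k10 + k12 + k21,  alpha * beta = k10 * k21,
#   coef_alpha = (alpha - k21)/(alpha - beta),
#   coef_beta  = (k21 - beta)/(alpha - beta).
.disposition <- function(params) {
  ncmt <- attr(params, "n_compartments")
  if (is.null(ncmt)) ncmt <- if (!is.null(params$V1)) 2L else 1L
  if (ncmt == 1L) {
    list(lambda = params$CL / params$V, coef = 1, v_central = params$V)
  } else {
    k10 <- params$CL / params$V1
    k12 <- params$Q / params$V1
    k21 <- params$Q / params$V2
    s <- k10 + k12 + k21
    disc <- sqrt(s^2 - 4 * k10 * k21)
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    list(lambda = c(alpha, beta),
         coef = c((alpha - k21), (k21 - beta)) / (alpha - beta),
         v_central = params$V1)
  }
}

# Concentration contribution of one infusion (rate r0 mg/h over [0, T])
# at elapsed times te (vectorised; te < 0 gives 0):
#   during: (r0/V) sum_i coef_i (1 - e^{-l_i te}) / l_i
#   after:  (r0/V) sum_i coef_i (1 - e^{-l_i T}) e^{-l_i (te - T)} / l_i
.infusion_conc <- function(disp, r0, T, te) {
  out <- numeric(length(te))
  for (i in seq_along(disp$lambda)) {
    l <- disp$lambda[i]
    a <- disp$coef[i] * r0 / (disp$v_central * l)
    during <- te >= 0 & te <= T
    after <- te > T
    out[during] <- out[during] + a * (1 - exp(-l * te[during]))
    out[after] <- out[after] +
      a * (1 - exp(-l * T)) * exp(-l * (te[after] - T))
  }
  out
}

# Running integral of the same contribution from 0 to te:
#   during: (r0/V) sum_i coef_i [te - (1 - e^{-l te})/l] / l
#   after:  value at T plus (r0/V) sum_i coef_i (1-e^{-lT})(1-e^{-l(te-T)})/l^2
.infusion_auc <- function(disp, r0, T, te) {
  out <- numeric(length(te))
  for (i in seq_along(disp$lambda)) {
    l <- disp$lambda[i]
    a <- disp$coef[i] * r0 / (disp$v_central * l)
    during <- te >= 0 & te <= T
    after <- te > T
    td <- te[during]
    out[during] <- out[during] + a * (td - (1 - exp(-l * td)) / l)
    ta <- te[after]
    out[after] <- out[after] + a * (T - (1 - exp(-l * T)) / l) +
      a * (1 - exp(-l * T)) * (1 - exp(-l * (ta - T))) / l
  }
  out
}

.as_dose_df <- function(doses) {
  if (inherits(doses, "vanc_regimen")) {
    stop("pass dose events (see dose_events()/regimen_doses()), not a regimen")
  }
  stopifnot(is.data.frame(doses),
            all(c("start_time", "amount", "duration") %in% names(doses)))
  doses
}

#' Predicted concentration-time profile for a dose history
#'
#' Linear superposition of closed-form intermittent-infusion solutions:
#' mono-exponential disposition for one-compartment parameters,
#' bi-exponential (macro-constants from CL, V1, V2, Q) for
#' two-compartment parameters.  Times before the first dose return 0;
#' overlapping infusions superpose.
#'
#' @param params `vanc_params` (typical or individual), or a list of one
#'   `vanc_params` per dose event when covariates (and hence parameters)
#'   change over the course.
#' @param doses Dose-event data frame from [dose_events()].
#' @param times Evaluation times, h from course start.
#' @return Data frame `time_h`, `conc` (mg/L).
#' @export
predict_concentration <- function(params, doses, times) {
  doses <- .as_dose_df(doses)
  per_dose <- is.list(params) && !inherits(params, "vanc_params")
  if (per_dose) stopifnot(length(params) == nrow(doses))
  conc <- numeric(length(times))
  for (j in seq_len(nrow(doses))) {
    p <- if (per_dose) params[[j]] else params
    disp <- .disposition(p)
    conc <- conc + .infusion_conc(disp, doses$amount[j] / doses$duration[j],
                                  doses$duration[j],
                                  times - doses$start_time[j])
  }
  data.frame(time_h = as.numeric(times), conc = conc)
}

#' Cumulative area under the curve since course start
#'
#' Exact closed-form integral of the superposed infusion solution from
#' time 0 to `t_end`.
#'
#' @inheritParams predict_concentration
#' @param t_end Upper integration limit, h (>= 0).
#' @return AUC in mg.h/L.
#' @export
cumulative_auc <- function(params, doses, t_end) {
  stopifnot(all(t_end >= 0))
  doses <- .as_dose_df(doses)
  per_dose <- is.list(params) && !inherits(params, "vanc_params")
  if (per_dose) stopifnot(length(params) == nrow(doses))
  auc <- numeric(length(t_end))
  for (j in seq_len(nrow(doses))) {
    p <- if (per_dose) params[[j]] else params
    disp <- .disposition(p)
    auc <- auc + .infusion_auc(disp, doses$amount[j] / doses$duration[j],
                               doses$duration[j],
                               t_end - doses$start_time[j])
  }
  auc
}

#' Steady-state exposure metrics of an intermittent-infusion regimen
#'
#' `auc24_ss` is exact: (24/tau) * dose / CL.  `trough_ss` is the
#' closed-form steady-state concentration at t = tau after a dose start
#' (immediately before the next dose), the conventional pre-dose trough:
#' each exponential term of the single-dose solution is divided by
#' (1 - exp(-lambda * tau)).
#'
#' @param params `vanc_params`.
#' @param reg A [regimen()].
#' @return List with `auc24_ss` (mg.h/L) and `trough_ss` (mg/L).
#' @export
steady_state_metrics <- function(params, reg) {
  stopifnot(inherits(reg, "vanc_regimen"))
  disp <- .disposition(params)
  r0 <- reg$dose / reg$infusion_duration
  trough <- 0
  for (i in seq_along(disp$lambda)) {
    l <- disp$lambda[i]
    a <- disp$coef[i] * r0 / (disp$v_central * l)
    trough <- trough + a * (1 - exp(-l * reg$infusion_duration)) *
      exp(-l * (reg$interval - reg$infusion_duration)) /
      (1 - exp(-l * reg$interval))
  }
  list(auc24_ss = (24 / reg$interval) * reg$dose / params$CL,
       trough_ss = trough)
}

#' Concentration profile on a regular plotting grid
#'
#' Convenience wrapper around [predict_concentration()] producing a tidy
#' table suitable for CSV export (`time_h`, `conc_mg_per_L`).
#'
#' @inheritParams predict_concentration
#' @param t_end End of the grid, h; defaults to one day past the last dose.
#' @param resolution Grid spacing, h (default 0.1).
#' @return Data frame `time_h`, `conc_mg_per_L`.
#' @export
profile_grid <- function(params, doses, t_end = NULL, resolution = 0.1) {
  doses <- .as_dose_df(doses)
  if (is.null(t_end)) t_end <- max(doses$start_time) + 24
  grid <- seq(0, t_end, by = resolution)
  prof <- predict_concentration(params, doses, grid)
  data.frame(time_h = prof$time_h, conc_mg_per_L = prof$conc)
}
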