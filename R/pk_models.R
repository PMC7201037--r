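# Population PK model registry, covariate equations, age-based selection.

.vanc_env <- new.env(parent = emptyenv())

#' Load the population model catalog
#'
#' Reads the versioned YAML catalog of population pharmacokinetic models
#' shipped with the package (or a user-supplied catalog with the same
#' layout) and returns it as a named list of model definitions.  The
#' catalog holds all numeric constants of the covariate equations, the
#' interindividual variability (IIV, CV% per parameter) and the combined
#' proportional + additive residual-error terms, so that parameter
#' revisions do not require code changes.
#'
#' @param path Path to a catalog YAML file; default is the catalog
#'   installed with the package.
#' @return Named list of `vanc_model` objects.
#' @export
model_registry <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.vanc_env$registry)) return(.vanc_env$registry)
  if (default) {
    path <- system.file("extdata", "models.yaml", package = "vancomipd")
  }
  cat_raw <- yaml::read_yaml(path)
  if (is.null(cat_raw$models)) stop("catalog has no 'models' section: ", path)
  reg <- lapply(names(cat_raw$models), function(id) {
    m <- cat_raw$models[[id]]
    structure(
      list(
        model_id = id,
        label = m$label,
        n_compartments = as.integer(m$n_compartments),
        parameters = as.character(m$parameters),
        constants = lapply(m$constants, as.numeric),
        required_covariates = as.character(m$required_covariates),
        iiv_cv = unlist(m$iiv_cv),
        residual_proportional = as.numeric(m$residual$prop_cv),
        residual_additive_sd = as.numeric(m$residual$add_sd)
      ),
      class = "vanc_model"
    )
  })
  names(reg) <- names(cat_raw$models)
  for (m in reg) {
    stopifnot(all(m$iiv_cv > 0), m$residual_proportional >= 0,
              m$residual_additive_sd >= 0)
  }
  if (default) .vanc_env$registry <- reg
  reg
}

#' Retrieve one population model by id
#'
#' @param model_id One of `"frymoyer_neonatal"`, `"le_pediatric"`,
#'   `"thomson"`, or an already-constructed `vanc_model` (returned as is).
#' @return A `vanc_model` definition.
#' @export
get_model <- function(model_id) {
  if (inherits(model_id, "vanc_model")) return(model_id)
  reg <- model_registry()
  if (!model_id %in% names(reg)) {
    stop("unknown model_id '", model_id, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[model_id]]
}

#' @export
print.vanc_model <- function(x, ...) {
  cat(sprintf("<vanc_model> %s: %s\n", x$model_id, x$label))
  cat(sprintf("  compartments: %d; parameters: %s\n", x$n_compartments,
              paste(x$parameters, collapse = ", ")))
  cat(sprintf("  IIV CV%%: %s\n",
              paste(sprintf("%s=%g", names(x$iiv_cv), x$iiv_cv),
                    collapse = ", ")))
  cat(sprintf("  residual: %g%% proportional + %g mg/L additive\n",
              x$residual_proportional, x$residual_additive_sd))
  invisible(x)
}

# Serum creatinine floor (mg/dL): assay-low values otherwise blow up the
# 1/Cr covariate terms.
.CR_FLOOR <- 0.1

.floor_creatinine <- function(cr) pmax(cr, .CR_FLOOR)

.need_covariate <- function(covariates, field, model_id) {
  v <- covariates[[field]]
  if (is.null(v) || length(v) != 1L || is.na(v)) {
    stop("model '", model_id, "' requires covariate '", field, "'")
  }
  if (!is.finite(v) || v <= 0) {
    stop("covariate '", field, "' must be a positive finite number, got ", v)
  }
  as.numeric(v)
}

#' Clearance maturation factor of the neonatal model
#'
#' Sigmoidal Hill function of postmenstrual age, in (0, 1), equal to 0.5
#' at the half-maturation PMA (34.8 weeks).
#'
#' @param pma_weeks Postmenstrual age in weeks (> 0).
#' @param pma50,hill Sigmoid location (weeks) and steepness.
#' @return Maturation multiplier in (0, 1).
#' @export
maturation_factor <- function(pma_weeks, pma50 = 34.8, hill = 4.53) {
  stopifnot(all(pma_weeks > 0))
  1 / (1 + (pma_weeks / pma50)^(-hill))
}

#' Typical (population) PK parameters for a patient
#'
#' Evaluates the covariate equations of the selected population model.
#' One-compartment models return clearance `CL` (L/h) and volume `V` (L);
#' the two-compartment model returns `CL`, central and peripheral volumes
#' `V1`, `V2` (L, scaled linearly by body weight) and intercompartmental
#' clearance `Q` (L/h).
#'
#' @param model_id Model id or `vanc_model`.
#' @param covariates Named list with the covariates the model requires:
#'   `weight` (kg), `serum_creatinine` (mg/dL, floored at 0.1),
#'   `postmenstrual_age` (weeks; neonatal model), `age_days`
#'   (pediatric model), `crcl` (ml/min; two-compartment model).
#' @return Named list of typical parameters with attribute
#'   `n_compartments`, class `vanc_params`.
#' @examples
#' typical_parameters("frymoyer_neonatal",
#'   list(weight = 2.9, serum_creatinine = 1.0, postmenstrual_age = 34.8))
#' @export
typical_parameters <- function(model_id, covariates) {
  m <- get_model(model_id)
  k <- m$constants
  p <- switch(
    m$model_id,
    frymoyer_neonatal = {
      wt <- .need_covariate(covariates, "weight", m$model_id)
      cr <- .floor_creatinine(
        .need_covariate(covariates, "serum_creatinine", m$model_id))
      pma <- .need_covariate(covariates, "postmenstrual_age", m$model_id)
      list(
        CL = k$cl_tv * (wt / k$wt_ref)^k$cl_wt_exp *
          (1 / cr)^k$cl_cr_exp *
          maturation_factor(pma, k$pma50, k$pma_hill),
        V = k$v_tv * (wt / k$wt_ref)
      )
    },
    le_pediatric = {
      wt <- .need_covariate(covariates, "weight", m$model_id)
      cr <- .floor_creatinine(
        .need_covariate(covariates, "serum_creatinine", m$model_id))
      age <- .need_covariate(covariates, "age_days", m$model_id)
      if (log(age) <= 0) stop("age_days must exceed 1 day for this model")
      list(
        CL = k$cl_tv * wt^k$cl_wt_exp *
          (k$cr_ref / cr)^k$cl_cr_exp *
          (log(age) / k$log_age_ref)^k$cl_age_exp,
        V = k$v_per_kg * wt
      )
    },
    thomson = {
      wt <- .need_covariate(covariates, "weight", m$model_id)
      crcl <- .need_covariate(covariates, "crcl", m$model_id)
      cl <- k$cl_tv * (1 + k$crcl_slope * (crcl - k$crcl_ref))
      if (cl <= 0) stop("creatinine clearance ", crcl,
                        " ml/min gives nonpositive typical clearance")
      list(CL = cl, V1 = k$v1_per_kg * wt, V2 = k$v2_per_kg * wt, Q = k$q_tv)
    },
    stop("no covariate equations registered for model '", m$model_id, "'")
  )
  stopifnot(all(unlist(p) > 0), all(is.finite(unlist(p))))
  structure(p, n_compartments = m$n_compartments, class = "vanc_params")
}

#' Age-based population model selection
#'
#' Neonates below 52 weeks postmenstrual age (PMA) are assigned the
#' neonatal model.  Patients at or above 52 weeks PMA (gestational age
#' known) — or at least 3 months of chronological age when gestational
#' age is unknown — fall in the pediatric tier, where the pediatric
#' one-compartment model is the default and the two-compartment
#' adult/adolescent model can be chosen by configuration.
#'
#' @param gestational_age Gestational age at birth, weeks; `NULL`/`NA`
#'   if unknown.
#' @param postmenstrual_age Postmenstrual age, weeks; derived as
#'   `gestational_age + chronological_age/7` when omitted.
#' @param chronological_age Postnatal age in days (required).
#' @param pediatric_model Model used in the pediatric tier
#'   (`"le_pediatric"` default, `"thomson"` selectable).
#' @return A model id string.
#' @export
select_model <- function(gestational_age = NULL, postmenstrual_age = NULL,
                         chronological_age,
                         pediatric_model = c("le_pediatric", "thomson")) {
  pediatric_model <- match.arg(pediatric_model)
  stopifnot(length(chronological_age) == 1L, chronological_age >= 0)
  ga_known <- !is.null(gestational_age) && !is.na(gestational_age)
  pma_known <- !is.null(postmenstrual_age) && !is.na(postmenstrual_age)
  if (ga_known && !pma_known) {
    postmenstrual_age <- gestational_age + chronological_age / 7
    pma_known <- TRUE
  }
  if (pma_known) {
    if (postmenstrual_age < 52) return("frymoyer_neonatal")
    return(pediatric_model)
  }
  if (chronological_age >= 3 * 30.4375) return(pediatric_model)
  stop("model undetermined: gestational age unknown and chronological age ",
       "below 3 months; supply gestational or postmenstrual age")
}

#' Convert an IIV CV% to a log-normal standard deviation
#'
#' Published between-subject variabilities are reported as CV%.  The
#' default convention takes omega = CV/100 directly (the common reporting
#' convention for these models); the alternative exact log-normal
#' relation omega = sqrt(ln(1 + (CV/100)^2)) is available as a switch.
#'
#' @param cv CV% value(s).
#' @param convention `"linear"` (default) or `"lognormal"`.
#' @return Standard deviation(s) of the log-scale random effect.
#' @export
omega_from_cv <- function(cv, convention = c("linear", "lognormal")) {
  convention <- match.arg(convention)
  stopifnot(all(cv > 0))
  if (convention == "linear") cv / 100 else sqrt(log(1 + (cv / 100)^2))
}

#' Log-scale omegas for every variable parameter of a model
#'
#' @inheritParams omega_from_cv
#' @param model Model id or `vanc_model`.
#' @return Named vector of omegas in model parameter order.
#' @export
model_omegas <- function(model, convention = c("linear", "lognormal")) {
  m <- get_model(model)
  omega_from_cv(m$iiv_cv[m$parameters], convention)
}

#' Apply individual random effects to typical parameters
#'
#' Each variable parameter is multiplied by `exp(eta)`, the standard
#' log-normal individual-parameter construction, so `eta = 0` reproduces
#' the typical values exactly and realized parameters stay positive.
#'
#' @param model Model id or `vanc_model`.
#' @param typical `vanc_params` from [typical_parameters()].
#' @param eta Numeric vector of log-scale random effects, one per model
#'   parameter (in `model$parameters` order), or named.
#' @return `vanc_params` of realized individual parameters, with the
#'   `eta` kept as an attribute.
#' @export
realize_individual <- function(model, typical, eta) {
  m <- get_model(model)
  vp <- m$parameters
  if (length(eta) != length(vp)) {
    stop("eta has length ", length(eta), " but model '", m$model_id,
         "' has ", length(vp), " variable parameters (",
         paste(vp, collapse = ", "), ")")
  }
  if (!is.null(names(eta))) eta <- eta[vp]
  stopifnot(all(is.finite(eta)))
  out <- typical
  for (i in seq_along(vp)) {
    out[[vp[i]]] <- unname(typical[[vp[i]]] * exp(eta[i]))
  }
  attr(out, "eta") <- stats::setNames(as.numeric(eta), vp)
  out
}

#' Covariates in effect at a given course time
#'
#' Last-observation-carried-forward lookup in a covariate timeline;
#' times before the first record fall back to the first record.
#'
#' @param covariates Data frame with a `time_h` column plus covariate
#'   columns (`weight`, `serum_creatinine`, ...).
#' @param time Time (hours from course start) at which covariates apply.
#' @return Named list of scalar covariates (NA columns dropped).
#' @export
covariates_at <- function(covariates, time) {
  stopifnot(is.data.frame(covariates), "time_h" %in% names(covariates),
            nrow(covariates) >= 1L)
  ord <- order(covariates$time_h)
  covariates <- covariates[ord, , drop = FALSE]
  out <- list()
  for (col in setdiff(names(covariates), "time_h")) {
    v <- covariates[[col]]
    seen <- which(!is.na(v) & covariates$time_h <= time)
    idx <- if (length(seen)) max(seen) else {
      nz <- which(!is.na(v))
      if (length(nz)) min(nz) else NA_integer_
    }
    if (!is.na(idx)) out[[col]] <- v[idx]
  }
  out
}
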