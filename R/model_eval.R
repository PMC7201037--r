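# Sheiner-Beal bias/precision evaluation of model predictions against
# observed TDM concentrations.

#' Paired prediction errors
#'
#' pe = predicted - observed (mg/L); ape = |pe|; `within_25` flags pairs
#' with |pe|/observed <= 0.25 (boundary inclusive, observed denominator).
#'
#' @param predicted,observed Equal-length positive concentration vectors.
#' @return Data frame `predicted`, `observed`, `pe`, `ape`, `within_25`.
#' @export
prediction_errors <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted (", length(predicted), ") and observed (",
         length(observed), ") differ in length")
  }
  stopifnot(all(predicted > 0), all(observed > 0))
  pe <- predicted - observed
  data.frame(predicted = predicted, observed = observed, pe = pe,
             ape = abs(pe), within_25 = abs(pe) / observed <= 0.25)
}

# Distribution-free order-statistic CI for the median: sorted-sample
# ranks (l, u) with l = qbinom(alpha/2, n, 1/2), u = n + 1 - l, widened
# until binomial coverage >= level.
.median_ci <- function(x, level = 0.95) {
  n <- length(x)
  s <- sort(x)
  if (n < 6) return(c(s[1], s[n]))
  l <- stats::qbinom((1 - level) / 2, n, 0.5)
  repeat {
    u <- n + 1 - l
    if (l < 1) return(c(s[1], s[n]))
    cover <- stats::pbinom(u - 1, n, 0.5) - stats::pbinom(l - 1, n, 0.5)
    if (cover >= level) break
    l <- l - 1
  }
  c(s[l], s[u])
}

#' Bias and precision summary (Sheiner-Beal style)
#'
#' Median prediction error (bias), median absolute prediction error
#' (precision), each with a distribution-free binomial order-statistic
#' confidence interval for the median, and the percentage of predictions
#' within 25% of the observed concentration.  With fewer than 6 pairs the
#' CI degrades to the full data range (with a warning).
#'
#' @param errors Data frame from [prediction_errors()].
#' @param ci_level Confidence level (default 0.95).
#' @return List of class `vanc_eval`: `median_pe`, `median_pe_ci`,
#'   `median_ape`, `median_ape_ci`, `pct_within_25`, `n_pairs`.
#' @export
summarize_errors <- function(errors, ci_level = 0.95) {
  stopifnot(nrow(errors) >= 1)
  if (nrow(errors) < 6) {
    warning("fewer than 6 pairs: CI reported as the full data range")
  }
  structure(
    list(median_pe = stats::median(errors$pe),
         median_pe_ci = .median_ci(errors$pe, ci_level),
         median_ape = stats::median(errors$ape),
         median_ape_ci = .median_ci(errors$ape, ci_level),
         pct_within_25 = 100 * mean(errors$within_25),
         n_pairs = nrow(errors)),
    class = "vanc_eval"
  )
}

#' @export
print.vanc_eval <- function(x, ...) {
  cat(sprintf(
    "Model evaluation (n = %d pairs)\n  median PE  %.2f [%.2f, %.2f] mg/L\n",
    x$n_pairs, x$median_pe, x$median_pe_ci[1], x$median_pe_ci[2]))
  cat(sprintf("  median APE %.2f [%.2f, %.2f] mg/L\n",
              x$median_ape, x$median_ape_ci[1], x$median_ape_ci[2]))
  cat(sprintf("  within 25%% of observed: %.1f%%\n", x$pct_within_25))
  invisible(x)
}

#' Population (a-priori) predictions at the TDM times of a course
#'
#' Model predictions with eta = 0, the external-validation flavor; set
#' `posterior_mode = TRUE` for a-posteriori predictions at the fitted
#' mode.
#'
#' @param model Model id or `vanc_model`.
#' @param course `vanc_course` with observations.
#' @param posterior_mode Use the MAP mode instead of eta = 0.
#' @return Data frame `time_h`, `observed`, `predicted`.
#' @export
course_predictions <- function(model, course, posterior_mode = FALSE) {
  m <- get_model(model)
  obs <- .usable_obs(course, warn = FALSE)
  if (nrow(obs) == 0) {
    return(data.frame(time_h = numeric(0), observed = numeric(0),
                      predicted = numeric(0)))
  }
  eta <- if (posterior_mode) fit_map(m, course)$eta_mode
         else numeric(length(m$parameters))
  data.frame(time_h = obs$time_h, observed = obs$conc,
             predicted = .individual_predictions(m, course, eta,
                                                 obs_times = obs$time_h))
}

#' Evaluate a model over a set of courses
#'
#' @param model Model id or `vanc_model`.
#' @param courses List of `vanc_course`.
#' @param posterior_mode Prediction flavor (see [course_predictions()]).
#' @param ci_level Confidence level.
#' @return `vanc_eval` summary over all pooled observation pairs.
#' @export
evaluate_model <- function(model, courses, posterior_mode = FALSE,
                           ci_level = 0.95) {
  pairs <- do.call(rbind, lapply(courses, function(cs) {
    course_predictions(model, cs, posterior_mode)
  }))
  summarize_errors(prediction_errors(pairs$predicted, pairs$observed),
                   ci_level)
}
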