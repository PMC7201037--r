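---
title: "Model-informed precision dosing of vancomycin: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-informed precision dosing of vancomycin: models, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancomipd)
```

## The problem

Vancomycin dosing in neonates and children is hard to individualize:
clearance varies several-fold with body size, renal maturation, and
kidney function, and the drug has a narrow therapeutic window. The
pharmacokinetic/pharmacodynamic target for invasive MRSA infection is a
steady-state 24-hour area under the concentration-time curve divided by
the pathogen MIC (AUC24/MIC) above 400, while steady-state troughs above
20 mg/L flag toxicity concern. `vancomipd` implements the quantitative
core of a model-informed precision dosing (MIPD) workflow: a population
pharmacokinetic model serves as a Bayesian prior, measured drug
concentrations (therapeutic drug monitoring, TDM) update it to an
individual posterior, and the posterior drives dose advice.

## Population models and covariate equations

Three published population models are shipped in a versioned YAML
catalog (`inst/extdata/models.yaml`) and selected by age:

* **Neonatal one-compartment model** (patients below 52 weeks
  postmenstrual age, PMA): clearance scales allometrically with weight
  (exponent 0.75, reference 2.9 kg), inversely with serum creatinine
  (power 0.267), and by a Hill-type maturation sigmoid of PMA that is
  exactly 0.5 at 34.8 weeks and saturates at 1; volume is linear in
  weight (1.75 L at 2.9 kg).
* **Pediatric one-compartment model** (52 weeks PMA and older, or at
  least 3 months of age when gestational age is unknown): clearance
  0.248 x Wt^0.75 x (0.48/Cr)^0.361 x (ln(age in days)/7.8)^0.995,
  volume 0.636 L/kg.
* **Adult/adolescent two-compartment model**: clearance
  2.99 x (1 + 0.0154 x (CrCl - 66)) L/h, central and peripheral volumes
  0.675 and 0.732 L/kg, intercompartmental clearance 2.28 L/h.

Between-subject variability is log-normal per parameter (reported as
CV%), and residual error combines a proportional CV% with an additive SD
in mg/L.

Decisions taken where the published descriptions leave room:

* **CV% to omega.** Reported CV% values are used directly as log-scale
  standard deviations (omega = CV/100), the common reporting convention
  for these models; the exact relation omega = sqrt(ln(1 + CV^2)) is
  available via the `convention` argument.
* **Pediatric tier choice.** The one-compartment pediatric model is the
  default for everyone at or above the 52-week PMA boundary; the
  two-compartment model is selectable by configuration
  (`pediatric_model = "thomson"`), reflecting its validation in the
  12-years-and-older subset. The exact deployment rule is not published,
  so this stays a configuration choice.
* **Boundary handling.** PMA of exactly 52 weeks goes to the pediatric
  tier. With gestational age unknown and age under 3 months the model is
  undetermined and selection refuses rather than guesses.
* **Two-compartment weight handling.** V1 and V2 scale linearly with
  weight as printed ("L/kg"); CL and Q are used as printed without
  weight scaling. As a consequence that model's typical clearance is
  flat in weight.
* **Creatinine clearance input.** The bedside Schwartz eGFR
  (0.413 x height/Cr, ml/min/1.73 m2) is used directly as CrCl in
  ml/min by default; Mosteller body-surface-area de-normalization is
  available (`denormalize_crcl = TRUE`).
* **Creatinine floor.** Serum creatinine is floored at 0.1 mg/dL so
  assay-low values cannot blow up the 1/Cr covariate terms.
* **Time-varying covariates.** Weight, height and creatinine are carried
  forward (LOCF) from the covariate timeline at each dose time, and
  ages advance with time, so each dose event gets its own typical
  parameter set; values before the first record fall back to the first
  record.

## Concentration dynamics

All concentration and exposure quantities are closed-form. A unit bolus
gives a 1- or 2-exponential disposition; macro-constants for the
two-compartment model come from the micro-constants k10 = CL/V1,
k12 = Q/V1, k21 = Q/V2 through the standard quadratic
(alpha + beta = k10 + k12 + k21, alpha x beta = k10 x k21). Each
infusion contributes the textbook rise-and-decay terms, and arbitrary
dose histories superpose linearly. Cumulative AUC is the exact integral
of those terms, never a quadrature. Steady-state AUC24 is the identity
(24/tau) x dose/CL; the steady-state trough divides each exponential
term by (1 - exp(-lambda tau)) and evaluates at t = tau after the dose
start — i.e. immediately before the next dose, the conventional pre-dose
trough. A 0.1-h plotting grid is available for export, but no
quantitative output depends on it. The default infusion duration is 1 h,
the usual vancomycin administration time, configurable per dose.

## MAP estimation and the posterior

Individual random effects eta (one per model parameter, log scale) are
estimated by minimizing

    sum_j [ (y_j - f_j(eta))^2 / g_j^2 + ln g_j^2 ]  +  sum_i eta_i^2 / omega_i^2

with g_j^2 = (prop x c_j)^2 + add^2. The anchor c_j of the proportional
term is the **observed** concentration by default. With the anchor at
the model prediction (offered as `residual_at = "prediction"`), the
ln g^2 term depends on eta and its gradient pulls fitted predictions
about prop^2 (about 4% for a 20% proportional error) below the data even
with unlimited noise-free sampling; anchoring at the observation keeps
the weights fixed during optimization, makes the mode a consistent
estimator, and leaves the objective value comparable across fits. This
is a deliberate design choice, documented here because the two variants
genuinely disagree at the few-percent level.

Optimization starts at the prior mode (eta = 0) with a derivative-free
Nelder-Mead pass followed by BFGS refinement; the posterior covariance
is the Laplace approximation 2 x H^-1 (the objective is -2 log
posterior), with H from central finite differences (step 1e-4). With no
usable observations the posterior equals the prior exactly: eta = 0,
covariance diag(omega^2). Observations drawn before the first dose are
excluded with a warning; an `excluded` flag supports manual removal.

Shrinkage is inherent to MAP estimation: with few observations the mode
sits between the data-interpolating eta and 0. Noise-free recovery of
the simulating eta to within 0.01 therefore requires rich sampling — the
consistency test uses 0.1-hourly noise-free sampling over a ten-dose
course, where at least 95% of simulated patients are recovered to that
tolerance. With four TDM samples and 5% measurement noise the median
relative error of individual clearance across 200 simulated patients is
well inside 5%.

## Probability of target attainment

Remaining parameter uncertainty is propagated by Monte Carlo: eta
samples from Normal(eta_mode, covariance) (default N = 10,000, default
seed 20200429, both overridable), steady-state AUC24 and trough per
draw, exceedance fractions against AUC24 > 400 mg.h/L and trough >
20 mg/L. Non-positive-semidefinite covariances are repaired by clipping
eigenvalues at 1e-10 with a warning. In the one-compartment
clearance-only case the Monte-Carlo probability matches the log-normal
closed form Phi((ln(D24/threshold) - ln CL_mode)/sd) to better than
0.01 at N = 1e5, which the test suite checks. A full MCMC posterior is
out of scope; the Laplace-plus-sampling scheme is this package's choice.

## Dose advice

The advisor mirrors clinical use: a five-row reference table at dose
multipliers 0.70/0.85/1.00/1.15/1.30 of the current regimen (interval
unchanged); free-form custom-regimen evaluation on the same computation
path; and a target-seeking search over intervals {6, 8, 12, 24} h and a
rounded dose grid. Because the pharmacokinetics are linear, the metric
is linear in dose, so per interval only the two grid doses bracketing
the band midpoint can be optimal; ties prefer the longer interval, then
the smaller dose. Dose rounding increments are 1 mg for neonates, 25 mg
for children under 40 kg and 50 mg above, all configurable — the source
publications are silent here, so these follow common formulary practice.

Empiric starts follow the institutional guideline: children get
15 mg/kg q6h (under 12 years) or q8h (12 and older); with bedside
Schwartz eGFR below 75 ml/min/1.73 m2 the interval is extended to 12 h
and the regimen flagged for clinician review — the guideline says
"lower dosing" without numbers, and extending the interval at unchanged
mg/kg is this package's operationalization. Neonatal starts are
model-based: the target-seeking search run on the prior-only posterior
from weight, PMA and serum creatinine. TDM advice recommends a trough
before the fourth dose, or earlier when renal function is impaired
(eGFR < 75) or unstable (creatinine rise above 0.3 mg/dL between
consecutive values) — the impaired/unstable operationalization is an
invention of this package, stated here because the source guideline
phrases it qualitatively.

## Model evaluation

Bias and precision against observed TDM concentrations use the
Sheiner-Beal summaries: median prediction error (predicted minus
observed, mg/L), median absolute prediction error, and the percentage
of predictions within 25% of the observed value (boundary inclusive,
observed concentration as denominator — the published description does
not say which denominator was used). Confidence intervals for the
medians are distribution-free binomial order-statistic intervals; below
six pairs the CI degrades to the data range with a warning. Population
(a-priori, eta = 0) predictions are the default flavor, matching
external-validation practice; a-posteriori predictions at the MAP mode
are available.

## Synthetic cohorts and the closed loop

The generator emulates the two served populations with independent
log-normal covariate marginals matched to published cohort medians and
IQRs (weight, height, creatinine, age, gestational age), truncated to
physiological ranges. True random effects are drawn from the model
prior; measured troughs add the model's own combined
proportional-plus-additive error (toggleable). The protocol per TDM
round is three administered doses, a trough immediately before what
would be the fourth, a posterior refit on all data so far, and — when
the predicted target metric leaves the target band — a regimen switch
effective at the next scheduled dose. The attainment report aggregates
per-round medians/IQRs of predicted steady-state AUC24 and trough and
the cumulative percentage of patients having attained AUC24/MIC > 400,
trough 5-20 and trough 10-20 mg/L (MIC fixed at 1 mg/L unless an
isolate MIC is supplied).

What the generator does **not** emulate: covariate correlations (weight
and age are sampled independently within a population), real clinicians'
target choices and non-adherence to the adjustment protocol, indication
mix, unstable renal function within a course, and assay censoring below
the quantification limit. Passing closed-loop tests therefore
demonstrate internal consistency of generator + estimator + advisor,
not clinical attainment rates; published cohort attainment percentages
depend on hospital patient mix and are deliberately not reproduction
targets.

Problem sizes used by the test suite — 50 randomized ODE-oracle cases at
100 time points, five 4-million-point exhaustive objective grids, 200
simulated patients for clearance recovery, 500 evaluation pairs, 100
rich-sampled recovery patients, cohorts of 500 for demographics — were
chosen as the smallest sizes at which the checked statistics are stable.

## Numerical choices and degenerate inputs

* Optimizer tolerance 1e-8 on the objective; Nelder-Mead then BFGS.
* Hessian step 1e-4; a singular Hessian falls back to the prior
  covariance with a warning.
* Eigenvalue clipping at 1e-10 for Monte-Carlo sampling covariances.
* A dose interval must be at least as long as the infusion duration;
  evaluation times before the first dose return 0 mg/L; overlapping
  infusions superpose.
* `find_regimen` returns `NULL` (with a message) when no grid regimen
  lands inside the target band.
* Courses split when the gap between consecutive doses strictly exceeds
  14 days.

## Known limitations

No nonlinear elimination, continuous-infusion optimization, dialysis
handling, loading-dose logic, albumin/unbound-fraction models, or
toxicity (AKI) prediction. The payload schema is a reconstruction of
the named clinical data elements (demographics, doses, TDM, creatinine,
height/weight, gestational/postmenstrual age), not a published EHR API.
Model parameters are used as published; no re-estimation from raw data
is performed.
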