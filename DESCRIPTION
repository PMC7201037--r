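Package: vancomipd
Title: Model-Informed Precision Dosing of Vancomycin in Neonates and Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian forecasting engine for individualizing intravenous
    vancomycin dosing in neonates and children from dose histories and
    therapeutic drug monitoring (TDM) concentrations. Implements an
    age-selected registry of published population pharmacokinetic models
    (one- and two-compartment intermittent-infusion kinetics in closed
    form), maximum a posteriori (MAP) empirical-Bayes estimation of
    individual parameters with a Laplace posterior, Monte-Carlo
    probability of attaining steady-state AUC24/MIC and trough targets,
    a dose-advisor layer (reference tables at +/-15 and +/-30 percent of
    the current dose, custom-regimen evaluation, target-seeking dose
    search, guideline empiric starting doses, bedside Schwartz eGFR),
    Sheiner-Beal bias/precision model evaluation, a synthetic
    neonatal/pediatric cohort simulator, and a JSON patient-record
    interface with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
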