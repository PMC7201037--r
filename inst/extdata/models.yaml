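# Versioned catalog of the population PK models behind the dosing engine.
# Constants can be revised here without code changes; equations that combine
# them live in the package (see typical_parameters).
#
# iiv_cv:      interindividual variability, CV% per parameter (log-normal).
# residual:    combined error model sd(e) = sqrt((prop/100 * f)^2 + add^2),
#              f = individual model prediction (mg/L).
catalog_version: "1.0"
models:
  frymoyer_neonatal:
    label: "Neonatal one-compartment model (weight, serum creatinine, PMA)"
    n_compartments: 1
    parameters: [CL, V]
    constants:
      cl_tv: 0.345          # L/h at reference covariates
      wt_ref: 2.9           # kg
      cl_wt_exp: 0.75
      cl_cr_exp: 0.267      # on (1/Cr)
      pma50: 34.8           # weeks, PMA of half-maximal clearance maturation
      pma_hill: 4.53
      v_tv: 1.75            # L at 2.9 kg, linear in weight
    required_covariates: [weight, serum_creatinine, postmenstrual_age]
    iiv_cv: {CL: 21.6, V: 10.9}
    residual: {prop_cv: 20.5, add_sd: 1.3}
  le_pediatric:
    label: "Pediatric one-compartment model (weight, serum creatinine, age)"
    n_compartments: 1
    parameters: [CL, V]
    constants:
      cl_tv: 0.248          # L/h per kg^0.75 at reference Cr and age
      cl_wt_exp: 0.75
      cr_ref: 0.48          # mg/dL
      cl_cr_exp: 0.361      # on (cr_ref/Cr)
      log_age_ref: 7.8      # ln(days); exp(7.8) ~ 2440.6 d ~ 6.7 y
      cl_age_exp: 0.995
      v_per_kg: 0.636       # L/kg
    required_covariates: [weight, serum_creatinine, age_days]
    iiv_cv: {CL: 35, V: 18}
    residual: {prop_cv: 29, add_sd: 0}
  thomson:
    label: "Adult/adolescent two-compartment model (creatinine clearance)"
    n_compartments: 2
    parameters: [CL, V1, V2, Q]
    constants:
      cl_tv: 2.99           # L/h at CrCl 66 ml/min
      crcl_slope: 0.0154    # per ml/min
      crcl_ref: 66          # ml/min
      v1_per_kg: 0.675      # L/kg
      v2_per_kg: 0.732      # L/kg
      q_tv: 2.28            # L/h
    required_covariates: [weight, crcl]
    iiv_cv: {CL: 27, V1: 15, V2: 130, Q: 149}
    residual: {prop_cv: 15, add_sd: 1.6}
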