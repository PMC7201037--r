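test_that("registry loads the three models with their variance terms", {
  reg <- model_registry()
  expect_setequal(names(reg), c("frymoyer_neonatal", "le_pediatric",
                                "thomson"))
  expect_equal(reg$thomson$n_compartments, 2L)
  expect_equal(reg$frymoyer_neonatal$n_compartments, 1L)
  expect_equal(reg$frymoyer_neonatal$iiv_cv[["CL"]], 21.6)
  expect_equal(reg$le_pediatric$residual_additive_sd, 0)
  expect_equal(reg$thomson$iiv_cv[["V2"]], 130)
  for (m in reg) {
    expect_true(all(m$iiv_cv > 0))
    expect_gt(m$residual_proportional^2 + m$residual_additive_sd^2, 0)
  }
  expect_error(get_model("nonexistent"), "unknown model_id")
})

test_that("typical parameters reproduce the printed worked examples", {
  th <- typical_parameters("thomson", list(weight = 70, crcl = 66))
  expect_equal(th$CL, 2.99)
  expect_equal(th$V1, 0.675 * 70)
  expect_equal(th$V2, 0.732 * 70)
  expect_equal(th$Q, 2.28)

  fr <- typical_parameters("frymoyer_neonatal",
                           list(weight = 2.9, serum_creatinine = 1,
                                postmenstrual_age = 34.8))
  expect_equal(fr$CL, 0.1725)  # 0.345 * maturation 0.5
  expect_equal(fr$V, 1.75)

  le <- typical_parameters("le_pediatric",
                           list(weight = 1, serum_creatinine = 0.48,
                                age_days = exp(7.8)))
  expect_equal(le$CL, 0.248)
  expect_equal(le$V, 0.636)

  # maturation saturates: CL -> 0.345 L/h as PMA grows without bound
  fr_inf <- typical_parameters("frymoyer_neonatal",
                               list(weight = 2.9, serum_creatinine = 1,
                                    postmenstrual_age = 1e6))
  expect_equal(fr_inf$CL, 0.345, tolerance = 1e-9)
})

test_that("maturation factor is a proper sigmoid", {
  pma <- exp(seq(log(20), log(300), length.out = 50))
  f <- maturation_factor(pma)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(f) > 0))
  expect_identical(maturation_factor(34.8), 0.5)
})

test_that("typical CL increases with weight and decreases with creatinine", {
  wts <- seq(2, 60, length.out = 100)
  crs <- seq(0.2, 2, length.out = 100)
  grids <- list(
    frymoyer_neonatal = function(w, cr) {
      typical_parameters("frymoyer_neonatal",
                         list(weight = w, serum_creatinine = cr,
                              postmenstrual_age = 40))$CL
    },
    le_pediatric = function(w, cr) {
      typical_parameters("le_pediatric",
                         list(weight = w, serum_creatinine = cr,
                              age_days = 2000))$CL
    },
    thomson = function(w, cr) {
      # creatinine enters through the Schwartz CrCl
      typical_parameters("thomson",
                         list(weight = w,
                              crcl = schwartz_egfr(110, cr)))$CL
    })
  for (id in names(grids)) {
    fn <- grids[[id]]
    cl_w <- vapply(wts, fn, 0, cr = 0.5)
    cl_c <- vapply(crs, fn, 0, w = 20)
    expect_true(all(diff(cl_w) >= 0), info = "CL nondecr. in weight")
    # the 2-cmt model's clearance is used as printed, without weight
    # scaling, so it is flat in weight; the 1-cmt models rise strictly
    if (id != "thomson") expect_true(all(diff(cl_w) > 0))
    expect_true(all(diff(cl_c) < 0), info = "CL decr. in creatinine")
  }
})

test_that("typical_parameters is pure and validates inputs", {
  cov <- list(weight = 3.2, serum_creatinine = 0.4, postmenstrual_age = 41)
  a <- typical_parameters("frymoyer_neonatal", cov)
  b <- typical_parameters("frymoyer_neonatal", cov)
  expect_identical(a, b)
  expect_error(
    typical_parameters("frymoyer_neonatal",
                       list(weight = 3.2, serum_creatinine = 0.4)),
    "postmenstrual_age")
  expect_error(
    typical_parameters("le_pediatric",
                       list(weight = -1, serum_creatinine = 0.4,
                           age_days = 100)),
    "weight")
})

test_that("serum creatinine is floored at 0.1 mg/dL", {
  lo <- typical_parameters("frymoyer_neonatal",
                           list(weight = 2.9, serum_creatinine = 0.01,
                                postmenstrual_age = 40))
  floor <- typical_parameters("frymoyer_neonatal",
                              list(weight = 2.9, serum_creatinine = 0.1,
                                   postmenstrual_age = 40))
  expect_identical(lo$CL, floor$CL)
})

test_that("age tier selection partitions the covariate space", {
  expect_identical(select_model(39.3, 42, 19), "frymoyer_neonatal")
  expect_identical(select_model(40, 52, 84), "le_pediatric")
  expect_identical(select_model(40, 52, 84, pediatric_model = "thomson"),
                   "thomson")
  expect_error(select_model(NULL, NULL, 60), "model undetermined")
  expect_identical(select_model(NULL, NULL, 200), "le_pediatric")
  # PMA derived from GA + age when not given
  expect_identical(select_model(30, NULL, 7 * 10), "frymoyer_neonatal")
  expect_identical(select_model(40, NULL, 7 * 20), "le_pediatric")
  # every valid input maps to exactly one model or one error
  set.seed(1)
  for (i in 1:50) {
    ga <- if (runif(1) < 0.5) runif(1, 23, 42) else NULL
    age <- runif(1, 0, 5000)
    res <- tryCatch(select_model(ga, NULL, age), error = function(e) "error")
    expect_true(res %in% c("frymoyer_neonatal", "le_pediatric", "error"))
    if (identical(res, "error")) expect_true(is.null(ga) && age < 92)
  }
})

test_that("realized parameters follow the log-normal construction", {
  typ <- typical_parameters("frymoyer_neonatal",
                            list(weight = 2.9, serum_creatinine = 0.5,
                                 postmenstrual_age = 40))
  id <- realize_individual("frymoyer_neonatal", typ, c(0, 0))
  expect_equal(id$CL, typ$CL)
  expect_equal(id$V, typ$V)
  dbl <- realize_individual("frymoyer_neonatal", typ, c(log(2), 0))
  expect_equal(dbl$CL, 2 * typ$CL)
  expect_equal(dbl$V, typ$V)
  # group property: -ln 2 then +ln 2 compose to the identity
  back <- realize_individual("frymoyer_neonatal", dbl, c(-log(2), 0))
  expect_equal(back$CL, typ$CL)
  expect_error(realize_individual("frymoyer_neonatal", typ, c(0, 0, 0)),
               "length")
  expect_error(realize_individual("thomson",
                                  typical_parameters("thomson",
                                                     list(weight = 70,
                                                          crcl = 100)),
                                  c(0, 0)),
               "4 variable parameters")
})

test_that("CV-to-omega conventions", {
  expect_equal(omega_from_cv(21.6), 0.216)
  expect_equal(omega_from_cv(21.6, "lognormal"), sqrt(log(1 + 0.216^2)))
  om <- model_omegas("thomson")
  expect_named(om, c("CL", "V1", "V2", "Q"))
  expect_equal(unname(om), c(0.27, 0.15, 1.30, 1.49))
})

test_that("covariate timeline lookup is LOCF with back-fill", {
  tl <- data.frame(time_h = c(0, 24, 48),
                   weight = c(3.0, NA, 3.2),
                   serum_creatinine = c(0.5, 0.8, NA))
  expect_equal(covariates_at(tl, 30)$serum_creatinine, 0.8)
  expect_equal(covariates_at(tl, 30)$weight, 3.0)
  expect_equal(covariates_at(tl, 100)$weight, 3.2)
  # before the first record: first measurement is carried backward
  expect_equal(covariates_at(tl, -5)$weight, 3.0)
  expect_equal(covariates_at(tl, 10)$serum_creatinine, 0.5)
})
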