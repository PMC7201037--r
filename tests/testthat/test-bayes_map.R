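test_that("objective reduces to the prior with no observations", {
  cs <- make_neonate_course()
  expect_identical(map_objective(c(0, 0), "frymoyer_neonatal", cs), 0)
  om <- model_omegas("frymoyer_neonatal")
  expect_equal(map_objective(c(0.3, -0.1), "frymoyer_neonatal", cs),
               0.3^2 / om[["CL"]]^2 + 0.1^2 / om[["V"]]^2)
})

test_that("objective is stationary at eta = 0 when data equal the typical
           prediction", {
  cs <- make_neonate_course(true_eta = c(CL = 0, V = 0), obs_times = 23.5)
  f0 <- map_objective(c(0, 0), "frymoyer_neonatal", cs)
  for (d in list(c(1e-4, 0), c(-1e-4, 0), c(0, 1e-4), c(0, -1e-4))) {
    expect_gte(map_objective(d, "frymoyer_neonatal", cs), f0)
  }
})

test_that("zero-data fit returns the prior exactly", {
  cs <- make_neonate_course()
  post <- fit_map("frymoyer_neonatal", cs)
  om <- model_omegas("frymoyer_neonatal")
  expect_identical(unname(post$eta_mode), c(0, 0))
  expect_equal(post$covariance, diag(om^2, 2),
               ignore_attr = "dimnames")
  expect_identical(post$n_obs_used, 0L)
  expect_identical(post$objective_value, 0)
})

test_that("optimizer minimum matches an exhaustive eta-grid oracle", {
  # independent oracle: vectorised objective over the [-1,1]^2 grid at
  # step 0.001, concentrations from the textbook 1-cmt infusion formula
  m <- get_model("frymoyer_neonatal")
  om <- model_omegas(m)
  set.seed(99)
  for (case in 1:5) {
    true_eta <- c(CL = runif(1, -0.5, 0.5), V = runif(1, -0.3, 0.3))
    reg <- regimen(45, 8)
    cs <- make_neonate_course(true_eta, scr = runif(1, 0.3, 0.8),
                              n_doses = 3, reg = reg)
    tt <- c(1.5, 7.9, 23.9)
    y <- true_concentration_of(cs, tt) * (1 + 0.05 * rnorm(3))
    cs$observations <- data.frame(time_h = tt, conc = y, flag = "used")

    # ages advance within the course, so typicals are dose-specific
    typs <- course_typical(m, cs)$per_dose
    e_grid <- seq(-1, 1, by = 0.001)
    obj <- outer(e_grid^2 / om[["CL"]]^2, e_grid^2 / om[["V"]]^2, `+`)
    g2 <- (m$residual_proportional / 100 * y)^2 + m$residual_additive_sd^2
    for (j in seq_along(tt)) {
      f <- matrix(0, length(e_grid), length(e_grid))
      for (dj in seq_len(nrow(cs$doses))) {
        te <- tt[j] - cs$doses$start_time[dj]
        if (te <= 0) next
        CLg <- typs[[dj]]$CL * exp(e_grid)
        Vg <- typs[[dj]]$V * exp(e_grid)
        kmat <- outer(CLg, 1 / Vg)
        r0 <- cs$doses$amount[dj] / cs$doses$duration[dj]
        Tj <- min(te, cs$doses$duration[dj])
        f <- f + (r0 / CLg) * (1 - exp(-kmat * Tj)) *
          exp(-kmat * pmax(te - cs$doses$duration[dj], 0))
      }
      obj <- obj + (y[j] - f)^2 / g2[j] + log(g2[j])
    }
    idx <- arrayInd(which.min(obj), dim(obj))
    eta_grid <- c(e_grid[idx[1]], e_grid[idx[2]])

    post <- fit_map(m, cs)
    expect_lt(max(abs(unname(post$eta_mode) - eta_grid)), 2e-3)
    expect_lte(post$objective_value, min(obj) + 1e-6)
  }
})

test_that("fit_map is deterministic", {
  cs <- make_neonate_course(c(CL = 0.25, V = -0.05),
                            obs_times = c(7.9, 23.9, 47.9))
  p1 <- fit_map("frymoyer_neonatal", cs)
  p2 <- fit_map("frymoyer_neonatal", cs)
  expect_identical(p1$eta_mode, p2$eta_mode)
  expect_identical(p1$covariance, p2$covariance)
})

test_that("rich noise-free sampling recovers the simulating eta", {
  # generator/estimator consistency: hourly-scale sampling, no residual
  # noise; the MAP mode should sit within +/-0.01 of the simulating eta
  # for at least 95% of patients
  set.seed(11)
  errs <- vapply(1:100, function(i) {
    om <- model_omegas("frymoyer_neonatal")
    true_eta <- stats::setNames(rnorm(2, 0, om), names(om))
    cs <- make_neonate_course(true_eta,
                              obs_times = seq(0.25, 80, by = 0.1),
                              id = sprintf("rec-%03d", i))
    post <- fit_map("frymoyer_neonatal", cs)
    max(abs(post$eta_mode - true_eta))
  }, 0)
  expect_gte(mean(errs <= 0.01), 0.95)
})

test_that("observations before the first dose are excluded with warning", {
  cs <- make_neonate_course(c(CL = 0.2, V = 0), obs_times = c(7.9, 23.9))
  cs$doses$start_time <- cs$doses$start_time + 5
  cs$observations <- rbind(
    data.frame(time_h = 2, conc = 4, flag = "used"), cs$observations)
  expect_warning(post <- fit_map("frymoyer_neonatal", cs),
                 "before the first dose")
  expect_identical(post$n_obs_used, 2L)
  # manually excluded observations are skipped silently
  cs$observations$flag[1] <- "excluded"
  expect_silent(post2 <- fit_map("frymoyer_neonatal", cs))
  expect_identical(post2$eta_mode, post$eta_mode)
})

test_that("a single observation is shrunk toward the prior mode", {
  # |eta_CL at the mode| < |eta_CL that interpolates the observation|
  # (V direction held at 0), oracle by root finding
  set.seed(21)
  for (case in 1:20) {
    c_true <- runif(1, -0.4, 0.4)
    tt <- runif(1, 20, 40)
    cs <- make_neonate_course(c(CL = c_true, V = 0), obs_times = tt)
    y <- cs$observations$conc
    typs <- course_typical("frymoyer_neonatal", cs)$per_dose
    interp <- uniroot(function(e) {
      pl <- lapply(typs, function(p) {
        realize_individual("frymoyer_neonatal", p, c(e, 0))
      })
      predict_concentration(pl, cs$doses, tt)$conc - y
    }, c(-1, 1), tol = 1e-10)$root
    expect_equal(interp, c_true, tolerance = 1e-6)  # oracle sanity
    post <- fit_map("frymoyer_neonatal", cs)
    if (abs(interp) > 1e-3) {
      expect_lt(abs(post$eta_mode[["CL"]]), abs(interp))
      expect_gte(post$eta_mode[["CL"]] * interp, 0)  # same direction
    }
  }
})

test_that("Laplace covariance shrinks with added data", {
  cs1 <- make_neonate_course(c(CL = 0.2, V = -0.1), obs_times = 23.9)
  cs2 <- make_neonate_course(c(CL = 0.2, V = -0.1),
                             obs_times = c(2, 7.9, 23.9, 31.9, 47.9, 63.9))
  v1 <- diag(fit_map("frymoyer_neonatal", cs1)$covariance)
  v2 <- diag(fit_map("frymoyer_neonatal", cs2)$covariance)
  om2 <- model_omegas("frymoyer_neonatal")^2
  expect_true(all(v1 <= om2 + 1e-8))
  expect_true(all(v2 < v1))
})

test_that("attainment probability handles degenerate posteriors and is
           monotone in the threshold", {
  cs <- make_neonate_course()
  post <- prior_posterior("frymoyer_neonatal", course_covariates(cs, 0))
  # degenerate posterior: point AUC above/below the threshold gives 1/0
  post0 <- post
  post0$covariance[] <- 0
  reg <- regimen(45, 8)
  point_auc <- steady_state_metrics(post$typical, reg)$auc24_ss
  p_lo <- attainment_probability(post0, reg,
                                 c(auc24 = point_auc * 0.8, trough = 20))
  p_hi <- attainment_probability(post0, reg,
                                 c(auc24 = point_auc * 1.2, trough = 20))
  expect_identical(p_lo$p_auc24_gt, 1)
  expect_identical(p_hi$p_auc24_gt, 0)
  # exceedance probability non-increasing over thresholds
  ps <- vapply(c(300, 400, 500, 600), function(thr) {
    attainment_probability(post, reg, c(auc24 = thr, trough = 20),
                           n = 4000, seed = 3)$p_auc24_gt
  }, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("Monte-Carlo attainment is seed-reproducible with binomial-scale
           spread across seeds", {
  cs <- make_neonate_course()
  post <- prior_posterior("frymoyer_neonatal", course_covariates(cs, 0))
  reg <- regimen(45, 8)
  a <- attainment_probability(post, reg, n = 5000, seed = 42)
  b <- attainment_probability(post, reg, n = 5000, seed = 42)
  expect_identical(a, b)
  ps <- vapply(1:8, function(s) {
    attainment_probability(post, reg, n = 5000, seed = s)$p_auc24_gt
  }, 0)
  p_bar <- mean(ps)
  expect_lt(sd(ps), 2.5 * sqrt(p_bar * (1 - p_bar) / 5000))
})

test_that("Monte-Carlo matches the log-normal closed form (CL-only)", {
  # 1-cmt with variability on CL only: AUC24 = D24/CL is log-normal
  cs <- make_neonate_course()
  post <- prior_posterior("frymoyer_neonatal", course_covariates(cs, 0))
  post$covariance[2, 2] <- 0  # freeze V
  post$covariance[1, 2] <- post$covariance[2, 1] <- 0
  post$eta_mode[] <- c(0.1, 0)
  reg <- regimen(45, 8)
  d24 <- 24 / reg$interval * reg$dose
  sd_cl <- sqrt(post$covariance[1, 1])
  closed <- stats::pnorm(
    (log(d24 / 400) - log(post$typical$CL) - post$eta_mode[[1]]) / sd_cl)
  mc <- attainment_probability(post, reg, n = 1e5, seed = 77)$p_auc24_gt
  expect_lt(abs(mc - closed), 0.01)
})
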