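# Shared builders for synthetic courses and independent oracles.

# Covariates of a reference neonate (weight 2.9 kg, PMA ~38 wk).
neonate_covariates <- function(scr = 0.5) {
  data.frame(time_h = 0, weight = 2.9, height = 49, serum_creatinine = scr)
}

# A neonatal course on a fixed q8h regimen, optionally with observations
# at given times simulated noise-free from true_eta.
make_neonate_course <- function(true_eta = c(CL = 0, V = 0),
                                obs_times = NULL, n_doses = 10,
                                reg = regimen(45, 8), scr = 0.5,
                                id = "neo-test") {
  cs <- patient_course(id, "frymoyer_neonatal", age_days = 20,
                       gestational_age = 38,
                       covariates = neonate_covariates(scr),
                       doses = regimen_doses(reg, n_doses),
                       true_eta = true_eta)
  if (!is.null(obs_times)) {
    f <- true_concentration_of(cs, obs_times)
    cs$observations <- data.frame(time_h = obs_times, conc = f,
                                  flag = "used")
  }
  attr(cs, "regimen") <- reg
  cs
}

# Noise-free individual prediction at given times (package path).
true_concentration_of <- function(course, times) {
  m <- get_model(course$model_id)
  typ <- course_typical(m, course)
  pl <- lapply(typ$per_dose, function(p) {
    realize_individual(m, p, course$true_eta)
  })
  predict_concentration(pl, course$doses, times)$conc
}

# Independent 1-compartment infusion superposition (oracle code path,
# written from the textbook formula, no package internals).
oracle_conc_1cmt <- function(CL, V, doses, times) {
  k <- CL / V
  conc <- numeric(length(times))
  for (j in seq_len(nrow(doses))) {
    r0 <- doses$amount[j] / doses$duration[j]
    te <- times - doses$start_time[j]
    Tj <- doses$duration[j]
    during <- te >= 0 & te <= Tj
    after <- te > Tj
    conc[during] <- conc[during] + r0 / CL * (1 - exp(-k * te[during]))
    conc[after] <- conc[after] +
      r0 / CL * (1 - exp(-k * Tj)) * exp(-k * (te[after] - Tj))
  }
  conc
}

# deSolve oracle for arbitrary 1-/2-compartment infusion histories.
# The infusion rate is piecewise constant, so each segment between dose
# boundaries is integrated separately with its own constant rate.
oracle_conc_ode <- function(params, doses, times) {
  two <- !is.null(params$V1)
  rhs <- function(t, y, rate) {
    if (two) {
      k10 <- params$CL / params$V1
      k12 <- params$Q / params$V1
      k21 <- params$Q / params$V2
      list(c(rate - (k10 + k12) * y[1] + k21 * y[2],
             k12 * y[1] - k21 * y[2]))
    } else {
      list(rate - params$CL / params$V * y[1])
    }
  }
  rate_at <- function(t) {
    sum(ifelse(t >= doses$start_time & t < doses$start_time + doses$duration,
               doses$amount / doses$duration, 0))
  }
  breaks <- sort(unique(c(0, times, doses$start_time,
                          doses$start_time + doses$duration,
                          max(times) + 1)))
  y <- if (two) c(0, 0) else 0
  out <- numeric(length(times))
  for (i in seq_len(length(breaks) - 1)) {
    seg <- c(breaks[i], breaks[i + 1])
    rate <- rate_at(mean(seg))
    sol <- deSolve::lsoda(y, seg, rhs, parms = rate,
                          rtol = 1e-11, atol = 1e-13)
    hit <- which(times == seg[1])
    vc <- if (two) params$V1 else params$V
    out[hit] <- y[1] / vc
    y <- sol[2, -1]
  }
  out
}
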