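## Internal structural equations of the synthetic world.
##
## One latent health-burden process U(t) per subject (AR(1) with feedback from
## prior low-income exposure) drives utilization, depresses income (raising
## exposure propensity), raises both outcomes, and raises the censoring
## hazard. Functional forms are the simplest ones exhibiting
## treatment-confounder feedback; constants below are documented in the
## methods vignette.

.msw <- list(
  urban_levels   = c("urban", "suburban", "rural"),
  urban_probs    = c(0.59, 0.31, 0.10),
  occ_levels     = 1:6,
  occ_probs      = c(0.20, 0.39, 0.16, 0.15, 0.01, 0.09),
  occ_income     = c(0.10, 0.15, 0.60, 0.60, -0.80, -0.90),
  urban_income   = c(0.00, -0.05, 0.30),   # rural residents earn more here
  p_move_urban   = 0.02,                    # per-year residence transition
  p_move_occ     = 0.01,                    # per-year occupation transition
  visits_icpt    = 2.3, visits_conf = 0.8,  # log outpatient-visit rate
  stays_icpt     = -2.2, stays_conf = 0.5,  # log inpatient-stay rate
  pd_base        = c(1.9, 1.5, 0.9),        # physician density by urbanization
  pd_drift       = 0.012, pd_noise = 0.05,
  hosp_icpt      = -3.6, hosp_age = 0.012, hosp_sex = 0.1,
  comorb_icpt    = c(-3.2, -3.4, -3.6, -3.8, -4.0, -4.2), # 6 toy categories
  comorb_age     = 0.02, comorb_persist = 0.85,
  censor_age     = 0.02,
  age_range      = c(20L, 79L),
  p_inp_route    = 0.2,   # comorbidity validated via 1 admission vs 2 visits
  p_acsc_distr   = 0.03,  # ACSC code in secondary position (non-qualifying)
  p_single_distr = 0.05,  # single ambulatory comorbidity mention
  p_noise_amb    = 0.3,   # unrelated ambulatory encounter per subject-year
  p_noise_inp    = 0.5    # unrelated inpatient record when stays > 0
)

wave_years_of <- function(cfg) {
  cfg$baseline_year + cfg$wave_interval_years * seq_len(cfg$n_waves)
}

## probability models shared by the observational and counterfactual paths
p_hosp_ <- function(A, U, age, sex, cfg) {
  plogis(.msw$hosp_icpt + cfg$beta_exposure * A + cfg$eta_outcome_confounding * U +
           .msw$hosp_age * (age - 50) + .msw$hosp_sex * sex)
}

p_comorb_new_ <- function(k, A, U, age, cfg) {
  plogis(.msw$comorb_icpt[k] + cfg$beta_comorbidity * A +
           cfg$eta_comorbidity * U + .msw$comorb_age * (age - 50))
}

p_censor_ <- function(A, U, age, cfg) {
  if (cfg$censor_rate == 0) return(rep(0, length(A)))
  plogis(qlogis(cfg$censor_rate) + cfg$censor_exposure_effect * A +
           cfg$censor_confounder_effect * U + .msw$censor_age * (age - 50))
}

step_confounder_ <- function(U_prev, A_prev, xi, cfg) {
  cfg$ar_coef * U_prev + cfg$gamma_feedback * A_prev + xi
}

confounder_noise_sd <- function(cfg) {
  cfg$sd_confounder * sqrt(1 - cfg$ar_coef^2)
}

## advance the comorbidity-category state one assessment: chronic persistence
## plus new onsets; `u` is one uniform draw per (subject, category).
step_comorb_ <- function(active_prev, A, U, age, u, cfg) {
  K <- ncol(active_prev)
  out <- active_prev
  for (k in seq_len(K)) {
    p_new <- p_comorb_new_(k, A, U, age, cfg)
    out[, k] <- ifelse(active_prev[, k], u[, k] < .msw$comorb_persist, u[, k] < p_new)
  }
  out
}

baseline_comorb_ <- function(U0, age0, cfg, u) {
  K <- length(.msw$comorb_icpt)
  active <- matrix(FALSE, length(U0), K)
  for (k in seq_len(K)) {
    active[, k] <- u[, k] < p_comorb_new_(k, 0, U0, age0, cfg)
  }
  active
}

## low-income threshold rule shared by the generator and the wave builder:
## strict "<" against the type-7 empirical quantile.
income_threshold_ <- function(x, cut) {
  as.numeric(quantile(x, cut / 100, type = 7, names = FALSE))
}

## ---------------------------------------------------------------------------
## Observational core: all causal draws (no claims dressing). Draw order is
## fixed and shared with generate_cohort so both are reproducible from the
## config seed. Returns matrices indexed [subject, wave + 1] (column 1 is
## baseline, i.e. wave 0).
sim_core_ <- function(cfg) {
  n <- cfg$n_subjects
  T <- cfg$n_waves
  iv <- cfg$wave_interval_years
  wy <- wave_years_of(cfg)
  ip <- cfg$income_lognormal_params
  years <- cfg$baseline_year:(wy[T] + 1)
  nY <- length(years)

  sex <- rbinom(n, 1, 0.5)
  age0 <- sample(seq(.msw$age_range[1], .msw$age_range[2]), n, replace = TRUE)
  urb <- matrix(0L, n, nY)
  occ <- matrix(0L, n, nY)
  urb[, 1] <- sample(1:3, n, replace = TRUE, prob = .msw$urban_probs)
  occ[, 1] <- sample(1:6, n, replace = TRUE, prob = .msw$occ_probs)
  for (j in 2:nY) {
    mv <- runif(n) < .msw$p_move_urban
    urb[, j] <- ifelse(mv, sample(1:3, n, replace = TRUE, prob = .msw$urban_probs), urb[, j - 1])
    mv <- runif(n) < .msw$p_move_occ
    occ[, j] <- ifelse(mv, sample(1:6, n, replace = TRUE, prob = .msw$occ_probs), occ[, j - 1])
  }

  U <- matrix(0, n, T + 1)
  A <- matrix(0L, n, T + 1)
  U[, 1] <- rnorm(n, 0, cfg$sd_confounder)

  income_at <- function(year_idx, U_wave) {
    y <- years[year_idx]
    exp(ip$meanlog + ip$growth * (y - cfg$baseline_year) +
          .msw$occ_income[occ[, year_idx]] + .msw$urban_income[urb[, year_idx]] -
          cfg$alpha_confounding * U_wave + ip$sdlog * rnorm(nrow(U)))
  }

  income <- matrix(NA_real_, n, nY)
  income[, 1] <- income_at(1, U[, 1])
  A[, 1] <- as.integer(income[, 1] < income_threshold_(income[, 1], cfg$income_cut))

  present <- matrix(FALSE, n, T + 1) # present at wave t (column t + 1)
  present[, 1] <- TRUE
  cens_int <- integer(n)             # 0 = uncensored; t = lost in interval (t-1, t]
  Y_hosp <- matrix(NA_integer_, n, T)
  comorb <- vector("list", T + 1)
  u0 <- matrix(runif(n * length(.msw$comorb_icpt)), n)
  comorb[[1]] <- baseline_comorb_(U[, 1], age0, cfg, u0)
  sd_xi <- confounder_noise_sd(cfg)
  cum_sum <- numeric(n); cum_n <- 0L

  for (t in seq_len(T)) {
    at_risk <- present[, t]
    pc <- p_censor_(A[, t], U[, t], age0 + iv * (t - 1), cfg)
    lost <- at_risk & (runif(n) < pc)
    cens_int[lost & cens_int == 0L] <- t
    present[, t + 1] <- at_risk & !lost

    U[, t + 1] <- step_confounder_(U[, t], A[, t], rnorm(n, 0, sd_xi), cfg)

    ## incomes for the interval's years (wy[t] - iv, wy[t]]
    yr_idx <- which(years > wy[t] - iv & years <= wy[t])
    for (j in yr_idx) income[, j] <- income_at(j, U[, t + 1])

    ## cumulative average income over [baseline + 1, wave_year - 1]
    add_idx <- which(years >= cfg$baseline_year + 1 + cum_n & years <= wy[t] - 1)
    if (length(add_idx)) {
      cum_sum <- cum_sum + rowSums(income[, add_idx, drop = FALSE])
      cum_n <- cum_n + length(add_idx)
    }
    cum_mean <- if (cum_n > 0) cum_sum / cum_n else income[, 1]
    thr <- income_threshold_(cum_mean[present[, t + 1]], cfg$income_cut)
    A[, t + 1] <- as.integer(cum_mean < thr)

    Y_hosp[, t] <- as.integer(runif(n) < p_hosp_(A[, t + 1], U[, t + 1],
                                                 age0 + iv * t, sex, cfg))
    u <- matrix(runif(n * length(.msw$comorb_icpt)), n)
    comorb[[t + 1]] <- step_comorb_(comorb[[t]], A[, t + 1], U[, t + 1],
                                    age0 + iv * t, u, cfg)
  }

  ## years past the last wave (the final outcome year) still need incomes for
  ## the subject-year table; they evolve under the final wave's state
  tail_idx <- which(years > wy[T])
  for (j in tail_idx) income[, j] <- income_at(j, U[, T + 1])

  list(sex = sex, age0 = age0, urb = urb, occ = occ, years = years,
       wave_years = wy, U = U, A = A, income = income, present = present,
       cens_int = cens_int, Y_hosp = Y_hosp, comorb = comorb,
       cum_mean = cum_sum / max(cum_n, 1L))
}

## ---------------------------------------------------------------------------
#' True marginal causal effect by counterfactual simulation
#'
#' Simulates each counterfactual subject twice — exposure forced to low income
#' at every wave, then forced to high income — with censoring disabled, and
#' returns the odds ratio of the pooled wave-outcome probabilities. Noise is
#' drawn once and shared between the two arms (common random numbers), so the
#' result is deterministic given the config seed and smooth in the effect
#' parameters, which the calibration root-finder relies on.
#'
#' @param config a [sim_config].
#' @param n_counterfactual number of simulated subjects per arm.
#' @param outcome `"preventable_hospitalization"` (any ACSC admission in the
#'   wave interval) or `"eci_positive"` (comorbidity index > 0 at the lagged
#'   assessment).
#' @return marginal odds ratio (scalar).
#' @export
true_marginal_effect <- function(config, n_counterfactual = 1e5,
                                 outcome = c("preventable_hospitalization", "eci_positive")) {
  outcome <- match.arg(outcome)
  validate_sim_config(config)
  n <- as.integer(n_counterfactual)
  if (n < 1) stop_invalid("true_marginal_effect: n_counterfactual must be >= 1")
  T <- config$n_waves
  iv <- config$wave_interval_years
  K <- length(.msw$comorb_icpt)

  with_seed(config$seed, {
    sex <- rbinom(n, 1, 0.5)
    age0 <- sample(seq(.msw$age_range[1], .msw$age_range[2]), n, replace = TRUE)
    U0 <- rnorm(n, 0, config$sd_confounder)
    u_base <- matrix(runif(n * K), n)
    xi <- lapply(seq_len(T), function(t) rnorm(n, 0, confounder_noise_sd(config)))
    u_hosp <- lapply(seq_len(T), function(t) runif(n))
    u_com <- lapply(seq_len(T), function(t) matrix(runif(n * K), n))

    run_arm <- function(a) {
      U <- U0
      active <- baseline_comorb_(U0, age0, config, u_base)
      events <- 0
      for (t in seq_len(T)) {
        U <- step_confounder_(U, a, xi[[t]], config)
        age_t <- age0 + iv * t
        if (outcome == "preventable_hospitalization") {
          events <- events + sum(u_hosp[[t]] < p_hosp_(a, U, age_t, sex, config))
        }
        active <- step_comorb_(active, rep(a, n), U, age_t, u_com[[t]], config)
        if (outcome == "eci_positive") {
          events <- events + sum(rowSums(active) > 0)
        }
      }
      events / (n * T)
    }

    p1 <- run_arm(1L)
    p0 <- run_arm(0L)
    if (p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1) {
      stop_invalid(
        "true_marginal_effect: degenerate world (arm probabilities %.4f / %.4f)",
        p1, p0
      )
    }
    (p1 / (1 - p1)) / (p0 / (1 - p0))
  })
}

#' Calibrate an exposure effect to a target marginal odds ratio
#'
#' Root-finds the exposure coefficient (`beta_exposure` for the
#' hospitalization outcome, `beta_comorbidity` for the comorbidity outcome)
#' so that [true_marginal_effect()] equals `target_or`. Every evaluation
#' reuses the same seed, making the objective smooth and monotone.
#'
#' @param config a [sim_config]; the relevant coefficient is overwritten.
#' @param target_or target marginal odds ratio.
#' @param outcome outcome whose coefficient is calibrated.
#' @param n_counterfactual simulation size per evaluation.
#' @param interval search interval for the coefficient.
#' @return the calibrated `sim_config`.
#' @export
calibrate_exposure_effect <- function(config, target_or,
                                      outcome = c("preventable_hospitalization", "eci_positive"),
                                      n_counterfactual = 2e5,
                                      interval = c(-1, 1)) {
  outcome <- match.arg(outcome)
  field <- if (outcome == "preventable_hospitalization") "beta_exposure" else "beta_comorbidity"
  f <- function(b) {
    cfg <- config
    cfg[[field]] <- b
    log(true_marginal_effect(cfg, n_counterfactual, outcome)) - log(target_or)
  }
  root <- uniroot(f, interval, tol = 1e-4)
  config[[field]] <- root$root
  config
}

#' Calibrate the baseline censoring hazard to a target attrition
#'
#' Root-finds `censor_rate` so the observed fraction of subjects lost over
#' the study equals `target_attrition` (default 0.108, i.e. 10.8%).
#'
#' @param config a [sim_config].
#' @param target_attrition overall attrition fraction in (0, 1).
#' @param n simulation size per evaluation.
#' @return the calibrated `sim_config`.
#' @export
calibrate_censor_rate <- function(config, target_attrition = 0.108, n = 1e5) {
  f <- function(r) {
    cfg <- config
    cfg$censor_rate <- r
    cfg$n_subjects <- as.integer(n)
    core <- with_seed(cfg$seed, sim_core_(cfg))
    mean(core$cens_int > 0) - target_attrition
  }
  root <- uniroot(f, c(1e-4, 0.2), tol = 1e-5)
  config$censor_rate <- root$root
  config
}
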