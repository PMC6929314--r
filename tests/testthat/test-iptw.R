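test_that("stabilized weight arithmetic: telescoping product", {
  ## hand-built 2-subject, 2-wave example with stated probabilities
  ws <- stabilized_weights_from_probs(
    subject_id = c(1L, 1L, 2L, 2L),
    wave = c(1L, 2L, 1L, 2L),
    p_num = c(0.4, 0.5, 0.3, 0.6),
    p_den = c(0.8, 0.5, 0.3, 0.4)
  )
  expect_equal(ws[ws$subject_id == 1L & ws$wave == 2L, ]$sw, (0.4 / 0.8) * (0.5 / 0.5))
  expect_equal(ws[ws$subject_id == 1L & ws$wave == 2L, ]$sw, 0.5)
  expect_equal(ws[ws$subject_id == 2L & ws$wave == 2L, ]$sw, 1.5)
  ## identical probabilities give sw exactly 1
  same <- stabilized_weights_from_probs(rep(1L, 3), 1:3, c(0.2, 0.7, 0.9),
                                        c(0.2, 0.7, 0.9))
  expect_identical(same$sw, rep(1, 3))
  expect_error(stabilized_weights_from_probs(1L, 1L, 0, 0.5), "probabilities")
})

test_that("numerator identical to denominator gives sw = 1 exactly", {
  ## a panel whose time-varying covariate list is empty: both model designs
  ## coincide, so the fitted probabilities cancel wave by wave
  w <- packaged_worlds()$confounded_feedback
  panel <- sample_world(w, 2000, seed = 4)
  attr(panel, "timevarying_covariates") <- character(0)
  models <- fit_exposure_models(panel)
  ws <- compute_stabilized_weights(panel, models)
  expect_equal(max(abs(ws$sw - 1)), 0, tolerance = 1e-12)
})

test_that("telescoping invariant holds on fitted weights", {
  ws <- data.table::as.data.table(small_paper_weights())
  recomputed <- ws[, cumprod(ratio), by = subject_id]$V1
  expect_equal(ws$sw, recomputed, tolerance = 1e-12)
  ## mean stabilized weight per wave is near one (tight check at larger n in
  ## the acceptance suite)
  by_wave <- ws[, mean(sw), by = wave]$V1
  expect_true(all(abs(by_wave - 1) < 0.15))
})

test_that("weighted exposure prevalence matches the numerator model", {
  panel <- small_paper_panel()
  models <- fit_exposure_models(panel)
  ws <- compute_stabilized_weights(panel, models)
  dt <- data.table::as.data.table(panel)
  for (k in c(1L, 5L)) {
    idx <- dt$wave == k
    wk <- ws[ws$wave == k, ]
    ## under sw the exposure prevalence equals the numerator-implied one
    ## (tolerance sized for the n = 4000 fixture)
    expect_lt(abs(weighted.mean(dt$A[idx], wk$sw) - mean(models$p_num[idx])), 0.05)
  }
})

test_that("combine_and_truncate caps and counts", {
  ws <- stabilized_weights_from_probs(1:3, rep(1L, 3), c(0.5, 0.9, 0.999),
                                      c(0.25, 0.9, 0.001))
  ws[, `:=`(c_num = 1, c_den = 1, cw = c(1.5, 1, 1))]
  class(ws) <- c("weight_set", class(ws))
  out <- combine_and_truncate(ws, cap = 50)
  expect_equal(out$total[out$subject_id == 1], 2 * 1.5)
  expect_equal(out$total_truncated[out$subject_id == 1], 3)
  ## 0.999/0.001 = 999 -> capped
  expect_equal(out$total_truncated[out$subject_id == 3], 50)
  d <- attr(out, "diagnostics")
  expect_identical(d$n_truncated, 1L)
  ## boundary: a weight exactly at the cap is kept
  ws2 <- data.table::data.table(subject_id = 1L, wave = 1L, p_num = 0.5,
                                p_den = 0.5, ratio = 1, sw = 50, c_num = 1,
                                c_den = 1, cw = 1)
  expect_equal(combine_and_truncate(ws2, cap = 50)$total_truncated, 50)
  ## truncation never increases a weight
  big <- data.table::as.data.table(small_paper_weights())
  expect_true(all(big$total_truncated <= big$total + 1e-12))
  ws3 <- data.table::copy(ws2)[, sw := -1]
  expect_error(combine_and_truncate(ws3), "non-positive")
})

test_that("censoring weights: degenerate and near-null cases", {
  ## no censoring at all: warning and cw identically 1
  coh <- generate_cohort(sim_config(n_subjects = 400, seed = 12))
  panel <- build_wave_panel(coh)
  expect_warning(cm <- fit_censoring_models(panel), "no censoring")
  ws <- compute_stabilized_weights(panel, fit_exposure_models(panel))
  ws2 <- add_censoring_weights(ws, panel, cm)
  expect_identical(ws2$cw, rep(1, nrow(ws2)))

  ## censoring independent of exposure and time-varying covariates:
  ## numerator and denominator estimate the same survival, cw ~ 1
  cfg <- sim_config(n_subjects = 6000, censor_rate = 0.03, seed = 13)
  panel2 <- build_wave_panel(generate_cohort(cfg))
  cm2 <- fit_censoring_models(panel2)
  ws3 <- add_censoring_weights(
    compute_stabilized_weights(panel2, fit_exposure_models(panel2)), panel2, cm2)
  expect_lt(mean(abs(ws3$cw - 1)), 0.02)
  expect_lt(max(abs(ws3$cw - 1)), 0.5)
})

test_that("informative censoring moves weights in the oracle direction", {
  ## censoring driven upward by the utilization burden: subjects observed at
  ## later waves are healthier than the full cohort, so high-burden survivors
  ## are up-weighted: cw > 1 for high-visit subjects on average
  cfg <- sim_config(n_subjects = 8000, censor_rate = 0.04,
                    censor_confounder_effect = 0.8, alpha_confounding = 0.5,
                    eta_outcome_confounding = 0.4, seed = 14)
  panel <- build_wave_panel(generate_cohort(cfg))
  ws <- add_censoring_weights(
    compute_stabilized_weights(panel, fit_exposure_models(panel)),
    panel, fit_censoring_models(panel))
  dt <- data.table::as.data.table(panel)
  merged <- merge(dt[wave == 5, .(subject_id, tv_visits)],
                  ws[ws$wave == 5, c("subject_id", "cw")], by = "subject_id")
  hi <- merged[tv_visits > stats::median(tv_visits), mean(cw)]
  lo <- merged[tv_visits <= stats::median(tv_visits), mean(cw)]
  expect_gt(hi, lo)
})

test_that("exposure model recovery and contracts", {
  ## randomized exposure: all slopes ~ 0, intercept ~ logit(prevalence)
  w <- discrete_world(2, 0.5, conf_init = c(0, 0.5), conf_trans = c(0, 1, 0.5),
                      exposure = c(qlogis(0.3), 0, 0, 0),
                      outcome = c(-1, 0.5, 0.5, 0.2))
  panel <- sample_world(w, 20000, seed = 6)
  models <- fit_exposure_models(panel)
  for (m in models$waves) {
    co <- m$denominator$coef
    expect_lt(abs(co[["(Intercept)"]] - qlogis(0.3)), 0.1)
    expect_true(all(abs(co[setdiff(names(co), "(Intercept)")]) < 0.15))
  }
  ## known propensity coefficients are recovered at large n
  w2 <- packaged_worlds()$confounded_feedback
  panel2 <- sample_world(w2, 50000, seed = 16)
  md <- fit_exposure_models(panel2)
  co2 <- md$waves[[2]]$denominator$coef
  expect_lt(abs(co2[["base_b"]] - w2$exposure[2]), 0.12)
  expect_lt(abs(co2[["tv_u"]] - w2$exposure[3]), 0.12)
  expect_lt(abs(co2[["A_prev"]] - w2$exposure[4]), 0.12)
  ## a single-wave panel yields exactly one model pair
  w1 <- discrete_world(1, 0.5, c(0, 0.5), c(0, 0, 0),
                       c(-0.5, 0.3, 0.8, 0), c(-1, 0.4, 0.6, 0.2))
  m1 <- fit_exposure_models(sample_world(w1, 3000, seed = 2))
  expect_length(m1$waves, 1L)
  ## constant exposure errors out with the wave named
  p_const <- sample_world(w1, 50, seed = 3)
  p_const$A <- 1L
  expect_error(fit_exposure_models(p_const), "constant at wave 1")
})
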