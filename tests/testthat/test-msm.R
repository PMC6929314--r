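unit_weight_set <- function(panel) {
  dt <- data.table::as.data.table(panel)[, .(subject_id, wave)]
  dt[, `:=`(p_num = 0.5, p_den = 0.5, ratio = 1, sw = 1, c_num = 1,
            c_den = 1, cw = 1, total = 1, total_truncated = 1)]
  structure(dt, class = c("weight_set", class(dt)),
            diagnostics = list(cap = 50))
}

test_that("unit weights reproduce the unweighted fit exactly", {
  panel <- sample_world(packaged_worlds()$confounded_feedback, 4000, seed = 23)
  res_w <- fit_msm(panel, unit_weight_set(panel), covariates = "base_b")
  res_u <- fit_msm(panel, NULL, covariates = "base_b")
  expect_equal(res_w$coefficient, res_u$coefficient, tolerance = 1e-12)
  expect_equal(res_w$se, res_u$se, tolerance = 1e-10)
  ## and both agree with stats::glm as an independent route
  dt <- data.table::as.data.table(panel)
  ref <- stats::glm(Y_hosp ~ A + base_b + factor(wave), binomial(), data = dt)
  expect_equal(res_u$coefficient, unname(coef(ref)[["A"]]), tolerance = 1e-8)
})

test_that("estimates are invariant to global weight rescaling", {
  panel <- small_paper_panel()
  ws <- small_paper_weights()
  res1 <- fit_msm(panel, ws)
  scaled <- data.table::copy(data.table::as.data.table(ws))
  scaled[, `:=`(total = total * 7.3, total_truncated = total_truncated * 7.3)]
  class(scaled) <- class(ws)
  attr(scaled, "diagnostics") <- attr(ws, "diagnostics")
  res2 <- fit_msm(panel, scaled)
  expect_equal(res1$coefficient, res2$coefficient, tolerance = 1e-9)
})

test_that("msm_result invariants and degenerate inputs", {
  panel <- small_paper_panel()
  ws <- small_paper_weights()
  res <- fit_msm(panel, ws)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
  expect_equal(res$odds_ratio, exp(res$coefficient))
  expect_gt(res$effective_sample_size, 0)
  ## constant outcome
  p2 <- data.table::copy(data.table::as.data.table(panel))
  p2[, Y_hosp := 0L]
  attrs <- c("baseline_covariates", "timevarying_covariates", "wave_years")
  for (a in attrs) attr(p2, a) <- attr(panel, a)
  class(p2) <- class(panel)
  expect_error(fit_msm(p2, ws), "constant")
  ## zero/NaN weights
  bad <- data.table::copy(data.table::as.data.table(ws))
  bad[1, total_truncated := 0]
  class(bad) <- class(ws)
  expect_error(fit_msm(panel, bad), "positive")
})

test_that("naive estimator is consistent when its assumptions hold", {
  ## no confounding, no feedback: the unadjusted estimate matches the truth
  w <- discrete_world(2, 0.5, conf_init = c(-0.5, 0), conf_trans = c(-0.5, 1, 0),
                      exposure = c(qlogis(0.3), 0, 0, 0),
                      outcome = c(-2, 0.4, 0.6, 0.3))
  truth <- oracle_marginal_or(w)
  panel <- sample_world(w, 40000, seed = 25)
  nv <- naive_estimate(panel, adjustment = "none")
  expect_lt(abs(nv$odds_ratio - truth), 0.08)
  ## baseline-only confounding: baseline adjustment approximately recovers
  ## the conditional effect; with a rare outcome it is near the marginal one
  w2 <- discrete_world(2, 0.5, conf_init = c(-0.5, 0), conf_trans = c(-0.5, 1, 0),
                       exposure = c(-1.2, 1.0, 0, 0),
                       outcome = c(-3, 0.4, 0.3, 0.8))
  panel2 <- sample_world(w2, 40000, seed = 26)
  nv2 <- naive_estimate(panel2, adjustment = "baseline")
  expect_lt(abs(nv2$coefficient - 0.4), 0.12)
})

test_that("eci outcomes: continuous and binary forms", {
  panel <- small_paper_panel()
  ws <- small_paper_weights()
  res_bin <- fit_msm(panel, ws, outcome = "eci_positive")
  expect_true(is.finite(res_bin$odds_ratio))
  res_cont <- fit_msm(panel, ws, outcome = "eci_continuous")
  expect_true(is.na(res_cont$odds_ratio))
  expect_true(is.finite(res_cont$coefficient))
  expect_true(res_cont$ci_low <= res_cont$coefficient &&
                res_cont$coefficient <= res_cont$ci_high)
})

test_that("cluster bootstrap: identity resample, determinism, edge cases", {
  panel <- small_paper_panel()
  ws <- small_paper_weights()
  res <- fit_msm(panel, ws)
  ## an identity resample through the fast bootstrap path must reproduce the
  ## public pipeline's point estimate exactly
  subjects <- unique(data.table::as.data.table(panel)$subject_id)
  ident <- msmwave:::bootstrap_msm_(
    panel, "preventable_hospitalization", res$data$covariates,
    weighted = TRUE, cap = 50, n_boot = 1, seed = 1,
    resamples = list(subjects)
  )
  expect_equal(ident, res$coefficient, tolerance = 1e-8)

  ## determinism: same seed, same interval
  ci1 <- confidence_interval(res, "cluster_bootstrap", n_boot = 60, seed = 99)
  ci2 <- confidence_interval(res, "cluster_bootstrap", n_boot = 60, seed = 99)
  expect_identical(ci1$ci_low, ci2$ci_low)
  expect_identical(ci1$ci_high, ci2$ci_high)
  expect_identical(ci1$variance_method, "cluster_bootstrap")
  expect_warning(confidence_interval(res, "cluster_bootstrap", n_boot = 10, seed = 1),
                 "n_boot")

  ## single subject cannot be cluster-resampled
  one <- data.table::as.data.table(panel)[subject_id == subject_id[1]]
  for (a in c("baseline_covariates", "timevarying_covariates", "wave_years")) {
    attr(one, a) <- attr(panel, a)
  }
  class(one) <- class(panel)
  res_one <- res
  res_one$data$panel <- one
  expect_error(confidence_interval(res_one, "cluster_bootstrap"), "single subject")
})

test_that("iptw regime probabilities validate against the oracle", {
  w <- packaged_worlds()$null_effect
  panel <- sample_world(w, 30000, seed = 27)
  models <- fit_exposure_models(panel)
  for (regime in list(c(0, 0), c(1, 1), c(1, 0))) {
    est <- iptw_regime_probability(panel, models, regime)
    exact <- gformula_regime_probability(w, regime)
    expect_lt(abs(est$pooled - exact$pooled), 0.02)
  }
  expect_error(iptw_regime_probability(panel, models, c(1, 1, 1)), "regime length")
})
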