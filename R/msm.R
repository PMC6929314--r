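## Second-stage estimation: weighted pooled outcome models on the
## pseudo-population, naive comparators, and uncertainty.

outcome_column_ <- function(outcome) {
  switch(outcome,
    preventable_hospitalization = "Y_hosp",
    eci_positive = "eci_positive",
    eci_continuous = "eci_index",
    stop_invalid("unknown outcome '%s'", outcome)
  )
}

## subject-clustered sandwich variance for a fitted (possibly weighted) GLM
cluster_sandwich_ <- function(X, y, mu, w, cluster, binary) {
  resid <- w * (y - mu)
  info_w <- if (binary) w * mu * (1 - mu) else w
  bread <- solve(crossprod(X, X * info_w))
  score <- X * resid
  score_by_cluster <- rowsum(score, cluster)
  meat <- crossprod(score_by_cluster)
  bread %*% meat %*% bread
}

msm_result_ <- function(outcome, coef_a, se, n_subjects, n_rows, ess,
                        method, coefs, binary, data = NULL) {
  z <- qnorm(0.975)
  structure(list(
    outcome = outcome,
    coefficient = coef_a,
    odds_ratio = if (binary) exp(coef_a) else NA_real_,
    ci_low = if (binary) exp(coef_a - z * se) else coef_a - z * se,
    ci_high = if (binary) exp(coef_a + z * se) else coef_a + z * se,
    se = se,
    n_subjects = n_subjects,
    n_rows = n_rows,
    effective_sample_size = ess,
    variance_method = method,
    coefficients = coefs,
    binary = binary,
    data = data
  ), class = "msm_result")
}

#' @export
print.msm_result <- function(x, ...) {
  cat(sprintf("<msm_result> outcome: %s (%s)\n", x$outcome, x$variance_method))
  if (x$binary) {
    cat(sprintf("  odds ratio %.4f (95%% CI %.4f-%.4f); log-OR %.4f (se %.4f)\n",
                x$odds_ratio, x$ci_low, x$ci_high, x$coefficient, x$se))
  } else {
    cat(sprintf("  mean difference %.4f (95%% CI %.4f-%.4f; se %.4f)\n",
                x$coefficient, x$ci_low, x$ci_high, x$se))
  }
  cat(sprintf("  %d subjects, %d subject-wave rows, ESS %.1f\n",
              x$n_subjects, x$n_rows, x$effective_sample_size))
  invisible(x)
}

#' Fit the weighted marginal structural outcome model
#'
#' Pooled subject-wave regression of the outcome on current exposure `A(t)`,
#' the baseline covariates used in the weight numerator, and wave indicators,
#' weighted by the truncated combined weight (logistic link for binary
#' outcomes, identity link for the continuous comorbidity index). The
#' reported standard error is a subject-clustered sandwich (documented as
#' anti-conservative relative to the cluster bootstrap, which re-estimates
#' the weights; see [confidence_interval()]).
#'
#' @param panel a `wave_panel`.
#' @param weights a complete `weight_set`, or `NULL` for unit weights.
#' @param outcome `"preventable_hospitalization"`, `"eci_positive"`, or
#'   `"eci_continuous"`.
#' @param covariates baseline covariate names (default: the panel's baseline
#'   covariate attribute; the comorbidity outcomes exclude the baseline
#'   comorbidity category).
#' @param use_truncated use `total_truncated` (default) rather than `total`.
#' @return an `msm_result`.
#' @export
fit_msm <- function(panel, weights,
                    outcome = c("preventable_hospitalization", "eci_positive", "eci_continuous"),
                    covariates = NULL, use_truncated = TRUE) {
  outcome <- match.arg(outcome)
  dt <- as.data.table(panel)
  ycol <- outcome_column_(outcome)
  if (!ycol %in% names(dt)) stop_invalid("fit_msm: panel lacks outcome column %s", ycol)
  if (is.null(covariates)) {
    covariates <- attr(panel, "baseline_covariates")
    if (outcome != "preventable_hospitalization") {
      covariates <- setdiff(covariates, "base_eci_cat")
    }
  }
  if (is.null(weights)) {
    dt[, w := 1]
  } else {
    wcol <- if (use_truncated) "total_truncated" else "total"
    ws <- as.data.table(weights)
    if (!wcol %in% names(ws)) stop_invalid("fit_msm: weight set lacks column %s", wcol)
    dt <- merge(dt, ws[, c("subject_id", "wave", wcol), with = FALSE],
                by = c("subject_id", "wave"), sort = FALSE)
    setnames(dt, wcol, "w")
  }
  if (any(!is.finite(dt$w)) || any(dt$w <= 0)) {
    stop_invalid("fit_msm: weights must be finite and positive")
  }
  setorder(dt, subject_id, wave)
  y <- dt[[ycol]]
  binary <- outcome != "eci_continuous"
  if (length(unique(y)) < 2) stop_invalid("fit_msm: outcome %s is constant", outcome)
  X <- cbind(A = as.numeric(dt$A),
             build_design_(dt, covariates),
             wave_dummies_(dt$wave))
  fit <- if (binary) fit_logistic_(X, y, dt$w, label = "msm outcome model")
         else fit_gaussian_(X, y, dt$w, label = "msm outcome model")
  Xk <- cbind(`(Intercept)` = 1, X[, setdiff(fit$kept, "(Intercept)"), drop = FALSE])
  mu <- if (binary) plogis(drop(Xk %*% fit$coef)) else drop(Xk %*% fit$coef)
  V <- cluster_sandwich_(Xk, y, mu, dt$w, dt$subject_id, binary)
  ai <- match("A", colnames(Xk))
  msm_result_(
    outcome, fit$coef[["A"]], sqrt(V[ai, ai]),
    n_subjects = length(unique(dt$subject_id)), n_rows = nrow(dt),
    ess = effective_sample_size(dt$w),
    method = "robust_sandwich", coefs = fit$coef, binary = binary,
    data = list(panel = panel, weights = weights, covariates = covariates,
                outcome = outcome, use_truncated = use_truncated)
  )
}

#' Unweighted comparator estimates
#'
#' The biased benchmarks used in the recovery experiments: ordinary pooled
#' regression of the outcome on exposure under three adjustment sets. With
#' treatment-confounder feedback, `baseline_timevarying` adjustment blocks
#' the confounder-mediated part of the effect and conditions on a variable
#' affected by prior exposure, which is exactly the failure mode weighting
#' avoids.
#'
#' @param panel a `wave_panel`.
#' @param outcome outcome name as in [fit_msm()].
#' @param adjustment `"none"`, `"baseline"`, or `"baseline_timevarying"`.
#' @return an `msm_result` with the adjustment recorded in
#'   `variance_method`.
#' @export
naive_estimate <- function(panel,
                           outcome = c("preventable_hospitalization", "eci_positive", "eci_continuous"),
                           adjustment = c("none", "baseline", "baseline_timevarying")) {
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  covariates <- switch(adjustment,
    none = character(0),
    baseline = attr(panel, "baseline_covariates"),
    baseline_timevarying = c(attr(panel, "baseline_covariates"),
                             attr(panel, "timevarying_covariates"))
  )
  if (outcome != "preventable_hospitalization") {
    covariates <- setdiff(covariates, c("base_eci_cat", "tv_eci_cat"))
  }
  res <- fit_msm(panel, weights = NULL, outcome = outcome,
                 covariates = covariates)
  res$variance_method <- paste0("naive_", adjustment)
  res
}

#' Confidence interval for an MSM estimate
#'
#' `robust_sandwich` re-reports the subject-clustered sandwich interval
#' already attached to the fit (anti-conservative: it ignores the sampling
#' variability of the estimated weights). `cluster_bootstrap` resamples
#' subjects with replacement, re-estimates the exposure and censoring models
#' and the weights inside every replicate, refits the outcome model, and
#' takes the percentile 95% interval; this is the headline method.
#'
#' @param result an `msm_result` from [fit_msm()].
#' @param method `"cluster_bootstrap"` or `"robust_sandwich"`.
#' @param n_boot bootstrap replicates (warning below 50).
#' @param seed RNG seed for resampling.
#' @return the updated `msm_result` (with `boot_coefficients` attached for
#'   the bootstrap method).
#' @export
confidence_interval <- function(result, method = c("cluster_bootstrap", "robust_sandwich"),
                                n_boot = 200, seed = 1L) {
  method <- match.arg(method)
  if (method == "robust_sandwich") {
    result$variance_method <- "robust_sandwich"
    return(result)
  }
  if (is.null(result$data)) stop_invalid("confidence_interval: result carries no stored design")
  panel <- result$data$panel
  n_sub <- length(unique(panel$subject_id))
  if (n_sub < 2) stop_invalid("confidence_interval: cannot cluster-resample a single subject")
  if (n_boot < 50) warning("n_boot < 50: bootstrap percentile interval will be unstable")
  boots <- bootstrap_msm_(panel, result$data$outcome, result$data$covariates,
                          weighted = !is.null(result$data$weights),
                          cap = attr(result$data$weights, "diagnostics")$cap %||% 50,
                          n_boot = n_boot, seed = seed)
  qs <- quantile(boots, c(0.025, 0.975), type = 7, names = FALSE)
  if (result$binary) {
    result$ci_low <- exp(qs[1]); result$ci_high <- exp(qs[2])
  } else {
    result$ci_low <- qs[1]; result$ci_high <- qs[2]
  }
  result$se <- sd(boots)
  result$variance_method <- "cluster_bootstrap"
  result$boot_coefficients <- boots
  result
}

#' IPTW estimate of a fixed-regime outcome probability
#'
#' Estimates the counterfactual outcome probability under a fixed exposure
#' regime by inverse-probability weighting of the regime-adherent rows:
#' subjects whose exposure history matches the regime through wave `t` are
#' weighted by the inverse of their cumulative denominator-model
#' probabilities. This is the direct pseudo-population analogue of the
#' g-formula and is compared against the exact enumeration oracle.
#'
#' @param panel a `wave_panel`.
#' @param models a [fit_exposure_models()] result for the panel.
#' @param regime 0/1 vector, one exposure level per wave.
#' @param outcome outcome name as in [fit_msm()].
#' @return list with `per_wave` probabilities and the `pooled` probability.
#' @export
iptw_regime_probability <- function(panel, models, regime,
                                    outcome = "preventable_hospitalization") {
  dt <- as.data.table(panel)
  waves <- sort(unique(dt$wave))
  if (length(regime) != length(waves)) {
    stop_invalid("iptw_regime_probability: regime length %d != number of waves %d",
                 length(regime), length(waves))
  }
  ycol <- outcome_column_(outcome)
  p_obs <- ifelse(dt$A == 1, models$p_den, 1 - models$p_den)
  p_obs <- as.numeric(clip_prob(p_obs))
  dt[, `:=`(p_obs = p_obs, match_w = A == regime[match(wave, waves)])]
  setorder(dt, subject_id, wave)
  dt[, adherent := cumprod(match_w) == 1, by = subject_id]
  dt[, cum_p := cumprod(p_obs), by = subject_id]
  per_wave <- numeric(length(waves))
  num_tot <- den_tot <- 0
  for (i in seq_along(waves)) {
    sub <- dt[wave == waves[i] & adherent == TRUE]
    if (!nrow(sub)) {
      per_wave[i] <- NA_real_
      next
    }
    w <- 1 / sub$cum_p
    per_wave[i] <- weighted_mean_(sub[[ycol]], w)
    num_tot <- num_tot + sum(w * sub[[ycol]])
    den_tot <- den_tot + sum(w)
  }
  list(per_wave = per_wave, pooled = num_tot / den_tot)
}

## ---------------------------------------------------------------------------
## Fast cluster bootstrap: designs are built once, replicates subset them by
## row index and refit with glm.fit. Verified against the public pipeline on
## an identity resample in the test suite.
bootstrap_msm_ <- function(panel, outcome, covariates, weighted, cap,
                           n_boot, seed, resamples = NULL) {
  dt <- add_history_columns_(panel)
  setorder(dt, subject_id, wave)
  base_covs <- attr(panel, "baseline_covariates")
  tv_covs <- attr(panel, "timevarying_covariates")
  extra <- intersect("tv_visits_lag", names(dt))
  ycol <- outcome_column_(outcome)
  binary <- outcome != "eci_continuous"

  y_out <- dt[[ycol]]
  y_A <- dt$A
  wave_v <- dt$wave
  waves <- sort(unique(wave_v))
  X_num <- build_design_(dt, c(base_covs, "A_prev"))
  X_den <- build_design_(dt, c(base_covs, "A_prev", tv_covs, extra))
  X_out <- cbind(A = as.numeric(dt$A), build_design_(dt, covariates),
                 wave_dummies_(wave_v))
  has_cens <- weighted && any(dt$C == 1L)
  if (has_cens) {
    X_cnum <- build_design_(dt, c(base_covs, "A"))
    X_cden <- build_design_(dt, c(base_covs, "A", tv_covs))
    y_stay <- 1L - dt$C
  }
  subjects <- unique(dt$subject_id)
  idx_by_subject <- split(seq_len(nrow(dt)), dt$subject_id)

  grouped_cumprod <- function(x, first_of_group) {
    cs <- cumsum(log(x))
    offset <- c(0, cs)[which(first_of_group)]
    exp(cs - rep(offset, diff(c(which(first_of_group), length(x) + 1L))))
  }

  one_rep <- function(resampled) {
    picked <- idx_by_subject[as.character(resampled)]
    rows <- unlist(picked, use.names = FALSE)
    lens <- lengths(picked)
    clust <- rep(seq_along(resampled), lens)
    wv <- wave_v[rows]
    w_total <- rep(1, length(rows))
    if (weighted) {
      ratio <- numeric(length(rows))
      for (k in waves) {
        sel <- which(wv == k)
        yk <- y_A[rows[sel]]
        if (length(unique(yk)) < 2) return(NA_real_)
        fn <- fit_logistic_(X_num[rows[sel], , drop = FALSE], yk)
        fd <- fit_logistic_(X_den[rows[sel], , drop = FALSE], yk)
        pn <- as.numeric(clip_prob(ifelse(yk == 1, fn$fitted, 1 - fn$fitted)))
        pd <- as.numeric(clip_prob(ifelse(yk == 1, fd$fitted, 1 - fd$fitted)))
        ratio[sel] <- pn / pd
      }
      first <- c(TRUE, clust[-1] != clust[-length(clust)])
      sw <- grouped_cumprod(ratio, first)
      cwf <- rep(1, length(rows))
      if (has_cens) {
        for (s in waves[-length(waves)]) {
          sel <- which(wv == s)
          ys <- y_stay[rows[sel]]
          if (all(ys == 1L)) next
          if (length(unique(ys)) < 2) next
          fn <- fit_logistic_(X_cnum[rows[sel], , drop = FALSE], ys)
          fd <- fit_logistic_(X_cden[rows[sel], , drop = FALSE], ys)
          r <- as.numeric(clip_prob(fn$fitted)) / as.numeric(clip_prob(fd$fitted))
          ## the stay-ratio measured at wave s applies to the same cluster's
          ## row at wave s+1; within-cluster rows are contiguous and ordered
          nxt <- sel + 1L
          ok <- nxt <= length(rows) & clust[nxt] == clust[sel] & ys == 1L
          cwf[nxt[ok]] <- cwf[nxt[ok]] * r[ok]
        }
        cw <- grouped_cumprod(cwf, first)
      } else {
        cw <- 1
      }
      w_total <- pmin(sw * cw, cap)
    }
    fit <- tryCatch({
      if (binary) fit_logistic_(X_out[rows, , drop = FALSE], y_out[rows], w_total)
      else fit_gaussian_(X_out[rows, , drop = FALSE], y_out[rows], w_total)
    }, error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    fit$coef[["A"]]
  }

  if (!is.null(resamples)) {
    ## test hook: run on explicitly supplied subject resamples
    return(vapply(resamples, one_rep, numeric(1)))
  }
  with_seed(seed, {
    out <- vapply(seq_len(n_boot), function(b) {
      one_rep(sample(subjects, length(subjects), replace = TRUE))
    }, numeric(1))
    out[is.finite(out)]
  })
}
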