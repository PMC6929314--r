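## Design-matrix machinery shared by the weight, censoring, and outcome
## models. Formula/predict interfaces are avoided on purpose: designs are
## built once as plain numeric matrices (factors expanded to treatment-coded
## dummies, utilization counts log1p-transformed, incomes log-transformed),
## constant columns are dropped at fit time, and fitted probabilities are
## taken directly from glm.fit. This keeps every fit deterministic, immune to
## empty-factor-level aliasing, and fast enough for the cluster bootstrap.

design_transform_ <- function(x, name) {
  if (grepl("visits|stays", name)) return(log1p(x))
  if (grepl("income", name)) return(log(pmax(x, 1e-8)))
  x
}

build_design_ <- function(dt, vars) {
  dt <- as.data.table(dt)
  cols <- list()
  for (v in vars) {
    x <- dt[[v]]
    if (is.null(x)) stop_invalid("design: column %s not found", v)
    if (is.numeric(x) || is.logical(x)) {
      cols[[v]] <- design_transform_(as.numeric(x), v)
    } else {
      lev <- sort(unique(as.character(x)))
      for (l in lev[-1]) {
        cols[[paste0(v, ".", l)]] <- as.numeric(x == l)
      }
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow(dt), 0))
  do.call(cbind, cols)
}

## logistic fit on a plain design matrix; intercept added, constant columns
## dropped; returns fitted probabilities and named coefficients
fit_logistic_ <- function(X, y, w = NULL, label = "model") {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1L)
  Xk <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
  fit <- suppressWarnings(
    glm.fit(Xk, y, weights = w, family = quasibinomial())
  )
  if (anyNA(fit$coefficients)) {
    ## aliased (collinear) columns: drop and refit
    Xk <- Xk[, !is.na(fit$coefficients), drop = FALSE]
    fit <- suppressWarnings(
      glm.fit(Xk, y, weights = w, family = quasibinomial())
    )
  }
  if (!fit$converged || any(!is.finite(fit$coefficients))) {
    stop_invalid("%s: logistic fit failed to converge (possible separation)", label)
  }
  list(coef = fit$coefficients, fitted = fit$fitted.values,
       converged = fit$converged, kept = colnames(Xk))
}

## weighted least squares on a plain design matrix (continuous outcomes)
fit_gaussian_ <- function(X, y, w = NULL, label = "model") {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1L)
  Xk <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
  fit <- stats::lm.wfit(Xk, y, w)
  if (anyNA(fit$coefficients)) {
    Xk <- Xk[, !is.na(fit$coefficients), drop = FALSE]
    fit <- stats::lm.wfit(Xk, y, w)
  }
  list(coef = fit$coefficients, fitted = drop(Xk %*% fit$coefficients),
       converged = TRUE, kept = colnames(Xk))
}

## wave-dummy columns for pooled outcome models
wave_dummies_ <- function(wave) {
  waves <- sort(unique(wave))
  if (length(waves) < 2) return(matrix(numeric(length(wave)), length(wave), 0))
  out <- vapply(waves[-1], function(t) as.numeric(wave == t), numeric(length(wave)))
  colnames(out) <- paste0("wave.", waves[-1])
  out
}

## history regressor for the denominator models of claims panels: the
## previous wave's aggregated utilization (the lagged confounder proxy),
## measured strictly before the current exposure. The lagged cumulative
## income is deliberately NOT conditioned on: the exposure is a deterministic
## function of cumulative income, so near-deterministic predictors of the
## observed group produce boundary probabilities and unstable weights
## (a practical positivity violation); see the methods vignette.
add_history_columns_ <- function(panel) {
  dt <- as.data.table(panel)
  if (!all(c("cum_income", "tv_visits") %in% names(dt))) return(dt)
  setorder(dt, subject_id, wave)
  dt[, tv_visits_lag := shift(tv_visits), by = subject_id]
  if ("base_visits" %in% names(dt)) {
    dt[is.na(tv_visits_lag), tv_visits_lag := as.numeric(base_visits)]
  }
  dt[]
}
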