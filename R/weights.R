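#' Fit per-wave exposure models for stabilized weights
#'
#' For each wave `k` fits two logistic models for the observed exposure
#' `A(k)`: a numerator model on the baseline covariates `L(0)` and the
#' previous exposure `A(k-1)`, and a denominator model adding the
#' time-varying covariates through wave `k` (the current wave's aggregates
#' plus, for claims panels, the previous wave's utilization). Model matrices
#' are treatment-coded with constant columns dropped; fits are deterministic.
#'
#' @param panel a `wave_panel`.
#' @return object of class `exposure_model_set`: per-wave coefficient vectors,
#'   convergence flags, and fitted numerator/denominator probabilities
#'   aligned with the panel rows.
#' @export
fit_exposure_models <- function(panel) {
  dt <- add_history_columns_(panel)
  base_covs <- attr(panel, "baseline_covariates")
  tv_covs <- attr(panel, "timevarying_covariates")
  extra <- intersect("tv_visits_lag", names(dt))
  waves <- sort(unique(dt$wave))
  out <- vector("list", length(waves))
  p_num <- rep(NA_real_, nrow(dt))
  p_den <- rep(NA_real_, nrow(dt))
  for (i in seq_along(waves)) {
    k <- waves[i]
    idx <- which(dt$wave == k)
    y <- dt$A[idx]
    if (length(unique(y)) < 2) {
      stop_invalid("fit_exposure_models: exposure is constant at wave %d", k)
    }
    sub <- dt[idx]
    X_num <- build_design_(sub, c(base_covs, "A_prev"))
    X_den <- build_design_(sub, c(base_covs, "A_prev", tv_covs, extra))
    fn <- fit_logistic_(X_num, y, label = sprintf("wave %d numerator", k))
    fd <- fit_logistic_(X_den, y, label = sprintf("wave %d denominator", k))
    p_num[idx] <- fn$fitted
    p_den[idx] <- fd$fitted
    out[[i]] <- list(wave = k, numerator = fn[c("coef", "converged")],
                     denominator = fd[c("coef", "converged")])
  }
  structure(list(waves = out, p_num = p_num, p_den = p_den,
                 wave_index = dt$wave, subject_id = dt$subject_id),
            class = "exposure_model_set")
}

#' @export
print.exposure_model_set <- function(x, ...) {
  cat(sprintf("<exposure_model_set> %d waves, %d subject-wave rows\n",
              length(x$waves), length(x$p_num)))
  invisible(x)
}

#' Stabilized treatment weights from running probability ratios
#'
#' The per-row probabilities of the exposure level actually observed are
#' formed from the fitted numerator and denominator models (probability of
#' `A(k) = 1` when observed low-income, of `A(k) = 0` otherwise), clipped to
#' `[1e-6, 1 - 1e-6]`, and telescoped: `sw(t)` is the running product of the
#' numerator/denominator ratio over waves `k <= t`.
#'
#' @param panel a `wave_panel`.
#' @param models an [fit_exposure_models()] result for the same panel.
#' @return a `weight_set`: data.table keyed by subject and wave with
#'   `p_num`, `p_den`, `sw`, censoring columns initialized to 1, and the
#'   clipped-probability count in the `diagnostics` attribute.
#' @export
compute_stabilized_weights <- function(panel, models) {
  dt <- as.data.table(panel)
  if (length(models$p_num) != nrow(dt)) {
    stop_invalid("compute_stabilized_weights: models were fitted on a different panel")
  }
  p1n <- ifelse(dt$A == 1, models$p_num, 1 - models$p_num)
  p1d <- ifelse(dt$A == 1, models$p_den, 1 - models$p_den)
  p1n <- clip_prob(p1n); n_clip <- attr(p1n, "n_clipped")
  p1d <- clip_prob(p1d); n_clip <- n_clip + attr(p1d, "n_clipped")
  ws <- stabilized_weights_from_probs(dt$subject_id, dt$wave,
                                      as.numeric(p1n), as.numeric(p1d))
  ws[, `:=`(c_num = 1, c_den = 1, cw = 1)]
  structure(ws, class = c("weight_set", class(ws)),
            diagnostics = list(n_clipped = n_clip))
}

#' Telescoping product of stabilized-weight ratios
#'
#' Pure arithmetic core of [compute_stabilized_weights()]: given per-row
#' numerator and denominator probabilities of the observed exposure, returns
#' the per-wave ratio and its running product within subject.
#'
#' @param subject_id,wave row identifiers; rows are sorted by subject then
#'   wave before the product is taken.
#' @param p_num,p_den probabilities of the observed exposure level.
#' @return data.table with `p_num`, `p_den`, `ratio`, and `sw`.
#' @export
stabilized_weights_from_probs <- function(subject_id, wave, p_num, p_den) {
  if (any(p_num <= 0 | p_num >= 1 | p_den <= 0 | p_den >= 1)) {
    stop_invalid("stabilized_weights_from_probs: probabilities must lie in (0,1)")
  }
  dt <- data.table(subject_id = subject_id, wave = wave,
                   p_num = p_num, p_den = p_den)
  setorder(dt, subject_id, wave)
  dt[, ratio := p_num / p_den]
  dt[, sw := cumprod(ratio), by = subject_id]
  ## unstabilized companion: the weight under which measured covariates are
  ## independent of exposure (used by the balance diagnostics; the stabilized
  ## weight intentionally preserves the numerator covariates' association)
  dt[, uw := cumprod(1 / p_den), by = subject_id]
  dt[]
}

#' Fit discrete-time censoring models
#'
#' Censoring is modelled per wave interval with binary-response models for
#' remaining under observation (the discrete-time analogue of the
#' proportional-hazards formulation; with multi-year intervals only the
#' interval survival probabilities enter the weights). The numerator model
#' conditions on baseline covariates and exposure history; the denominator
#' adds the time-varying covariates. The first interval's two models share
#' one design (baseline only), so its ratio is exactly 1.
#'
#' @param panel a `wave_panel`.
#' @return object of class `censoring_model_set` with per-interval
#'   stay-probability ratios per subject, or a degenerate set (all ratios 1,
#'   with a warning) when the panel contains no censoring events.
#' @export
fit_censoring_models <- function(panel) {
  dt <- as.data.table(panel)
  base_covs <- attr(panel, "baseline_covariates")
  tv_covs <- attr(panel, "timevarying_covariates")
  waves <- sort(unique(dt$wave))
  if (!any(dt$C == 1L)) {
    warning("no censoring events in panel: censoring weights are identically 1")
    return(structure(list(intervals = list(), ratios = NULL, degenerate = TRUE),
                     class = "censoring_model_set"))
  }
  ratios <- vector("list", 0L)
  intervals <- vector("list", 0L)
  for (s in waves[-length(waves)]) {
    risk <- dt[dt$wave == s]
    y <- 1L - risk$C
    if (all(y == 1L)) {
      r <- data.table(subject_id = risk$subject_id, wave = s + 1L,
                      c_num = 1, c_den = 1)
      ratios[[length(ratios) + 1L]] <- r
      intervals[[length(intervals) + 1L]] <- list(interval = s + 1L, events = 0L)
      next
    }
    X_num <- build_design_(risk, c(base_covs, "A"))
    X_den <- build_design_(risk, c(base_covs, "A", tv_covs))
    fn <- fit_logistic_(X_num, y, label = sprintf("censoring interval %d numerator", s + 1L))
    fd <- fit_logistic_(X_den, y, label = sprintf("censoring interval %d denominator", s + 1L))
    stay <- y == 1L
    r <- data.table(subject_id = risk$subject_id[stay], wave = s + 1L,
                    c_num = clip_prob(fn$fitted[stay]),
                    c_den = clip_prob(fd$fitted[stay]))
    ratios[[length(ratios) + 1L]] <- r
    intervals[[length(intervals) + 1L]] <- list(
      interval = s + 1L, events = sum(y == 0L),
      numerator = fn[c("coef", "converged")],
      denominator = fd[c("coef", "converged")]
    )
  }
  structure(list(intervals = intervals, ratios = rbindlist(ratios),
                 degenerate = FALSE),
            class = "censoring_model_set")
}

#' Attach inverse-probability-of-censoring weights to a weight set
#'
#' The censoring weight at wave `t` is the running product over intervals
#' `s <= t` of the numerator/denominator stay-probability ratios, evaluated
#' along the subject's own history.
#'
#' @param weights a `weight_set` from [compute_stabilized_weights()].
#' @param panel the panel the weights were computed on.
#' @param cens_models a [fit_censoring_models()] result.
#' @return the `weight_set` with `c_num`, `c_den`, and `cw` filled in.
#' @export
add_censoring_weights <- function(weights, panel, cens_models) {
  ws <- as.data.table(weights)
  if (isTRUE(cens_models$degenerate) || is.null(cens_models$ratios) ||
      !nrow(cens_models$ratios)) {
    ws[, `:=`(c_num = 1, c_den = 1, cw = 1)]
  } else {
    ws[, c("c_num", "c_den", "cw") := NULL]
    r <- cens_models$ratios
    ws <- merge(ws, r, by = c("subject_id", "wave"), all.x = TRUE)
    ws[is.na(c_num), `:=`(c_num = 1, c_den = 1)]
    setorder(ws, subject_id, wave)
    ws[, cw := cumprod(c_num / c_den), by = subject_id]
  }
  ws[, ucw := cumprod(1 / c_den), by = subject_id]
  structure(ws, class = c("weight_set", class(as.data.table(ws))),
            diagnostics = attr(weights, "diagnostics"))
}

#' Combine treatment and censoring weights and truncate
#'
#' `total = sw * cw`, truncated at `cap` (inclusive): weights above the cap
#' are set to the cap, all others are unchanged.
#'
#' @param weights a `weight_set` with `sw` and `cw` populated.
#' @param cap truncation cap (default 50).
#' @return the `weight_set` with `total` and `total_truncated`, and the
#'   truncation count/fraction appended to its `diagnostics` attribute.
#' @export
combine_and_truncate <- function(weights, cap = 50) {
  if (cap <= 0) stop_invalid("combine_and_truncate: cap must be positive")
  ws <- as.data.table(weights)
  if (any(!is.finite(ws$sw)) || any(ws$sw <= 0) ||
      any(!is.finite(ws$cw)) || any(ws$cw <= 0)) {
    stop_invalid("combine_and_truncate: non-positive or non-finite weights")
  }
  ws[, total := sw * cw]
  ws[, total_truncated := pmin(total, cap)]
  if (!"ucw" %in% names(ws)) ws[, ucw := 1]
  if (!"uw" %in% names(ws)) ws[, uw := sw]
  ws[, total_unstab_truncated := pmin(uw * ucw, cap)]
  diag <- attr(weights, "diagnostics") %||% list()
  diag$n_truncated <- sum(ws$total > cap)
  diag$frac_truncated <- mean(ws$total > cap)
  diag$cap <- cap
  structure(ws, class = c("weight_set", class(as.data.table(ws))),
            diagnostics = diag)
}

#' @export
print.weight_set <- function(x, ...) {
  d <- attr(x, "diagnostics") %||% list()
  cat(sprintf("<weight_set> %d rows; mean sw %.3f", nrow(x), mean(x$sw)))
  if ("total_truncated" %in% names(x)) {
    cat(sprintf("; mean total %.3f; truncated %d (%.2f%%) at cap %s",
                mean(x$total), d$n_truncated %||% 0L,
                100 * (d$frac_truncated %||% 0), format(d$cap %||% NA)))
  }
  cat("\n")
  invisible(x)
}

#' Compute the full weight set for a panel in one call
#'
#' Convenience wrapper chaining [fit_exposure_models()],
#' [compute_stabilized_weights()], [fit_censoring_models()],
#' [add_censoring_weights()], and [combine_and_truncate()].
#'
#' @param panel a `wave_panel`.
#' @param cap truncation cap.
#' @param censoring fit censoring weights (default TRUE; skipped
#'   automatically when the panel carries no censoring events).
#' @return a complete `weight_set`.
#' @export
compute_weights <- function(panel, cap = 50, censoring = TRUE) {
  models <- fit_exposure_models(panel)
  ws <- compute_stabilized_weights(panel, models)
  if (censoring && any(panel$C == 1L)) {
    cm <- fit_censoring_models(panel)
    ws <- add_censoring_weights(ws, panel, cm)
  }
  combine_and_truncate(ws, cap = cap)
}
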