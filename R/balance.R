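#' Absolute standardized mean difference between exposure groups
#'
#' `|m1 - m0| / sqrt((v1 + v0) / 2)` with (optionally weighted) group means
#' and variances. Binary 0/1 indicators use the proportion variance
#' `p(1 - p)`; continuous covariates use the frequency-weighted variance that
#' reduces exactly to the sample variance under unit weights, so the weighted
#' SMD with all weights equal reproduces the unweighted SMD. A zero pooled
#' variance yields 0 when the means agree and `Inf` otherwise.
#'
#' @param values numeric covariate vector.
#' @param group_labels vector with exactly two distinct values; the SMD is
#'   symmetric in the labels.
#' @param weights optional positive weights.
#' @return non-negative scalar.
#' @export
standardized_mean_difference <- function(values, group_labels, weights = NULL) {
  g <- unique(group_labels)
  if (length(g) != 2) stop_invalid("standardized_mean_difference: need exactly two groups")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights <= 0)) stop_invalid("standardized_mean_difference: weights must be positive")
  i1 <- group_labels == g[1]
  m1 <- weighted_mean_(values[i1], weights[i1])
  m0 <- weighted_mean_(values[!i1], weights[!i1])
  if (is_binary01(values)) {
    v1 <- m1 * (1 - m1); v0 <- m0 * (1 - m0)
  } else {
    v1 <- weighted_var_(values[i1], weights[i1])
    v0 <- weighted_var_(values[!i1], weights[!i1])
  }
  pooled <- (v1 + v0) / 2
  if (pooled <= 0) {
    return(if (isTRUE(all.equal(m1, m0))) 0 else Inf)
  }
  abs(m1 - m0) / sqrt(pooled)
}

#' Covariate balance table before and after weighting
#'
#' Computes the absolute standardized mean difference of every panel
#' covariate across exposure groups at every wave, unweighted and weighted.
#' Categorical covariates contribute one row per level (as 0/1 indicators).
#'
#' The weighted column uses the *unstabilized* truncated weight
#' (`total_unstab_truncated`, the product of inverse denominator
#' probabilities): that is the weight under which measured covariates should
#' be independent of exposure. The stabilized weight used for estimation
#' intentionally preserves the association between exposure and the numerator
#' (baseline) covariates, which the outcome model adjusts for, so it is the
#' wrong yardstick for balance. Weight sets lacking the unstabilized column
#' fall back to `total_truncated`.
#'
#' @param panel a `wave_panel`.
#' @param weights a complete `weight_set`, or `NULL` for unweighted-only
#'   diagnostics.
#' @param threshold flag level for the weighted SMD (default 0.1).
#' @return object of class `balance_table`: data.table with columns `wave`,
#'   `covariate`, `level`, `smd_unweighted`, `smd_weighted`, `flag`, with the
#'   per-wave maxima in the `summary` attribute.
#' @export
balance_table <- function(panel, weights = NULL, threshold = 0.1) {
  dt <- as.data.table(panel)
  covs <- c(attr(panel, "baseline_covariates"), attr(panel, "timevarying_covariates"))
  if (!is.null(weights)) {
    w <- as.data.table(weights)
    wcol <- if ("total_unstab_truncated" %in% names(w)) "total_unstab_truncated"
            else "total_truncated"
    w <- w[, c("subject_id", "wave", wcol), with = FALSE]
    setnames(w, wcol, "bal_w")
    dt <- merge(dt, w, by = c("subject_id", "wave"), sort = FALSE)
  } else {
    dt[, bal_w := 1]
  }
  rows <- list()
  for (t in sort(unique(dt$wave))) {
    sub <- dt[dt$wave == t]
    if (length(unique(sub$A)) < 2) next
    for (v in covs) {
      x <- sub[[v]]
      if (is.numeric(x) || is.logical(x)) {
        rows[[length(rows) + 1L]] <- data.table(
          wave = t, covariate = v, level = NA_character_,
          smd_unweighted = standardized_mean_difference(as.numeric(x), sub$A),
          smd_weighted = standardized_mean_difference(as.numeric(x), sub$A,
                                                      sub$bal_w)
        )
      } else {
        for (l in sort(unique(as.character(x)))) {
          ind <- as.numeric(x == l)
          rows[[length(rows) + 1L]] <- data.table(
            wave = t, covariate = v, level = l,
            smd_unweighted = standardized_mean_difference(ind, sub$A),
            smd_weighted = standardized_mean_difference(ind, sub$A,
                                                        sub$bal_w)
          )
        }
      }
    }
  }
  out <- rbindlist(rows)
  out[, flag := smd_weighted > threshold]
  summary <- out[, .(max_unweighted = max(smd_unweighted),
                     max_weighted = max(smd_weighted)), by = wave]
  structure(out, class = c("balance_table", class(out)),
            threshold = threshold, summary = summary)
}

#' @export
print.balance_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<balance_table> %d covariate-wave rows (flag threshold %.2f)\n",
              nrow(x), attr(x, "threshold")))
  print(s)
  invisible(x)
}
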