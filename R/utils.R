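#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Clip probabilities away from 0 and 1
#'
#' Weight denominators are clipped to `[eps, 1 - eps]` before ratio formation
#' so a numerically degenerate fit cannot produce infinite weights. The number
#' of clipped values is returned as an attribute so it can be logged.
#'
#' @param p numeric vector of probabilities.
#' @param eps clip bound (default `1e-6`).
#' @return clipped vector with attribute `n_clipped`.
#' @export
clip_prob <- function(p, eps = 1e-6) {
  n_clipped <- sum(p < eps | p > 1 - eps, na.rm = TRUE)
  out <- pmin(pmax(p, eps), 1 - eps)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Percentage of a count within a total
#'
#' The column-percentage convention used by the descriptive wave summaries:
#' `100 * x / total`.
#'
#' @param x count.
#' @param total group total.
#' @return percentage on the 0-100 scale.
#' @export
prop_within <- function(x, total) {
  if (any(total <= 0)) stop_invalid("prop_within: total must be positive")
  100 * x / total
}

#' Overall attrition rate from per-wave cohort sizes
#'
#' Percentage of the baseline cohort lost by the final wave,
#' `100 * (n[1] - n[length(n)]) / n[1]`.
#'
#' @param n_by_wave vector of cohort sizes ordered from baseline to last wave.
#' @return attrition percentage on the 0-100 scale.
#' @export
attrition_rate <- function(n_by_wave) {
  if (length(n_by_wave) < 2) stop_invalid("attrition_rate: need at least two waves")
  if (any(diff(n_by_wave) > 0)) warning("cohort sizes are not monotone non-increasing")
  100 * (n_by_wave[1] - n_by_wave[length(n_by_wave)]) / n_by_wave[1]
}

#' Kish effective sample size of a weight vector
#'
#' @param w positive weights.
#' @return `sum(w)^2 / sum(w^2)`.
#' @export
effective_sample_size <- function(w) {
  sum(w)^2 / sum(w^2)
}

weighted_mean_ <- function(x, w) sum(w * x) / sum(w)

## Weighted variance that reduces exactly to stats::var when all weights are
## equal (frequency-weight denominator sum(w) - sum(w^2)/sum(w)).
weighted_var_ <- function(x, w) {
  m <- weighted_mean_(x, w)
  sw <- sum(w)
  denom <- sw - sum(w^2) / sw
  if (denom <= 0) return(0)
  sum(w * (x - m)^2) / denom
}

is_binary01 <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
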