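#' Small discrete worlds for exact g-formula computation
#'
#' A `discrete_world` is a fully specified longitudinal causal system with
#' binary baseline covariate `B`, binary time-varying confounder `U(t)`,
#' binary exposure `A(t)`, and binary wave outcome `Y(t)`, over at most three
#' waves so counterfactual quantities can be computed by exhaustive
#' enumeration. Conditional distributions are parameterised through logistic
#' links (coefficient vectors), so every conditional "table row" sums to one
#' by construction and the sampled data satisfy the working models of the
#' weight engine exactly:
#'
#' * `P(U(1) = 1 | B)` from `conf_init = c(intercept, b_base)`;
#' * `P(U(t) = 1 | U(t-1), A(t-1))` from `conf_trans = c(intercept, b_uprev, b_aprev)`;
#' * `P(A(t) = 1 | B, U(t), A(t-1))` from `exposure = c(intercept, b_base, b_u, b_aprev)`;
#' * `P(Y(t) = 1 | A(t), U(t), B)` from `outcome = c(intercept, b_a, b_u, b_base)`.
#'
#' @param n_waves number of waves (1-3).
#' @param p_baseline `P(B = 1)`.
#' @param conf_init,conf_trans,exposure,outcome logistic coefficient vectors
#'   as above.
#' @param name optional label.
#' @return object of class `discrete_world`.
#' @export
discrete_world <- function(n_waves, p_baseline, conf_init, conf_trans,
                           exposure, outcome, name = "world") {
  n_waves <- as.integer(n_waves)
  if (n_waves < 1 || n_waves > 3) {
    stop_invalid("discrete_world: n_waves must be 1-3 (exhaustive enumeration cap)")
  }
  if (p_baseline < 0 || p_baseline > 1) stop_invalid("discrete_world: p_baseline not a probability")
  lens <- c(conf_init = 2L, conf_trans = 3L, exposure = 4L, outcome = 4L)
  args <- list(conf_init = conf_init, conf_trans = conf_trans,
               exposure = exposure, outcome = outcome)
  for (nm in names(lens)) {
    if (length(args[[nm]]) != lens[[nm]] || any(!is.finite(args[[nm]]))) {
      stop_invalid("discrete_world: %s must be %d finite coefficients", nm, lens[[nm]])
    }
  }
  structure(c(list(n_waves = n_waves, p_baseline = p_baseline, name = name), args),
            class = "discrete_world")
}

#' @export
print.discrete_world <- function(x, ...) {
  cat(sprintf("<discrete_world> '%s': %d wave(s), P(B=1) = %.2f\n",
              x$name, x$n_waves, x$p_baseline))
  invisible(x)
}

p_u1_ <- function(world, b) plogis(world$conf_init[1] + world$conf_init[2] * b)
p_utrans_ <- function(world, u_prev, a_prev) {
  plogis(world$conf_trans[1] + world$conf_trans[2] * u_prev + world$conf_trans[3] * a_prev)
}
p_expo_ <- function(world, b, u, a_prev) {
  plogis(world$exposure[1] + world$exposure[2] * b + world$exposure[3] * u +
           world$exposure[4] * a_prev)
}
p_out_ <- function(world, a, u, b) {
  plogis(world$outcome[1] + world$outcome[2] * a + world$outcome[3] * u +
           world$outcome[4] * b)
}

#' Exact counterfactual outcome probability under a fixed regime
#'
#' Sums over every baseline-confounder trajectory `(B, U(1), ..., U(T))`,
#' weighting each wave's outcome probability by the trajectory's probability
#' under the fixed exposure sequence (censoring absent in the counterfactual
#' world). The trajectory partition is exhaustive; its total mass is returned
#' for the mass-conservation check.
#'
#' @param world a [discrete_world].
#' @param regime 0/1 vector of length `n_waves`.
#' @return list with `per_wave` outcome probabilities, the `pooled`
#'   (wave-averaged) probability, and the trajectory `mass`.
#' @export
gformula_regime_probability <- function(world, regime) {
  T <- world$n_waves
  if (length(regime) != T || !all(regime %in% c(0, 1))) {
    stop_invalid("gformula_regime_probability: regime must be a 0/1 vector of length %d", T)
  }
  per_wave <- numeric(T)
  mass <- 0
  u_grid <- as.matrix(expand.grid(rep(list(0:1), T)))
  for (b in 0:1) {
    pb <- if (b == 1) world$p_baseline else 1 - world$p_baseline
    for (r in seq_len(nrow(u_grid))) {
      u <- u_grid[r, ]
      p_traj <- pb
      p1 <- p_u1_(world, b)
      p_traj <- p_traj * (if (u[1] == 1) p1 else 1 - p1)
      if (T > 1) {
        for (t in 2:T) {
          pt <- p_utrans_(world, u[t - 1], regime[t - 1])
          p_traj <- p_traj * (if (u[t] == 1) pt else 1 - pt)
        }
      }
      mass <- mass + p_traj
      for (t in seq_len(T)) {
        per_wave[t] <- per_wave[t] + p_traj * p_out_(world, regime[t], u[t], b)
      }
    }
  }
  list(per_wave = per_wave, pooled = mean(per_wave), mass = mass)
}

#' Marginal odds ratio between the always- and never-exposed regimes
#'
#' @param world a [discrete_world].
#' @return odds ratio of the pooled counterfactual outcome probabilities,
#'   always-exposed versus never-exposed.
#' @export
oracle_marginal_or <- function(world) {
  p1 <- gformula_regime_probability(world, rep(1, world$n_waves))$pooled
  p0 <- gformula_regime_probability(world, rep(0, world$n_waves))$pooled
  if (p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1) {
    stop_invalid("oracle_marginal_or: degenerate regime probability (%.4f / %.4f)", p1, p0)
  }
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Sample an observational panel from a discrete world
#'
#' Simulates the world's observational law (exposure assigned by its own
#' logistic model) and returns a `wave_panel` with baseline covariate
#' `base_b`, time-varying confounder `tv_u`, exposure `A`, lagged exposure
#' `A_prev`, and outcome `Y_hosp`, suitable for the full weight-and-estimate
#' pipeline.
#'
#' @param world a [discrete_world].
#' @param n number of subjects.
#' @param seed RNG seed.
#' @return a `wave_panel` (uncensored).
#' @export
sample_world <- function(world, n, seed = 1L) {
  with_seed(seed, {
    T <- world$n_waves
    b <- rbinom(n, 1, world$p_baseline)
    rows <- vector("list", T)
    u <- rbinom(n, 1, p_u1_(world, b))
    a_prev <- rep(0L, n)
    for (t in seq_len(T)) {
      if (t > 1) u <- rbinom(n, 1, p_utrans_(world, u, a_prev))
      a <- rbinom(n, 1, p_expo_(world, b, u, a_prev))
      y <- rbinom(n, 1, p_out_(world, a, u, b))
      rows[[t]] <- data.table(subject_id = seq_len(n), wave = t, year = t,
                              A = a, A_prev = a_prev, C = 0L,
                              Y_hosp = y, base_b = b, tv_u = u)
      a_prev <- a
    }
    new_wave_panel(rbindlist(rows), baseline_covariates = "base_b",
                   timevarying_covariates = "tv_u", wave_years = seq_len(T))
  })
}

#' Packaged validation worlds
#'
#' Three small discrete worlds used by the oracle-equivalence tests: a
#' confounded world with feedback and a harmful exposure effect, a null-effect
#' world with confounding, and a three-wave world with a protective effect.
#'
#' @return named list of [discrete_world] objects.
#' @export
packaged_worlds <- function() {
  list(
    confounded_feedback = discrete_world(
      2, 0.4,
      conf_init = c(-0.5, 0.8), conf_trans = c(-0.8, 1.2, 0.8),
      exposure = c(-1.0, 0.5, 0.9, 1.2), outcome = c(-1.5, 0.5, 0.8, 0.3),
      name = "confounded_feedback"
    ),
    ## truly null: the outcome ignores exposure AND the confounder transition
    ## ignores prior exposure, so every regime has identical outcome law
    null_effect = discrete_world(
      2, 0.5,
      conf_init = c(-0.3, 0.6), conf_trans = c(-0.6, 1.0, 0.0),
      exposure = c(-0.8, 0.4, 1.0, 0.8), outcome = c(-1.2, 0.0, 0.9, 0.4),
      name = "null_effect"
    ),
    protective_3wave = discrete_world(
      3, 0.3,
      conf_init = c(-0.2, 0.5), conf_trans = c(-0.7, 1.1, 0.7),
      exposure = c(-0.9, 0.3, 0.8, 1.0), outcome = c(-1.8, -0.6, 0.7, 0.4),
      name = "protective_3wave"
    )
  )
}

#' Read or write a discrete world as JSON
#'
#' @param path file path.
#' @param world a [discrete_world].
#' @return `read_world` returns a `discrete_world`.
#' @export
read_world <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  discrete_world(raw$n_waves, raw$p_baseline, raw$conf_init, raw$conf_trans,
                 raw$exposure, raw$outcome, name = raw$name %||% "world")
}

#' @rdname read_world
#' @export
write_world <- function(world, path) {
  jsonlite::write_json(unclass(world), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
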