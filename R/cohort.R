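#' Generate a claims-style longitudinal cohort with known causal structure
#'
#' Runs the structural engine (latent AR(1) health burden with
#' treatment-confounder feedback, lognormal income, percentile-defined
#' low-income exposure, informative censoring) and emits three claims-style
#' tables:
#'
#' * `subject_year` — one row per subject per observed year: income,
#'   occupation category (1-6), urbanization, sex, age, outpatient visit and
#'   inpatient stay counts, physician density.
#' * `encounters` — diagnosis-level records (`setting`, `position`, `code`)
#'   from which [build_wave_panel()] recovers both outcomes purely from codes:
#'   validated comorbidity categories (two ambulatory visits or one
#'   admission), ACSC primary-diagnosis admissions, plus non-qualifying
#'   distractors (secondary-position ACSC codes, single ambulatory comorbidity
#'   mentions) and unrelated noise encounters.
#' * `censoring` — per subject: last observed year and reason (death
#'   dominates, then transfer and administrative).
#'
#' @param config a [sim_config].
#' @param codes code sets used for emission; must be [default_code_sets()]
#'   compatible (6 comorbidity categories).
#' @return object of class `longitudinal_cohort`: list of the three
#'   data.tables with the config, wave years, and study end year attached as
#'   attributes, plus the generator's internal truth (`truth` attribute:
#'   per-wave exposure, outcomes, and presence) for validation tests.
#' @export
generate_cohort <- function(config, codes = default_code_sets()) {
  validate_sim_config(config)
  if (length(codes$elixhauser_map) != length(.msw$comorb_icpt)) {
    stop_invalid("generate_cohort: codes must have exactly %d comorbidity categories",
                 length(.msw$comorb_icpt))
  }
  cfg <- config
  n <- cfg$n_subjects
  T <- cfg$n_waves
  iv <- cfg$wave_interval_years

  with_seed(cfg$seed, {
    core <- sim_core_(cfg)
    years <- core$years
    nY <- length(years)
    wy <- core$wave_years
    end_year <- wy[T] + 1

    ## wave index (0..T) governing each calendar year's latent state
    wave_of_year <- pmin(pmax(ceiling((years - cfg$baseline_year) / iv), 0L), T)
    Ucol <- wave_of_year + 1L

    lam_v <- exp(.msw$visits_icpt + .msw$visits_conf * core$U[, Ucol, drop = FALSE])
    visits <- matrix(rpois(n * nY, lam_v), n, nY)
    lam_s <- exp(.msw$stays_icpt + .msw$stays_conf * core$U[, Ucol, drop = FALSE])
    stays <- matrix(rpois(n * nY, lam_s), n, nY)
    pd <- pmax(matrix(.msw$pd_base[core$urb], n, nY) +
                 .msw$pd_drift * matrix(years - cfg$baseline_year, n, nY, byrow = TRUE) +
                 matrix(rnorm(n * nY, 0, .msw$pd_noise), n, nY), 0.05)

    ## last observed year and censoring reason
    last_year <- rep(end_year, n)
    cens <- core$cens_int > 0L
    if (any(cens)) {
      jitter <- sample.int(max(1L, iv - 1L), sum(cens), replace = TRUE)
      last_year[cens] <- pmin(wy[core$cens_int[cens]] - iv + jitter,
                              wy[core$cens_int[cens]] - 1L)
    }
    reason <- rep("administrative", n)
    reason[cens] <- sample(c("death", "transfer", "administrative"), sum(cens),
                           replace = TRUE, prob = c(0.80, 0.15, 0.05))

    ## ---- encounters -------------------------------------------------------
    elix <- codes$elixhauser_map
    elix_codes <- unlist(elix, use.names = FALSE)
    elix_off <- c(0L, cumsum(lengths(elix)))
    pick_elix <- function(k) {
      j <- floor(runif(length(k)) * lengths(elix)[k]) + 1L
      elix_codes[elix_off[k] + j]
    }
    enc <- vector("list", 0L)
    add <- function(subject, year, setting, position, code) {
      enc[[length(enc) + 1L]] <<- data.table(
        subject_id = subject, year = year, setting = setting,
        position = position, code = code
      )
    }

    for (t in 0:T) {
      assess_year <- if (t == 0) cfg$baseline_year else wy[t] + 1L
      act <- core$comorb[[t + 1]] & (last_year >= assess_year)
      hit <- which(act, arr.ind = TRUE)
      if (nrow(hit)) {
        route_inp <- runif(nrow(hit)) < .msw$p_inp_route
        k <- hit[, 2]
        if (any(route_inp)) {
          add(hit[route_inp, 1], assess_year, "inpatient", "primary",
              pick_elix(k[route_inp]))
        }
        if (any(!route_inp)) {
          amb_i <- rep(hit[!route_inp, 1], 2L)
          amb_k <- rep(k[!route_inp], 2L)
          add(amb_i, assess_year, "ambulatory", "primary", pick_elix(amb_k))
        }
      }
      if (t > 0) {
        at_wave <- core$present[, t + 1]
        ev <- which(at_wave & core$Y_hosp[, t] == 1L)
        if (length(ev)) {
          add(ev, wy[t] + 1L, "inpatient", "primary",
              sample(codes$acsc_codes, length(ev), replace = TRUE))
        }
        dis <- which(at_wave & runif(n) < .msw$p_acsc_distr)
        if (length(dis)) {
          add(dis, wy[t] + 1L, "inpatient", "primary",
              sample(.other_codes, length(dis), replace = TRUE))
          add(dis, wy[t] + 1L, "inpatient", "secondary",
              sample(codes$acsc_codes, length(dis), replace = TRUE))
        }
        sgl <- which(at_wave & runif(n) < .msw$p_single_distr)
        if (length(sgl)) {
          add(sgl, wy[t], "ambulatory", "primary",
              pick_elix(sample.int(length(elix), length(sgl), replace = TRUE)))
        }
      }
    }

    observed <- outer(last_year, years, ">=")
    amb_noise <- which(observed & matrix(runif(n * nY), n, nY) < .msw$p_noise_amb,
                       arr.ind = TRUE)
    if (nrow(amb_noise)) {
      add(amb_noise[, 1], years[amb_noise[, 2]], "ambulatory", "primary",
          sample(.other_codes, nrow(amb_noise), replace = TRUE))
    }
    inp_noise <- which(observed & stays > 0L &
                         matrix(runif(n * nY), n, nY) < .msw$p_noise_inp,
                       arr.ind = TRUE)
    if (nrow(inp_noise)) {
      add(inp_noise[, 1], years[inp_noise[, 2]], "inpatient", "primary",
          sample(.other_codes, nrow(inp_noise), replace = TRUE))
    }
    encounters <- rbindlist(enc)
    setorder(encounters, subject_id, year, setting, position, code)

    ## ---- subject-year table ----------------------------------------------
    n_obs_years <- last_year - cfg$baseline_year + 1L
    sy_i <- rep(seq_len(n), n_obs_years)
    sy_j <- sequence(n_obs_years)
    flat <- cbind(sy_i, sy_j)
    subject_year <- data.table(
      subject_id = sy_i,
      year = years[sy_j],
      income = core$income[flat],
      occupation = core$occ[flat],
      urbanization = .msw$urban_levels[core$urb[flat]],
      sex = core$sex[sy_i],
      age = core$age0[sy_i] + years[sy_j] - cfg$baseline_year,
      visits = visits[flat],
      stays = stays[flat],
      physician_density = pd[flat]
    )

    censoring <- data.table(
      subject_id = seq_len(n),
      last_observed_year = last_year,
      reason = reason
    )

    truth <- list(
      A = core$A, present = core$present, cens_int = core$cens_int,
      Y_hosp = core$Y_hosp,
      eci_index = vapply(core$comorb, function(m) as.integer(rowSums(m)),
                         integer(n)),
      U = core$U
    )

    structure(
      list(subject_year = subject_year, encounters = encounters,
           censoring = censoring),
      class = "longitudinal_cohort",
      config = cfg, wave_years = wy, end_year = end_year, truth = truth
    )
  })
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<longitudinal_cohort> %d subjects, years %d-%d, %d subject-years, %d encounters\n",
              cfg$n_subjects, cfg$baseline_year, attr(x, "end_year"),
              nrow(x$subject_year), nrow(x$encounters)))
  invisible(x)
}

#' Write or read cohort tables as CSV
#'
#' Each table carries a versioned schema comment in its first line.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param dir output directory (created if missing).
#' @return `read_cohort` returns a `longitudinal_cohort` (without the
#'   generator's `truth` attribute).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- "# msmwave cohort schema v1"
  for (nm in names(cohort)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    writeLines(hdr, path)
    fwrite(cohort[[nm]], path, append = TRUE, col.names = TRUE)
  }
  meta <- list(
    schema = "msmwave-cohort-v1",
    config = unclass(attr(cohort, "config")),
    wave_years = attr(cohort, "wave_years"),
    end_year = attr(cohort, "end_year")
  )
  jsonlite::write_json(meta, file.path(dir, "cohort_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tabs <- lapply(c("subject_year", "encounters", "censoring"), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop_invalid("read_cohort: missing table file %s", path)
    fread(path, skip = 1L)
  })
  names(tabs) <- c("subject_year", "encounters", "censoring")
  meta_path <- file.path(dir, "cohort_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  cfg <- if (!is.null(meta$config)) {
    raw <- meta$config
    raw$income_lognormal_params <- as.list(raw$income_lognormal_params)
    do.call(sim_config, raw)
  } else NULL
  structure(tabs, class = "longitudinal_cohort",
            config = cfg,
            wave_years = meta$wave_years,
            end_year = meta$end_year)
}
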