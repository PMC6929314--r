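#' Interval aggregation of a yearly continuous variable
#'
#' Arithmetic mean of the values observed in the window
#' `[wave_year - window_years + 1, wave_year]`, ignoring missing years.
#'
#' @param yearly_values numeric vector named by calendar year.
#' @param wave_year wave year closing the window.
#' @param window_years window length in years.
#' @return mean over observed in-window years, or `NA` if none.
#' @export
aggregate_continuous <- function(yearly_values, wave_year, window_years) {
  yrs <- as.integer(names(yearly_values))
  inw <- yrs >= wave_year - window_years + 1 & yrs <= wave_year
  v <- yearly_values[inw]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Interval aggregation of a yearly categorical variable
#'
#' Most frequent category in the window; ties are broken in favour of the
#' most recent year's value.
#'
#' @inheritParams aggregate_continuous
#' @param yearly_values vector named by calendar year.
#' @return modal category, or `NA` if no in-window year is observed.
#' @export
aggregate_categorical <- function(yearly_values, wave_year, window_years) {
  yrs <- as.integer(names(yearly_values))
  inw <- yrs >= wave_year - window_years + 1 & yrs <= wave_year & !is.na(yearly_values)
  if (!any(inw)) return(yearly_values[NA_integer_])
  v <- yearly_values[inw]
  yrs <- yrs[inw]
  tab <- tapply(yrs, v, function(y) c(n = length(y), recent = max(y)))
  m <- do.call(rbind, tab)
  cand <- rownames(m)[order(-m[, "n"], -m[, "recent"])][1]
  v[match(cand, as.character(v))]
}

#' Cumulative average income up to a wave year
#'
#' Mean income over `[start_year, wave_year - 1]` — the income history that
#' defines the wave's income group (e.g. the 2009 wave uses 2001-2008).
#'
#' @param yearly_income numeric vector named by calendar year.
#' @param wave_year wave year.
#' @param start_year first year of the accumulation window.
#' @return mean over observed years in the window, or `NA` if none.
#' @export
cumulative_income <- function(yearly_income, wave_year, start_year = 2001L) {
  aggregate_continuous(yearly_income,
                       wave_year = wave_year - 1L,
                       window_years = wave_year - start_year)
}

#' Assign low-income exposure labels by percentile cut
#'
#' A subject is low-income (label 1) iff their cumulative income is strictly
#' below the `percentile_cut` empirical quantile (type 7, linear
#' interpolation) of the supplied incomes. With all incomes identical the
#' strict inequality labels everyone high-income, with a warning.
#'
#' @param cum_income cumulative incomes of the subjects at risk at the wave.
#' @param percentile_cut percentile on the 0-100 scale (default 25).
#' @return integer vector of 0/1 labels.
#' @export
assign_income_group <- function(cum_income, percentile_cut = 25) {
  if (any(is.na(cum_income))) stop_invalid("assign_income_group: missing incomes")
  thr <- income_threshold_(cum_income, percentile_cut)
  out <- as.integer(cum_income < thr)
  if (all(out == 0L) && length(unique(cum_income)) == 1L) {
    warning("all incomes identical: no subject is labelled low-income")
  }
  out
}

## wave panel constructor shared by build_wave_panel and sample_world
new_wave_panel <- function(dt, baseline_covariates, timevarying_covariates,
                           wave_years, baseline_table = NULL, spec = NULL) {
  setorder(dt, subject_id, wave)
  structure(dt, class = c("wave_panel", class(dt)),
            baseline_covariates = baseline_covariates,
            timevarying_covariates = timevarying_covariates,
            wave_years = wave_years, baseline_table = baseline_table,
            spec = spec)
}

#' @export
print.wave_panel <- function(x, ...) {
  cat(sprintf("<wave_panel> %d rows, %d subjects, waves %s\n",
              nrow(x), length(unique(x$subject_id)),
              paste(attr(x, "wave_years"), collapse = ", ")))
  NextMethod()
}

## vectorised window aggregates for one wave
wave_aggregates_ <- function(sy, wave_year, window, ids) {
  w <- sy[year >= wave_year - window + 1 & year <= wave_year & subject_id %in% ids]
  cont <- w[, .(
    tv_visits = mean(visits), tv_stays = mean(stays),
    tv_pd = mean(physician_density)
  ), by = subject_id]
  mode_of <- function(col) {
    agg <- w[, .(cnt = .N, recent = max(year)), by = c("subject_id", col)]
    setorderv(agg, c("subject_id", "cnt", "recent"), c(1, -1, -1))
    agg[, .SD[1], by = subject_id][, c("subject_id", col), with = FALSE]
  }
  out <- merge(cont, mode_of("urbanization"), by = "subject_id")
  out <- merge(out, mode_of("occupation"), by = "subject_id")
  setnames(out, c("urbanization", "occupation"), c("tv_urban", "tv_occ"))
  out
}

#' Build the subject-by-wave analysis panel from a longitudinal cohort
#'
#' Applies, in order: the eligibility exclusion (no record before
#' `spec$eligibility_before`), monotone censoring (a subject contributes a
#' wave row iff still observed at the wave year), interval aggregation of
#' time-varying covariates (mean for continuous, most-recent-tie-break mode
#' for categorical), the cumulative-average-income exposure rule with the
#' percentile cut recomputed per wave among uncensored subjects, and claims
#' coding of both outcomes (ACSC primary-diagnosis admissions in the 3-year
#' window ending at the outcome year; validated comorbidity index at the
#' lagged assessment year).
#'
#' @param cohort a `longitudinal_cohort` (generated or read from CSV).
#' @param spec a [wave_spec]; defaults to the cohort's own scheme when the
#'   cohort carries a config, else `wave_spec()`.
#' @param codes a [code_sets] object.
#' @return a `wave_panel`: one row per subject per wave with exposure `A`,
#'   lagged exposure `A_prev`, censoring flag `C`, outcomes (`Y_hosp`,
#'   `eci_index`, `eci_positive`, `eci_cat`), baseline covariates (`base_*`),
#'   and time-varying covariates (`tv_*`, plus `cum_income`). The baseline
#'   cohort (including subjects censored before the first wave) is attached
#'   as the `baseline_table` attribute for censoring-weight estimation.
#' @export
build_wave_panel <- function(cohort, spec = NULL, codes = default_code_sets()) {
  if (is.null(spec)) {
    cfg <- attr(cohort, "config")
    spec <- if (!is.null(cfg)) wave_spec_for(cfg) else wave_spec()
  }
  sy <- as.data.table(cohort$subject_year)
  enc <- as.data.table(cohort$encounters)
  cens <- as.data.table(cohort$censoring)
  need <- c("subject_id", "year", "income", "occupation", "urbanization",
            "sex", "age", "visits", "stays", "physician_density")
  missing_cols <- setdiff(need, names(sy))
  if (length(missing_cols)) {
    stop_invalid("build_wave_panel: subject_year table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }

  ## eligibility: at least one enrollment record before the cutoff year
  eligible <- sy[year < spec$eligibility_before, unique(subject_id)]
  if (!length(eligible)) stop_invalid("build_wave_panel: no eligible subjects")
  sy <- sy[subject_id %in% eligible]
  enc <- enc[subject_id %in% eligible]

  last_year <- sy[, .(last_year = max(year)), by = subject_id]
  if (nrow(cens)) {
    last_year <- merge(last_year,
                       cens[, .(subject_id, cens_last = last_observed_year)],
                       by = "subject_id", all.x = TRUE)
    last_year[!is.na(cens_last), last_year := pmin(last_year, cens_last)]
    last_year[, cens_last := NULL]
  }

  wy <- spec$exposure_wave_years
  window <- spec$aggregation_window_years
  base_year <- spec$baseline_year

  ## baseline covariates L(0)
  base <- sy[year == base_year,
             .(subject_id, base_sex = sex, base_age = age,
               base_urban = urbanization, base_occ = occupation,
               base_visits = visits, base_stays = stays,
               base_pd = physician_density, base_income = income)]
  base_eci <- eci_batch(enc, base_year, window, codes, subjects = base$subject_id)
  base <- merge(base, base_eci, by = "subject_id")
  setnames(base, "eci_index", "base_eci_index")
  base[, base_eci_cat := eci_category(base_eci_index)]
  base[, base_A0 := assign_income_group(base_income, spec$income_percentile_cut)]
  base <- merge(base, last_year, by = "subject_id")

  rows <- vector("list", length(wy))
  prevA <- base[, .(subject_id, A_prev = base_A0)]
  for (t in seq_along(wy)) {
    ids <- base[last_year >= wy[t], subject_id]
    if (!length(ids)) next
    agg <- wave_aggregates_(sy, wy[t], window, ids)

    cum <- sy[subject_id %in% ids & year >= spec$cumulative_income_start &
                year <= wy[t] - 1,
              .(cum_income = mean(income)), by = subject_id]
    if (nrow(cum) < length(ids)) {
      ## no income history yet: fall back to the baseline-year income
      fb <- base[subject_id %in% setdiff(ids, cum$subject_id),
                 .(subject_id, cum_income = base_income)]
      cum <- rbind(cum, fb)
    }
    dt <- merge(agg, cum, by = "subject_id")
    dt[, A := assign_income_group(cum_income, spec$income_percentile_cut)]
    dt[, wave := t]
    dt[, year := wy[t]]

    out_year <- wy[t] + spec$outcome_lag_years
    acsc_ids <- acsc_batch(enc, out_year - window + 1, out_year, codes)
    dt[, Y_hosp := as.integer(subject_id %in% acsc_ids)]
    eci_out <- eci_batch(enc, out_year, window, codes, subjects = dt$subject_id)
    dt <- merge(dt, eci_out, by = "subject_id")
    eci_cov <- eci_batch(enc, wy[t], window, codes, subjects = dt$subject_id)
    setnames(eci_cov, "eci_index", "tv_eci_index")
    dt <- merge(dt, eci_cov, by = "subject_id")
    dt[, tv_eci_cat := eci_category(tv_eci_index)]
    dt[, eci_positive := as.integer(eci_index > 0)]
    dt <- merge(dt, prevA, by = "subject_id")
    nxt <- if (t < length(wy)) wy[t + 1] else NA_integer_
    dt <- merge(dt, base[, .(subject_id, last_year)], by = "subject_id")
    dt[, C := if (is.na(nxt)) 0L else as.integer(last_year < nxt)]
    dt[, last_year := NULL]
    rows[[t]] <- dt
    prevA <- dt[, .(subject_id, A_prev = A)]
  }
  panel <- rbindlist(rows, use.names = TRUE)
  if (!nrow(panel)) stop_invalid("build_wave_panel: empty panel after exclusions")
  panel <- merge(panel, base[, !c("base_income", "last_year")], by = "subject_id")

  baseline_covs <- c("base_sex", "base_age", "base_urban", "base_occ",
                     "base_visits", "base_stays", "base_pd", "base_eci_cat",
                     "base_A0")
  tv_covs <- c("tv_visits", "tv_stays", "tv_pd", "tv_urban", "tv_occ",
               "tv_eci_cat")
  new_wave_panel(panel, baseline_covs, tv_covs, wy,
                 baseline_table = base, spec = spec)
}

#' Descriptive summary of one wave by exposure group
#'
#' Reproduces the descriptive-table layout: counts with within-exposure-group
#' column percentages for residence, occupation category, and the 3-level
#' comorbidity index, and means with 95% confidence intervals for the
#' utilization covariates and physician density. Wave 0 summarizes baseline
#' covariates grouped by the baseline income group.
#'
#' @param panel a `wave_panel`.
#' @param wave wave index (0 for baseline, 1..T for exposure waves).
#' @return list with `n` (group sizes), `categorical` (long data.table:
#'   variable, level, group, n, pct), and `continuous` (variable, group,
#'   mean, ci_low, ci_high).
#' @export
summarize_wave <- function(panel, wave) {
  dt <- as.data.table(panel)
  if (wave == 0) {
    bt <- attr(panel, "baseline_table")
    if (is.null(bt)) stop_invalid("summarize_wave: panel carries no baseline table")
    d <- bt[, .(group = ifelse(base_A0 == 1, "low", "high"),
                residence = base_urban, occupation = base_occ,
                eci = base_eci_cat, visits = base_visits,
                stays = base_stays, physician_density = base_pd)]
  } else if (wave %in% unique(dt$wave)) {
    idx <- which(dt[["wave"]] == wave)
    d <- dt[idx][, .(group = ifelse(A == 1, "low", "high"),
                                residence = tv_urban, occupation = tv_occ,
                                eci = tv_eci_cat, visits = tv_visits,
                                stays = tv_stays, physician_density = tv_pd)]
  } else {
    stop_invalid("summarize_wave: unknown wave %s", wave)
  }
  nvec <- d[, .N, by = group]
  cat_long <- rbindlist(lapply(c("residence", "occupation", "eci"), function(v) {
    tab <- d[, .(n = .N), by = c("group", v)]
    setnames(tab, v, "level")
    tab <- merge(tab, nvec[, .(group, total = N)], by = "group")
    tab[, pct := prop_within(n, total)]
    tab[, variable := v]
    tab[, total := NULL]
    tab
  }))
  cont_long <- rbindlist(lapply(c("visits", "stays", "physician_density"), function(v) {
    d[, {
      x <- get(v)
      m <- mean(x); se <- sd(x) / sqrt(.N)
      .(variable = v, mean = m, ci_low = m - 1.96 * se, ci_high = m + 1.96 * se)
    }, by = group]
  }))
  list(n = nvec, categorical = cat_long[, .(variable, level, group, n, pct)],
       continuous = cont_long)
}
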