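#' Wave scheme for panel construction
#'
#' Defines the analysis waves: the baseline year, the exposure wave years, the
#' lag to the comorbidity outcome assessment, the covariate aggregation
#' window, the income percentile cut, and the eligibility rule (subjects with
#' no enrollment record before `eligibility_before` are dropped).
#'
#' @param baseline_year baseline calendar year (default 2000).
#' @param exposure_wave_years ordered wave years (default
#'   `c(2003, 2006, 2009, 2012, 2015)`).
#' @param outcome_lag_years lag from wave year to outcome assessment year
#'   (default 1, giving 2004, 2007, 2010, 2013, 2016).
#' @param aggregation_window_years covariate window: each wave year and the
#'   `aggregation_window_years - 1` preceding years (default 3).
#' @param income_percentile_cut percentile defining the low-income group
#'   (default 25).
#' @param cumulative_income_start first year of the cumulative income average
#'   (default `baseline_year + 1`).
#' @param eligibility_before subjects with no record strictly before this year
#'   are excluded (default `baseline_year + 6`).
#' @return object of class `wave_spec`.
#' @export
wave_spec <- function(baseline_year = 2000L,
                      exposure_wave_years = c(2003L, 2006L, 2009L, 2012L, 2015L),
                      outcome_lag_years = 1L,
                      aggregation_window_years = 3L,
                      income_percentile_cut = 25,
                      cumulative_income_start = baseline_year + 1L,
                      eligibility_before = baseline_year + 6L) {
  if (is.unsorted(exposure_wave_years, strictly = TRUE)) {
    stop_invalid("wave_spec: exposure_wave_years must be strictly increasing")
  }
  if (aggregation_window_years < 1) stop_invalid("wave_spec: window must be >= 1")
  if (income_percentile_cut <= 0 || income_percentile_cut >= 100) {
    stop_invalid("wave_spec: income_percentile_cut must lie strictly between 0 and 100")
  }
  structure(list(
    baseline_year = as.integer(baseline_year),
    exposure_wave_years = as.integer(exposure_wave_years),
    outcome_lag_years = as.integer(outcome_lag_years),
    aggregation_window_years = as.integer(aggregation_window_years),
    income_percentile_cut = income_percentile_cut,
    cumulative_income_start = as.integer(cumulative_income_start),
    eligibility_before = as.integer(eligibility_before)
  ), class = "wave_spec")
}

#' Wave spec matching a generator config
#'
#' @param config a [sim_config].
#' @return the `wave_spec` whose wave years, window, and income cut mirror the
#'   generator's scheme, so a generated cohort round-trips exactly.
#' @export
wave_spec_for <- function(config) {
  wave_spec(
    baseline_year = config$baseline_year,
    exposure_wave_years = wave_years_of(config),
    outcome_lag_years = 1L,
    aggregation_window_years = config$wave_interval_years,
    income_percentile_cut = config$income_cut,
    cumulative_income_start = config$baseline_year + 1L,
    eligibility_before = config$baseline_year + 6L
  )
}
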