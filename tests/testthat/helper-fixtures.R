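# Shared fixtures, generated once per test run and cached in an environment.
# Sizes are scaled for the test budget; the acceptance tests use larger runs.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_paper_cohort <- function() {
  fixture("small_paper_cohort", function() {
    generate_cohort(paper_like_config(n_subjects = 4000, seed = 42))
  })
}

small_paper_panel <- function() {
  fixture("small_paper_panel", function() {
    build_wave_panel(small_paper_cohort())
  })
}

small_paper_weights <- function() {
  fixture("small_paper_weights", function() {
    compute_weights(small_paper_panel())
  })
}

# 3-subject hand-built cohort used to trace every panel rule by hand.
# Subject 1: observed throughout, switches residence, has a validated
#   comorbidity and an ACSC admission.
# Subject 2: censored between waves 1 and 2 (last year 2005).
# Subject 3: observed throughout, no encounters of interest.
hand_cohort <- function() {
  fixture("hand_cohort", function() {
    yrs1 <- 2000:2007
    yrs2 <- 2000:2005
    yrs3 <- 2000:2007
    sy <- data.table::data.table(
      subject_id = c(rep(1L, length(yrs1)), rep(2L, length(yrs2)), rep(3L, length(yrs3))),
      year = c(yrs1, yrs2, yrs3),
      income = c(
        c(1000, 900, 1100, 1000, 1000, 1000, 1000, 1000),  # subject 1
        c(300, 310, 290, 300, 305, 300),                   # subject 2 (low)
        c(2000, 2000, 2000, 2000, 2000, 2000, 2000, 2000)  # subject 3
      ),
      occupation = c(
        c(2, 2, 2, 3, 3, 3, 3, 3),    # subject 1: mode over 2001-2003 is 2
        rep(6, 6),
        rep(1, 8)
      ),
      urbanization = c(
        c("urban", "urban", "urban", "rural", "rural", "rural", "rural", "rural"),
        rep("suburban", 6),
        rep("urban", 8)
      ),
      sex = c(rep(1L, 8), rep(0L, 6), rep(1L, 8)),
      age = c(40:47, 60:65, 30:37),
      visits = c(
        c(9, 9, 12, 12, 6, 6, 6, 6),  # mean over 2001-2003 = 11
        rep(4, 6),
        rep(2, 8)
      ),
      stays = c(rep(0L, 8), rep(1L, 6), rep(0L, 8)),
      physician_density = rep(1.5, 22)
    )
    enc <- data.table::data.table(
      subject_id = c(1L, 1L, 1L, 2L, 3L),
      year = c(2004L, 2004L, 2004L, 2003L, 2002L),
      setting = c("ambulatory", "ambulatory", "inpatient", "ambulatory", "ambulatory"),
      position = c("primary", "primary", "primary", "primary", "primary"),
      code = c("I50.1", "I50.2", "J45.9", "E11.0", "Z00.0")
      # subject 1: two ambulatory CHF visits (validated) and an ACSC asthma
      #   admission in 2004; subject 2: single diabetes mention (not validated)
    )
    cens <- data.table::data.table(
      subject_id = 1:3,
      last_observed_year = c(2007L, 2005L, 2007L),
      reason = c("administrative", "death", "administrative")
    )
    structure(list(subject_year = sy, encounters = enc, censoring = cens),
              class = "longitudinal_cohort")
  })
}

hand_spec <- function() {
  wave_spec(
    baseline_year = 2000L,
    exposure_wave_years = c(2003L, 2006L),
    outcome_lag_years = 1L,
    aggregation_window_years = 3L,
    income_percentile_cut = 25,
    eligibility_before = 2006L
  )
}
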