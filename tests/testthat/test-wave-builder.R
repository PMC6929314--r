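test_that("interval aggregation rules", {
  ## worked rule: 2001-2003 average is the wave-2003 value
  v <- c(`2001` = 9, `2002` = 12, `2003` = 12)
  expect_equal(aggregate_continuous(v, 2003, 3), 11)
  ## idempotence on a constant series
  expect_equal(aggregate_continuous(c(`2001` = 5, `2002` = 5, `2003` = 5), 2003, 3), 5)
  ## missing years are ignored
  expect_equal(aggregate_continuous(c(`2002` = 4, `2003` = 8), 2003, 3), 6)
  expect_true(is.na(aggregate_continuous(c(`1999` = 4), 2003, 3)))

  ## categorical mode, most-recent tie-break
  expect_identical(
    aggregate_categorical(c(`2001` = "urban", `2002` = "urban", `2003` = "rural"), 2003, 3)[[1]],
    "urban"
  )
  expect_identical(
    aggregate_categorical(c(`2002` = "urban", `2003` = "rural"), 2003, 3)[[1]],
    "rural"
  )
  expect_identical(
    aggregate_categorical(c(`2003` = "suburban"), 2003, 3)[[1]], "suburban"
  )
})

test_that("cumulative income covers [start_year, wave_year - 1]", {
  inc <- setNames(rep(500, 8), 2001:2008)
  expect_equal(cumulative_income(inc, 2009), 500)
  expect_equal(cumulative_income(c(`2001` = 300, `2002` = 600), 2003), 450)
  ## the 2009 window is 2001-2008 inclusive: make each year distinct and
  ## check the mean uses exactly those 8 values
  inc2 <- setNames(1:10, 2000:2009)
  expect_equal(cumulative_income(inc2, 2009), mean(2:9))
})

test_that("percentile exposure assignment", {
  expect_identical(assign_income_group(c(100, 200, 300, 400), 25), c(1L, 0L, 0L, 0L))
  expect_warning(out <- assign_income_group(rep(5, 10), 25), "identical")
  expect_identical(out, rep(0L, 10))
  ## order-statistics check: fraction below the cut is cut/100 within 1/n
  set.seed(3)
  x <- rlnorm(1000, 7, 0.5)
  expect_lt(abs(mean(assign_income_group(x, 25)) - 0.25), 1 / 1000 + 1e-9)
  expect_error(assign_income_group(c(1, NA)), "missing")
})

test_that("hand-built 3-subject cohort traces every panel rule", {
  panel <- build_wave_panel(hand_cohort(), hand_spec())
  dt <- data.table::as.data.table(panel)

  ## wave membership: subject 2 censored after 2005 -> wave 1 only, C = 1
  expect_identical(dt[wave == 1][order(subject_id), subject_id], 1:3)
  expect_identical(dt[wave == 2][order(subject_id), subject_id], c(1L, 3L))
  expect_identical(dt[wave == 1 & subject_id == 2, C], 1L)
  expect_identical(dt[wave == 1 & subject_id == 1, C], 0L)

  ## exposure: cumulative means 2001-2002 are (1000, 300, 2000); the type-7
  ## 25th percentile is 650, so only subject 2 is low-income at wave 1
  expect_identical(dt[wave == 1][order(subject_id), A], c(0L, 1L, 0L))
  ## wave 2: cumulative means 2001-2005 are (1000, 2000); Q25 = 1250
  expect_identical(dt[wave == 2][order(subject_id), A], c(1L, 0L))
  ## baseline group from year-2000 income (1000, 300, 2000)
  expect_identical(dt[wave == 1][order(subject_id), base_A0], c(0L, 1L, 0L))
  ## exposure history: A_prev at wave 2 is A at wave 1
  expect_identical(dt[wave == 2][order(subject_id), A_prev], c(0L, 0L))

  ## aggregation: subject 1 visits 2001-2003 average to 11; mode occupation 2;
  ## mode residence urban (2 of 3 years)
  s1w1 <- dt[wave == 1 & subject_id == 1]
  expect_equal(s1w1$tv_visits, 11)
  expect_identical(s1w1$tv_occ, 2)
  expect_identical(s1w1$tv_urban, "urban")
  s1w2 <- dt[wave == 2 & subject_id == 1]
  expect_equal(s1w2$tv_visits, 6)
  expect_identical(s1w2$tv_occ, 3)
  expect_identical(s1w2$tv_urban, "rural")

  ## outcomes: subject 1 has an ACSC admission (J45.9, 2004) in the wave-1
  ## outcome window [2002, 2004] and a validated CHF comorbidity (two
  ## ambulatory visits, 2004)
  expect_identical(s1w1$Y_hosp, 1L)
  expect_identical(s1w1$eci_index, 1L)
  expect_identical(s1w1$eci_positive, 1L)
  ## subject 2's single diabetes mention does not validate
  expect_identical(dt[wave == 1 & subject_id == 2, eci_index], 0L)
  ## nothing in the wave-2 outcome window [2005, 2007]
  expect_identical(s1w2$Y_hosp, 0L)
  expect_identical(s1w2$eci_index, 0L)
  ## the wave-2 covariate window [2004, 2006] sees the 2004 CHF visits
  expect_identical(s1w2$tv_eci_index, 1L)
  expect_identical(s1w2$tv_eci_cat, "1-3")

  ## determinism / idempotence at the panel level
  panel2 <- build_wave_panel(hand_cohort(), hand_spec())
  expect_equal(as.data.frame(panel), as.data.frame(panel2))
})

test_that("eligibility exclusion drops subjects without early records", {
  coh <- hand_cohort()
  late <- data.table::copy(coh$subject_year)
  ## shift subject 3's records to start in 2006: no record before 2006
  late[subject_id == 3L, year := year + 6L]
  coh2 <- structure(list(subject_year = late, encounters = coh$encounters,
                         censoring = coh$censoring),
                    class = "longitudinal_cohort")
  ## only subject 1 survives to wave 2, triggering the documented
  ## all-incomes-identical warning for the single-member percentile cut
  expect_warning(panel <- build_wave_panel(coh2, hand_spec()), "identical")
  expect_false(3L %in% panel$subject_id)
})

test_that("panel invariants on a generated cohort", {
  panel <- small_paper_panel()
  dt <- data.table::as.data.table(panel)
  spec <- attr(panel, "spec")
  n_by_wave <- dt[, .N, by = wave][order(wave), N]
  expect_true(all(diff(n_by_wave) <= 0))
  ## exposure fraction per wave equals the percentile cut (continuous incomes)
  frac <- dt[, mean(A), by = wave]$V1
  expect_true(all(abs(frac - 0.25) < 0.002))
  ## monotone censoring: a wave-t row requires a row at every earlier wave
  waves_per_subject <- dt[, .(ok = identical(sort(wave), seq_len(.N))), by = subject_id]
  expect_true(all(waves_per_subject$ok))
  ## no-censoring world: every subject appears at every wave
  coh0 <- generate_cohort(sim_config(n_subjects = 300, seed = 8))
  p0 <- build_wave_panel(coh0)
  expect_identical(nrow(data.table::as.data.table(p0)), 300L * 5L)
})

test_that("summarize_wave produces coherent descriptive tables", {
  panel <- small_paper_panel()
  s <- summarize_wave(panel, 1)
  ## column percentages within each categorical block sum to 100
  sums <- s$categorical[, sum(pct), by = .(variable, group)]
  expect_true(all(abs(sums$V1 - 100) < 1e-9))
  expect_true(all(s$continuous$ci_low <= s$continuous$mean))
  expect_true(all(s$continuous$ci_high >= s$continuous$mean))
  ## baseline summary exists and uses the baseline exposure groups
  s0 <- summarize_wave(panel, 0)
  expect_true(all(c("low", "high") %in% s0$n$group))
  expect_error(summarize_wave(panel, 99), "unknown wave")
  ## a single-member category gets 100%
  h <- summarize_wave(build_wave_panel(hand_cohort(), hand_spec()), 1)
  one_member <- h$categorical[group == "low" & variable == "residence"]
  expect_equal(one_member$pct, 100)
})

test_that("descriptive share arithmetic matches the percentage convention", {
  expect_equal(prop_within(1, 1), 100)
  expect_equal(round(prop_within(44262, 44262 + 220148), 1), 16.7)
  expect_equal(round(prop_within(410251, 694162), 1), 59.1)
  expect_equal(round(attrition_rate(c(2844334, 2844334, 2753224, 2644668, 2538246)), 1), 10.8)
  expect_warning(attrition_rate(c(10, 12)), "monotone")
})
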