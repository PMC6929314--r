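enc_row <- function(subject, year, setting, position, code) {
  data.table::data.table(subject_id = subject, year = year, setting = setting,
                         position = position, code = code)
}

test_that("the comorbidity validity rule is applied per category", {
  codes <- default_code_sets()
  ## a single ambulatory mention never validates a condition
  e1 <- enc_row(1L, 2004L, "ambulatory", "primary", "E11.0")
  expect_identical(compute_eci(e1, 1L, 2004L, 3, codes)$index, 0L)
  ## one admission does
  e2 <- enc_row(1L, 2004L, "inpatient", "primary", "E11.0")
  r2 <- compute_eci(e2, 1L, 2004L, 3, codes)
  expect_identical(r2$index, 1L)
  expect_true(r2$positive_flag)
  ## two ambulatory visits in two different categories validate neither
  e3 <- rbind(enc_row(1L, 2004L, "ambulatory", "primary", "E11.0"),
              enc_row(1L, 2003L, "ambulatory", "primary", "I50.1"))
  expect_identical(compute_eci(e3, 1L, 2004L, 3, codes)$index, 0L)
  ## two ambulatory visits in the same category (different codes) validate it
  e4 <- rbind(enc_row(1L, 2004L, "ambulatory", "primary", "I50.1"),
              enc_row(1L, 2003L, "ambulatory", "secondary", "I50.2"))
  expect_identical(compute_eci(e4, 1L, 2004L, 3, codes)$index, 1L)
  ## encounters outside the lookback window are ignored
  e5 <- enc_row(1L, 2000L, "inpatient", "primary", "E11.0")
  expect_identical(compute_eci(e5, 1L, 2004L, 3, codes)$index, 0L)
  ## absent subject: index 0
  expect_identical(compute_eci(e1, 42L, 2004L, 3, codes)$index, 0L)
})

test_that("compute_eci is monotone in the encounter set", {
  codes <- default_code_sets()
  set.seed(11)
  all_codes <- c(unlist(codes$elixhauser_map), "Z00.0")
  enc <- data.table::data.table(
    subject_id = 1L,
    year = sample(2001:2004, 40, replace = TRUE),
    setting = sample(c("ambulatory", "inpatient"), 40, TRUE, prob = c(0.8, 0.2)),
    position = "primary",
    code = sample(all_codes, 40, TRUE)
  )
  prev <- 0L
  for (m in seq(5, 40, by = 5)) {
    idx <- compute_eci(enc[1:m], 1L, 2004L, 4, codes)$index
    expect_gte(idx, prev)
    prev <- idx
  }
})

test_that("eci_category bins agree with direct binning for indices 0-40", {
  expect_identical(eci_category(0L), "0")
  expect_identical(eci_category(3L), "1-3")
  expect_identical(eci_category(4L), ">=4")
  direct <- ifelse(0:40 == 0, "0", ifelse(0:40 <= 3, "1-3", ">=4"))
  expect_identical(eci_category(0:40), direct)
  expect_error(eci_category(-1L), "non-negative")
})

test_that("preventable hospitalization requires a primary ACSC diagnosis", {
  codes <- default_code_sets()
  hit <- enc_row(1L, 2004L, "inpatient", "primary", "J45.9")
  expect_true(flag_preventable_hospitalization(hit, 1L, c(2002, 2004), codes))
  ## secondary position never triggers (warning: no primary in window)
  sec <- enc_row(1L, 2004L, "inpatient", "secondary", "J45.9")
  expect_warning(
    expect_false(flag_preventable_hospitalization(sec, 1L, c(2002, 2004), codes)),
    "primary"
  )
  ## secondary ACSC next to a non-ACSC primary: still FALSE, no warning
  pair <- rbind(enc_row(1L, 2004L, "inpatient", "primary", "Z00.0"),
                enc_row(1L, 2004L, "inpatient", "secondary", "J45.9"))
  expect_false(flag_preventable_hospitalization(pair, 1L, c(2002, 2004), codes))
  ## no stays in the interval
  expect_false(flag_preventable_hospitalization(hit, 1L, c(2005, 2007), codes))
  ## ambulatory ACSC codes do not count
  amb <- enc_row(1L, 2004L, "ambulatory", "primary", "J45.9")
  expect_false(flag_preventable_hospitalization(amb, 1L, c(2002, 2004), codes))
})

test_that("the flag is monotone in the ACSC code set", {
  small <- code_sets(acsc_codes = "J45.9",
                     elixhauser_map = default_code_sets()$elixhauser_map)
  big <- default_code_sets()
  set.seed(5)
  for (i in 1:20) {
    enc <- enc_row(1L, sample(2002:2004, 3, TRUE), "inpatient", "primary",
                   sample(c(big$acsc_codes, "Z00.0"), 3, TRUE))
    f_small <- flag_preventable_hospitalization(enc, 1L, c(2002, 2004), small)
    f_big <- flag_preventable_hospitalization(enc, 1L, c(2002, 2004), big)
    if (f_small) expect_true(f_big)
  }
})

test_that("code sets round-trip through plain-text files", {
  codes <- default_code_sets()
  acsc_path <- tempfile(fileext = ".txt")
  elix_path <- tempfile(fileext = ".txt")
  write_code_sets(codes, acsc_path, elix_path)
  back <- read_code_sets(acsc_path, elix_path)
  expect_identical(back$acsc_codes, codes$acsc_codes)
  expect_identical(back$elixhauser_map, codes$elixhauser_map)
  ## packaged default files match the in-code defaults
  pk_acsc <- system.file("extdata", "codes", "acsc_codes.txt", package = "msmwave")
  pk_elix <- system.file("extdata", "codes", "elixhauser_map.txt", package = "msmwave")
  packaged <- read_code_sets(pk_acsc, pk_elix)
  expect_identical(packaged$acsc_codes, codes$acsc_codes)
  expect_identical(packaged$elixhauser_map, codes$elixhauser_map)
})

test_that("overlapping category codes are rejected", {
  expect_error(code_sets("A1", list(x = c("B1", "B2"), y = "B2")), "disjoint")
  expect_error(code_sets(character(0), list(x = "B1")), "non-empty")
})
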