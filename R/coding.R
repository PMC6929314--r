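#' Elixhauser comorbidity index with the claims validity rule
#'
#' A comorbidity category counts toward the index if and only if, within the
#' lookback window ending at `assessment_year`, the subject has at least two
#' ambulatory encounters or at least one inpatient encounter carrying a
#' diagnosis code from that category. The rule is applied per category: a
#' single ambulatory mention of a condition never validates it, and two
#' single mentions of two different conditions validate neither.
#'
#' @param encounters encounter table (`subject_id`, `year`, `setting`
#'   (`ambulatory`/`inpatient`), `position` (`primary`/`secondary`), `code`).
#' @param subject subject id to assess.
#' @param assessment_year year at which the index is assessed.
#' @param lookback_years window length; encounters in
#'   `[assessment_year - lookback_years + 1, assessment_year]` are counted.
#' @param codes a [code_sets] object.
#' @return list of class `eci_result`: `subject_id`, `assessment_year`,
#'   `index` (count of validated categories), `category_3level`
#'   (`"0"`, `"1-3"`, `">=4"`), `positive_flag`.
#' @export
compute_eci <- function(encounters, subject, assessment_year, lookback_years = 3,
                        codes = default_code_sets()) {
  tab <- eci_batch(encounters, assessment_year, lookback_years, codes,
                   subjects = subject)
  index <- if (nrow(tab)) tab$eci_index[1] else 0L
  structure(
    list(subject_id = subject, assessment_year = assessment_year,
         index = index, category_3level = eci_category(index),
         positive_flag = index > 0L),
    class = "eci_result"
  )
}

## Vectorised ECI for a whole cohort at one assessment year; returns a
## data.table (subject_id, eci_index) restricted to subjects with index > 0
## unless `subjects` is given, in which case all requested subjects appear.
eci_batch <- function(encounters, assessment_year, lookback_years, codes,
                      subjects = NULL) {
  enc <- as.data.table(encounters)
  lo <- assessment_year - lookback_years + 1
  code_map <- data.table(
    code = unlist(codes$elixhauser_map, use.names = FALSE),
    category = rep(names(codes$elixhauser_map), lengths(codes$elixhauser_map))
  )
  enc <- enc[year >= lo & year <= assessment_year]
  if (!is.null(subjects)) enc <- enc[subject_id %in% subjects]
  enc <- merge(enc, code_map, by = "code")
  if (nrow(enc)) {
    counts <- enc[, .(
      n_amb = sum(setting == "ambulatory"),
      n_inp = sum(setting == "inpatient")
    ), by = .(subject_id, category)]
    counts <- counts[n_amb >= 2L | n_inp >= 1L]
    out <- counts[, .(eci_index = .N), by = subject_id]
  } else {
    out <- data.table(subject_id = integer(0), eci_index = integer(0))
  }
  if (!is.null(subjects)) {
    out <- merge(data.table(subject_id = subjects), out,
                 by = "subject_id", all.x = TRUE)
    out[is.na(eci_index), eci_index := 0L]
  }
  out[]
}

#' Three-level comorbidity-index category
#'
#' Bins the integer index into the conventional reporting levels
#' `0`, `1-3`, and `>=4`.
#'
#' @param index non-negative integer vector.
#' @return character vector with levels `"0"`, `"1-3"`, `">=4"`.
#' @export
eci_category <- function(index) {
  if (any(is.na(index)) || any(index < 0)) {
    stop_invalid("eci_category: index must be non-negative")
  }
  ifelse(index == 0, "0", ifelse(index <= 3, "1-3", ">=4"))
}

#' Flag a preventable hospitalization from ACSC codes
#'
#' `TRUE` when any inpatient stay in the interval carries a primary diagnosis
#' from the ACSC code set; secondary diagnoses never trigger the flag. An
#' inpatient record set with no primary diagnosis in the interval raises a
#' warning and does not qualify.
#'
#' @param admissions encounter table (see [compute_eci]); only
#'   `setting == "inpatient"` rows are considered.
#' @param subject subject id.
#' @param interval length-2 numeric `c(first_year, last_year)`, inclusive.
#' @param codes a [code_sets] object.
#' @return logical scalar.
#' @export
flag_preventable_hospitalization <- function(admissions, subject, interval,
                                             codes = default_code_sets()) {
  adm <- as.data.table(admissions)
  adm <- adm[subject_id == subject & setting == "inpatient" &
               year >= interval[1] & year <= interval[2]]
  if (nrow(adm) && !any(adm$position == "primary")) {
    warning(sprintf("subject %s: inpatient records without a primary diagnosis in [%s, %s]",
                    subject, interval[1], interval[2]))
    return(FALSE)
  }
  any(adm$position == "primary" & adm$code %in% codes$acsc_codes)
}

## Vectorised ACSC flag: subjects with any qualifying admission in the window.
acsc_batch <- function(encounters, first_year, last_year, codes) {
  enc <- as.data.table(encounters)
  unique(enc[setting == "inpatient" & position == "primary" &
               year >= first_year & year <= last_year &
               code %in% codes$acsc_codes, subject_id])
}

#' @export
print.eci_result <- function(x, ...) {
  cat(sprintf("<eci_result> subject %s @ %d: index %d (%s)\n",
              x$subject_id, x$assessment_year, x$index, x$category_3level))
  invisible(x)
}
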