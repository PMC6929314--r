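#' Diagnosis code sets for outcome and comorbidity coding
#'
#' A `code_sets` object holds the ambulatory-care-sensitive-condition (ACSC)
#' code list used to flag preventable hospitalizations and a map from
#' comorbidity category name to its diagnosis codes used for the Elixhauser
#' comorbidity index. The package deliberately does not bundle the full
#' AHRQ/Elixhauser ICD catalogs; [default_code_sets()] returns a small
#' ICD-10-style toy set (11 ACSC codes, 6 comorbidity categories) and real
#' catalogs can be supplied as plain-text files via [read_code_sets()].
#'
#' @param acsc_codes character vector of diagnosis codes whose presence as an
#'   inpatient primary diagnosis marks a preventable hospitalization.
#' @param elixhauser_map named list of character vectors, one per comorbidity
#'   category.
#' @return object of class `code_sets`.
#' @export
code_sets <- function(acsc_codes, elixhauser_map) {
  acsc_codes <- unique(as.character(acsc_codes))
  if (length(acsc_codes) == 0) stop_invalid("code_sets: acsc_codes must be non-empty")
  if (length(elixhauser_map) == 0 || is.null(names(elixhauser_map)) ||
      any(names(elixhauser_map) == "")) {
    stop_invalid("code_sets: elixhauser_map must be a named list of code vectors")
  }
  elixhauser_map <- lapply(elixhauser_map, function(x) unique(as.character(x)))
  if (any(lengths(elixhauser_map) == 0)) {
    stop_invalid("code_sets: every comorbidity category needs at least one code")
  }
  all_codes <- unlist(elixhauser_map, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    stop_invalid("code_sets: comorbidity category code sets must be disjoint")
  }
  structure(list(acsc_codes = acsc_codes, elixhauser_map = elixhauser_map),
            class = "code_sets")
}

#' @rdname code_sets
#' @export
default_code_sets <- function() {
  code_sets(
    acsc_codes = c(
      "I10", "I50.9", "E11.9", "J18.9", "J44.1", "J45.9",
      "N39.0", "E10.1", "I20.9", "J81", "L03.9"
    ),
    elixhauser_map = list(
      chf        = c("I50.1", "I50.2"),
      diabetes   = c("E11.0", "E11.2"),
      copd       = c("J44.0", "J44.8"),
      renal      = c("N18.3", "N18.4"),
      arthritis  = c("M05.9", "M06.9"),
      depression = c("F32.0", "F32.1")
    )
  )
}

## codes used for noise encounters; deliberately outside both code sets
.other_codes <- c("Z00.0", "K21.0", "M54.5", "H52.1", "S62.6", "R51")

#' Read code sets from plain-text files
#'
#' The ACSC file lists one code per line. The comorbidity map file uses
#' `[category]` header lines followed by one code per line. Blank lines and
#' `#` comments are ignored.
#'
#' @param acsc_path path to the ACSC code list.
#' @param elix_path path to the comorbidity category map.
#' @return a `code_sets` object.
#' @export
read_code_sets <- function(acsc_path, elix_path) {
  clean <- function(x) {
    x <- trimws(sub("#.*$", "", x))
    x[nzchar(x)]
  }
  acsc <- clean(readLines(acsc_path))
  lines <- clean(readLines(elix_path))
  is_header <- grepl("^\\[.+\\]$", lines)
  if (!length(lines) || !is_header[1]) {
    stop_invalid("read_code_sets: comorbidity map must start with a [category] header")
  }
  cat_names <- gsub("^\\[|\\]$", "", lines[is_header])
  grp <- cumsum(is_header)
  elix <- split(lines[!is_header], factor(grp[!is_header], labels = cat_names))
  code_sets(acsc, elix)
}

#' @rdname read_code_sets
#' @param codes a `code_sets` object.
#' @export
write_code_sets <- function(codes, acsc_path, elix_path) {
  writeLines(codes$acsc_codes, acsc_path)
  out <- unlist(lapply(names(codes$elixhauser_map), function(nm) {
    c(sprintf("[%s]", nm), codes$elixhauser_map[[nm]])
  }))
  writeLines(out, elix_path)
  invisible(NULL)
}

#' @export
print.code_sets <- function(x, ...) {
  cat(sprintf("<code_sets> %d ACSC codes; %d comorbidity categories (%s)\n",
              length(x$acsc_codes), length(x$elixhauser_map),
              paste(names(x$elixhauser_map), collapse = ", ")))
  invisible(x)
}
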