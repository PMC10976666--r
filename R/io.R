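#' Read a patient-level cohort CSV
#'
#' Column dictionary (empty cells are missing): `admission_id`, `cluster_id`,
#' `age` (years), `sex` (`male`/`female`), `active_ulcer`, `bleed_3mo`,
#' `platelet` (x10^9/L), `inr`, `creatinine` (mg/dL) and/or `gfr`
#' (mL/min/m^2), `icu_ccu`, `cvc`, `rheumatic`, `cancer`, `los_days`,
#' `any_bleed`, `major_bleed`, `bleed_day`, `prophylaxis`
#' (`none`/`heparin`/`foot_pump`/`both`), and the eligibility flags `trauma`,
#' `surgery`, `pregnancy`, `on_anticoagulation`, `admitted_for_vte_or_bleed`.
#' Logical columns accept TRUE/FALSE or 0/1.
#'
#' @param path CSV file path
#' @return A cohort data frame with validated types.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  logical_cols <- c("active_ulcer", "bleed_3mo", "icu_ccu", "cvc", "rheumatic",
                    "cancer", "any_bleed", "major_bleed", "trauma", "surgery",
                    "pregnancy", "on_anticoagulation", "admitted_for_vte_or_bleed")
  for (v in intersect(logical_cols, names(raw)))
    raw[[v]] <- as.logical(raw[[v]])
  validate_cohort(raw)
  raw
}

#' Write a cohort (scored or not) to CSV
#'
#' @param cohort cohort data frame
#' @param path output path
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate the record-level invariants of a cohort
#'
#' Checks: `major_bleed` implies `any_bleed`; `bleed_day` present iff
#' `any_bleed` and non-negative; `age >= 0`; `platelet`/`inr`/`gfr` each
#' missing or strictly positive; sex levels.
#'
#' @param cohort cohort data frame
#' @return Invisibly TRUE; stops with a message on the first violation.
#' @export
validate_cohort <- function(cohort) {
  if (!all(cohort$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(cohort$age < 0, na.rm = TRUE)) stop("age must be >= 0")
  if (!is.null(cohort$major_bleed) && !is.null(cohort$any_bleed) &&
      any(cohort$major_bleed & !cohort$any_bleed))
    stop("major_bleed implies any_bleed")
  if (!is.null(cohort$bleed_day) && !is.null(cohort$any_bleed)) {
    if (any(cohort$any_bleed & is.na(cohort$bleed_day)))
      stop("bleed_day is required when any_bleed is TRUE")
    if (any(!cohort$any_bleed & !is.na(cohort$bleed_day)))
      stop("bleed_day must be absent when any_bleed is FALSE")
    if (any(cohort$bleed_day < 0, na.rm = TRUE)) stop("bleed_day must be >= 0")
  }
  for (v in c("platelet", "inr", "gfr")) {
    if (!is.null(cohort[[v]]) && any(cohort[[v]] <= 0, na.rm = TRUE))
      stop(v, " must be missing or strictly positive")
  }
  invisible(TRUE)
}

#' Read grouped risk-group counts
#'
#' The grouped-input mode: a small CSV with one row per risk group, columns
#' `group` (label or 1-11 index, ordered lowest risk first), `n`,
#' `events_any`, `events_major`. A bundled example from an external
#' validation cohort of 3,876 admissions ships with the package:
#' `system.file("extdata", "validation_grouped_counts.csv",
#' package = "improvebleed")`.
#'
#' @param path CSV path
#' @return data frame with validated counts.
#' @export
read_grouped_counts <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("group", "n", "events_any", "events_major")
  if (!all(req %in% names(g)))
    stop("grouped counts need columns: ", paste(req, collapse = ", "))
  if (any(g$n < 0 | g$events_any < 0 | g$events_major < 0))
    stop("counts must be >= 0")
  if (any(g$events_any > g$n) || any(g$events_major > g$events_any))
    stop("events must satisfy major <= any <= n per group")
  g
}
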