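#' IMPROVE bleeding score weight table
#'
#' The 13-item point system of the IMPROVE bleeding risk assessment model.
#' Items on the same underlying predictor (the two age bands, the two reduced
#' GFR bands) are mutually exclusive; every other item is a simple flag.
#'
#' @return A data frame with columns `item` (identifier), `label`
#'   (human-readable description) and `points`.
#' @export
#' @examples
#' improve_weights()
improve_weights <- function() {
  data.frame(
    item = c("gfr_30_59", "male", "age_40_84", "cancer", "rheumatic", "cvc",
             "icu_ccu", "gfr_lt_30", "inr_gt_1_5", "age_ge_85", "plt_lt_50",
             "bleed_3mo", "ulcer"),
    label = c("Moderate renal failure (GFR 30-59 mL/min/m^2)",
              "Male sex",
              "Age 40-84 years",
              "Current cancer",
              "Rheumatic disease",
              "Central venous catheter",
              "ICU/CCU admission",
              "Severe renal failure (GFR < 30 mL/min/m^2)",
              "Hepatic failure (INR > 1.5)",
              "Age >= 85 years",
              "Platelet count < 50 x 10^9/L",
              "Bleeding in the 3 months before admission",
              "Active gastroduodenal ulcer"),
    points = c(1, 1, 1.5, 2, 2, 2, 2.5, 2.5, 2.5, 3.5, 4, 4, 4.5),
    stringsAsFactors = FALSE
  )
}

# Scores are multiples of 0.5; half-point integer units (0..61) are used
# internally so band edges never suffer floating-point misclassification.
.half <- function(points) as.integer(round(points * 2))

# group bins in half-point units: lower edges of the 11 intervals
.group_breaks_half <- c(0L, 3L, 5L, 6L, 9L, 11L, 14L, 15L, 17L, 20L, 25L)
.group_midpoints <- c(0.5, 1.75, 2.5, 3.5, 4.75, 6, 7, 7.75, 9, 11, 12.5)
.group_labels <- c("0-1", "1.5-2", "2.5", "3-4", "4.5-5", "5.5-6.5", "7",
                   "7.5-8", "8.5-9.5", "10-12", ">=12.5")

#' Estimated glomerular filtration rate (Japanese equation)
#'
#' Computes eGFR as 194 x creatinine^-1.094 x age^-0.287, multiplied by
#' 0.739 for women. Creatinine must be in mg/dL (the equation's convention);
#' results are in mL/min/m^2.
#'
#' @param creatinine serum creatinine in mg/dL (strictly positive)
#' @param age age in years (>= 15)
#' @param sex `"male"` or `"female"` (vectorized, recycled)
#' @return Numeric vector of eGFR values.
#' @export
#' @examples
#' compute_egfr(1.0, 60, "male")
#' compute_egfr(1.0, 60, "female")
compute_egfr <- function(creatinine, age, sex) {
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  if (any(!is.finite(creatinine) | creatinine <= 0))
    stop("creatinine must be positive and finite (mg/dL)")
  if (any(!is.finite(age) | age < 15))
    stop("age must be >= 15 years for the eGFR equation")
  194 * creatinine^-1.094 * age^-0.287 * ifelse(sex == "female", 0.739, 1)
}

# per-item points for one set of vectorized predictors, in half-point units;
# returns a matrix with one column per weight-table item
.item_points_half <- function(age, sex, ulcer, bleed_3mo, platelet, inr, gfr,
                              icu_ccu, cvc, rheumatic, cancer) {
  cbind(
    gfr_30_59  = ifelse(gfr >= 30 & gfr < 60, 2L, 0L),
    male       = ifelse(sex == "male", 2L, 0L),
    age_40_84  = ifelse(age >= 40 & age < 85, 3L, 0L),
    cancer     = ifelse(cancer, 4L, 0L),
    rheumatic  = ifelse(rheumatic, 4L, 0L),
    cvc        = ifelse(cvc, 4L, 0L),
    icu_ccu    = ifelse(icu_ccu, 5L, 0L),
    gfr_lt_30  = ifelse(gfr < 30, 5L, 0L),
    inr_gt_1_5 = ifelse(inr > 1.5, 5L, 0L),
    age_ge_85  = ifelse(age >= 85, 7L, 0L),
    plt_lt_50  = ifelse(platelet < 50, 8L, 0L),
    bleed_3mo  = ifelse(bleed_3mo, 8L, 0L),
    ulcer      = ifelse(ulcer, 9L, 0L)
  )
}

#' Score a cohort with the IMPROVE bleeding point system
#'
#' Assigns per-item points exactly per the published weight table, totals the
#' score, and stratifies each admission into the 11-group and two-group
#' (low/high, threshold 7 points) schemes. When `gfr` is absent or `NA` and
#' `creatinine` is available, eGFR is computed with [compute_egfr()]; if both
#' are present, `gfr` wins.
#'
#' Band conventions (the published table prints closed ranges): GFR bands are
#' the partition \[0, 30) / \[30, 60) / \[60, Inf) scoring 2.5 / 1 / 0; age
#' bands \[0, 40) / \[40, 85) / \[85, Inf) scoring 0 / 1.5 / 3.5; INR scores
#' only when strictly > 1.5 and platelets only when strictly < 50.
#'
#' @param cohort data frame with columns `age`, `sex`, `active_ulcer`,
#'   `bleed_3mo`, `platelet`, `inr`, `gfr` and/or `creatinine`, `icu_ccu`,
#'   `cvc`, `rheumatic`, `cancer` (see [read_cohort_csv()] for the dictionary)
#' @param top_midpoint representative score for the open top group
#'   (">= 12.5"); default 12.5
#' @return The cohort with appended columns: one `pts_*` column per item,
#'   `total` (points), `group11` (ordinal 1-11), `midpoint`, and `high_risk`
#'   (logical, total >= 7).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' score_cohort(cohort)[, c("total", "group11", "midpoint", "high_risk")]
score_cohort <- function(cohort, top_midpoint = 12.5) {
  req <- c("age", "sex", "active_ulcer", "bleed_3mo", "platelet", "inr",
           "icu_ccu", "cvc", "rheumatic", "cancer")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "))

  gfr <- if ("gfr" %in% names(cohort)) cohort$gfr else rep(NA_real_, nrow(cohort))
  need_gfr <- is.na(gfr)
  if (any(need_gfr)) {
    if (!"creatinine" %in% names(cohort) || any(is.na(cohort$creatinine[need_gfr])))
      stop("gfr (or creatinine) is missing for ", sum(need_gfr),
           " admissions; impute first with impute_chained()")
    gfr[need_gfr] <- compute_egfr(cohort$creatinine[need_gfr],
                                  cohort$age[need_gfr], cohort$sex[need_gfr])
  }
  for (v in c("platelet", "inr")) {
    if (anyNA(cohort[[v]]))
      stop(v, " is missing for ", sum(is.na(cohort[[v]])),
           " admissions; impute first with impute_chained()")
  }
  if (anyNA(cohort$age)) stop("age must be known for every admission")

  items <- .item_points_half(cohort$age, cohort$sex, cohort$active_ulcer,
                             cohort$bleed_3mo, cohort$platelet, cohort$inr,
                             gfr, cohort$icu_ccu, cohort$cvc,
                             cohort$rheumatic, cohort$cancer)
  total_half <- as.integer(rowSums(items))
  grp <- assign_group11(total_half / 2, top_midpoint = top_midpoint)

  pts <- as.data.frame(items / 2)
  names(pts) <- paste0("pts_", colnames(items))
  out <- cbind(cohort, pts)
  out$total <- total_half / 2
  out$group11 <- grp$group
  out$midpoint <- grp$midpoint
  out$high_risk <- dichotomize(out$total) == "high"
  out
}

.check_score <- function(total) {
  half <- total * 2
  bad <- !is.finite(half) | half < 0 | half > 61 | abs(half - round(half)) > 1e-9
  if (any(bad))
    stop("invalid score(s): ", paste(utils::head(total[bad], 5), collapse = ", "),
         " (must be a multiple of 0.5 in [0, 30.5])")
  as.integer(round(half))
}

#' Assign the 11-group risk stratum for a total score
#'
#' Bins: 0-1, 1.5-2, 2.5, 3-4, 4.5-5, 5.5-6.5, 7, 7.5-8, 8.5-9.5, 10-12,
#' >= 12.5, with midpoints 0.5, 1.75, 2.5, 3.5, 4.75, 6, 7, 7.75, 9, 11 and a
#' configurable top-group midpoint.
#'
#' @param total vector of total scores (multiples of 0.5 in \[0, 30.5\])
#' @param top_midpoint representative score for the open ">= 12.5" group
#' @return data frame with columns `group` (1-11), `midpoint`, `label`.
#' @export
#' @examples
#' assign_group11(c(0, 6.5, 13))
assign_group11 <- function(total, top_midpoint = 12.5) {
  half <- .check_score(total)
  g <- findInterval(half, .group_breaks_half)
  mids <- .group_midpoints
  mids[11] <- top_midpoint
  data.frame(group = g, midpoint = mids[g], label = .group_labels[g],
             stringsAsFactors = FALSE)
}

#' Dichotomize total scores at the 7-point threshold
#'
#' @param total vector of total scores
#' @return factor with levels `low` (< 7) and `high` (>= 7).
#' @export
#' @examples
#' dichotomize(c(6.5, 7, 0))
dichotomize <- function(total) {
  half <- .check_score(total)
  factor(ifelse(half >= 14L, "high", "low"), levels = c("low", "high"))
}
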