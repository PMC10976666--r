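#' Specification of a synthetic validation cohort
#'
#' Describes the admission-level structure an external-validation run assumes:
#' marginal predictor prevalences, a score-conditional bleeding risk on the
#' logistic scale, length-of-stay distribution, lab missingness rates, and a
#' repeat-admission (cluster) fraction. Defaults emulate a tertiary-care
#' general-internal-medicine cohort of acutely ill medical inpatients: 53.6%
#' male, age bands 7.8% / 66.5% / 25.7% (< 40 / 40-84 / >= 85), active ulcer
#' 0.1%, recent bleeding 0.8%, platelets < 50 in 1.9%, INR > 1.5 in 3.3%,
#' GFR bands 15.8% / 29.0% / 54.0% (< 30 / 30-59 / >= 60), rheumatic disease
#' 1.8%, cancer 4.0%, CVC 14.6%, ICU/CCU 16.9%; missingness 2.4% (platelet),
#' 18.0% (INR), 2.8% (GFR); median length of stay 14 days; and a latent
#' outcome model `logit P(bleed) = alpha + beta * score` whose defaults give
#' an overall 14-day bleeding rate near 1.5%.
#'
#' @param n number of admissions (>= 1)
#' @param seed integer RNG seed; the generator is fully reproducible given it
#' @param p_male,p_ulcer,p_bleed3mo,p_plt_lt50,p_inr_gt15,p_rheumatic,p_cancer,p_cvc,p_icu
#'   marginal prevalences in \[0, 1\]
#' @param p_age,p_gfr length-3 band probability vectors (must each sum to 1):
#'   age < 40 / 40-84 / >= 85 and GFR < 30 / 30-59 / >= 60
#' @param icu_cvc_or odds ratio linking CVC use to ICU/CCU admission while
#'   preserving the marginal CVC prevalence (all other predictors are
#'   independent); default 4, reflecting that central lines are far more
#'   common in critical care
#' @param miss named missingness rates for `platelet`, `inr`, `gfr`
#' @param alpha,beta latent outcome-model intercept and slope (per point of
#'   total score); defaults -4.8 and 0.15
#' @param major_frac fraction of bleeds that are major (default 49/58)
#' @param los_meanlog,los_sdlog log-normal length-of-stay parameters
#'   (median `exp(los_meanlog)` = 14 days; `los_sdlog` = 0.9 reproduces an
#'   interquartile range close to 8-27 days); stays are floored at 3 days
#' @param repeat_frac fraction of admissions that are second admissions of an
#'   earlier patient (shared predictors, independent outcome); default 0.10
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n,
                        seed = 1L,
                        p_male = 0.536,
                        p_age = c(0.078, 0.665, 0.257),
                        p_ulcer = 0.001,
                        p_bleed3mo = 0.008,
                        p_plt_lt50 = 0.019,
                        p_inr_gt15 = 0.033,
                        p_gfr = c(611, 1125, 2031) / 3767,
                        p_rheumatic = 0.018,
                        p_cancer = 0.040,
                        p_cvc = 0.146,
                        p_icu = 0.169,
                        icu_cvc_or = 4,
                        miss = c(platelet = 0.024, inr = 0.180, gfr = 0.028),
                        alpha = -4.8,
                        beta = 0.15,
                        major_frac = 49 / 58,
                        los_meanlog = log(14),
                        los_sdlog = 0.9,
                        repeat_frac = 0.10) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("invalid spec: n must be a positive integer")
  probs <- c(p_male, p_ulcer, p_bleed3mo, p_plt_lt50, p_inr_gt15,
             p_rheumatic, p_cancer, p_cvc, p_icu, p_age, p_gfr, miss,
             repeat_frac, major_frac)
  if (any(!is.finite(probs) | probs < 0 | probs > 1))
    stop("invalid spec: all prevalences, rates and fractions must lie in [0, 1]")
  if (abs(sum(p_age) - 1) > 1e-8 || abs(sum(p_gfr) - 1) > 1e-8)
    stop("invalid spec: age and GFR band prevalences must each sum to 1")
  if (icu_cvc_or <= 0) stop("invalid spec: icu_cvc_or must be positive")
  spec <- list(n = as.integer(n), seed = as.integer(seed), p_male = p_male,
               p_age = p_age, p_ulcer = p_ulcer, p_bleed3mo = p_bleed3mo,
               p_plt_lt50 = p_plt_lt50, p_inr_gt15 = p_inr_gt15,
               p_gfr = p_gfr, p_rheumatic = p_rheumatic, p_cancer = p_cancer,
               p_cvc = p_cvc, p_icu = p_icu, icu_cvc_or = icu_cvc_or,
               miss = miss, alpha = alpha, beta = beta,
               major_frac = major_frac, los_meanlog = los_meanlog,
               los_sdlog = los_sdlog, repeat_frac = repeat_frac)
  class(spec) <- "cohort_spec"
  spec
}

# conditional P(cvc | icu) and P(cvc | !icu) matching the marginal prevalence
# and a target odds ratio
.cvc_conditionals <- function(p_cvc, p_icu, or) {
  if (p_cvc %in% c(0, 1) || abs(or - 1) < 1e-12)
    return(c(p1 = p_cvc, p0 = p_cvc))
  f <- function(p0) {
    p1 <- stats::plogis(stats::qlogis(p0) + log(or))
    p1 * p_icu + p0 * (1 - p_icu) - p_cvc
  }
  p0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(p1 = stats::plogis(stats::qlogis(p0) + log(or)), p0 = p0)
}

# inverse of the eGFR equation: creatinine giving the target gfr
.creatinine_from_gfr <- function(gfr, age, sex) {
  (gfr / (194 * age^-0.287 * ifelse(sex == "female", 0.739, 1)))^(-1 / 1.094)
}

#' Generate a synthetic cohort of admissions
#'
#' Draws complete admission records (no missing values) from a
#' [cohort_spec()]: predictor bands are drawn at their marginal prevalences
#' (with an optional ICU-CVC association), continuous labs are drawn within
#' their bands (log-normal shapes, band-truncated), creatinine is back-solved
#' from the drawn GFR through the eGFR equation, and the 14-day bleeding
#' outcome is Bernoulli with `plogis(alpha + beta * total_score)`. Event days
#' are uniform on 1-14 and stays are extended to cover the event day. A
#' configurable fraction of admissions are repeats of an earlier patient
#' (identical predictors, same `cluster_id`, independently drawn outcome and
#' stay), giving the cluster structure sandwich variance estimators need.
#'
#' The latent truth (per-admission true risk and the generating
#' `alpha`/`beta`) is attached as `attr(cohort, "truth")` so recovery tests
#' can compare estimates with what generated the data.
#'
#' @param spec a [cohort_spec()]
#' @return data frame with one row per admission: identifiers, predictors,
#'   labs, outcome flags, timing, prophylaxis and eligibility flags, plus the
#'   scored columns of [score_cohort()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 100, seed = 42))
#' mean(cohort$any_bleed)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, as.list(spec))
  set.seed(spec$seed)
  n <- spec$n

  n_rep <- round(spec$repeat_frac * n)
  n_base <- n - n_rep

  age_band <- sample.int(3, n_base, replace = TRUE, prob = spec$p_age)
  age <- c(sample(15:39, n_base, replace = TRUE),
           sample(40:84, n_base, replace = TRUE),
           sample(85:100, n_base, replace = TRUE))[(age_band - 1) * n_base + seq_len(n_base)]
  sex <- ifelse(stats::runif(n_base) < spec$p_male, "male", "female")
  icu <- stats::runif(n_base) < spec$p_icu
  pc <- .cvc_conditionals(spec$p_cvc, spec$p_icu, spec$icu_cvc_or)
  cvc <- stats::runif(n_base) < ifelse(icu, pc["p1"], pc["p0"])

  gfr_band <- sample.int(3, n_base, replace = TRUE, prob = spec$p_gfr)
  gfr <- ifelse(gfr_band == 1, stats::runif(n_base, 5, 30),
         ifelse(gfr_band == 2, stats::runif(n_base, 30, 60),
                60 + stats::rgamma(n_base, shape = 2, scale = 15)))
  creatinine <- .creatinine_from_gfr(gfr, age, sex)

  plt_low <- stats::runif(n_base) < spec$p_plt_lt50
  platelet <- ifelse(plt_low, stats::runif(n_base, 5, 50),
                     50 + stats::rlnorm(n_base, log(150), 0.5))
  inr_high <- stats::runif(n_base) < spec$p_inr_gt15
  inr <- ifelse(inr_high, 1.5 + stats::rexp(n_base, rate = 2),
                stats::runif(n_base, 0.8, 1.5))

  base <- data.frame(
    cluster_id = seq_len(n_base),
    age = age, sex = sex,
    active_ulcer = stats::runif(n_base) < spec$p_ulcer,
    bleed_3mo = stats::runif(n_base) < spec$p_bleed3mo,
    platelet = platelet, inr = inr, creatinine = creatinine, gfr = gfr,
    icu_ccu = icu, cvc = cvc,
    rheumatic = stats::runif(n_base) < spec$p_rheumatic,
    cancer = stats::runif(n_base) < spec$p_cancer,
    stringsAsFactors = FALSE
  )

  cohort <- base
  if (n_rep > 0) {
    idx <- sample.int(n_base, n_rep, replace = FALSE)
    cohort <- rbind(base, base[idx, , drop = FALSE])
  }
  cohort$admission_id <- sprintf("A%06d", seq_len(n))
  cohort <- score_cohort(cohort)

  p_true <- stats::plogis(spec$alpha + spec$beta * cohort$total)
  any_bleed <- stats::runif(n) < p_true
  bleed_day <- ifelse(any_bleed, sample(1:14, n, replace = TRUE), NA_integer_)
  major <- any_bleed & stats::runif(n) < spec$major_frac

  los <- pmax(3L, as.integer(round(stats::rlnorm(n, spec$los_meanlog, spec$los_sdlog))))
  los <- pmax(los, ifelse(any_bleed, bleed_day, 1L))

  cohort$any_bleed <- any_bleed
  cohort$major_bleed <- major
  cohort$bleed_day <- bleed_day
  cohort$los_days <- los
  cohort$prophylaxis <- sample(c("none", "heparin", "foot_pump", "both"), n,
                               replace = TRUE, prob = c(0.807, 0.054, 0.080, 0.059))
  for (flag in c("trauma", "surgery", "pregnancy", "on_anticoagulation",
                 "admitted_for_vte_or_bleed"))
    cohort[[flag]] <- FALSE
  rownames(cohort) <- NULL

  attr(cohort, "truth") <- list(alpha = spec$alpha, beta = spec$beta,
                                seed = spec$seed, p_true = p_true)
  cohort
}

#' Inject missingness into lab predictors
#'
#' Blanks `platelet`, `inr` and `gfr` (with `creatinine`, since one determines
#' the other) at the given rates, under MCAR or a MAR mechanism in which the
#' log-odds of missingness increase by `mar_coef` for ICU/CCU admissions while
#' preserving the marginal rate. The pre-deletion values and the mask are kept
#' in attributes `"miss_truth"` and `"miss_mask"` so imputation accuracy can
#' be checked against ground truth.
#'
#' @param cohort a complete cohort (e.g. from [generate_cohort()])
#' @param rates named vector of target missingness rates for `platelet`,
#'   `inr`, `gfr`
#' @param mechanism `"MCAR"` or `"MAR"`
#' @param mar_coef log-odds-ratio of missingness for ICU/CCU admissions under
#'   MAR (default 1)
#' @param seed optional RNG seed
#' @return The cohort with `NA`s inserted and attributes `"miss_mask"`
#'   (logical data frame) and `"miss_truth"` (deleted values).
#' @export
inject_missingness <- function(cohort,
                               rates = c(platelet = 0.024, inr = 0.180, gfr = 0.028),
                               mechanism = c("MCAR", "MAR"),
                               mar_coef = 1,
                               seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  vars <- intersect(names(rates), c("platelet", "inr", "gfr"))

  mask <- as.data.frame(matrix(FALSE, n, length(vars), dimnames = list(NULL, vars)))
  truth <- cohort[vars]
  for (v in vars) {
    r <- rates[[v]]
    if (r == 0) next
    if (mechanism == "MCAR") {
      p <- rep(r, n)
    } else {
      p_icu <- mean(cohort$icu_ccu)
      g0 <- stats::uniroot(function(g)
        mean(stats::plogis(g + mar_coef * cohort$icu_ccu)) - r,
        c(-30, 30), tol = 1e-12)$root
      p <- stats::plogis(g0 + mar_coef * cohort$icu_ccu)
    }
    mis <- stats::runif(n) < p
    mask[[v]] <- mis
    cohort[[v]][mis] <- NA
    if (v == "gfr" && "creatinine" %in% names(cohort))
      cohort$creatinine[mis] <- NA
  }
  attr(cohort, "miss_mask") <- mask
  attr(cohort, "miss_truth") <- truth
  cohort
}
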