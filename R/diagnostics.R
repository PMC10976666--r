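# outcome indicator at the horizon: bleed on or before `horizon` days.
# The binary (non-KM) reading is what the two-group counts use.
.event_at_horizon <- function(cohort, outcome = c("any", "major"), horizon = 14) {
  outcome <- match.arg(outcome)
  flag <- if (outcome == "any") cohort$any_bleed else cohort$major_bleed
  flag & !is.na(cohort$bleed_day) & cohort$bleed_day <= horizon
}

#' Two-by-two table of risk classification versus bleeding
#'
#' Cross-tabulates the dichotomized score (test positive = high risk) against
#' bleeding on or before the horizon. Either a scored cohort or the four
#' counts directly (grouped-input mode) may be supplied.
#'
#' @param cohort scored cohort (needs `high_risk`, outcome flags, `bleed_day`)
#' @param outcome `"any"` or `"major"`
#' @param horizon days from admission (default 14)
#' @param counts optional named vector/list with `tp`, `fp`, `fn`, `tn`
#'   overriding the cohort
#' @return Object of class `two_by_two` with fields `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' two_by_two(counts = c(tp = 15, fp = 580, fn = 43, tn = 3238))
two_by_two <- function(cohort = NULL, outcome = c("any", "major"),
                       horizon = 14, counts = NULL) {
  if (!is.null(counts)) {
    counts <- as.list(counts)
    t <- lapply(counts[c("tp", "fp", "fn", "tn")], as.numeric)
    if (any(vapply(t, function(x) length(x) != 1 || is.na(x) || x < 0, logical(1))))
      stop("counts must supply non-negative tp, fp, fn, tn")
  } else {
    if (is.null(cohort$high_risk)) stop("cohort must be scored (see score_cohort)")
    ev <- .event_at_horizon(cohort, outcome, horizon)
    hr <- cohort$high_risk
    t <- list(tp = sum(hr & ev), fp = sum(hr & !ev),
              fn = sum(!hr & ev), tn = sum(!hr & !ev))
  }
  structure(t, class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("high risk", "low risk"),
                              bleeding = c("yes", "no")))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact confidence interval for a proportion
#'
#' @param x number of successes
#' @param n number of trials
#' @param conf confidence level
#' @return Named vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

.prop_ci <- function(x, n, conf) {
  if (n == 0)
    return(list(estimate = NA_real_, ci = c(lower = NA_real_, upper = NA_real_),
                note = "undefined: zero denominator"))
  list(estimate = x / n, ci = clopper_pearson(x, n, conf), note = NULL)
}

#' Diagnostic accuracy of the two-risk-group classification
#'
#' Sensitivity, specificity, PPV and NPV with Clopper-Pearson exact
#' confidence intervals, the odds ratio (with Woolf log-scale CI and Wald
#' p-value), and per-group event rates. Metrics with a zero denominator are
#' reported as `NA` with an explanatory note rather than an error.
#'
#' @param t a [two_by_two()] table
#' @param conf confidence level
#' @return Object of class `diagnostic_summary`.
#' @export
#' @examples
#' diagnostic_metrics(two_by_two(counts = c(tp = 15, fp = 580, fn = 43, tn = 3238)))
diagnostic_metrics <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  res <- list(
    sensitivity = .prop_ci(t$tp, t$tp + t$fn, conf),
    specificity = .prop_ci(t$tn, t$tn + t$fp, conf),
    ppv = .prop_ci(t$tp, t$tp + t$fp, conf),
    npv = .prop_ci(t$tn, t$tn + t$fn, conf),
    event_rate_high = .prop_ci(t$tp, t$tp + t$fp, conf),
    event_rate_low = .prop_ci(t$fn, t$fn + t$tn, conf)
  )
  if (min(t$tp, t$fp, t$fn, t$tn) > 0) {
    lor <- log(t$tp) + log(t$tn) - log(t$fp) - log(t$fn)
    se <- sqrt(1 / t$tp + 1 / t$fp + 1 / t$fn + 1 / t$tn)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    res$odds_ratio <- list(
      estimate = exp(lor),
      ci = c(lower = exp(lor - z * se), upper = exp(lor + z * se)),
      p_value = 2 * stats::pnorm(-abs(lor / se)))
  } else {
    res$odds_ratio <- list(estimate = NA_real_,
                           ci = c(lower = NA_real_, upper = NA_real_),
                           p_value = NA_real_,
                           note = "undefined: zero cell in the 2x2 table")
  }
  res$table <- t
  res$conf <- conf
  class(res) <- "diagnostic_summary"
  res
}

#' @export
print.diagnostic_summary <- function(x, digits = 1, ...) {
  pct <- function(p) format(round(100 * p, digits), nsmall = digits)
  for (nm in c("sensitivity", "specificity", "npv", "ppv")) {
    e <- x[[nm]]
    if (is.na(e$estimate)) {
      cat(sprintf("%-12s undefined (%s)\n", nm, e$note))
    } else {
      cat(sprintf("%-12s %s%% (%s%% CI: %s-%s%%)\n", nm, pct(e$estimate),
                  format(100 * x$conf), pct(e$ci[1]), pct(e$ci[2])))
    }
  }
  o <- x$odds_ratio
  if (!is.na(o$estimate))
    cat(sprintf("odds ratio   %.2f (%.2f-%.2f), P = %.3f\n",
                o$estimate, o$ci[1], o$ci[2], o$p_value))
  invisible(x)
}

#' Odds ratio of bleeding for high versus low risk, cluster-robust
#'
#' Logistic regression of the horizon outcome on the high-risk indicator with
#' a cluster-robust sandwich variance over `cluster_id` (patients contributing
#' several admissions). With all-singleton clusters this reduces to the
#' ordinary heteroskedasticity-robust (HC0-type) variance. Separation is
#' flagged and the CI reported as unbounded.
#'
#' @param cohort scored cohort with `cluster_id`
#' @param outcome,horizon as in [two_by_two()]
#' @param conf confidence level
#' @return list with `or`, `ci`, `p_value`, `se_log_or`, `separation`.
#' @export
odds_ratio_cluster_robust <- function(cohort, outcome = c("any", "major"),
                                      horizon = 14, conf = 0.95) {
  ev <- .event_at_horizon(cohort, outcome, horizon)
  dat <- data.frame(y = ev, hr = cohort$high_risk)
  fit <- suppressWarnings(stats::glm(y ~ hr, family = stats::binomial(), data = dat))
  co <- stats::coef(fit)["hrTRUE"]
  separation <- !fit$converged || abs(co) > 15
  # cadjust = FALSE so the estimator reduces exactly to the ordinary HC0
  # sandwich when every cluster is a singleton
  V <- sandwich::vcovCL(fit, cluster = cohort$cluster_id, type = "HC0",
                        cadjust = FALSE)
  se <- sqrt(V["hrTRUE", "hrTRUE"])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (separation) {
    ci <- c(lower = 0, upper = Inf)
    p <- NA_real_
  } else {
    ci <- c(lower = exp(co - z * se), upper = exp(co + z * se))
    p <- 2 * stats::pnorm(-abs(co / se))
  }
  list(or = unname(exp(co)), ci = ci, p_value = unname(p),
       se_log_or = unname(se), separation = separation)
}

#' Kaplan-Meier cumulative incidence of bleeding by a horizon
#'
#' Product-limit estimate of the cumulative bleeding incidence (1 - survival)
#' over days 0 to `horizon`. By default, admissions discharged before the
#' horizon without bleeding are censored at discharge
#' (`censor = "discharge"`); `censor = "administrative"` instead carries every
#' bleeding-free admission to the horizon. Events after the horizon count as
#' non-events by the horizon.
#'
#' @param cohort cohort with outcome flags, `bleed_day`, `los_days`
#' @param outcome `"any"` or `"major"`
#' @param horizon days (default 14)
#' @param censor censoring rule for early discharges
#' @param conf confidence level
#' @return Object of class `km_estimate`: `time` (0:horizon grid),
#'   `incidence`, `ci` (matrix), `at_risk`, `incidence_at_horizon`, plus the
#'   underlying `survival::survfit` object.
#' @export
km_cumulative_incidence <- function(cohort, outcome = c("any", "major"),
                                    horizon = 14,
                                    censor = c("discharge", "administrative"),
                                    conf = 0.95) {
  censor <- match.arg(censor)
  ev <- .event_at_horizon(cohort, outcome, horizon)
  time <- ifelse(ev, cohort$bleed_day,
                 if (censor == "discharge") pmin(cohort$los_days, horizon)
                 else horizon)
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1, conf.int = conf)
  sm <- summary(fit, times = 0:horizon, extend = TRUE)
  out <- list(time = sm$time,
              incidence = 1 - sm$surv,
              ci = cbind(lower = 1 - sm$upper, upper = 1 - sm$lower),
              at_risk = sm$n.risk,
              incidence_at_horizon = 1 - sm$surv[length(sm$surv)],
              survfit = fit)
  class(out) <- "km_estimate"
  out
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier cumulative incidence at day %d: %.4g [%.4g, %.4g]\n",
              max(x$time), x$incidence_at_horizon,
              x$ci[nrow(x$ci), 1], x$ci[nrow(x$ci), 2]))
  invisible(x)
}
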