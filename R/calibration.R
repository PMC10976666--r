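#' Expected-risk table for risk groups
#'
#' Maps each risk group to an expected (predicted) event probability per
#' outcome. Probabilities must lie strictly inside (0, 1).
#'
#' @param group group identifiers (either the two-group labels `low`/`high`
#'   or the 11-group indices 1-11)
#' @param p_any,p_major expected probabilities per group
#' @param provenance `"derivation-study"`, `"user-supplied"` or `"updated"`
#' @return Object of class `expected_risk_table` (a data frame).
#' @export
expected_risk_table <- function(group, p_any, p_major = NULL,
                                provenance = "user-supplied") {
  probs <- c(p_any, p_major)
  if (any(!is.finite(probs) | probs <= 0 | probs >= 1))
    stop("expected probabilities must lie strictly in (0, 1)")
  out <- data.frame(group = group, p_any = p_any, stringsAsFactors = FALSE)
  if (!is.null(p_major)) out$p_major <- p_major
  attr(out, "provenance") <- provenance
  class(out) <- c("expected_risk_table", "data.frame")
  out
}

#' Derivation-study expected risks for the two-group scheme
#'
#' The originally reported expected 14-day bleeding risks for the low- and
#' high-risk groups: 1.5% / 7.9% for any bleeding and 0.4% / 4.1% for major
#' bleeding. The full 11-group derivation-study table is not shipped; supply
#' one via [expected_risk_table()] when available.
#'
#' @return An `expected_risk_table` with rows `low` and `high`.
#' @export
#' @examples
#' improve_expected_risks()
improve_expected_risks <- function() {
  expected_risk_table(group = c("low", "high"),
                      p_any = c(0.015, 0.079),
                      p_major = c(0.004, 0.041),
                      provenance = "derivation-study")
}

#' Per-admission expected probability and linear predictor
#'
#' Looks up each admission's risk group in an expected-risk table and returns
#' the expected probability and its logit (the linear predictor used by the
#' calibration measures).
#'
#' @param groups per-admission group identifiers matching `table$group`
#' @param table an [expected_risk_table()]
#' @param outcome `"any"` or `"major"`
#' @return data frame with columns `p_exp` and `lp`.
#' @export
#' @examples
#' expected_probs(c("low", "high", "low"), improve_expected_risks())
expected_probs <- function(groups, table, outcome = c("any", "major")) {
  outcome <- match.arg(outcome)
  col <- paste0("p_", outcome)
  if (!col %in% names(table)) stop("table has no expected risks for outcome ", outcome)
  idx <- match(as.character(groups), as.character(table$group))
  if (anyNA(idx)) {
    missing_groups <- unique(groups[is.na(idx)])
    stop("expected-risk table does not cover group(s): ",
         paste(missing_groups, collapse = ", "))
  }
  p <- table[[col]][idx]
  data.frame(p_exp = p, lp = stats::qlogis(p))
}

#' Expected/observed event ratio
#'
#' E = sum of expected probabilities, O = observed events; the confidence
#' interval is computed on the log scale with a Poisson-type standard error
#' `sqrt(1/O)` for the observed count.
#'
#' @param p_exp per-admission expected probabilities
#' @param y per-admission binary outcomes
#' @param conf confidence level
#' @return list with `E`, `O`, `ratio`, `ci`, `se_log`, `defined`.
#' @export
eo_ratio <- function(p_exp, y, conf = 0.95) {
  E <- sum(p_exp)
  O <- sum(y)
  if (O == 0)
    return(list(E = E, O = 0, ratio = NA_real_,
                ci = c(lower = NA_real_, upper = NA_real_),
                se_log = NA_real_, defined = FALSE))
  se <- sqrt(1 / O)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  r <- E / O
  list(E = E, O = O, ratio = r,
       ci = c(lower = r * exp(-z * se), upper = r * exp(z * se)),
       se_log = se, defined = TRUE)
}

#' Calibration-in-the-large and calibration slope
#'
#' CITL is the intercept of `logit P(y = 1) = alpha + offset(lp)`; the slope
#' is the coefficient of `lp` in `logit P(y = 1) = alpha + beta * lp`. Both
#' use cluster-robust sandwich standard errors when `cluster` is given.
#'
#' @param lp per-admission linear predictor (logit of expected risk)
#' @param y per-admission binary outcomes
#' @param cluster optional cluster (patient) identifiers
#' @param conf confidence level
#' @return list with components `citl` and `slope`, each holding `estimate`,
#'   `se`, `ci`; plus `converged`.
#' @export
citl_and_slope <- function(lp, y, cluster = NULL, conf = 0.95) {
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  dat <- data.frame(y = y, lp = lp)

  f1 <- suppressWarnings(stats::glm(y ~ 1 + offset(lp), family = stats::binomial(),
                                    data = dat))
  f2 <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial(), data = dat))
  vc <- function(fit) {
    if (is.null(cluster)) stats::vcov(fit)
    else sandwich::vcovCL(fit, cluster = cluster, type = "HC0", cadjust = FALSE)
  }
  citl <- unname(stats::coef(f1)[1])
  se1 <- sqrt(vc(f1)[1, 1])
  slope <- unname(stats::coef(f2)["lp"])
  se2 <- sqrt(vc(f2)["lp", "lp"])
  list(
    citl = list(estimate = citl, se = se1,
                ci = c(lower = citl - z * se1, upper = citl + z * se1)),
    slope = list(estimate = slope, se = se2,
                 ci = c(lower = slope - z * se2, upper = slope + z * se2)),
    converged = f1$converged && f2$converged
  )
}

#' Loess calibration curve
#'
#' Locally estimated scatterplot smoothing of the binary outcome on the
#' expected probability (span 0.75, degree 1), evaluated on a grid restricted
#' to the observed range of predictions — the smooth curve of a standard
#' calibration plot.
#'
#' @param p_exp per-admission expected probabilities
#' @param y per-admission binary outcomes
#' @param span,degree loess settings
#' @param grid number of evaluation points
#' @return data frame with `p_exp` and smoothed `p_obs`; attribute
#'   `"degenerate"` is TRUE when the predictions have no spread.
#' @export
loess_curve <- function(p_exp, y, span = 0.75, degree = 1, grid = 100) {
  if (length(y) < 50) stop("need at least 50 admissions for a stable smoother")
  rng <- range(p_exp)
  if (diff(rng) < .Machine$double.eps^0.5) {
    out <- data.frame(p_exp = rep(rng[1], 2), p_obs = rep(mean(y), 2))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::loess(y ~ p_exp, data = data.frame(p_exp = p_exp, y = as.numeric(y)),
                      span = span, degree = degree,
                      family = "gaussian")
  gx <- seq(rng[1], rng[2], length.out = grid)
  out <- data.frame(p_exp = gx, p_obs = stats::predict(fit, newdata = data.frame(p_exp = gx)))
  attr(out, "degenerate") <- FALSE
  out
}

#' Grouped observed-versus-expected table
#'
#' One row per 11-group: size, observed events and rate with Clopper-Pearson
#' exact CI, and the expected rate from the supplied table. Empty groups get
#' a row with n = 0.
#'
#' @param cohort scored cohort
#' @param table an [expected_risk_table()] keyed by 11-group index (or by
#'   `low`/`high`, in which case groups map through the 7-point threshold)
#' @param outcome,horizon,conf as elsewhere
#' @return data frame with columns `group`, `label`, `n`, `events`,
#'   `obs_rate`, `obs_lower`, `obs_upper`, `exp_rate`.
#' @export
grouped_obs_vs_exp <- function(cohort, table, outcome = c("any", "major"),
                               horizon = 14, conf = 0.95) {
  outcome <- match.arg(outcome)
  ev <- .event_at_horizon(cohort, outcome, horizon)
  g <- factor(cohort$group11, levels = 1:11)
  n <- as.vector(table(g))
  events <- as.vector(tapply(ev, g, sum, default = 0))
  ci <- t(vapply(seq_len(11), function(i) {
    if (n[i] == 0) c(NA_real_, NA_real_) else clopper_pearson(events[i], n[i], conf)
  }, numeric(2)))
  key <- if (all(as.character(table$group) %in% c("low", "high")))
    ifelse(1:11 >= 7, "high", "low") else as.character(1:11)
  exp_rate <- expected_probs(key, table, outcome)$p_exp
  data.frame(group = 1:11, label = .group_labels, n = n, events = events,
             obs_rate = ifelse(n > 0, events / n, NA_real_),
             obs_lower = ci[, 1], obs_upper = ci[, 2],
             exp_rate = exp_rate, stringsAsFactors = FALSE)
}

#' Update the model by logistic recalibration
#'
#' `intercept_slope` (default) refits `logit P(y = 1) = alpha + beta * score`
#' on the validation data — the standard logistic recalibration whose
#' in-sample re-evaluation necessarily gives E/O = 1, CITL = 0 and slope = 1
#' (maximum-likelihood score equations). `intercept_only` keeps the original
#' predictions and refits only the intercept with the original linear
#' predictor as offset, which restores E/O = 1 and CITL = 0 while leaving the
#' slope unchanged.
#'
#' @param total per-admission total scores
#' @param y per-admission binary outcomes
#' @param mode `"intercept_slope"` or `"intercept_only"`
#' @param lp original per-admission linear predictor (required for
#'   `intercept_only`)
#' @param top_midpoint representative score of the open top group, used to
#'   tabulate updated per-group risks
#' @param cluster optional cluster identifiers for robust SEs
#' @return Object of class `recalibration`: `mode`, `coef`, the `updated_table`
#'   (per-11-group expected risks, provenance `"updated"`), per-admission
#'   `lp_new`, and `summary` (in-sample [eo_ratio()] and [citl_and_slope()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 2000, seed = 7))
#' rec <- recalibrate(cohort$total, cohort$any_bleed)
#' rec$summary$citl_slope$citl$estimate   # ~0
recalibrate <- function(total, y, mode = c("intercept_slope", "intercept_only"),
                        lp = NULL, top_midpoint = 12.5, cluster = NULL) {
  mode <- match.arg(mode)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  mids <- .group_midpoints
  mids[11] <- top_midpoint

  if (mode == "intercept_slope") {
    fit <- stats::glm(y ~ total, family = stats::binomial(),
                      data = data.frame(y = y, total = total))
    cf <- stats::coef(fit)
    lp_new <- unname(cf[1] + cf[2] * total)
    p_group <- stats::plogis(cf[1] + cf[2] * mids)
  } else {
    if (is.null(lp))
      stop("intercept_only recalibration needs the original linear predictor lp")
    fit <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial(),
                      data = data.frame(y = y, lp = lp))
    cf <- stats::coef(fit)
    lp_new <- lp + unname(cf[1])
    # updated per-group risks: shift each group's original lp by the refit
    grp_lp <- tapply(lp, assign_group11(total, top_midpoint)$group, mean)
    p_group <- rep(NA_real_, 11)
    p_group[as.integer(names(grp_lp))] <- stats::plogis(grp_lp + unname(cf[1]))
  }
  updated <- data.frame(group = 1:11, p = p_group)
  names(updated)[2] <- "p_any"
  attr(updated, "provenance") <- "updated"
  class(updated) <- c("expected_risk_table", "data.frame")

  out <- list(mode = mode, coef = cf, model = fit, lp_new = lp_new,
              updated_table = updated,
              summary = list(
                eo = eo_ratio(stats::plogis(lp_new), y),
                citl_slope = citl_and_slope(lp_new, y, cluster = cluster)))
  class(out) <- "recalibration"
  out
}

#' @export
print.recalibration <- function(x, ...) {
  cs <- x$summary$citl_slope
  cat(sprintf("Logistic recalibration (%s): E/O = %.3f, CITL = %.4f, slope = %.4f\n",
              x$mode, x$summary$eo$ratio, cs$citl$estimate, cs$slope$estimate))
  invisible(x)
}
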