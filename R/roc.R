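#' Grouped ordinal ROC data
#'
#' Event / non-event counts per ordered risk group (lowest risk first), the
#' input for empirical and binormal ROC analysis over the 11-group scheme.
#'
#' @param events,nonevents non-negative integer vectors of equal length,
#'   ordered from lowest to highest risk group
#' @param labels optional group labels
#' @return Object of class `ordinal_roc_data` (a data frame).
#' @export
#' @examples
#' d <- ordinal_roc_data(events = c(1, 2, 5), nonevents = c(100, 60, 20))
ordinal_roc_data <- function(events, nonevents, labels = NULL) {
  if (length(events) != length(nonevents)) stop("count vectors differ in length")
  if (any(events < 0) || any(nonevents < 0)) stop("counts must be >= 0")
  out <- data.frame(group = seq_along(events),
                    label = if (is.null(labels)) as.character(seq_along(events)) else labels,
                    events = events, nonevents = nonevents,
                    stringsAsFactors = FALSE)
  class(out) <- c("ordinal_roc_data", "data.frame")
  out
}

#' Build grouped ROC data from a scored cohort
#'
#' @param cohort scored cohort (with `group11`)
#' @param outcome,horizon as in [two_by_two()]
#' @return An [ordinal_roc_data()] with one row per 11-group.
#' @export
cohort_roc_data <- function(cohort, outcome = c("any", "major"), horizon = 14) {
  ev <- .event_at_horizon(cohort, outcome, horizon)
  g <- factor(cohort$group11, levels = 1:11)
  ordinal_roc_data(events = as.vector(tapply(ev, g, sum, default = 0)),
                   nonevents = as.vector(tapply(!ev, g, sum, default = 0)),
                   labels = .group_labels)
}

#' Empirical ROC over ordered risk groups
#'
#' Operating points from classifying "group >= k" as positive, for every
#' threshold k, plus the trapezoidal AUC — identical to the grouped
#' Mann-Whitney statistic with tie correction (P(event group > non-event
#' group) + 0.5 P(tie)).
#'
#' @param data an [ordinal_roc_data()]
#' @return list with `points` (data frame of FPR/TPR, including (0,0) and
#'   (1,1)), `auc`, and `defined` (FALSE when either class is empty).
#' @export
empirical_roc <- function(data) {
  ne <- sum(data$nonevents)
  nev <- sum(data$events)
  if (ne == 0 || nev == 0) {
    return(list(points = NULL, auc = NA_real_, defined = FALSE))
  }
  # survivor proportions above each threshold (high risk last)
  tpr <- rev(cumsum(rev(data$events))) / nev
  fpr <- rev(cumsum(rev(data$nonevents))) / ne
  pts <- data.frame(fpr = c(1, fpr[-1], 0), tpr = c(1, tpr[-1], 0))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc, defined = TRUE)
}

# negative log-likelihood of the ordinal binormal (Dorfman-Alf) model.
# par = c(a, log b, t1, log diff(t)); non-events latent N(0,1), events
# N(a/b, 1/b) so P(cat <= k | event) = pnorm(b * t_k - a)
.binormal_nll <- function(par, events, nonevents) {
  K <- length(events)
  a <- par[1]
  b <- exp(par[2])
  t <- cumsum(c(par[3], exp(par[-(1:3)])))
  pn <- diff(c(0, stats::pnorm(t), 1))
  pe <- diff(c(0, stats::pnorm(b * t - a), 1))
  -sum(nonevents * log(pmax(pn, 1e-300))) - sum(events * log(pmax(pe, 1e-300)))
}

#' Binormal maximum-likelihood ROC fit on grouped ordinal data
#'
#' Fits the latent binormal model in which non-events follow N(0, 1) and
#' events N(a/b, 1/b) on an unobserved scale cut at K-1 thresholds, by
#' maximizing the two-sample multinomial likelihood (the classical
#' ordinal-rating ML formulation). `a` is the standardized mean separation
#' and `b` the non-event/event SD ratio, so AUC = pnorm(a / sqrt(1 + b^2)).
#' Standard errors come from the observed information at the optimum and the
#' AUC interval from the delta method.
#'
#' Groups with zero total count are dropped (they cannot anchor a
#' threshold); at least 3 informative groups are required.
#'
#' @param data an [ordinal_roc_data()]
#' @param conf confidence level for the AUC interval
#' @return Object of class `binormal_fit`: `a`, `b`, `thresholds`, `auc`,
#'   `auc_se`, `auc_ci`, `loglik`, `converged`, `vcov` (for `(a, log b)`),
#'   `curve` (function mapping FPR to fitted TPR).
#' @export
#' @examples
#' d <- ordinal_roc_data(events = c(2, 5, 9, 20), nonevents = c(50, 40, 30, 10))
#' fit_binormal_ml(d)
fit_binormal_ml <- function(data, conf = 0.95) {
  keep <- data$events + data$nonevents > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " empty group(s)")
    data <- data[keep, ]
  }
  K <- nrow(data)
  if (K < 3) stop("need at least 3 informative groups for the binormal fit")
  ne <- sum(data$nonevents)
  nev <- sum(data$events)
  if (ne == 0 || nev == 0) stop("need events and non-events to fit")

  # starting values: probit of smoothed empirical cumulative proportions
  cn <- cumsum(data$nonevents + 0.5) / (ne + 0.5 * K)
  ce <- cumsum(data$events + 0.5) / (nev + 0.5 * K)
  t0 <- stats::qnorm(pmin(pmax(cn[-K], 1e-4), 1 - 1e-4))
  ze <- stats::qnorm(pmin(pmax(ce[-K], 1e-4), 1 - 1e-4))
  sl <- stats::coef(stats::lm(ze ~ t0))
  b0 <- max(unname(sl[2]), 0.2)
  a0 <- -unname(sl[1])
  t0 <- sort(t0 + seq_along(t0) * 1e-6) # enforce strict increase
  par0 <- c(a0, log(b0), t0[1], log(pmax(diff(t0), 1e-4)))

  opt <- stats::optim(par0, .binormal_nll, events = data$events,
                      nonevents = data$nonevents, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  a <- opt$par[1]
  b <- exp(opt$par[2])
  thresholds <- cumsum(c(opt$par[3], exp(opt$par[-(1:3)])))
  converged <- opt$convergence == 0

  vc <- tryCatch(solve(opt$hessian)[1:2, 1:2], error = function(e) matrix(NA, 2, 2))
  auc <- stats::pnorm(a / sqrt(1 + b^2))
  u <- a / sqrt(1 + b^2)
  # gradient of AUC wrt (a, log b)
  g <- c(stats::dnorm(u) / sqrt(1 + b^2),
         stats::dnorm(u) * a * (-b^2) * (1 + b^2)^(-3 / 2))
  auc_var <- drop(t(g) %*% vc %*% g)
  auc_se <- if (is.finite(auc_var) && auc_var >= 0) sqrt(auc_var) else NA_real_
  z <- stats::qnorm(1 - (1 - conf) / 2)
  auc_ci <- if (is.na(auc_se)) c(NA_real_, NA_real_)
            else c(max(0, auc - z * auc_se), min(1, auc + z * auc_se))

  out <- list(a = a, b = b, thresholds = thresholds, auc = auc,
              auc_se = auc_se, auc_ci = auc_ci, loglik = -opt$value,
              converged = converged, vcov = vc,
              curve = function(fpr) stats::pnorm(a + b * stats::qnorm(fpr)))
  class(out) <- "binormal_fit"
  out
}

#' @export
print.binormal_fit <- function(x, ...) {
  cat(sprintf("Binormal ROC fit: a = %.3f, b = %.3f, AUC = %.3f [%.3f, %.3f]%s\n",
              x$a, x$b, x$auc, x$auc_ci[1], x$auc_ci[2],
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Pool C statistics across imputations
#'
#' Rubin pooling of per-imputation binormal AUCs on the logit scale
#' (delegating to [pool_rubin()]); non-converged fits are excluded with a
#' warning.
#'
#' @param fits list of [fit_binormal_ml()] results
#' @param conf confidence level
#' @return A [pool_rubin()] `pooled_estimate` for the AUC.
#' @export
pooled_c_statistic <- function(fits, conf = 0.95) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$auc_se),
               logical(1))
  if (any(!ok)) warning("excluding ", sum(!ok), " non-converged fit(s)")
  fits <- fits[ok]
  if (length(fits) < 1) stop("no converged fits to pool")
  est <- vapply(fits, `[[`, numeric(1), "auc")
  var <- vapply(fits, function(f) f$auc_se^2, numeric(1))
  pool_rubin(est, var, scale = "logit", conf = conf)
}
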