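#' Apply the eligibility filter
#'
#' Retains admissions aged >= 15 years and hospitalized >= 3 days, excluding
#' trauma, surgery, pregnancy, anticoagulation at admission, and admissions
#' for VTE or bleeding. The tally counts each criterion separately (an
#' admission may trip several).
#'
#' @param cohort cohort data frame with eligibility fields
#' @return list with `cohort` (eligible rows) and `tally` (named integer
#'   vector of exclusions per criterion plus `excluded_total`).
#' @export
filter_eligibility <- function(cohort) {
  crit <- list(
    age_lt_15 = cohort$age < 15,
    los_lt_3 = cohort$los_days < 3,
    trauma = isTRUE_vec(cohort$trauma, nrow(cohort)),
    surgery = isTRUE_vec(cohort$surgery, nrow(cohort)),
    pregnancy = isTRUE_vec(cohort$pregnancy, nrow(cohort)),
    on_anticoagulation = isTRUE_vec(cohort$on_anticoagulation, nrow(cohort)),
    admitted_for_vte_or_bleed = isTRUE_vec(cohort$admitted_for_vte_or_bleed,
                                           nrow(cohort))
  )
  excl <- Reduce(`|`, crit)
  tally <- c(vapply(crit, sum, integer(1)), excluded_total = sum(excl))
  list(cohort = cohort[!excl, , drop = FALSE], tally = tally)
}

isTRUE_vec <- function(x, n) if (is.null(x)) rep(FALSE, n) else x %in% TRUE

# validation of one completed (no missing labs) scored cohort for one outcome
.validate_once <- function(scored, outcome, table, horizon, cluster) {
  ep <- expected_probs(ifelse(scored$high_risk, "high", "low"), table, outcome)
  if (!all(as.character(table$group) %in% c("low", "high")))
    ep <- expected_probs(scored$group11, table, outcome)
  t22 <- two_by_two(scored, outcome, horizon)
  diag <- diagnostic_metrics(t22)
  roc <- cohort_roc_data(scored, outcome, horizon)
  emp <- empirical_roc(roc)
  bin <- tryCatch(fit_binormal_ml(roc), error = function(e) NULL)
  y <- .event_at_horizon(scored, outcome, horizon)
  cs <- if (length(unique(y)) > 1)
    citl_and_slope(ep$lp, y, cluster = cluster) else NULL
  list(two_by_two = t22, diagnostics = diag, empirical = emp, binormal = bin,
       eo = eo_ratio(ep$p_exp, y), citl_slope = cs,
       km = km_cumulative_incidence(scored, outcome, horizon),
       events = sum(y))
}

#' Run the full external-validation pipeline
#'
#' End-to-end orchestration: ingest a cohort (patient-level data frame / CSV
#' path, a synthetic [cohort_spec()], or a grouped-counts CSV), filter
#' eligibility, score, impute missing labs (m chained-equation datasets),
#' compute the two-group diagnostics, ROC discrimination and calibration
#' measures per imputation, pool with Rubin's rules on the appropriate scales
#' (identity for CITL and slope, log for E/O, logit for proportions and C
#' statistics), recalibrate, and assemble a report bundle. Deterministic
#' given `seed`. A warning is raised when fewer than 100 events are observed
#' (below the recommended size for external validation of a binary-outcome
#' model).
#'
#' With grouped counts as input, only the two-group diagnostics and the
#' empirical/binormal ROC are computed (no admission-level data to impute or
#' recalibrate on).
#'
#' @param input a cohort data frame, a CSV path, a [cohort_spec()], or a
#'   grouped-counts data frame / CSV path (columns `group`, `n`,
#'   `events_any`, `events_major`)
#' @param m number of imputations when labs are missing (default 20)
#' @param seed RNG seed for imputation
#' @param expected an [expected_risk_table()]; default the derivation-study
#'   two-group risks
#' @param mode recalibration mode, see [recalibrate()]
#' @param outcomes outcomes to evaluate
#' @param horizon days (default 14)
#' @param outdir optional directory for report CSVs and the run manifest
#' @return Object of class `validation_report`.
#' @export
#' @examples
#' rep <- run_validation(cohort_spec(n = 500, seed = 3), m = 2)
#' rep$pooled$any$auc
run_validation <- function(input, m = 20, seed = 1L,
                           expected = improve_expected_risks(),
                           mode = c("intercept_slope", "intercept_only"),
                           outcomes = c("any", "major"), horizon = 14,
                           outdir = NULL) {
  mode <- match.arg(mode)
  outcomes <- match.arg(outcomes, several.ok = TRUE)

  if (is.character(input)) {
    header <- names(utils::read.csv(input, nrows = 1))
    input <- if (all(c("group", "n", "events_any") %in% header))
      read_grouped_counts(input) else read_cohort_csv(input)
  }
  if (is.data.frame(input) && all(c("group", "n", "events_any") %in% names(input)))
    return(.run_grouped(input, outcomes, outdir))
  cohort <- if (inherits(input, "cohort_spec")) generate_cohort(input) else input
  validate_cohort(cohort)

  flt <- filter_eligibility(cohort)
  cohort <- flt$cohort

  labs <- c("platelet", "inr", "gfr")
  has_missing <- any(vapply(labs, function(v)
    !is.null(cohort[[v]]) && anyNA(cohort[[v]]), logical(1)))
  imp <- if (has_missing) impute_chained(cohort, m = m, seed = seed)
         else list(m = 1, data = list(cohort))

  cluster <- cohort$cluster_id
  per_imp <- lapply(imp$data, function(d) {
    scored <- score_cohort(d)
    res <- lapply(outcomes, function(oc)
      .validate_once(scored, oc, expected, horizon, cluster))
    names(res) <- outcomes
    y_any <- .event_at_horizon(scored, "any", horizon)
    rec <- if (length(unique(y_any)) > 1)
      recalibrate(scored$total, y_any, mode = mode,
                  lp = expected_probs(ifelse(scored$high_risk, "high", "low"),
                                      expected, "any")$lp,
                  cluster = cluster) else NULL
    list(metrics = res, recal = rec, scored = scored)
  })

  pooled <- lapply(outcomes, function(oc) .pool_outcome(per_imp, oc, imp$m))
  names(pooled) <- outcomes

  n_events <- sum(.event_at_horizon(score_cohort(imp$data[[1]]), "any", horizon))
  if (n_events < 100)
    warning("only ", n_events, " events observed; below the recommended ",
            "100 events for external validation", call. = FALSE)

  out <- list(
    n = nrow(cohort), m = imp$m, seed = seed, exclusions = flt$tally,
    per_imputation = per_imp, pooled = pooled,
    recalibration = per_imp[[1]]$recal,
    scored = per_imp[[1]]$scored,
    manifest = list(package_version = as.character(utils::packageVersion("improvebleed")),
                    seed = seed, m = imp$m, mode = mode, horizon = horizon,
                    outcomes = outcomes, n = nrow(cohort),
                    expected_provenance = attr(expected, "provenance"))
  )
  class(out) <- "validation_report"
  if (!is.null(outdir)) .write_report(out, outdir)
  out
}

# pool one outcome's per-imputation metrics on the declared scales
.pool_outcome <- function(per_imp, oc, m) {
  get <- function(f) lapply(per_imp, function(x) f(x$metrics[[oc]]))
  num <- function(f) vapply(per_imp, function(x) f(x$metrics[[oc]]), numeric(1))

  pool_prop <- function(name, x_of, n_of) {
    xs <- num(x_of); ns <- num(n_of)
    if (any(ns == 0))
      return(list(estimate = NA_real_, note = "undefined: zero denominator"))
    est <- xs / ns
    # binomial variance with a continuity floor so boundary proportions pool
    v <- pmax(est * (1 - est), 0.25 / (mean(ns) + 1)) / ns
    pool_rubin(est, v, scale = "logit", n = round(mean(ns)))
  }
  res <- list(
    sensitivity = pool_prop("sens", function(t) t$two_by_two$tp,
                            function(t) t$two_by_two$tp + t$two_by_two$fn),
    specificity = pool_prop("spec", function(t) t$two_by_two$tn,
                            function(t) t$two_by_two$tn + t$two_by_two$fp),
    ppv = pool_prop("ppv", function(t) t$two_by_two$tp,
                    function(t) t$two_by_two$tp + t$two_by_two$fp),
    npv = pool_prop("npv", function(t) t$two_by_two$tn,
                    function(t) t$two_by_two$tn + t$two_by_two$fn)
  )
  bins <- get(function(t) t$binormal)
  bins <- Filter(Negate(is.null), bins)
  res$auc <- if (length(bins) >= 2) tryCatch(pooled_c_statistic(bins),
                                             error = function(e) NULL)
             else if (length(bins) == 1) bins[[1]]$auc else NULL
  eo_ok <- vapply(get(function(t) t$eo), function(e) isTRUE(e$defined), logical(1))
  if (all(eo_ok)) {
    est <- num(function(t) t$eo$ratio)
    v <- num(function(t) t$eo$se_log)^2 * est^2
    res$eo <- pool_rubin(est, v, scale = "log")
  }
  cs <- get(function(t) t$citl_slope)
  if (!any(vapply(cs, is.null, logical(1)))) {
    res$citl <- pool_rubin(vapply(cs, function(x) x$citl$estimate, numeric(1)),
                           vapply(cs, function(x) x$citl$se^2, numeric(1)),
                           scale = "identity")
    res$slope <- pool_rubin(vapply(cs, function(x) x$slope$estimate, numeric(1)),
                            vapply(cs, function(x) x$slope$se^2, numeric(1)),
                            scale = "identity")
  }
  res
}

.run_grouped <- function(g, outcomes, outdir) {
  res <- lapply(outcomes, function(oc) {
    ev <- if (oc == "any") g$events_any else g$events_major
    low <- as.integer(g$group) < 7L  # groups 1-6 are the low-risk stratum
    t22 <- two_by_two(counts = c(tp = sum(ev[!low]), fp = sum((g$n - ev)[!low]),
                                 fn = sum(ev[low]), tn = sum((g$n - ev)[low])))
    roc <- ordinal_roc_data(events = ev, nonevents = g$n - ev)
    list(two_by_two = t22, diagnostics = diagnostic_metrics(t22),
         empirical = empirical_roc(roc),
         binormal = tryCatch(fit_binormal_ml(roc), error = function(e) NULL))
  })
  names(res) <- outcomes
  out <- list(n = sum(g$n), m = 0, grouped = TRUE, pooled = res,
              manifest = list(mode = "grouped-counts", n = sum(g$n)))
  class(out) <- "validation_report"
  if (!is.null(outdir)) .write_report(out, outdir)
  out
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$scored))
    write_cohort_csv(report$scored, file.path(outdir, "scored_cohort.csv"))
  if (!is.null(report$recalibration)) {
    tab <- report$recalibration$updated_table
    utils::write.csv(tab, file.path(outdir, "updated_risk_table.csv"),
                     row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("External validation report (n =", x$n, ")\n")
  for (oc in names(x$pooled)) {
    p <- x$pooled[[oc]]
    cat("\n--", oc, "bleeding --\n")
    if (inherits(p$diagnostics, "diagnostic_summary")) print(p$diagnostics)
    if (!is.null(p$npv) && inherits(p$npv, "pooled_estimate")) {
      for (nm in c("sensitivity", "specificity", "npv", "ppv"))
        cat(sprintf("%-12s %.1f%% (%.1f-%.1f%%)\n", nm, 100 * p[[nm]]$estimate,
                    100 * p[[nm]]$ci[1], 100 * p[[nm]]$ci[2]))
    }
    if (inherits(p$auc, "pooled_estimate"))
      cat(sprintf("C statistic  %.3f (%.3f-%.3f)\n", p$auc$estimate,
                  p$auc$ci[1], p$auc$ci[2]))
    else if (inherits(p$binormal, "binormal_fit")) print(p$binormal)
    if (inherits(p$eo, "pooled_estimate"))
      cat(sprintf("E/O          %.2f (%.2f-%.2f)\n", p$eo$estimate,
                  p$eo$ci[1], p$eo$ci[2]))
    if (inherits(p$citl, "pooled_estimate"))
      cat(sprintf("CITL         %.2f (%.2f-%.2f)\n", p$citl$estimate,
                  p$citl$ci[1], p$citl$ci[2]))
    if (inherits(p$slope, "pooled_estimate"))
      cat(sprintf("slope        %.2f (%.2f-%.2f)\n", p$slope$estimate,
                  p$slope$ci[1], p$slope$ci[2]))
  }
  if (!is.null(x$recalibration)) print(x$recalibration)
  invisible(x)
}
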