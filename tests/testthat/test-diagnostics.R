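# two-group diagnostic accuracy, cluster-robust OR, Kaplan-Meier incidence

test_that("the printed two-group counts reproduce the reported accuracy", {
  any_tab <- two_by_two(counts = printed_two_group("any"))
  d <- diagnostic_metrics(any_tab)
  expect_equal(round_half_up(100 * d$ppv$estimate), 2.5)
  expect_equal(round_half_up(100 * d$npv$estimate), 98.7)
  expect_equal(round_half_up(100 * d$specificity$estimate), 84.8)
  expect_equal(round_half_up(100 * d$event_rate_low$estimate), 1.3)
  expect_equal(round_half_up(100 * d$event_rate_high$estimate), 2.5)

  maj <- diagnostic_metrics(two_by_two(counts = printed_two_group("major")))
  expect_equal(round_half_up(100 * maj$npv$estimate), 99.0)
  expect_equal(round_half_up(100 * maj$ppv$estimate), 2.5)
  expect_equal(round_half_up(100 * maj$event_rate_low$estimate), 1.0)

  # low-risk fraction of the cohort
  t <- any_tab
  expect_equal(round_half_up(100 * (t$fn + t$tn) / (t$tp + t$fp + t$fn + t$tn)),
               84.6)
})

test_that("proportions and exact CIs agree with brute-force enumeration", {
  set.seed(41)
  for (i in 1:20) {
    t <- two_by_two(counts = c(tp = rpois(1, 20) + 1, fp = rpois(1, 50) + 1,
                               fn = rpois(1, 10) + 1, tn = rpois(1, 200) + 1))
    d <- diagnostic_metrics(t)
    expect_equal(d$sensitivity$estimate, t$tp / (t$tp + t$fn))
    expect_equal(d$specificity$estimate, t$tn / (t$tn + t$fp))
    expect_equal(d$ppv$estimate, t$tp / (t$tp + t$fp))
    expect_equal(d$npv$estimate, t$tn / (t$tn + t$fn))
    expect_equal(d$odds_ratio$estimate, t$tp * t$tn / (t$fp * t$fn))
    # Clopper-Pearson against the binom.test oracle
    bt <- binom.test(t$tp, t$tp + t$fn)$conf.int
    expect_equal(unname(d$sensitivity$ci), as.vector(bt), tolerance = 1e-9)
  }
})

test_that("degenerate tables are handled: perfection, emptiness, zero cells", {
  perf <- diagnostic_metrics(two_by_two(counts = c(tp = 10, fp = 0, fn = 0, tn = 90)))
  for (nm in c("sensitivity", "specificity", "ppv", "npv"))
    expect_equal(perf[[nm]]$estimate, 1)
  expect_match(perf$odds_ratio$note, "zero cell")

  empty <- two_by_two(data.frame(high_risk = logical(0), any_bleed = logical(0),
                                 major_bleed = logical(0), bleed_day = integer(0)))
  expect_equal(unlist(empty[c("tp", "fp", "fn", "tn")]), c(tp = 0, fp = 0, fn = 0, tn = 0))
  d0 <- diagnostic_metrics(empty)
  expect_true(is.na(d0$sensitivity$estimate))
  expect_match(d0$sensitivity$note, "zero denominator")
  expect_error(two_by_two(counts = c(tp = -1, fp = 0, fn = 0, tn = 0)), "non-negative")
})

test_that("exact CIs shrink with n at a fixed proportion and cover the point", {
  widths <- vapply(c(50, 500, 5000), function(n) {
    ci <- clopper_pearson(round(0.1 * n), n)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  ci <- clopper_pearson(3, 30)
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
})

test_that("cluster-robust OR reduces to the plain sandwich for singletons and
           survives duplication", {
  co <- generate_cohort(cohort_spec(n = 4000, seed = 51, repeat_frac = 0))
  res <- odds_ratio_cluster_robust(co)
  ev <- co$any_bleed & !is.na(co$bleed_day) & co$bleed_day <= 14
  fit <- glm(ev ~ co$high_risk, family = binomial())
  se_hc <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))[2]
  expect_equal(res$se_log_or, unname(se_hc), tolerance = 1e-8)

  # duplicating every admission into 2-admission clusters leaves the OR
  # unchanged and the clustered SE equal to the original independence SE
  dup <- rbind(co, co)
  dup$cluster_id <- rep(co$cluster_id, 2)
  res2 <- odds_ratio_cluster_robust(dup)
  expect_equal(res2$or, res$or, tolerance = 1e-8)
  expect_equal(res2$se_log_or, res$se_log_or, tolerance = 1e-6)

  # score-independent risk: OR compatible with 1
  flat <- generate_cohort(cohort_spec(n = 30000, seed = 52, alpha = -4, beta = 0))
  r0 <- odds_ratio_cluster_robust(flat)
  expect_lt(abs(log(r0$or)), 3 * r0$se_log_or)
})

test_that("Kaplan-Meier incidence matches hand computation and KM identities", {
  # staggered 10-admission cohort, hand-computed product limit:
  # day 2 event with 9 at risk, day 5 event with 7 at risk
  # S(14) = (8/9) * (6/7), incidence = 5/21
  hand <- data.frame(
    any_bleed = c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 6)),
    major_bleed = FALSE,
    bleed_day = c(2, NA, NA, 5, rep(NA, 6)),
    los_days = c(2, 1, 3, 5, 5, rep(20, 5))
  )
  km <- km_cumulative_incidence(hand)
  expect_equal(km$incidence_at_horizon, 5 / 21, tolerance = 1e-12)
  expect_equal(km$incidence[1], 0)          # incidence at day 0 is 0
  expect_true(all(diff(km$incidence) >= 0)) # nondecreasing

  # no censoring before the horizon: KM equals the simple event proportion
  co <- generate_cohort(cohort_spec(n = 3000, seed = 53))
  co$los_days <- pmax(co$los_days, 14)
  ev_prop <- mean(co$any_bleed & co$bleed_day <= 14)
  expect_equal(km_cumulative_incidence(co)$incidence_at_horizon, ev_prop,
               tolerance = 1e-12)

  # with censoring at discharge, KM incidence >= the naive proportion
  co2 <- generate_cohort(cohort_spec(n = 5000, seed = 54))
  km2 <- km_cumulative_incidence(co2)
  expect_gte(km2$incidence_at_horizon, mean(co2$any_bleed & co2$bleed_day <= 14))
  # administrative censoring reproduces the naive proportion
  km3 <- km_cumulative_incidence(co2, censor = "administrative")
  expect_equal(km3$incidence_at_horizon, mean(co2$any_bleed & co2$bleed_day <= 14),
               tolerance = 1e-12)

  # all censored at day 1, no events
  quiet <- data.frame(any_bleed = rep(FALSE, 5), major_bleed = FALSE,
                      bleed_day = NA_integer_, los_days = 1)
  expect_equal(km_cumulative_incidence(quiet)$incidence_at_horizon, 0)
})
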