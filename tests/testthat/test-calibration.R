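# calibration measures and logistic model updating

test_that("expected probabilities and linear predictors come from the table", {
  tab <- improve_expected_risks()
  ep <- expected_probs(c("low", "high", "low"), tab, "any")
  expect_equal(ep$p_exp, c(0.015, 0.079, 0.015))
  expect_equal(ep$lp, qlogis(c(0.015, 0.079, 0.015)))
  expect_equal(expected_probs("low", tab, "major")$p_exp, 0.004)
  # p = 0.5 maps to lp = 0
  t5 <- expected_risk_table("g", 0.5)
  expect_equal(expected_probs("g", t5, "any")$lp, 0)
  # a monotone table gives monotone linear predictors
  tm <- expected_risk_table(1:4, c(0.01, 0.02, 0.05, 0.2))
  expect_true(all(diff(expected_probs(1:4, tm, "any")$lp) > 0))
  expect_error(expected_probs("unknown", tab, "any"), "does not cover")
  expect_error(expected_risk_table("g", 1.2), "strictly in")
})

test_that("E/O on the printed two-group cohort matches the hand sum", {
  # 0.015 * 3281 + 0.079 * 595 = 96.22 expected vs 58 observed
  p_exp <- c(rep(0.015, 3281), rep(0.079, 595))
  y <- c(rep(TRUE, 43), rep(FALSE, 3281 - 43), rep(TRUE, 15), rep(FALSE, 595 - 15))
  r <- eo_ratio(p_exp, y)
  expect_equal(r$E, 96.22, tolerance = 1e-9)
  expect_equal(r$ratio, 96.22 / 58, tolerance = 1e-9)
  expect_true(r$ci[1] < r$ratio && r$ratio < r$ci[2])
  # predictions equal to the overall rate give E/O = 1
  r1 <- eo_ratio(rep(mean(y), length(y)), y)
  expect_equal(r1$ratio, 1, tolerance = 1e-12)
  # no observed events: ratio undefined but flagged, not an error
  r0 <- eo_ratio(c(0.1, 0.2), c(FALSE, FALSE))
  expect_false(r0$defined)
})

test_that("CITL/slope obey offset algebra and recover simulator truth", {
  co <- generate_cohort(cohort_spec(n = 50000, seed = 71))
  truth <- attr(co, "truth")
  lp_true <- qlogis(truth$p_true)
  y <- co$any_bleed

  cs <- citl_and_slope(lp_true, y)
  expect_lt(abs(cs$citl$estimate), 3 * cs$citl$se)
  expect_lt(abs(cs$slope$estimate - 1), 3 * cs$slope$se)

  # shifting every lp by +c moves citl by -c and leaves the slope unchanged
  cshift <- citl_and_slope(lp_true + 0.7, y)
  expect_equal(cshift$citl$estimate, cs$citl$estimate - 0.7, tolerance = 1e-6)
  expect_equal(cshift$slope$estimate, cs$slope$estimate, tolerance = 1e-8)

  # doubling the predicted odds drives citl to -log 2
  cdouble <- citl_and_slope(lp_true + log(2), y)
  expect_lt(abs(cdouble$citl$estimate + log(2)), 3 * cdouble$citl$se)

  expect_error(citl_and_slope(lp_true, rep(FALSE, length(y))), "both outcome")
})

test_that("loess calibration curves track the construction", {
  co <- generate_cohort(cohort_spec(n = 20000, seed = 72))
  p_true <- attr(co, "truth")$p_true
  y <- co$any_bleed

  # calibrated data: curve within a band around the diagonal
  cal <- loess_curve(p_true, y)
  expect_lt(max(abs(cal$p_obs - cal$p_exp), na.rm = TRUE), 0.05)

  # overprediction by doubled risk: curve below the diagonal throughout
  over <- loess_curve(pmin(2 * p_true, 0.99), y)
  mid <- over[over$p_exp > quantile(over$p_exp, 0.1) &
              over$p_exp < quantile(over$p_exp, 0.9), ]
  expect_true(all(mid$p_obs < mid$p_exp, na.rm = TRUE))

  # constant predictions: flat curve at the event rate
  flat <- loess_curve(rep(0.02, length(y)), y)
  expect_true(attr(flat, "degenerate"))
  expect_equal(unique(flat$p_obs), mean(y))
  expect_error(loess_curve(runif(10), rbinom(10, 1, 0.5)), "at least 50")
})

test_that("grouped observed-vs-expected rows are complete and consistent", {
  co <- generate_cohort(cohort_spec(n = 5000, seed = 73))
  tab <- grouped_obs_vs_exp(co, improve_expected_risks(), "any")
  expect_equal(nrow(tab), 11)
  expect_equal(sum(tab$n), nrow(co))
  expect_equal(sum(tab$events), sum(co$any_bleed & co$bleed_day <= 14))
  # groups 1-6 carry the low-risk expectation, 7-11 the high-risk one
  expect_equal(tab$exp_rate, c(rep(0.015, 6), rep(0.079, 5)))
  zero <- tab[tab$events == 0 & tab$n > 0, ]
  if (nrow(zero)) {
    expect_true(all(zero$obs_rate == 0))
    expect_true(all(zero$obs_lower == 0 & zero$obs_upper > 0))
  }
})

test_that("logistic recalibration is self-calibrating in-sample", {
  co <- generate_cohort(cohort_spec(n = 10000, seed = 74))
  y <- co$any_bleed

  rec <- recalibrate(co$total, y, mode = "intercept_slope")
  expect_equal(rec$summary$eo$ratio, 1, tolerance = 1e-6)
  expect_equal(rec$summary$citl_slope$citl$estimate, 0, tolerance = 1e-6)
  expect_equal(rec$summary$citl_slope$slope$estimate, 1, tolerance = 1e-6)
  # updated per-group risks increase with the group midpoint
  expect_true(all(diff(rec$updated_table$p_any) > 0))

  # intercept-only: E/O = 1 and CITL = 0, slope unchanged from the original
  lp0 <- expected_probs(ifelse(co$high_risk, "high", "low"),
                        improve_expected_risks(), "any")$lp
  rec0 <- recalibrate(co$total, y, mode = "intercept_only", lp = lp0)
  expect_equal(rec0$summary$eo$ratio, 1, tolerance = 1e-6)
  expect_equal(rec0$summary$citl_slope$citl$estimate, 0, tolerance = 1e-6)
  slope_before <- citl_and_slope(lp0, y)$slope$estimate
  expect_equal(rec0$summary$citl_slope$slope$estimate, slope_before,
               tolerance = 1e-6)

  # already-calibrated data: refit recovers the generating coefficients
  truth <- attr(co, "truth")
  ses <- sqrt(diag(vcov(rec$model)))
  expect_lt(abs(unname(rec$coef[1]) - truth$alpha), 3.5 * ses[1])
  expect_lt(abs(unname(rec$coef[2]) - truth$beta), 3.5 * ses[2])
})
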