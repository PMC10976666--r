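# scoring engine: eGFR equation, point assignment, grouping, dichotomization

test_that("eGFR follows the Japanese equation with the female factor applied once", {
  # frozen from direct evaluation of 194 * cr^-1.094 * age^-0.287 (* 0.739)
  expect_equal(compute_egfr(1.0, 60, "male"), 59.906276, tolerance = 1e-6)
  expect_equal(compute_egfr(1.0, 60, "female"), 44.270738, tolerance = 1e-6)
  # female/male ratio is exactly 0.739 for any inputs
  cr <- c(0.5, 1.3, 4); age <- c(20, 55, 90)
  expect_equal(compute_egfr(cr, age, "female") / compute_egfr(cr, age, "male"),
               rep(0.739, 3))
  expect_error(compute_egfr(0, 60, "male"), "positive")
  expect_error(compute_egfr(-1, 60, "male"), "positive")
  expect_error(compute_egfr(1, 10, "male"), "age")
})

base_record <- function(...) {
  r <- data.frame(age = 30, sex = "female", active_ulcer = FALSE,
                  bleed_3mo = FALSE, platelet = 200, inr = 1.0, gfr = 70,
                  icu_ccu = FALSE, cvc = FALSE, rheumatic = FALSE,
                  cancer = FALSE, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) r[[nm]] <- mods[[nm]]
  r
}

test_that("point assignment matches the published weight table", {
  expect_equal(score_cohort(base_record())$total, 0)
  # male, 70 y, ICU, GFR 45: 1 + 1.5 + 2.5 + 1 = 6, low risk
  r <- score_cohort(base_record(sex = "male", age = 70, icu_ccu = TRUE, gfr = 45))
  expect_equal(r$total, 6)
  expect_false(r$high_risk)
  # maximum attainable: every factor at its worst band
  mx <- score_cohort(base_record(sex = "male", age = 86, active_ulcer = TRUE,
                                 bleed_3mo = TRUE, platelet = 30, inr = 2,
                                 gfr = 20, icu_ccu = TRUE, cvc = TRUE,
                                 rheumatic = TRUE, cancer = TRUE))
  expect_equal(mx$total, 30.5)
  expect_equal(mx$group11, 11)
})

test_that("band boundaries follow the partition convention strictly", {
  gfr_pts <- function(g) score_cohort(base_record(gfr = g))$pts_gfr_30_59 +
    score_cohort(base_record(gfr = g))$pts_gfr_lt_30
  expect_equal(gfr_pts(60), 0)
  expect_equal(gfr_pts(59.999), 1)
  expect_equal(gfr_pts(30), 1)
  expect_equal(gfr_pts(29.999), 2.5)
  age_pts <- function(a) score_cohort(base_record(age = a))$total
  expect_equal(age_pts(39), 0)
  expect_equal(age_pts(40), 1.5)
  expect_equal(age_pts(84), 1.5)
  expect_equal(age_pts(85), 3.5)
  expect_equal(score_cohort(base_record(inr = 1.5))$pts_inr_gt_1_5, 0)
  expect_equal(score_cohort(base_record(inr = 1.5000001))$pts_inr_gt_1_5, 2.5)
  expect_equal(score_cohort(base_record(platelet = 50))$pts_plt_lt_50, 0)
  expect_equal(score_cohort(base_record(platelet = 49.9))$pts_plt_lt_50, 4)
})

test_that("scores agree with a brute-force 13-row weight-table summation", {
  cohort <- random_records(10000, seed = 202)
  scored <- score_cohort(cohort)
  expect_equal(scored$total, brute_force_scores(cohort))
  # total equals the sum of the item columns
  pts <- scored[, grep("^pts_", names(scored))]
  expect_equal(rowSums(pts), scored$total, ignore_attr = TRUE)
})

test_that("scoring is monotone in every risk factor", {
  cohort <- random_records(300, seed = 7)
  base <- score_cohort(cohort)$total
  flips <- list(active_ulcer = TRUE, bleed_3mo = TRUE, icu_ccu = TRUE,
                cvc = TRUE, rheumatic = TRUE, cancer = TRUE)
  for (nm in names(flips)) {
    mod <- cohort; mod[[nm]] <- TRUE
    expect_true(all(score_cohort(mod)$total >= base), label = nm)
  }
  worse <- cohort
  worse$gfr <- pmax(worse$gfr - 31, 1)
  worse$platelet <- pmin(worse$platelet, 49)
  worse$inr <- pmax(worse$inr, 1.6)
  worse$age <- pmin(worse$age + 45, 100)
  expect_true(all(score_cohort(worse)$total >= base))
})

test_that("group assignment, midpoints and the 7-point dichotomy agree", {
  expect_equal(assign_group11(0)$group, 1)
  expect_equal(assign_group11(0)$midpoint, 0.5)
  expect_equal(assign_group11(6.5)$group, 6)
  expect_equal(assign_group11(6.5)$midpoint, 6)
  expect_equal(assign_group11(13)$group, 11)
  expect_equal(assign_group11(13, top_midpoint = 14)$midpoint, 14)
  expect_error(assign_group11(31), "invalid score")
  expect_error(assign_group11(-0.5), "invalid score")
  expect_error(assign_group11(3.25), "invalid score")

  expect_equal(as.character(dichotomize(c(6.5, 7, 0))), c("low", "high", "low"))

  totals <- seq(0, 30.5, by = 0.5)
  g <- assign_group11(totals)$group
  expect_equal(g >= 7, as.character(dichotomize(totals)) == "high")
  # group midpoints are nondecreasing in the score
  expect_true(all(diff(assign_group11(totals)$midpoint) >= 0))
})

test_that("missing predictors raise an error directing to imputation", {
  r <- base_record(); r$platelet <- NA
  expect_error(score_cohort(r), "impute")
  r2 <- base_record(); r2$gfr <- NA
  expect_error(score_cohort(r2), "impute")
  # creatinine substitutes for a missing gfr
  r3 <- base_record(age = 60, sex = "male"); r3$gfr <- NA; r3$creatinine <- 1.0
  expect_equal(score_cohort(r3)$pts_gfr_30_59, 1)  # eGFR 59.9
})
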