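# shared oracles and fixtures, all built in code

# half-up rounding to `d` decimals, as printed reports round percentages
round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d

# brute-force grouped Mann-Whitney AUC (tie-corrected): independent of the
# package's trapezoid implementation
mw_auc_oracle <- function(events, nonevents) {
  num <- 0
  K <- length(events)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i > j) num <- num + events[i] * nonevents[j]
    if (i == j) num <- num + 0.5 * events[i] * nonevents[j]
  }
  num / (sum(events) * sum(nonevents))
}

# printed two-risk-group counts of the validation cohort (n = 3,876):
# 595 high risk, 58 any bleeds (15 high), 49 major bleeds (15 high)
printed_two_group <- function(outcome = c("any", "major")) {
  outcome <- match.arg(outcome)
  if (outcome == "any") c(tp = 15, fp = 580, fn = 43, tn = 3238)
  else c(tp = 15, fp = 580, fn = 34, tn = 3247)
}

# bundled 11-group counts
grouped_counts <- function() {
  read_grouped_counts(system.file("extdata", "validation_grouped_counts.csv",
                                  package = "improvebleed"))
}

# independent re-scoring from an explicit 13-row weight table
brute_force_scores <- function(cohort) {
  w <- c(1, 1, 1.5, 2, 2, 2, 2.5, 2.5, 2.5, 3.5, 4, 4, 4.5)
  ind <- cbind(
    cohort$gfr >= 30 & cohort$gfr < 60,
    cohort$sex == "male",
    cohort$age >= 40 & cohort$age < 85,
    cohort$cancer,
    cohort$rheumatic,
    cohort$cvc,
    cohort$icu_ccu,
    cohort$gfr < 30,
    cohort$inr > 1.5,
    cohort$age >= 85,
    cohort$platelet < 50,
    cohort$bleed_3mo,
    cohort$active_ulcer
  )
  as.vector(ind %*% w)
}

# random complete predictor records spanning all bands
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    age = sample(15:100, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    active_ulcer = runif(n) < 0.3,
    bleed_3mo = runif(n) < 0.3,
    platelet = runif(n, 10, 400),
    inr = runif(n, 0.8, 3),
    gfr = runif(n, 5, 120),
    icu_ccu = runif(n) < 0.3,
    cvc = runif(n) < 0.3,
    rheumatic = runif(n) < 0.3,
    cancer = runif(n) < 0.3,
    stringsAsFactors = FALSE
  )
}

# grouped ordinal counts simulated from the latent binormal model:
# non-events N(0,1), events N(a/b, 1/b), cut at the given thresholds
simulate_binormal_counts <- function(n_nonevents, n_events, a = 1, b = 1,
                                     thresholds = qnorm(seq(0.1, 0.9, 0.1)),
                                     seed = 1) {
  set.seed(seed)
  cuts <- c(-Inf, thresholds, Inf)
  ne <- table(cut(rnorm(n_nonevents), cuts))
  ev <- table(cut(rnorm(n_events, mean = a / b, sd = 1 / b), cuts))
  ordinal_roc_data(events = as.vector(ev), nonevents = as.vector(ne))
}
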