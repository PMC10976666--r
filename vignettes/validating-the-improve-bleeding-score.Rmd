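---
title: "Validating and updating the IMPROVE bleeding score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and updating the IMPROVE bleeding score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(improvebleed)
```

This vignette is the package's account of its statistical machinery: the
models behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic cohorts do and do not emulate, and the
design decisions that were genuinely open.

## The score and its conventions

The IMPROVE bleeding score is an additive 13-item point system
(`improve_weights()`), totalling 0 to 30.5 points, predicting clinically
relevant bleeding within 14 days of a medical admission. Two strata are in
use: eleven ordinal groups with representative midpoints (0–1 → 0.5,
1.5–2 → 1.75, …, ≥ 12.5 → top midpoint) and the dichotomy at 7 points.

Three conventions are worth stating because the published weight table
prints closed ranges and leaves the edges ambiguous:

* **GFR bands** are implemented as the partition [0, 30) → 2.5 points,
  [30, 60) → 1, [60, ∞) → 0. Whether a GFR of exactly 60 (or 30) belongs to
  the lower or upper band is not decidable from the printed table; the
  partition above is this package's documented choice.
* **Age bands**: [0, 40) → 0, [40, 85) → 1.5, [85, ∞) → 3.5.
* **Strict inequalities** for the labs: INR scores only when > 1.5;
  platelets only when < 50 × 10⁹/L.

Scores are held internally in half-point integer units (0–61) so band and
group boundaries can never be misclassified by floating-point noise. Renal
function uses the Japanese eGFR equation
`194 · Cr⁻¹·⁰⁹⁴ · age⁻⁰·²⁸⁷ (× 0.739 for women)` with creatinine strictly in
mg/dL; when both a measured GFR and creatinine are present the GFR wins.
The midpoint of the open top group ("≥ 12.5") is not defined by the source
table; the default is the conservative boundary value 12.5 and it is
configurable (`top_midpoint`).

## Synthetic cohorts: what they emulate

`generate_cohort()` is first-class, tested code, not a fixture. Its defaults
are the study conditions of a tertiary-care general-internal-medicine
validation cohort: the marginal predictor prevalences listed in
`?cohort_spec` (e.g. 16.9% ICU/CCU, 25.7% aged ≥ 85), lab missingness rates
of 2.4% (platelets), 18.0% (INR) and 2.8% (GFR), a log-normal length of stay
with median 14 days (σ = 0.9 on the log scale reproduces an IQR close to
8–27 days, floored at the 3-day eligibility minimum), and a latent outcome
model

> logit P(bleed ≤ 14 d) = α* + β* · score,  α* = −4.8, β* = 0.15,

whose defaults give an overall event rate near 1.5% and a mild positive
score–risk gradient comparable to observed per-group rates (≈ 0.5% in the
lowest group to ≈ 3.5% in the highest). β* was set from the logit-scale
spread of those published per-group rates against the group midpoints, and
α* then fixed so that the mean risk at the default predictor mix is ≈ 1.5%;
neither is revisited by tests. The GFR band probabilities are the
observed-count conditionals (the printed band percentages sum to 97.2%
because 2.8% of GFRs were missing; the generator needs a full partition).

Invented structure, stated as such: continuous labs are drawn within their
bands (uniform inside the reduced-GFR and low-platelet bands, log-normal
bodies above them, an exponential tail for elevated INR) because only band
prevalences are anchored; creatinine is back-solved from the drawn GFR
through the eGFR inverse so the two are always consistent. Predictors are
mutually independent except a configurable ICU–CVC odds ratio (default 4,
chosen as clinically plausible; the conditional probabilities are solved
numerically to preserve the marginal CVC prevalence). A configurable
fraction of admissions (default 10%) are second admissions of an earlier
patient with identical predictors and independently drawn outcomes — enough
cluster structure to exercise sandwich variances, not a model of real
readmission dynamics. Missingness is MCAR or MAR through the ICU flag only.

Consequently, passing tests on synthetic data demonstrate *internal*
correctness (the estimators recover what generated the data) — they say
nothing about predictor correlations, outcome adjudication, informative
missingness or secular trends in real cohorts.

The latent truth (α*, β*, per-admission true risk) travels with the cohort
as an attribute and is the oracle for the recovery tests: logistic
regression of the outcome on the score recovers (α*, β*) within Monte-Carlo
error, and feeding the true logit risks to the calibration stage returns
CITL ≈ 0 and slope ≈ 1.

## Multiple imputation

Only the three labs are imputed (never outcomes or binary predictors).
The chained-equation scheme follows standard practice where the source
methodology names only the algorithm family:

* **Conditional model**: predictive mean matching, type 1 — a Bayesian
  linear-regression draw on the transformed scale, each missing cell matched
  to its 5 nearest observed predictions and a donor's observed value taken.
  PMM keeps imputations inside the observed support, so positivity is
  automatic.
* **Transforms**: GFR on `log(x + shift)` with shift = 1 (the shift constant
  is not dictated by anything; 1 keeps the transform defined and is
  documented); INR on the Box–Cox scale with λ re-estimated from the
  observed INRs by profile maximum likelihood each run; platelets raw.
* **Regressors**: all score predictors, the outcome indicator, and the other
  two labs (transformed, current iterate).
* **Iterations**: 10 burn-in sweeps per dataset; m = 20 datasets by default.

Pooling (`pool_rubin()`) applies Rubin's rules on a declared scale —
identity for CITL and slope, log for E/O and odds ratios, logit for
proportions and C statistics — with total variance W + (1 + 1/m)B,
Barnard–Rubin degrees of freedom when a finite complete-data df is given,
and back-transformed intervals. Proportions exactly 0 or 1 cannot enter the
logit; they are pulled in by 0.5/(n + 1), a continuity correction that keeps
the transform finite and is reported as such.

## Discrimination

The empirical grouped AUC is the trapezoid over the 11-group operating
points, identical to the tie-corrected Mann–Whitney statistic (a brute-force
double loop over groups serves as the oracle in the tests).

The parametric fit is the classical ordinal-category binormal model:
non-events latent N(0, 1), events N(a/b, 1/b), cut at K − 1 thresholds, with
the two-sample multinomial likelihood maximized by BFGS on an unconstrained
reparameterization (a, log b, t₁, log-increments of the thresholds — the
standard way to keep b > 0 and the thresholds ordered). Starting values are
probit-transformed smoothed empirical operating points. Standard errors come
from the observed information; the AUC = Φ(a/√(1+b²)) interval by the delta
method. Groups with zero total are dropped with a warning (they cannot
anchor a threshold) and at least three informative groups are required.
The ROC "score" is the ordinal group index — rank-invariant, so midpoints
would give the same fit. Per-imputation fits are pooled on the logit scale;
the package fits either patient-level-derived grouped counts per imputation
(the default inside `run_validation()`) or a single printed grouped table.

## Calibration and updating

Expected risks come from an `expected_risk_table()` keyed by group. The
original derivation-study values shipped with the package are the two-group
ones (1.5%/7.9% any, 0.4%/4.1% major); the 11-group derivation table is not
public and must be supplied by the user when available — which is why E/O
computed from the shipped two-group fallback approximates but does not equal
an 11-group E/O.

E/O uses a Poisson-type log-scale interval (SE = √(1/O)), treating E as
fixed. CITL and slope are the intercept-with-offset and slope logistic
refits, with cluster-robust sandwich SEs (HC0 meat, no small-sample cluster
adjustment, so the estimator reduces *exactly* to the ordinary robust
variance under singleton clusters). The loess calibration curve uses span
0.75, degree 1, evaluated at 100 points inside the observed prediction range
(no smoother settings are dictated by the methodology being reproduced;
these are the common defaults for calibration plots).

Recalibration defaults to `intercept_slope` — the logistic refit of the
outcome on the total score — because an updated model whose in-sample slope
is exactly 1.0 is the signature of that refit (the maximum-likelihood score
equations force E/O = 1, CITL = 0 and slope = 1 on the fitting data; the
package's acceptance script recomputes exactly this identity).
`intercept_only` (offset refit) is provided and documented: it restores
E/O = 1 and CITL = 0 while leaving the slope untouched. Updated per-group
risks are the refit probabilities at the group midpoints
(`intercept_slope`) or the shifted group-mean linear predictors
(`intercept_only`).

## Degenerate inputs and numerical choices

* Zero denominators in the 2×2 metrics yield `NA` with an explanatory note,
  never an exception; a zero cell makes the odds ratio undefined the same
  way. Separation in the logistic fits is flagged and the CI reported
  unbounded.
* Admissions discharged bleeding-free before day 14 are censored at
  discharge in the Kaplan–Meier estimate (configurable to administrative
  censoring at the horizon only; the censoring rule is not dictated by the
  source methodology). The 2×2 condition is the *binary* "bled on or before
  day 14" — the reading under which printed validation counts reproduce —
  with KM reported alongside, not inside, the table.
* Reported percentages round half-up to one decimal in the printed report;
  machine outputs are unrounded.
* `run_validation()` warns below 100 events, the recommended minimum for
  external validation of a binary-outcome model.

## Problem sizes used in the test suite

Margin and recovery checks run at n = 50,000 admissions (3 binomial SEs),
imputation fidelity at n = 10,000 with m = 20, binormal parameter recovery
on grouped tables of 10⁵ per class, and the recalibration identities on
n = 10,000 cohorts — sizes at which Monte-Carlo error is well below every
tolerance asserted, while a full suite run stays in the tens of seconds.

## Known limitations

Outcome adjudication, predictor extraction from records, and competing-risk
(death) adjustment are out of scope; the KM estimate is the plain
product-limit form. The synthetic generator's joint predictor distribution
is stipulated, not estimated. Prophylaxis is carried as a descriptive field
only and has no effect on simulated bleeding. Re-estimating individual item
weights or extending the model with new predictors is deliberately not
offered: with event counts typical of single-center cohorts, recalibration
of the intercept (and at most the slope) is the defensible update.
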