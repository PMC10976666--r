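# improvebleed

External validation and recalibration of the IMPROVE bleeding risk score in R.

## The problem

Acutely ill medical inpatients face a trade-off: pharmacologic prophylaxis
against venous thromboembolism carries a bleeding risk. The IMPROVE
(International Medical Prevention Registry on Venous Thromboembolism)
bleeding risk assessment model is the recommended tool for predicting
clinically relevant bleeding within 14 days of admission. It is an additive
point score over 13 items (renal function bands, sex, age bands, cancer,
rheumatic disease, central venous catheter, ICU/CCU admission, hepatic
failure by INR > 1.5, low platelets, recent bleeding, active
gastroduodenal ulcer), with a threshold of 7 points separating low- from
high-risk admissions.

A score derived in one population cannot be assumed to transfer to another:
both its *discrimination* (can it rank bleeders above non-bleeders?) and its
*calibration* (are the predicted risks numerically right?) must be
re-measured locally, and the model updated when calibration fails. This
package implements that whole validation pipeline for cohorts of hospital
admissions — and, because no patient-level validation data are public, a
synthetic-cohort generator with known latent risk so every stage can be
exercised and tested end to end.

## What it computes

For the **two-risk-group** reading (score < 7 vs >= 7): sensitivity,
specificity, PPV and NPV with Clopper–Pearson exact CIs; per-group event
rates; odds ratios with cluster-robust (sandwich) variances over repeated
admissions of the same patient; Kaplan–Meier 14-day cumulative incidence
with censoring at discharge.

For the **11-risk-group** reading: empirical ROC (grouped Mann–Whitney AUC)
and the fully parametric binormal ROC fitted by maximum likelihood on the
ordinal groups — non-events latent N(0, 1), events N(a/b, 1/b), so
C = Φ(a / √(1 + b²)) — with delta-method CIs. Calibration is quantified by
the expected/observed ratio E/O = Σpᵢ / O, calibration-in-the-large (the
intercept α of logit P(y=1) = α + offset(LP)), the calibration slope (β in
logit P(y=1) = α + β·LP), loess calibration curves, and grouped
observed-vs-expected tables.

Missing laboratory predictors (platelets, INR, GFR) are multiply imputed by
chained equations with predictive mean matching (GFR on a shifted-log scale,
INR on a Box–Cox scale with λ estimated by ML), and all estimates are pooled
with Rubin's rules on the appropriate scale: identity for CITL and slope,
log for E/O and odds ratios, logit for proportions and C statistics.

The model is **updated** by logistic recalibration: refitting
logit P(y=1) = α + β·score on the validation data (or intercept-only with
the original linear predictor as offset), after which the in-sample E/O, CITL
and slope are 1, 0 and 1 by the maximum-likelihood score equations.

## Worked example

The package ships grouped counts from an external validation cohort
(11 risk groups, 3,876 admissions, 58 any / 49 major bleeds) as an example
of the grouped-input mode:

```r
library(improvebleed)
g <- system.file("extdata", "validation_grouped_counts.csv", package = "improvebleed")
print(run_validation(g))
```

```
-- any bleeding --
sensitivity  26.3% (95% CI: 15.5-39.7%)
specificity  84.8% (95% CI: 83.7-86.0%)
npv          98.7% (95% CI: 98.3-99.1%)
ppv          2.5% (95% CI: 1.4-4.1%)
odds ratio   2.00 (1.10-3.63), P = 0.023
Binormal ROC fit: a = 0.597, b = 1.117, AUC = 0.655 [0.588, 0.721]
```

Read: high-risk admissions bleed about twice as often as low-risk ones, but
a PPV of 2.5% means very few flagged admissions actually bleed; an AUC of
0.655 is the moderate discrimination typical of bleeding scores. On
patient-level data the same call also imputes missing labs, pools across
imputations, evaluates calibration, and recalibrates:

```r
rep <- run_validation(cohort_spec(n = 5000, seed = 42), m = 1)
rep$recalibration
#> Logistic recalibration (intercept_slope): E/O = 1.000, CITL = 0.0000, slope = 1.0000
```

A thin command-line front end lives at `inst/cli/improvebleed.R`
(subcommands `simulate`, `score`, `validate`).

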