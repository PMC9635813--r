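# predictval

Tools for externally validating PREDICT-style prognostic models for early
breast cancer in R: the v2.1 scoring computation (prognostic index,
competing-risk survival composition, treatment effects) from a versioned
coefficient configuration, plus the full validation battery —
discrimination (Royston D, fixed-horizon ROC/AUC, median-split survival
curves) and calibration (predicted-versus-observed tables, Integrated
Calibration Index, restricted-cubic-spline calibration curves) — and a
synthetic-cohort generator that provides exact ground truth for every
stage.

Intended users are biostatisticians and clinical epidemiologists who want
to validate a published prognostic score on their own cohort, or to study
the behaviour of validation statistics on simulated cohorts with known
truth.

## The model

For a patient with prognostic index PI (weighted sum of transformed
clinicopathological factors for her ER stratum), treatment effect TE (sum
of adjuvant-treatment log-hazard-ratios) and age-driven mortality index
MI = 0.0698252·((age/10)² − 34.23391957), survival at time *t* is composed
under independent competing risks:

    bS(t) = exp(−exp(L0_br(t) + PI + TE))     breast-cancer-specific
    oS(t) = exp(−exp(L0_oth(t) + MI))         other-cause
     S(t) = bS(t) · oS(t)                     overall

where L0 are baseline log cumulative hazards per cause (and per ER stratum
for the breast baseline). Coefficients, transforms and baselines are read
from a versioned YAML/JSON configuration; a transcription of the public
v2.1 weights ships with the package (`predict_v21_path()`).

## Worked example

Score one patient and validate the model on a simulated cohort:

```r
library(predictval)
coeffs <- load_coefficients(predict_v21_path())

patient <- tibble::tibble(id = "example", age_years = 54, menopause = "post",
  detection = "screening", size_mm = 18, grade = 2L, nodes = 1L,
  er = "positive", her2 = "negative", ki67 = "unknown",
  hormone = TRUE, chemo = FALSE, trastuzumab = FALSE, radiotherapy = TRUE)
predict_overall_survival(patient, coeffs)
#>   id      er          pi     mi     te horizon    bs    os     s
#> 1 example positive 0.863 -0.354 -0.386       5 0.969 0.981 0.950
#> 2 example positive 0.863 -0.354 -0.386      10 0.920 0.946 0.870
```

The patient's five-year overall survival estimate is 95.0%: a 96.9%
probability of escaping breast-cancer death (hormone therapy contributing
TE = −0.386 on the log-hazard scale) times a 98.1% probability of
surviving other causes at her age.

```r
sim <- simulate_cohort(synthetic_spec(), coeffs, n = 873, seed = 1)
report <- run_validation(sim$cohort, coeffs)
m <- report$metrics[["positive_5"]]
#> ER+ 5y:  AUC 0.741 (0.682-0.801)  Royston D 1.40 (SE 0.21)  ICI 0.0084

report$predicted_observed$er
#>    stratum horizon   n predicted       observed (95% CI)
#>   positive       5 744     0.919    0.915 (0.893-0.933)
#>   positive      10 744     0.801    0.785 (0.750-0.815)
```

Because this cohort was simulated from the model itself, predictions
discriminate (AUC 0.74) and are calibrated (ICI 0.008; mean predicted
five-year survival 91.9% against 91.5% observed) — which is exactly the
kind of ground-truth check the generator exists to provide. On a real
cohort the same report quantifies how well the published model transports.

A command-line front end wraps the same functions:

```sh
predictval simulate --coeffs predict_v2.1.yaml --n 873 --seed 1 --out cohort.csv
predictval score    --cohort cohort.csv --coeffs predict_v2.1.yaml --out scores.csv
predictval validate --cohort cohort.csv --coeffs predict_v2.1.yaml --out report/
```

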