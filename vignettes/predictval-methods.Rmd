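---
title: "Validating a PREDICT-style prognostic model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a PREDICT-style prognostic model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predictval)
```

## The model

PREDICT estimates overall survival after surgery for early breast cancer
from routine clinicopathological variables. predictval implements the
scoring computation of PREDICT version 2.1 together with a complete
external-validation pipeline (discrimination and calibration), and a
synthetic-cohort generator so the pipeline can be exercised against known
ground truth.

Three linear predictors are computed per patient:

* the **prognostic index** PI, the weighted sum of transformed prognostic
  factors for the patient's ER stratum (fractional-polynomial transforms of
  age, tumour size in mm and positive-node count, a grade score, and
  categorical offsets for detection mode, HER2 and Ki67 status);
* the **mortality index** MI for other-cause mortality,
  `MI = a * ((age/10)^2 - b)` with published constants
  `a = 0.0698252`, `b = 34.23391957`;
* the **treatment effect** TE, the sum of log-hazard-ratios of received
  adjuvant treatments (hormone therapy counts only in ER-positive disease;
  a coefficient entry may carry an additional `requires` condition, e.g.
  trastuzumab restricted to HER2-positive tumours; radiotherapy carries no
  term in v2.1 and is retained for subgrouping only).

Survival is composed under independent competing risks:

$$bS(t) = \exp(-e^{L_0(t) + PI + TE}), \qquad
  oS(t) = \exp(-e^{L_0^{oth}(t) + MI}), \qquad
  S(t) = bS(t)\,oS(t).$$

A deliberate interpretation is baked in here: the "baseline survival at
time t" appearing inside the double exponential is the baseline **log
cumulative hazard** $L_0(t) = \log H_0(t)$. That is the only reading under
which the composition yields probabilities in $(0,1)$ that decrease in
$t$, and it makes $bS$ the familiar proportional-hazards survival
$\exp(-H_0(t)e^{PI+TE})$.

### Coefficient configuration

Coefficients live in a versioned YAML/JSON file (see
`predict_v21_path()` for the shipped transcription of the public v2.1
source). Numeric PI terms are described by a small transform DSL —
`(value + shift) / scale` raised to a fractional-polynomial power in
{−2, −1, −0.5, 0, 0.5, 1, 2, 3} (0 meaning log), optionally multiplied by
the log for repeated-power FP2 terms — so the same engine evaluates any
term of this family; categorical terms carry per-level offsets. Baselines
may be fractional polynomials in time or monotone-interpolated
year-indexed tables. Every invariant (both ER strata present, known
covariate names, complete treatment map, non-decreasing baseline
cumulative hazards over the stated support) is checked at load, never at
scoring time.

Two numerical choices matter at the edges. Below the lower support bound
the cumulative hazard is extended linearly from $(0,0)$, keeping early
horizons and event-time inversion defined (the transcribed ER-negative
breast baseline is non-monotone as $t \to 0$, so its support starts at
0.5 years). Out-of-range covariates are clamped to the configured
admissible ranges with a warning by default; strict mode raises instead.
The shipped chemotherapy log-hazard-ratio is the third-generation regimen
value; single-flag cohorts cannot distinguish regimen generations.

## Validation statistics

All follow-up is internally in years (days / 365.25), administratively
censored at the longest requested horizon with death from any cause as the
event.

**Kaplan–Meier and Cox.** Estimation is delegated to the survival package;
the module fixes the conventions: Greenwood variance, complementary
log-log pointwise intervals by default (bounded in [0,1]; the variance at
steps where the estimate reaches 0 is defined as 0), Efron tie handling
with Breslow optional, Newton iteration to a 1e-9 tolerance with at most
50 iterations, and hard errors (never silent results) on non-convergence
or diverging coefficients. The multivariable Cox table codes age and size
linearly, grade as a linear score, node count, and ER-negative /
screening / treatment indicators; patients with unknown detection mode are
excluded from that model and counted in the report metadata.

**Royston D.** Prognostic values are ranked, replaced by Blom rankits
$\Phi^{-1}((i - 3/8)/(n + 1/4))$ (ties receive averaged rankits), scaled
by $1/\sqrt{8/\pi}$, and a one-covariate Cox model is fitted; D is the
coefficient and its SE the reported uncertainty. D estimates the log
hazard ratio between equal-sized risk halves, and depends on the risk
score only through ranks — so computing it on predicted mortality or on
the raw PI gives identical values. "D at horizon h" censors follow-up at
h first. For a unit-coefficient standard-normal PI without censoring the
large-sample value is $\sqrt{8/\pi} \approx 1.596$, which the test suite
recovers by simulation.

**Horizon ROC/AUC.** At horizon h, cases died at or before h, controls
were followed beyond h (censoring exactly at h counts as surviving to h);
patients censored alive before h are excluded — the default is a plain
binary ROC on the determinate patients rather than an IPCW estimator,
which keeps the statistic identical to the exhaustive Mann–Whitney
pair count (half credit for ties) that the tests compare against.
Confidence intervals use DeLong's method (midrank implementation,
cross-checked against pROC) for determinism; a seeded bootstrap is
available.

**Median split.** Risk is dichotomized strictly above the median; ties at
the median deterministically join the low-risk group. The two groups get
Kaplan–Meier curves and a log-rank comparison.

**Calibration.** Predicted-versus-observed tables report, per stratum and
horizon, the mean predicted survival with a normal-approximation CI of the
mean against the Kaplan–Meier estimate with its Greenwood-based CI. The
Integrated Calibration Index (ICI) is the mean absolute difference between
predicted mortality by the horizon and a smoothed observed mortality: the
smoother is a Cox model of all-cause death on a restricted cubic spline
basis of $\log(-\log(1 - p))$ with 3 knots at the 10th/50th/90th
percentiles (configurable; Harrell's default quantiles for 4–5 knots),
Breslow baseline, each patient's smoothed risk read off at the horizon.
Predicted risks are clipped to $[10^{-6}, 1 - 10^{-6}]$ before the
transform; mortality scale (not survival) is used throughout. Near-constant
predictions (SD of the transformed risk below 1e-8, or a smoother that
fails to fit) fall back to the overall Kaplan–Meier risk for every patient
and are flagged degenerate. Calibration curves evaluate the same smoother
on a grid and ship with an identity-line reference and a kernel density of
predicted risk.

## The synthetic-cohort generator

Because patient-level validation cohorts are generally not shareable, the
generator is a first-class module. Its defaults emulate a hospital cohort
of 873 women with early breast cancer (ER-negative fraction 130/873):
per-stratum truncated-normal age (ER+ mean 58.5, SD 12.7; ER− 55.6, 13.1),
truncated log-normal tumour size matched to the target mean/SD (21.1/12.8
and 26.4/14.0 mm), zero-inflated negative-binomial node counts tuned to a
median of 0 with interquartile ranges of 1 (ER+) and 2 (ER−), and the
published category frequencies for grade, menopause, detection mode, HER2
and Ki67. Treatment assignment draws whole regimens per stratum (ER+:
51.8% hormone only, 39.4% hormone+chemo, 6.2% hormone+chemo+trastuzumab,
2.0% chemo only, plus rare combinations; ER−: 78.5% chemo only, 21.5%
chemo+trastuzumab) with independent radiotherapy flags. Covariates are
sampled independently within stratum: real joint structure (grade–size,
age–menopause) is deliberately not modelled, so passing tests demonstrate
the statistical machinery, not realism of covariate correlations.

Event times come from the engine's own model by inverse-transform
sampling: with $u_1, u_2$ uniform, the breast-cancer death time solves
$H_0^{br}(t)e^{PI+TE} = -\log u_1$ by vectorized monotone bisection
(tolerance 1e-8 years; the linear below-support segment is inverted
exactly), other-cause analogously with MI. Administrative censoring
emulates a 15-year accrual window with a fixed study end guaranteeing 5
years of potential follow-up (censoring times uniform on 5–20 years),
followed by the 10-year cap. A single top-level seed is split into
documented sub-seeds for the covariate and outcome stages, so the full
composition and each stage are independently reproducible.

Because predictions and outcomes share one model, the generator provides
exact ground truth: ICI on the true predicted risks shrinks toward zero as
n grows, a known +0.10 risk shift is recovered as ICI ≈ 0.10, shuffled
predictions give AUC ≈ 0.5, and Royston D on a normal PI approaches its
analytic limit. These are the recovery checks the test suite and the
acceptance script run (cohorts of 5 000 for calibration recovery, 50
replicates of 5 000 for D, 100 replicates of 2 000 for Cox recovery —
sizes chosen to keep Monte Carlo error well inside the asserted
tolerances while the whole suite runs in well under a minute for these
stages).

## Degenerate inputs and tie-breaks

* Constant prognostic values: D = 0 with a degenerate flag, not an error.
* Zero cases or zero controls at a horizon: explicit "degenerate horizon"
  error.
* All risks equal at the median: "no split possible" error.
* Contingency tables with a zero margin: test reported not-applicable.
* 2×2 baseline-table tests use the Yates continuity correction, larger
  tables none — the convention under which the published baseline-table
  p-values are exactly recomputable from their printed counts; "unknown"
  levels are retained as categories. The t-test defaults to Welch; node
  counts use the Mann–Whitney test.
* Perfect separation or non-convergence in any Cox fit raises a
  diagnostic error.

## Limitations

* The shipped v2.1 coefficients are a transcription of the public source;
  the test suite establishes correctness exclusively on toy coefficient
  sets, so transcription fidelity affects only end-to-end illustrations,
  not any tested property.
* The ROC default ignores patients censored alive before the horizon
  rather than reweighting them; with heavy early censoring an IPCW
  estimator (available as an option point for extension) would be
  preferable.
* The generator's independence assumptions understate real covariate
  correlation, and its node-count distribution is only quantile-matched.
* No time-varying covariates, stratified or frailty Cox models, and no
  recalibration/updating methods — the package validates, it does not
  re-estimate.
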