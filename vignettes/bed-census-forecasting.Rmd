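---
title: "Forecasting surgical bed utilization: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting surgical bed utilization: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surgecast)
```

## The problem

A surgical service needs to know, days to weeks in advance, how many
inpatient beds its post-operative patients will occupy each night. Two
separate signals drive that number: how many cases are performed on each day,
and how long each case stays afterwards. `surgecast` implements a three-stage
pipeline that models each signal and then fuses them:

1. **Per-case length of stay (LOS).** A random-forest regressor predicts the
   number of nights each scheduled case will stay, from case attributes and a
   low-rank embedding of the patient's comorbidity codes.
2. **Daily surgical volume.** A seasonal ARIMA model with a holiday
   exogenous regressor forecasts the daily case count, whose dominant
   structure is the 7-day operating-room week.
3. **Bed census.** Per-case stays are aggregated into a daily occupancy
   array (one bed per case per night from the surgery night through
   discharge), and SARIMAX / OLS / VAR forecasters are evaluated at three
   horizons — long-term (information frozen at the end of training),
   two-week-ahead, and same-day (prior to the start of the operating-room
   day) — under an audited information-cutoff discipline.

Because encounter-level hospital data cannot be redistributed, the package
ships a synthetic hospital-year generator with known ground truth; every
claim the test suite makes is a property of the method demonstrated on that
generator, not a reproduction of any institution's numbers.

## The synthetic hospital year

`gen_config()` describes one year of activity. The defaults emulate a large
academic surgical service: roughly 100,000 encounters over 365 days (about
290–300 cases on a typical weekday-dominated calendar, median ~295/day),
72.4% of encounters classified as outpatient procedures, median LOS of 1 day
with quartiles (1, 2) among admitted patients, and a mean of 10.9 (SD 11.2,
range 1–160) comorbidity codes per patient drawn from a 2,000-code
vocabulary with Zipf-decaying frequencies.

Design choices worth knowing:

* **Daily counts** are negative-binomial around a regime mean (weekday /
  weekend / holiday; defaults 320 / 170 / 120 with dispersion 60). Poisson is
  the `volume_dispersion = Inf` limit and `NULL` gives deterministic counts
  for degenerate-case tests.
* **LOS law** is zero-inflated per surgery type: a point mass at zero
  (same-day discharge) plus `1 + NegBin` for admitted cases, giving the
  short median with a long tail. Per-type parameters are drawn once,
  deterministically from the seed, and calibrated on the logit scale (via
  `uniroot`) so the popularity-weighted marginal reproduces the configured
  outpatient fraction.
* **Comorbidity signal.** Each patient's code set is drawn without
  replacement with power-law inclusion probabilities. A latent burden score —
  the standardized count of the most frequent `comorbidity_effect_codes`
  codes — multiplies the positive-LOS mean by
  `exp(effect * z)`. This is what makes the truncated-SVD components
  genuinely predictive, so permutation-importance and model-vs-baseline
  tests measure something real.
* **Plan-time vs realized knowledge.** The inpatient/outpatient admission
  class — a model feature — is the realized same-day status observed through
  a 10% plan-level error (`admission_class_error_rate`), standing in for
  unplanned admissions after outpatient surgery and early discharges. The
  finer-grained `planned_same_day_discharge` flag (realized status with its
  own 5% error) is deliberately *not* a model feature; it only enters the
  "adjusted" census scenario. Without this separation, the admission class
  would reveal same-day discharge perfectly and advance discharge knowledge
  could never improve a forecast.
* **Comorbidity count calibration.** Counts are a rounded normal clipped to
  `[min, max]`; clipping inflates the mean, so the latent mean is calibrated
  in closed form so the realized per-patient mean equals the configured one.
* **Patients recur**: cases sample a patient pool of about 0.66 times the
  case count, and comorbidity sets are patient-level.

What the generator does **not** emulate: real ICD-9/10 semantics (codes are
opaque strings), intra-day timing, bed types (ICU vs ward), non-surgical
admissions, seasonal (annual) volume drift, and pandemic-style shocks.
Passing tests therefore demonstrate correctness and qualitative behaviour of
the method — error orderings, information-value comparisons, seasonality
handling — not clinical performance on real data.

## Preprocessing

The split is chronological and contiguous: by default the first 225 days
train, the next 70 validate, the last 70 test (`split_spec()`). Every fitted
statistic — imputation means and modes, the code vocabulary, decomposition
loadings, historic mean LOS — is a pure function of its fitting window;
final test evaluation refits them on train + validation.

Imputation (`fit_imputer()`): missing scheduled duration and LOS take the
per-surgery-type mean; missing ASA PS takes the per-type mode with ties
broken toward the smaller score; a type absent from the window falls back to
the global mean for numeric fields and to an explicit "unknown" category for
ASA (encoded as its own indicator column, since an unknown physical status
is categorical information, not an ordinal value). Imputation is idempotent.

The comorbidity matrix is binary case-by-code incidence, stored sparse. The
vocabulary is the `top_n` most frequent training codes (default 1,750;
frequency-descending, lexicographic tie-break). Three reductions to `k`
components (default 12) are available, none of which densifies the matrix:

* `truncated_svd` — uncentered truncated SVD via the eigendecomposition of
  the code-by-code Gram matrix (exact, since `k` ≪ columns);
* `pca` — mean-centered components computed from the Gram matrix and column
  means;
* `feature_agglomeration` — average-linkage clustering of columns on cosine
  distance, mean-pooled per cluster.

`tune_n_and_k()` scores grid points by the validation MSE of the downstream
forest. The default mode is sequential — vocabulary size first, then method
and component count — because the vocabulary determines what signal exists
for any decomposition to find; a joint grid is available.

## The LOS model

Features: age, scheduled duration, comorbidity count, historic mean LOS of
the surgery type (computed on the fitting window only, to avoid target
leakage), ASA PS (ordinal value plus unknown indicator), the `k`
decomposition scores, and one-hot blocks for sex, service line and planned
admission class; unseen categories at prediction time map to all-zero
blocks. The forest defaults follow the tuned configuration for this task —
at most 92% of training rows per tree (sampled without replacement) and at
most 580 leaves per tree — with 500 trees (ensemble-size error curves are
flat well before this) and `mtry = p/3`. Predictions are clipped at zero,
an explicit contract even though trees cannot extrapolate below nonnegative
targets. Evaluation reports RMSE and MAE overall and stratified at 10 days,
since short stays dominate the case mix. Permutation importance shuffles one
column at a time and reports the mean MSE increase over 10 repeats on the
validation set.

The per-type-mean baseline (`predict_mean_los_baseline()`) is the comparison
model everywhere: a forecaster that knows only the surgery type.

## Volume forecasting

`correlogram()` computes the sample ACF/PACF with the ±1.96/√n white-noise
band; on generator output the lag-7 ACF is overwhelmingly significant, and a
first seasonal difference leaves isolated spikes at holiday offsets —
exactly the diagnostic sequence that motivates a (0,0,0)(0,1,1)₇ model with
a holiday indicator as exogenous regressor. Estimation is state-space
maximum likelihood (`stats::arima`), falling back to conditional sum of
squares when ML fails to converge, and raising a classed error otherwise.
Two degenerate regimes are reduced exactly rather than estimated: an exactly
periodic series (zero-variance seasonal difference) becomes the seasonal
random walk with drift, and an exogenous set that explains the target with
zero residual variance becomes a pure linear regression. Counts are modelled
on the raw scale (no transformation), and point forecasts only.

`rolling_forecast()` implements rolling-origin evaluation: by default the
model is refit at every origin on an expanding window (the conservative
reading of "rolling"); reusing first-origin parameters is available.
Fit failures at an origin are skipped and reported, never silently replaced
by a naive forecast.

## Census forecasting

The census convention: a case with surgery day `d` and LOS `ℓ` occupies one
bed on nights `d, …, d+ℓ−1`; `ℓ = 0` occupies none; nights beyond the
calendar are truncated. This makes the conservation identity
`Σ census = Σ min(ℓ, n_days − d)` exact, which the suite verifies against a
double-loop oracle. Fractional (imputed or predicted) LOS is rounded half-up
per case before aggregation; unrounded expectation-aggregation is available
as a switch.

Census variants differ only in the per-case LOS source: observed, forest
prediction, prediction overridden to zero for planned same-day discharges
("adjusted"), the actual LOS ("perfect", an oracle lower bound identical to
the observed array), and the per-type historic mean (upper bound).

Information discipline: each forecast day has a cutoff (training end for
long-term, `t − 14` for two-week, `t − 1` for same-day), and every exogenous
value is classified — calendar-known (holidays), schedule-known (the census
arrays, which derive from the surgical schedule and pre-operating-day LOS
predictions, including at the two-week horizon where elective booking
precedes the cutoff), observed (usable only up to the cutoff), or
forecast-fed (lagged surgery counts beyond the cutoff are replaced by the
volume model's forecast and flagged). Requesting an observed value beyond
its cutoff raises a classed leak error; an escape hatch
(`allow_future_exog`) exists for replication studies and is recorded as an
audit violation — the planted OLS canary (regressing the census on itself)
must trip it. "SD" in every report is the standard deviation of absolute
forecast errors across evaluated days, the only reading consistent with a
per-evaluation statistic; it is labelled as such.

The grid (`run_table2_grid()`) covers: long-term SARIMA with/without
holidays and a VAR of census and counts with holiday exogenous (lag order 7,
per-equation OLS); two-week OLS on the predicted census, SARIMAX on the
predicted census, and SARIMAX on holidays plus forecast-fed 7-day-lagged
counts; same-day SARIMAX on holidays and on the predicted / adjusted /
perfect / per-type-mean census arrays. The two-week protocol advances
origins daily and scores only day `t`, so each test day is scored once.
`relative_error_report()` exposes RMSE divided by a caller-supplied bed
reference; because any true bed capacity exceeds the maximum observed
census, the quotient is reported and never asserted against a fixed figure.

## Problem sizes and numerical choices in the test suite

The suite demonstrates the paired-seed properties on a scaled hospital year
(daily volume means 64/34/24 — one fifth of the defaults with identical
weekday:weekend:holiday proportions — 40 surgery types, a 300-code
vocabulary with the LOS effect concentrated in the top 40, vocabulary 150,
k = 8, 50-tree forests), chosen once as a realistic small surgical service;
seasonality-detection and sparsity checks run on the full default
configuration. Ten fixed seeds drive each paired comparison (twenty for
seasonality detection), and 580-leaf/92%-sample defaults are kept wherever
the forest's shape matters. Tolerances follow the quantity: exact identities
(census, conservation, partition laws) are asserted exactly; linear-algebra
oracles at 1e-6–1e-10; stochastic orderings as per-seed win counts. The
per-type LOS fidelity check uses a 10% relative band with a 0.02-day
absolute floor, because several realistic types are almost always same-day
(mean LOS below 0.05 days) and a purely relative band at that scale would
test sampling noise, not fidelity.

## Known limitations

* The generator's calendar is day-indexed; no real dates, no annual
  seasonality, no structural breaks — so two-week and long-term horizons
  perform similarly by construction, as they do on any stable year.
* The VAR is a fixed-lag per-equation OLS without order selection or
  cointegration handling; it is a comparison baseline, not a tuned model.
* Same-day census exogenous arrays assume the day's schedule is final at the
  start of the operating-room day; cancellations and add-ons after that
  point are out of scope.
* LOS prediction is a point forecast; census uncertainty bands are not
  produced.
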