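---
title: "Methods: microdialysis versus pressure in subject-clustered hourly panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microdialysis versus pressure in subject-clustered hourly panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

An hourly cerebral microdialysis (MD) panel is doubly structured: values
within a patient are strongly autocorrelated over tens of hours, and
patients differ substantially in level. The package's working model for a
transformed marker \(m_{ij}(t)\) (marker \(j\), patient \(i\), hour \(t\)) is

\[ m_{ij}(t) = \alpha_j(\text{location}) + a_{ij}
   + \beta_{j,\mathrm{ICP}}\,\mathrm{ICP}_i(t)
   + \beta_{j,\mathrm{CPP}}\,\mathrm{CPP}_i(t) + s_{ij}(t), \]

with subject effects \(a_{ij} \sim N(0, \sigma_b^2)\) and stationary
ARMA(1,1) deviations \(s_{ij}\). Modeling scales are the standard
normalizing transforms: square root for glucose, lactate and pyruvate,
log10 for glycerol. The lactate:pyruvate and lactate:glucose ratios are
computed from raw (limited) concentrations with units harmonized
(lactate in mM/l is scaled by 1000 against pyruvate in uM/l) and are not
transformed by default. Pressures enter as hour-prior means: for a vial
whose membrane time is \(t\), ICP is averaged over the half-open window
\((t - 60\text{ min}, t]\) and CPP over timestamp-matched MAP−ICP pairs in
the same window.

The intraclass correlation
\(\mathrm{ICC} = \sigma_b^2/(\sigma_b^2+\sigma_w^2)\), with \(\sigma_w\)
the stationary SD of \(s\), is the population quantity estimated by the
identity-variance \(r^2 = 1 - SS_\text{within}/SS_\text{total}\).

## The synthetic cohort generator

`cohort_config()` / `simulate_cohort()` emulate the second-order structure
of a ~90-patient severe-TBI monitoring cohort: negative-binomial series
lengths around 84 hourly vials; minute-level AR(1) ICP around a truncated
normal patient level \(N(14, 4^2)\) mmHg and MAP around \(N(80, 6^2)\)
(so CPP sits near the 60–70 mmHg clinical target); marker dynamics as
above with adjacent-hour deviation correlation in the 0.77–0.83 range
(glucose least, glycerol most autocorrelated); between-patient SDs chosen
so subject identity explains roughly 52–75% of marker variance; weak
default pressure coupling (at most a few percent of explained variance);
GOS from a cumulative-logit model on mean ICP and CPP; marker-wise
missingness at 5%.

Deliberate simplifications, hence what passing tests do *not* show about
real data:

* no waveform-level pressure physiology, interventions (CSF drainage,
  thiopental), or artifact processes — artifacts enter preprocessing only
  as a manual exclusion list;
* pressure coupling is linear on the modeling scale and constant in time;
* within-patient dynamics are stationary; real cohorts have secular trends
  and regime changes;
* with `hours_mean = 84` and `missing_rate = 0.05`, *complete* four-marker
  sets average about 70 per patient (marker-wise thinning removes
  \(1 - 0.95^4 \approx 19\%\) of vials); both defaults are kept as primary
  dials, so the complete-set count is an emergent quantity;
* GOS is driven by pressures only. Because markers couple to pressures
  *between* subjects, an MD summary can still reach nominal significance
  against GOS through that indirect route — the same confounding logic
  that makes pooled tables treacherous.
* Minute-level pressure deviations use AR(1) with \(\phi = 0.8\) per
  minute; hourly means of such a process are nearly uncorrelated hour to
  hour, so within-patient hourly pressure dynamics are close to white
  around the patient level. Scenario configs that need strong hourly
  coupling raise `icp_phi`/`icp_sd`.

A single RNG stream is seeded from the config; patient-level draws come
first, then each patient's series from a deterministically derived
substream, so identical config + seed give byte-identical cohorts.

## Correlogram estimators

Pairing always respects patient boundaries and true clock-hour offsets
(`hour_index`), so gaps from dropped vials never masquerade as adjacent
hours. Two pooling modes are provided and they answer different questions:

* **pooled** — one Pearson correlation over all subject-hours at each lag.
  This is the display mode in which between-subject mean structure is
  visible, and the default. For the *autocorrelation* of short, strongly
  autocorrelated series it is also the low-bias choice: a per-series
  Pearson autocorrelation at \(\phi \approx 0.9\), \(n \approx 84\)
  carries an \(O((1+2\sum_k \rho_k)/n)\) negative bias of several
  hundredths, while pooled demeaning spreads that bias over the whole
  cohort.
* **per_patient** — a Pearson correlation per patient (patients with fewer
  than 3 pairs or constant series are skipped) combined by pair-count
  weighting.

The within-subject permutation null (`permute_within_subjects`) scrambles
each patient's MD order, keeping pressures fixed; it preserves every
patient's marginal distribution and hence all between-subject mean
structure, and destroys only temporal alignment. Bands are pointwise
percentile intervals over `B` replicates (default `B = 1000`, 0.95 level;
the number of permutations and the pointwise-versus-simultaneous choice
are design decisions documented here — simultaneous bands are not
implemented). A cross-patient full scramble is computed alongside as the
zero-structure control.

Calibration subtlety: the *pooled* statistic is intentionally not
calibrated against this null. Its deviation from the permutation
distribution contains a term coupling each patient's within-window partial
sums of the autocorrelated MD series to the patient's pressure level —
variance the permutation cannot reproduce (empirically ~34% of lags fall
outside a nominal 0.95 band under a zero-coupling generator). The
per-patient statistic removes subject levels inside each correlation and
is calibrated (~5% outside over 20 seeds at `B = 500`). Calibration
checks therefore use `pooling = "per_patient"`; qualitative
band-invariance comparisons of the published-style pooled curves compare
the observed curve against the band *width*.

## REML mixed models

`fit_reml()` maximizes the restricted likelihood of
\(V_i = \sigma_b^2 J + \sigma^2 R_i(\phi, \theta)\) per patient, with
\(R_i\) the ARMA(1,1) correlation \(\rho(k) = \gamma\phi^{k-1}\),
\(\gamma = (1+\phi\theta)(\phi+\theta)/(1+2\phi\theta+\theta^2)\),
evaluated on observed clock-hour offsets so correlation decays correctly
across gaps. Numerical choices:

* fixed effects are profiled out by GLS inside the objective, and the
  overall scale \(\sigma^2\) is profiled analytically, leaving a 3-parameter
  search over \(\log\lambda\) (\(\lambda = \sigma_b^2/\sigma^2\)),
  \(\tanh^{-1}\phi\), \(\tanh^{-1}\theta\) — the transforms enforce
  positivity and stationarity;
* patients sharing an offset pattern share one Cholesky factorization per
  objective evaluation;
* Nelder-Mead then BFGS, with multi-start over initial \(\phi\)
  (default 3 starts); convergence is reported as a relative
  gradient-norm diagnostic;
* Wald z tests (normal reference) for fixed effects, justified by large
  per-patient sample sizes; predictors are standardized internally and
  coefficients (with their covariance) back-transformed to raw units;
* with near-white within-patient residuals the ARMA parameters are weakly
  identified and the optimizer may land near the \(|\phi|, |\theta| \to 1\)
  boundary with a near-zero implied \(\rho(1)\); the fit is still valid —
  \(\rho(1)\) is the quantity to read, not \(\phi\) alone.

Both joint-predictor and single-predictor fits are supported by passing
the desired `predictors` vector (the underlying analysis question of
marker-level significance can be posed either way; both are exposed rather
than choosing one silently).

The implementation is validated against a dense multivariate-normal REML
evaluation on a small fixture (agreement to 1e-8) and cross-checked
against an independent REML implementation (nlme) on simulated panels.

## RBF cross-validation

The network is Gaussian-basis regression: k-means centers on standardized
predictors, per-center widths equal to the mean distance to the two
nearest other centers (shared-width fallback below three nodes), and a
ridge-regularized linear output layer with unpenalized bias. This replaces
epoch-based network training with a deterministic classical scheme of
equivalent capacity; the iteration count enters only through k-means
restarts. Model selection (node count) is nested: for each held-out
patient, grouped k-fold CV over the *remaining* patients only.
Uncertainty (“±”) is the SD over repeated CV runs with different seeds
(default 10 repeats). Negative pooled correlations are reported as-is.

Two structural facts matter when reading LOSO results on
subject-dominated data: held-out predictions track the training
leave-one-out mean, which is *negatively* correlated with the held-out
patient's level, so the null distribution of the pooled r is centred
below zero; and the effective sample size is the number of patients, not
rows. The null-skill check is therefore "not significantly greater than
zero" across seeds rather than a \(2/\sqrt{n_\text{rows}}\) band.

The representation search compares per-patient targets (whole-period
hourly mean; hours and percent of monitoring above/below each cutoff —
ICP cutoffs 15/20/25/30, CPP 40–90 mmHg) predicted from per-patient mean
MD by leave-one-out linear regression (PRESS form); zero-variance
representations are flagged and skipped.

## Short-term and outcome analyses

Differences \(\Delta_k x_t = x_t - x_{t-k}\) (k = 1..4) pair only
observations exactly k clock hours apart — bridging across dropped rows
would mix implied dynamics. Differenced MD is paired with the pressure
level at \(t\) by default (\(t-k\) by flag) and with the pressure
difference over the same window. The design grid reports raw p-values as
the primary quantity with Holm adjustment alongside. Per-subject
normalization sets each patient's mean to 0 and SD to 1 (patients with
under 3 rows or zero SD are dropped with a warning). Subject-mean
regressions use one row per patient (significance against the number of
patients) and refit after excluding observations with Cook's distance
above 1, reporting both fits.

Outcome analysis takes best GOS = the maximum over the recorded epochs,
excludes patients with fewer than 12 complete MD hours, and runs the
classical equal-variance one-way F (via the linear-model decomposition,
which tolerates singleton GOS groups) and the tie-corrected
Kruskal-Wallis H on every per-patient summary, with a two-test
concordance flag at 0.05. The "increased LP ratio" burden threshold is
configurable with default 25, a conventional clinical cutoff; burden
percentages are over complete-set hours (the hours actually analysable),
not raw monitored time.

## Descriptive surfaces

Binned pooled tables use ICP edges 15/20/25/30 and CPP edges 40–90 mmHg;
SDs are over samples (consistent with printed per-bin sample counts), and
a per-patient-weighted variant is provided because pooled bins let
unevenly distributed patients dominate. The lowess implementation is
degree-1 local regression with tricube weights, span 2/3, two bisquare
robustness iterations, and a pointwise SE band from the local weighted
residual variance — settings chosen here since "lowess" alone does not
pin them down; it is tested against closed-form linear/quadratic truths
and the global least-squares line at span 1.

## Problem sizes used by the tests

The test-suite and acceptance script run scaled-down cohorts chosen to
exercise each property well inside a desktop budget: ACF equivalence at
50 patients x 84 h; permutation-band calibration at 30 x 60 over 20 seeds
with B = 500; the means-only invariance demonstration at 40 x 50 with
B = 300; ICC recovery at 25 x 150 (balanced, 2-min pressures) over 20
seeds per ICC level; REML recovery at 60 x 84 over 10 seeds; LOSO checks
at 20 x 40; determinism at 12 x 30. Pointwise ACF agreement is asserted
for lags 1–5 and on average over lags 1–10, because the Monte-Carlo sd of
the lag-10 estimate at this cohort size (~0.04) exceeds the 0.03
agreement band that is meaningful at short lags.

## Known limitations

* The ARMA(1,1) residual family is the only within-patient covariance
  offered (no random slopes, crossed effects, or GLMMs).
* Pointwise permutation bands understate simultaneous coverage across 71
  lags; read band exceedances at isolated lags accordingly.
* The pooled correlogram mode is descriptive, not calibrated (see above).
* Real-data ingestion expects the package's tidy CSV schema; vendor
  monitor exports must be converted upstream.
* p-values from Wald z in the mixed model can differ slightly from
  t-reference implementations at small patient counts.
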