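# neuromd

Time-series analysis of cerebral microdialysis (MD) against intracranial
pressure (ICP) and cerebral perfusion pressure (CPP) in neurocritical care.

## The problem

Cerebral microdialysis samples brain extracellular fluid hourly through an
implanted catheter; the routinely assayed markers are glucose, lactate,
pyruvate and glycerol (plus the lactate:pyruvate and lactate:glucose
ratios). ICP and MAP are monitored at 1–2-minute resolution, with
CPP = MAP − ICP. The analytical difficulty is that hourly MD values from one
patient are strongly autocorrelated and patients differ greatly in their
baseline chemistry, so naive pooled correlations of MD against ICP/CPP are
dominated by *which patient* a sample came from rather than by any
hour-to-hour physiological coupling. This package implements an analysis
pipeline that takes that structure seriously, together with a synthetic
cohort generator that reproduces it, so every stage is testable by
parameter recovery.

## What is implemented

* **Synthetic cohort generator** — per patient: minute-level AR(1) ICP and
  MAP streams around clinical targets (ICP ≤ 20 mmHg, CPP 60–70 mmHg);
  hourly markers on their modeling scales,
  `m(t) = α + a_i + β_ICP·ICP(t) + β_CPP·CPP(t) + s(t)`, with subject
  effects `a_i ~ N(0, σ_b²)` and stationary ARMA(1,1) deviations `s(t)`;
  ordinal-logistic GOS outcomes driven by mean pressures; marker-wise
  missingness. Deterministic given a seed.
* **Preprocessing** — 17-min membrane-to-vial transfer-time shift, assay
  limiters, complete-set extraction (all four markers), ratios from raw
  concentrations, square-root/log10 normalizing transforms, and hour-prior
  pressure means over `(t−60 min, t]` with a 50% coverage rule.
* **Correlograms** — panel ACF/CCF over exact clock-hour offsets (pooled
  and per-patient pooling), a within-subject permutation null with
  Monte-Carlo percentile bands plus a cross-patient full-scramble control,
  and the subject-identity variance decomposition
  `r² = 1 − SS_within/SS_total`.
* **Mixed models** — REML linear mixed models with patient random
  intercepts and ARMA(1,1) within-patient residual correlation
  (`ρ(k) = γφ^{k−1}`, `γ = (1+φθ)(φ+θ)/(1+2φθ+θ²)`), written directly from
  the restricted likelihood with GLS-profiled fixed effects and Wald z
  tests.
* **RBF networks** — Gaussian radial-basis-function regression (k-means
  centers, nearest-neighbour widths, ridge output layer) with
  leave-one-subject-out cross-validation, nested model selection, permuted
  controls, and a search over alternative pressure representations
  (hours/percent of monitoring above cutoffs).
* **Short-term probes** — 1–4-hour differenced regressions, per-subject
  z-normalization, subject-mean regressions with Cook's distance > 1
  screening.
* **Outcome** — best-GOS (maximum over follow-up epochs) versus per-patient
  summaries by one-way ANOVA and Kruskal-Wallis, excluding patients with
  under 12 h of MD.

## Worked example

```r
library(neuromd)

cfg     <- cohort_config(n_patients = 30, hours_mean = 60, seed = 42)
cohort  <- simulate_cohort(cfg)
aligned <- preprocess_cohort(cohort)

identity_variance(aligned, c("glucose_t", "lactate_t", "lg_ratio"))
#>   variable  r_squared n_patients n_samples
#> 1 glucose_t     0.640         30      1519
#> 2 lactate_t     0.782         30      1519
#> 3 lg_ratio      0.342         30      1519
```

Subject identity alone explains 34–78% of marker variance — the long-term,
patient-specific character of MD. The permutation correlogram shows the
same thing from the time-series side:

```r
pg <- permute_within_subjects(aligned, "lg_ratio", "icp_hour",
                              max_lag = 10, B = 300, seed = 1)
pg[pg$lag %in% -2:2, c("lag", "r", "lo", "hi", "scramble_r")]
#>   lag    r   lo   hi scramble_r
#> 1  -2 0.13 0.10 0.14    0.00282
#> 2  -1 0.13 0.11 0.14    0.00022
#> 3   0 0.13 0.11 0.13    0.00175
#> 4   1 0.13 0.10 0.14    0.00190
#> 5   2 0.12 0.10 0.14    0.00232
```

The observed cross-correlation (~0.13 at every lag) sits *inside* the band
obtained by scrambling each patient's MD hours: the MD–ICP association here
carries no information beyond subject means (the cross-patient scramble
control near 0 confirms the correlation is real but between-subject). The
mixed model quantifies the within-subject side while accounting for the
residual autocorrelation:

```r
fit_reml(aligned, "icp_hour", c("glucose_t", "lg_ratio"), n_starts = 2)
#> REML mixed model: icp_hour ~ glucose_t + lg_ratio
#> n = 1519 rows, 30 patients
#> sigma_b = 3.6085  sigma = 1.1179  ...
#>          term  estimate std_error z_value   p_value
#> 1 (Intercept) 13.839190  0.672410 20.5815 4.021e-94
#> 2   glucose_t -0.151856  0.090912 -1.6704 9.485e-02
#> 3    lg_ratio  0.001897  0.002777  0.6829 4.947e-01
```

The between-patient SD (3.6 mmHg) dwarfs any marker effect: even an extreme
marker excursion predicts well under 1 mmHg of ICP change.

## The analysis workflow

`analysis/01_simulate_cohort.R` … `analysis/08_outcome.R` are thin numbered
drivers over the package that reproduce the full study flow on the default
synthetic cohort (simulate → preprocess → descriptive tables and lowess
fits → correlograms and identity variance → mixed models → RBF
cross-validation → short-term probes → outcome tests), each writing its
tables under `results/` and printing a short narrative of what it found.

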