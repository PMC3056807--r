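Package: neuromd
Title: Time-Series Analysis of Cerebral Microdialysis Against Intracranial
    and Perfusion Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating hourly cerebral microdialysis (MD) markers
    (glucose, lactate, pyruvate, glycerol and their ratios) to intracranial
    pressure (ICP) and cerebral perfusion pressure (CPP) in neurocritical-care
    cohorts, while respecting the strongly autocorrelated, subject-clustered
    structure of the data. Includes a synthetic cohort generator with
    configurable within-subject ARMA dynamics and between-subject variance;
    preprocessing (transfer-time shift, limiters, transforms, ratio
    computation, hour-prior pressure alignment, complete-set extraction);
    pooled binned summaries and lowess fits; auto- and cross-correlograms with
    within-subject permutation nulls and Monte-Carlo confidence bands;
    subject-identity variance decomposition; restricted maximum likelihood
    (REML) linear mixed models with ARMA(1,1) within-subject residual
    correlation implemented from the likelihood up; radial-basis-function
    network regression with leave-one-subject-out cross-validation and
    permuted controls; differenced and per-subject normalized short-term
    regressions with Cook's-distance screening; and Glasgow Outcome Scale
    comparisons by one-way ANOVA and Kruskal-Wallis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
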