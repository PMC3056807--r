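#!/usr/bin/env Rscript
# Simulate the default synthetic monitoring cohort (90 patients, ~84 hourly
# microdialysis samples each, minute-level ICP/MAP) and write it as tidy CSV.
suppressMessages(library(neuromd))

cfg <- cohort_config(seed = 1)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat("Simulated", nrow(cohort$patients), "patients:",
    sum(cohort$patients$location == "pericontusional"), "pericontusional /",
    sum(cohort$patients$location == "nonpericontusional"),
    "nonpericontusional\n")
cat("MD assay rows:", nrow(cohort$md),
    "| pressure samples:", nrow(cohort$pressures), "\n")
cat("Cohort CSVs written to results/cohort/\n")
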