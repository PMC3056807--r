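#!/usr/bin/env Rscript
# Clean and align the cohort: transfer-time shift (17 min), limiters,
# complete-set extraction, ratios, normalizing transforms, hour-prior
# pressure means.
suppressMessages(library(neuromd))

cohort <- read_cohort("results/cohort")
aligned <- preprocess_cohort(cohort)
readr::write_csv(aligned, "results/aligned.csv", progress = FALSE)

clamp <- attr(aligned, "clamp_log")
drops <- attr(aligned, "drop_report")
cat("Aligned complete MD hours:", nrow(aligned), "from",
    length(unique(aligned$patient_id)), "patients\n")
cat("Values clamped by limiters:", sum(clamp$n_clamped), "\n")
cat("Rows dropped (incomplete sets / pressure coverage):",
    sum(drops$dropped), "\n")
cat("Mean complete samples per patient:",
    round(mean(table(aligned$patient_id)), 1), "\n")
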