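#!/usr/bin/env Rscript
# Descriptive surfaces: pooled MD binned by ICP and CPP interval (with the
# per-patient-weighted variant), lowess scatter fits, and the
# time-since-insertion trend check.
suppressMessages(library(neuromd))

aligned <- readr::read_csv("results/aligned.csv", show_col_types = FALSE)

t1 <- bin_pooled(aligned, "icp")
t2 <- bin_pooled(aligned, "cpp")
readr::write_csv(t1, "results/table1_icp_bins.csv", progress = FALSE)
readr::write_csv(t2, "results/table2_cpp_bins.csv", progress = FALSE)
t1w <- bin_pooled(aligned, "icp", per_patient_weighted = TRUE)
readr::write_csv(t1w, "results/table1_icp_bins_patient_weighted.csv",
                 progress = FALSE)
cat("Binned tables written; note: pooled bins mix repeated measures from\n")
cat("the same patient and must be read descriptively only.\n")

lw <- lowess_fit(aligned$icp_hour, aligned$lg_ratio)
readr::write_csv(lw, "results/lowess_lg_ratio_vs_icp.csv", progress = FALSE)

tc <- trend_check(aligned)
readr::write_csv(tc$r_squared, "results/trend_r2.csv", progress = FALSE)
cat("Polynomial time-trend r^2 range:",
    round(min(tc$r_squared$r_squared), 4), "-",
    round(max(tc$r_squared$r_squared), 4),
    "| detrending changes prediction scores:",
    tc$detrending_matters, "\n")
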