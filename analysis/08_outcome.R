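#!/usr/bin/env Rscript
# Outcome: per-patient MD and pressure summaries vs best GOS score by
# one-way ANOVA and Kruskal-Wallis, excluding patients with < 12 h of MD.
suppressMessages(library(neuromd))

aligned <- readr::read_csv("results/aligned.csv", show_col_types = FALSE)
patients <- readr::read_csv("results/cohort/patients.csv",
                            show_col_types = FALSE)

ot <- build_outcome_table(aligned, patients, lp_threshold = 25)
readr::write_csv(ot, "results/outcome_table.csv", progress = FALSE)
cat("Included:", sum(ot$included), "of", nrow(ot), "patients (",
    sum(!ot$included), "excluded )\n")

sc <- outcome_screen(ot)
readr::write_csv(sc, "results/outcome_tests.csv", progress = FALSE)
cat("GOS groups:", attr(sc, "n_groups"), "\n")
print(as.data.frame(sc[, c("variable", "p_anova", "p_kruskal",
                           "concordant")]), row.names = FALSE, digits = 3)
sig <- sc$variable[sc$p_anova < 0.05 & sc$p_kruskal < 0.05]
cat("Concordantly significant vs GOS:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
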