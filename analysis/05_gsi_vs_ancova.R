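#!/usr/bin/env Rscript

# Stage 5: does the gonadosomatic index inflate tactic differences?
#
# Re-analyses the raw testes-allometry tables two ways — the GSI route
# (Hedges' d between per-individual 100*testes/soma values) and the ANCOVA
# route (testes mass on soma mass and tactic, partial eta-squared converted
# to Hedges' d) — and compares the paired estimates. Because the tables are
# generated with allometric slope 0.5, 2x body-size dimorphism and NO true
# tactic effect, any systematic difference between morphs is an artefact of
# the ratio measure.

library(artmeta)

in_dir <- file.path("results", "inputs", "allometry")
out_dir <- file.path("results", "gsi")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
tables <- lapply(files, read_allometry_table)
names(tables) <- sub("\\.csv$", "", basename(files))

rule <- direction_rule(high = "sneaker", low = "guarder")
cmp <- gsi_compare(tables, rule, alpha = 0.05)

cat(sprintf("N = %d studies\n", nrow(cmp$per_study)))
cat(sprintf("mean d (GSI route)    = %.2f\n", mean(cmp$per_study$d_gsi)))
cat(sprintf("mean d (ANCOVA route) = %.2f\n", mean(cmp$per_study$d_ancova)))
cat(sprintf("paired t(%d) = %.2f, p = %.3g\n",
            cmp$paired_test$df, cmp$paired_test$t, cmp$paired_test$p))
cat(sprintf("significant tactic difference: GSI %d/%d, ANCOVA %d/%d\n",
            cmp$counts$count_gsi_sig, cmp$counts$n_tables,
            cmp$counts$count_ancova_sig, cmp$counts$n_tables))

write.csv(cmp$per_study, file.path(out_dir, "gsi_compare.csv"), row.names = FALSE)
summary_row <- data.frame(
  n = cmp$paired_test$n, mean_d_gsi = mean(cmp$per_study$d_gsi),
  mean_d_ancova = mean(cmp$per_study$d_ancova),
  paired_t = cmp$paired_test$t, df = cmp$paired_test$df, p = cmp$paired_test$p,
  gsi_sig = cmp$counts$count_gsi_sig, ancova_sig = cmp$counts$count_ancova_sig)
write.csv(summary_row, file.path(out_dir, "gsi_summary.csv"), row.names = FALSE)
cat("tables written to", out_dir, "\n")
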