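#!/usr/bin/env Rscript

# Stage 4: publication-bias diagnostics.
#
# Two meta-regressions per trait dataset inside the same multilevel model:
# effect size on study precision (1/SE; a slope whose CI excludes zero
# flags funnel asymmetry / a small-study effect) and effect size on
# publication year (a CI entirely below zero flags a decline effect).

library(artmeta)

in_dir <- file.path("results", "inputs")
out_dir <- file.path("results", "bias")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

effects <- read_effects_table(file.path(in_dir, "effects.csv"))
tree <- ape::read.tree(file.path(in_dir, "tree.nwk"))
datasets <- split_by_trait(effects, tree, rho = 0.5)

rows <- list()
for (nm in names(datasets)) {
  ds <- datasets[[nm]]
  for (kind in c("precision", "time_lag")) {
    br <- if (kind == "precision") precision_regression(ds) else time_lag_regression(ds)
    cat(sprintf("%s / %s: slope = %.4f [%.4f, %.4f]%s\n", nm, br$covariate,
                br$slope, br$ci_low, br$ci_high,
                if (br$flagged) " <- flagged" else ""))
    rows[[paste(nm, kind)]] <- data.frame(
      dataset = nm, covariate = br$covariate, slope = br$slope,
      ci_low = br$ci_low, ci_high = br$ci_high, QM = br$QM, p = br$p,
      flagged = br$flagged)
  }
}
write.csv(do.call(rbind, rows), file.path(out_dir, "bias.csv"), row.names = FALSE)
cat("tables written to", out_dir, "\n")
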