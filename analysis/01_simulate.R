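#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Writes a complete fixture bundle — effect-size table, Newick tree and raw
# testes-allometry tables — under results/inputs/, emulating a cross-species
# dataset of post-mating trait comparisons between male alternative
# reproductive tactics: ~160 Hedges' d values over 40 species with crossed
# phylogeny/species/study/observation structure, plus 35 raw allometry
# studies with negative allometry (slope 0.5), 2x body-size dimorphism and
# no true tactic difference.

library(artmeta)

seed <- 20260924L
out_dir <- file.path("results", "inputs")

cfg <- sim_config(seed = seed, n_species = 40)
paths <- write_fixtures(out_dir, cfg, n_allometry = 35)

eff <- read_effects_table(paths$effects)
cat("wrote", nrow(eff), "effect sizes over",
    length(unique(eff$species)), "species and",
    length(unique(eff$study_id)), "studies\n")
cat("trait categories:\n")
print(table(eff$trait_category))
cat("allometry tables:", length(paths$allometry), "\n")
cat("bundle in", out_dir, "(see manifest.json for the configuration)\n")
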