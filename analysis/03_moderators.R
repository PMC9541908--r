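#!/usr/bin/env Rscript

# Stage 3: moderator meta-regressions, one at a time.
#
# For each trait dataset: categorical moderators (taxonomic group,
# fertilisation mode, tactic type, measurement) tested by the omnibus Q_M
# statistic with marginal R2; per-level mean effect sizes from the
# no-intercept refit; and the sneaker-frequency models (quadratic first,
# then linear). Levels with fewer than five effect sizes are excluded.

library(artmeta)

in_dir <- file.path("results", "inputs")
out_dir <- file.path("results", "moderators")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

effects <- read_effects_table(file.path(in_dir, "effects.csv"))
tree <- ape::read.tree(file.path(in_dir, "tree.nwk"))
datasets <- split_by_trait(effects, tree, rho = 0.5)

mods <- c("taxon_group", "fert_mode", "tactic_type", "measurement")
mod_rows <- list(); lvl_rows <- list()
for (nm in names(datasets)) {
  ds <- datasets[[nm]]
  for (mod in mods) {
    fit <- tryCatch(meta_regression(ds, mod, type = "categorical"),
                    error = function(e) NULL)
    if (is.null(fit)) {
      cat(sprintf("%s / %s: skipped (not enough usable levels)\n", nm, mod))
      next
    }
    cat(sprintf("%s / %s: k = %d, QM = %.2f (df %d), p = %.3g, R2 = %.3f\n",
                nm, mod, attr(fit, "data_k"), fit$QM, fit$QM_df, fit$QM_p,
                fit$R2_marginal))
    mod_rows[[paste(nm, mod)]] <- data.frame(
      dataset = nm, moderator = mod, k = attr(fit, "data_k"),
      QM = fit$QM, df = fit$QM_df, p = fit$QM_p, R2_marginal = fit$R2_marginal)
    lvl_rows[[paste(nm, mod)]] <- cbind(dataset = nm, level_means(ds, mod))
  }
  sf <- tryCatch(sneaker_frequency_models(ds), error = function(e) NULL)
  if (!is.null(sf)) {
    cat(sprintf("%s / sneaker_freq: quadratic term z = %.2f (p = %.3g); linear slope = %.2f [%.2f, %.2f]\n",
                nm, sf$quadratic_term$z, sf$quadratic_term$p,
                sf$linear$beta["sneaker_freq"], sf$linear$ci_low["sneaker_freq"],
                sf$linear$ci_high["sneaker_freq"]))
    for (w in c("linear", "quadratic")) {
      f <- sf[[w]]
      mod_rows[[paste(nm, "sneaker", w)]] <- data.frame(
        dataset = nm, moderator = paste0("sneaker_freq_", w),
        k = attr(f, "data_k"), QM = f$QM, df = f$QM_df, p = f$QM_p,
        R2_marginal = f$R2_marginal)
    }
  }
}
write.csv(do.call(rbind, mod_rows), file.path(out_dir, "moderators.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, lvl_rows), file.path(out_dir, "levels.csv"),
          row.names = FALSE)
cat("tables written to", out_dir, "\n")
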