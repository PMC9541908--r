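#' Split an effect-size table into per-trait datasets
#'
#' The analysis treats testes size, sperm quantity and sperm traits as
#' separate datasets, each fitted with its own appropriately pruned tree.
#'
#' @param effects Effect-size data frame with a \code{trait_category} column.
#' @param tree Tree covering all species.
#' @param rho Within-experiment correlation passed to
#'   \code{\link{meta_dataset}}.
#' @return Named list of \code{meta_dataset}s, one per non-empty category.
#' @export
split_by_trait <- function(effects, tree, rho = 0.5) {
  cats <- c("testes_size", "sperm_quantity", "sperm_trait")
  out <- list()
  for (cat in cats) {
    idx <- which(effects$trait_category == cat)
    if (length(idx) < 2) {
      if (length(idx) > 0) warning("category ", cat, " has < 2 effects; skipped")
      next
    }
    out[[cat]] <- meta_dataset(effects[idx, , drop = FALSE], tree, rho = rho)
  }
  if (length(out) == 0) stop("no trait category has >= 2 effect sizes")
  out
}

#' Filter a dataset by declarative row rules
#'
#' Applies measurement exclusions, tactic-type restrictions and optional
#' removal of directionless zeros, re-prunes the tree, and records the
#' effect count before and after. Filters that would empty the dataset are
#' an error.
#'
#' @param dataset A \code{\link{meta_dataset}}.
#' @param exclude_measurements Character vector of \code{measurement}
#'   values to drop.
#' @param keep_tactic_types If non-NULL, keep only these
#'   \code{tactic_type} values.
#' @param drop_directionless Drop rows flagged directionless.
#' @param exclude_species Character vector of species to drop.
#' @return A filtered \code{meta_dataset} with attribute \code{k_before}.
#' @export
subset_filters <- function(dataset, exclude_measurements = NULL,
                           keep_tactic_types = NULL,
                           drop_directionless = FALSE,
                           exclude_species = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  eff <- dataset$effects
  keep <- rep(TRUE, nrow(eff))
  if (!is.null(exclude_measurements)) {
    keep <- keep & !(eff$measurement %in% exclude_measurements)
  }
  if (!is.null(keep_tactic_types) && "tactic_type" %in% names(eff)) {
    keep <- keep & eff$tactic_type %in% keep_tactic_types
  }
  if (drop_directionless && "directionless" %in% names(eff)) {
    keep <- keep & !eff$directionless
  }
  if (!is.null(exclude_species)) {
    keep <- keep & !(eff$species %in% exclude_species)
  }
  if (sum(keep) < 2) stop("filter leaves fewer than two effect sizes")
  if (all(keep)) {
    out <- dataset
  } else {
    out <- subset_dataset(dataset, which(keep))
  }
  attr(out, "k_before") <- nrow(eff)
  out
}

#' Run the full analysis over every trait category
#'
#' For each trait category present in the effects table: the intercept-only
#' pooled fit with its heterogeneity partition, one meta-regression per
#' moderator (one at a time), the sneaker-frequency quadratic/linear pair,
#' the sensitivity suite, and both publication-bias diagnostics. When
#' allometry tables are supplied the GSI-versus-ANCOVA comparison is run
#' too. Stage failures are logged per dataset and do not abort the
#' remaining stages. All result tables are written as CSV under
#' \code{output_dir} together with a JSON run manifest.
#'
#' @param effects Effect-size data frame (or path to an interchange CSV).
#' @param tree \code{phylo} object (or path to a Newick file).
#' @param allometry_tables Optional named list of allometry tables (or a
#'   directory of CSVs).
#' @param rho Within-experiment correlation.
#' @param alpha Significance level used in the allometry comparison.
#' @param moderators Moderator columns to test (categorical unless named
#'   \code{sneaker_freq}).
#' @param output_dir Optional directory for CSV outputs; when NULL nothing
#'   is written.
#' @param direction High/low tactic labels for the allometry comparison.
#' @param seed Optional seed recorded in the manifest.
#' @return A list with per-category results (\code{fits}), the allometry
#'   comparison (\code{gsi}), accumulated \code{errors}, and the paths of
#'   written tables.
#' @export
run_all <- function(effects, tree, allometry_tables = NULL, rho = 0.5,
                    alpha = 0.05,
                    moderators = c("taxon_group", "fert_mode", "tactic_type",
                                   "measurement"),
                    output_dir = NULL, direction = c("sneaker", "guarder"),
                    seed = NULL) {
  if (is.character(effects)) effects <- read_effects_table(effects)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.null(tree)) stop("a phylogenetic tree is required")
  if (is.character(allometry_tables)) {
    files <- list.files(allometry_tables, pattern = "\\.csv$", full.names = TRUE)
    allometry_tables <- lapply(files, read_allometry_table)
    names(allometry_tables) <- sub("\\.csv$", "", basename(files))
  }

  datasets <- split_by_trait(effects, tree, rho = rho)
  errors <- character(0)
  note <- function(where, e) {
    errors <<- c(errors, sprintf("%s: %s", where, conditionMessage(e)))
    NULL
  }

  fit_rows <- list(); mod_rows <- list(); level_rows <- list()
  bias_rows <- list(); sens_rows <- list(); fits <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    res <- list()
    res$pooled <- tryCatch(fit_reml(ds), error = function(e) note(paste(nm, "pooled"), e))
    if (!is.null(res$pooled)) {
      het <- i2_partition(res$pooled)
      fit_rows[[nm]] <- data.frame(
        dataset = nm, k = ds$k, mean_d = unname(res$pooled$beta[1]),
        ci_low = unname(res$pooled$ci_low[1]), ci_high = unname(res$pooled$ci_high[1]),
        I2_total = het$I2_total,
        I2_phylogeny = het$I2_partition[["phylogeny"]],
        I2_species = het$I2_partition[["species"]],
        I2_study = het$I2_partition[["study"]],
        I2_observation = het$I2_partition[["observation"]],
        stringsAsFactors = FALSE
      )
      res$heterogeneity <- het
    }
    res$moderators <- list()
    for (mod in moderators) {
      if (!mod %in% names(ds$effects)) next
      fit <- tryCatch(meta_regression(ds, mod, type = "categorical"),
                      error = function(e) note(paste(nm, mod), e))
      if (is.null(fit)) next
      res$moderators[[mod]] <- fit
      mod_rows[[paste(nm, mod)]] <- data.frame(
        dataset = nm, moderator = mod, k = attr(fit, "data_k"),
        QM = fit$QM, df = fit$QM_df, p = fit$QM_p,
        R2_marginal = fit$R2_marginal, stringsAsFactors = FALSE
      )
      lv <- tryCatch(level_means(ds, mod), error = function(e) note(paste(nm, mod, "levels"), e))
      if (!is.null(lv)) {
        lv <- cbind(dataset = nm, lv)
        level_rows[[paste(nm, mod)]] <- lv
      }
    }
    if ("sneaker_freq" %in% names(ds$effects) &&
        sum(!is.na(ds$effects$sneaker_freq)) >= 5) {
      res$sneaker <- tryCatch(sneaker_frequency_models(ds),
                              error = function(e) note(paste(nm, "sneaker_freq"), e))
      if (!is.null(res$sneaker)) {
        for (which_m in c("linear", "quadratic")) {
          f <- res$sneaker[[which_m]]
          mod_rows[[paste(nm, "sneaker", which_m)]] <- data.frame(
            dataset = nm, moderator = paste0("sneaker_freq_", which_m),
            k = attr(f, "data_k"), QM = f$QM, df = f$QM_df, p = f$QM_p,
            R2_marginal = f$R2_marginal, stringsAsFactors = FALSE
          )
        }
      }
    }
    res$sensitivity <- tryCatch(sensitivity_suite(ds),
                                error = function(e) note(paste(nm, "sensitivity"), e))
    if (!is.null(res$sensitivity)) {
      sens_rows[[nm]] <- cbind(dataset = nm, res$sensitivity)
    }
    for (fn in c("precision", "time_lag")) {
      br <- tryCatch(
        if (fn == "precision") precision_regression(ds) else time_lag_regression(ds),
        error = function(e) note(paste(nm, fn), e))
      if (!is.null(br)) {
        res[[paste0("bias_", fn)]] <- br
        bias_rows[[paste(nm, fn)]] <- data.frame(
          dataset = nm, covariate = br$covariate, slope = br$slope,
          ci_low = br$ci_low, ci_high = br$ci_high, QM = br$QM, p = br$p,
          stringsAsFactors = FALSE
        )
      }
    }
    fits[[nm]] <- res
  }

  gsi <- NULL
  if (!is.null(allometry_tables) && length(allometry_tables) > 0) {
    rule <- direction_rule(high = direction[1], low = direction[2])
    gsi <- tryCatch(gsi_compare(allometry_tables, rule, alpha = alpha),
                    error = function(e) note("gsi_compare", e))
  }

  out <- list(
    fits = fits, gsi = gsi, errors = errors,
    tables = list(
      fit_summary = do.call(rbind, unname(fit_rows)),
      moderators = do.call(rbind, unname(mod_rows)),
      levels = do.call(rbind, unname(level_rows)),
      bias = do.call(rbind, unname(bias_rows)),
      sensitivity = do.call(rbind, unname(sens_rows)),
      gsi_compare = if (!is.null(gsi)) gsi$per_study else NULL
    )
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (nm in names(out$tables)) {
      tab <- out$tables[[nm]]
      if (is.null(tab)) next
      p <- file.path(output_dir, paste0(nm, ".csv"))
      utils::write.csv(tab, p, row.names = FALSE)
      paths[nm] <- p
    }
    manifest <- list(
      seed = seed, rho = rho, alpha = alpha,
      k_total = nrow(effects),
      datasets = lapply(datasets, function(d) d$k),
      moderators = moderators,
      r_version = as.character(getRversion()),
      errors = errors,
      tables = as.list(paths)
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
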