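#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator. The defaults describe a dataset of
#' the size and structure typical of cross-species syntheses of alternative
#' reproductive tactics: a few hundred effect sizes over tens of species,
#' moderate heterogeneity at every grouping level, sampling variances in
#' the range usual for d-based effect sizes, and a sneaker-male frequency
#' distribution centred near 0.4.
#'
#' @param seed Integer seed fixing the whole stream (optional; when NULL the
#'   current RNG state is used).
#' @param n_species Number of species (tips of the simulated tree).
#' @param studies_per_species Integer vector sampled from (uniformly) for
#'   the number of studies per species; a single value gives a fixed count.
#' @param effects_per_study As above, effects per study.
#' @param beta True fixed effect(s). A single number simulates a common mean;
#'   a named list \code{list(intercept=, slope=, moderator=)} adds a linear
#'   moderator effect.
#' @param sigma2 Named true variance components
#'   (\code{phylogeny, species, study, observation}).
#' @param rho_true Within-experiment correlation of the sampling errors.
#' @param v_range Range of sampling variances (drawn uniformly).
#' @param prop_multi_effect_experiments Fraction of studies whose effects
#'   share one experiment id (same male sample) rather than being singletons.
#' @param taxon_probs Named probabilities for the taxonomic-group moderator.
#' @param fert_probs Named probabilities for fertilisation mode.
#' @param tactic_probs Named probabilities for tactic type.
#' @param sneaker_shape Beta-distribution shape parameters (length 2) for
#'   species sneaker frequency.
#' @param year_range Publication-year range.
#' @param allometry List of allometric-simulation defaults: \code{slope}
#'   (log-log allometric slope b), \code{intercept} (log(a) for the
#'   reference tactic), \code{dimorphism} (ratio of guarder to sneaker body
#'   mass), \code{sdlog} (residual SD on the log scale), \code{n_per_tactic},
#'   \code{body_meanlog}, \code{body_sdlog}.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = NULL,
                       n_species = 40,
                       studies_per_species = 1:3,
                       effects_per_study = 1:3,
                       beta = 0.4,
                       sigma2 = c(phylogeny = 0.2, species = 0.1,
                                  study = 0.1, observation = 0.05),
                       rho_true = 0.5,
                       v_range = c(0.05, 0.5),
                       prop_multi_effect_experiments = 0.5,
                       taxon_probs = c(fish = 0.7, invertebrate = 0.2, other_vertebrate = 0.1),
                       fert_probs = c(external = 0.7, internal = 0.3),
                       tactic_probs = c(fixed = 0.45, state_dependent = 0.45, plastic = 0.1),
                       sneaker_shape = c(2, 3),
                       year_range = c(1990, 2020),
                       allometry = list(slope = 0.5, intercept = -3,
                                        dimorphism = 2, sdlog = 0.15,
                                        n_per_tactic = 30,
                                        body_meanlog = 2, body_sdlog = 0.2)) {
  if (any(sigma2 < 0)) stop("variance components must be >= 0")
  if (rho_true < 0 || rho_true >= 1) stop("rho_true must lie in [0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology with the pipeline's branch-length contract
#' already applied: unit branch lengths followed by the Grafen transform,
#' so the output is ultrametric with depth 1 and feeds straight into
#' \code{\link{vcv_from_tree}}.
#'
#' @param n_species Number of tips (>= 2). Tips are labelled
#'   \code{sp01, sp02, ...}.
#' @param seed Optional integer seed.
#' @return A \code{phylo} object.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (n_species < 2) stop("need >= 2 species")
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
    grafen_transform(unit_branch_lengths(tree))
  })
}

#' Simulate an effect-size dataset with the full model structure
#'
#' Draws \code{y_i = x_i' beta + a_sp(i) + b_sp(i) + c_study(i) + e_i +
#' eps_i}: a phylogeny-correlated species effect \code{a ~ N(0,
#' sigma2_phylo A)}, iid species, study and observation effects, and
#' sampling errors \code{eps} with variances drawn from \code{v_range} and
#' correlation \code{rho_true} within an experiment. Moderators (taxonomic
#' group, fertilisation mode, tactic type, sneaker frequency, publication
#' year, trait category, measurement) are attached at the species, study or
#' observation level as appropriate.
#'
#' @param config A \code{\link{sim_config}}.
#' @param tree Optional tree (simulated from the config when NULL).
#' @return A \code{\link{meta_dataset}} whose effects table also stores the
#'   true row means in \code{true_mu}.
#' @export
simulate_effects <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    if (is.null(tree)) {
      tree <- simulate_tree(config$n_species)
    }
    sp_names <- tree$tip.label
    S <- length(sp_names)
    A <- vcv_from_tree(tree)

    a <- drop(crossprod(chol(A + diag(1e-10, S)),
                        stats::rnorm(S, 0, sqrt(config$sigma2[["phylogeny"]]))))
    b <- stats::rnorm(S, 0, sqrt(config$sigma2[["species"]]))

    draw_count <- function(choices) {
      if (length(choices) == 1) choices else sample(choices, 1)
    }
    sp_taxon <- sample(names(config$taxon_probs), S, TRUE, config$taxon_probs)
    sp_fert <- sample(names(config$fert_probs), S, TRUE, config$fert_probs)
    sp_tactic <- sample(names(config$tactic_probs), S, TRUE, config$tactic_probs)
    sp_freq <- stats::rbeta(S, config$sneaker_shape[1], config$sneaker_shape[2])

    beta <- config$beta
    has_mod <- is.list(beta)

    rows <- list(); study_counter <- 0L
    for (s in seq_len(S)) {
      n_st <- draw_count(config$studies_per_species)
      for (st in seq_len(n_st)) {
        study_counter <- study_counter + 1L
        study_id <- sprintf("study%03d", study_counter)
        c_st <- stats::rnorm(1, 0, sqrt(config$sigma2[["study"]]))
        year <- sample(seq(config$year_range[1], config$year_range[2]), 1)
        n_eff <- draw_count(config$effects_per_study)
        shared <- n_eff > 1 &&
          stats::runif(1) < config$prop_multi_effect_experiments
        exp_id <- if (shared) paste0(study_id, "_exp1") else NA_character_
        v <- stats::runif(n_eff, config$v_range[1], config$v_range[2])
        if (shared && config$rho_true > 0) {
          R <- matrix(config$rho_true, n_eff, n_eff); diag(R) <- 1
          Sv <- diag(sqrt(v), n_eff) %*% R %*% diag(sqrt(v), n_eff)
          eps <- drop(crossprod(chol(Sv), stats::rnorm(n_eff)))
        } else {
          eps <- stats::rnorm(n_eff, 0, sqrt(v))
        }
        for (j in seq_len(n_eff)) {
          e_obs <- stats::rnorm(1, 0, sqrt(config$sigma2[["observation"]]))
          xmod <- if (has_mod) stats::runif(1) else NA_real_
          mu_fix <- if (has_mod) beta$intercept + beta$slope * xmod else beta
          rows[[length(rows) + 1L]] <- data.frame(
            observation_id = sprintf("obs%04d", length(rows) + 1L),
            study_id = study_id,
            experiment_id = if (shared) exp_id else sprintf("%s_e%d", study_id, j),
            species = sp_names[s],
            trait_category = sample(c("testes_size", "sperm_quantity", "sperm_trait"), 1,
                                    prob = c(0.3, 0.2, 0.5)),
            measurement = NA_character_,
            d = mu_fix + a[s] + b[s] + c_st + e_obs + eps[j],
            var = v[j],
            directionless = FALSE,
            taxon_group = sp_taxon[s],
            fert_mode = sp_fert[s],
            tactic_type = sp_tactic[s],
            sneaker_freq = sp_freq[s],
            pub_year = year,
            true_mu = mu_fix,
            moderator_x = xmod,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    effects <- do.call(rbind, rows)
    effects$measurement <- ifelse(
      effects$trait_category == "testes_size",
      sample(c("GSI", "relative_testes"), nrow(effects), TRUE, c(0.6, 0.4)),
      ifelse(effects$trait_category == "sperm_quantity",
             sample(c("sperm_number", "sperm_density", "sperm_volume"),
                    nrow(effects), TRUE),
             sample(c("length", "speed", "longevity", "atp", "motile_viable"),
                    nrow(effects), TRUE)))
    effects$se <- sqrt(effects$var)
    meta_dataset(effects, tree, rho = config$rho_true)
  })
}

#' Simulate an individual-level testes allometry table
#'
#' Draws log-normal body masses per tactic (with the configured guarder-to-
#' sneaker dimorphism ratio) and testes masses from the allometric law
#' \code{log(testes) = intercept + tactic_effect + slope * log(body) +
#' N(0, sdlog^2)}, with \code{tactic_effect} added for the sneaker tactic.
#' With a slope below 1 and body-size dimorphism, the GSI of the smaller
#' morph is inflated even when \code{tactic_effect = 0} (GSI is
#' proportional to \code{body^(slope - 1)}).
#'
#' @param config A \code{\link{sim_config}} (its \code{allometry} entry is
#'   used) or a bare list with the same fields.
#' @param tactic_effect Shift in log intercept for the sneaker tactic
#'   (default 0: no true investment difference).
#' @param seed Optional integer seed.
#' @param tactics Labels for the two morphs (larger morph first).
#' @return An allometry table (data frame).
#' @export
simulate_allometry <- function(config, tactic_effect = 0, seed = NULL,
                               tactics = c("guarder", "sneaker")) {
  al <- if (inherits(config, "sim_config")) config$allometry else config
  if (al$slope <= 0) stop("allometric slope must be > 0")
  with_seed(seed, {
    n <- al$n_per_tactic
    body_g <- stats::rlnorm(n, al$body_meanlog + log(al$dimorphism), al$body_sdlog)
    body_s <- stats::rlnorm(n, al$body_meanlog, al$body_sdlog)
    testes_g <- exp(al$intercept + al$slope * log(body_g) +
                      stats::rnorm(n, 0, al$sdlog))
    testes_s <- exp(al$intercept + tactic_effect + al$slope * log(body_s) +
                      stats::rnorm(n, 0, al$sdlog))
    tab <- data.frame(
      individual_id = sprintf("ind%03d", seq_len(2 * n)),
      tactic = rep(tactics, each = n),
      body_mass = c(body_g, body_s),
      testes_mass = c(testes_g, testes_s),
      stringsAsFactors = FALSE
    )
    if (any(tab$testes_mass >= tab$body_mass)) {
      stop("simulated testes mass >= body mass; lower the intercept or noise")
    }
    tab
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Emits the effect-size table, the Newick tree, a directory of allometry
#' tables and a JSON manifest (config and seed) in the pipeline's
#' interchange formats, so that every downstream stage can run from files
#' alone. Re-running with the manifest's seed reproduces the files
#' byte-identically.
#'
#' @param output_dir Directory (created if needed).
#' @param config A \code{\link{sim_config}} with a non-NULL seed.
#' @param n_allometry Number of allometry study tables to write.
#' @return Invisibly, the list of written paths.
#' @export
write_fixtures <- function(output_dir, config, n_allometry = 6) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("config must carry a seed for reproducible fixtures")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  allo_dir <- file.path(output_dir, "allometry")
  dir.create(allo_dir, showWarnings = FALSE)

  ds <- simulate_effects(config)
  eff_path <- file.path(output_dir, "effects.csv")
  write_effects_table(ds$effects, eff_path)
  tree_path <- file.path(output_dir, "tree.nwk")
  ape::write.tree(ds$tree, tree_path)
  allo_paths <- character(n_allometry)
  for (i in seq_len(n_allometry)) {
    tab <- simulate_allometry(config, seed = config$seed + i)
    allo_paths[i] <- file.path(allo_dir, sprintf("allometry_%02d.csv", i))
    utils::write.csv(tab, allo_paths[i], row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    seed = config$seed,
    n_species = config$n_species,
    sigma2 = as.list(config$sigma2),
    beta = config$beta,
    rho_true = config$rho_true,
    v_range = config$v_range,
    allometry = config$allometry,
    files = list(effects = basename(eff_path), tree = basename(tree_path),
                 allometry = file.path("allometry", basename(allo_paths)))
  )
  man_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(effects = eff_path, tree = tree_path,
                 allometry = allo_paths, manifest = man_path))
}
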