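test_that("the marginal covariance assembles exactly as specified", {
  ds <- make_tiny_dataset(k = 8, seed = 31, rho = 0)
  # all components zero: Sigma is the diagonal of sampling variances
  S0 <- build_covariance(ds, c(phylogeny = 0, species = 0, study = 0, observation = 0))
  expect_equal(S0, diag(ds$effects$var, 8))

  # two effects sharing one experiment at rho = 0.5 and v = 0.2 each:
  # off-diagonal 0.1
  tree <- grafen_transform(unit_branch_lengths(ape::read.tree(text = "(A,B);")))
  eff <- data.frame(observation_id = c("o1", "o2"), study_id = "s1",
                    experiment_id = "s1_e1", species = c("A", "B"),
                    d = c(0.1, 0.2), var = c(0.2, 0.2))
  ds2 <- meta_dataset(eff, tree, rho = 0.5)
  expect_equal(ds2$V[1, 2], 0.1)

  # symmetric PSD at random admissible component values
  set.seed(32)
  for (i in 1:8) {
    dsr <- make_tiny_dataset(k = 10, seed = 100 + i, rho = 0.5,
                             shared_experiments = TRUE)
    th <- runif(4, 0, 1)
    S <- build_covariance(dsr, c(phylogeny = th[1], species = th[2],
                                 study = th[3], observation = th[4]))
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(build_covariance(ds, c(phylo_typo = 1)), "unknown")
})

test_that("species absent from the tree are rejected", {
  tree <- grafen_transform(unit_branch_lengths(ape::rtree(3)))
  tree$tip.label <- c("a", "b", "c")
  eff <- data.frame(observation_id = 1:2, study_id = "s", species = c("a", "zz"),
                    d = c(0, 1), var = c(0.1, 0.1))
  expect_error(meta_dataset(eff, tree), "missing from tree")
})

test_that("with variance components fixed at zero the fit is the weighted mean", {
  set.seed(33)
  for (i in 1:10) {
    ds <- make_tiny_dataset(k = sample(5:15, 1), seed = 200 + i, rho = 0)
    fit <- fit_reml(ds, fix_sigma2 = c(phylogeny = 0, species = 0,
                                       study = 0, observation = 0))
    w <- 1 / ds$effects$var
    expect_equal(unname(fit$beta[1]), sum(w * ds$effects$d) / sum(w),
                 tolerance = 1e-10)
    expect_equal(unname(fit$se_beta[1]), sqrt(1 / sum(w)), tolerance = 1e-10)
  }
})

test_that("two symmetric effects pool to their common value", {
  tree <- grafen_transform(unit_branch_lengths(ape::read.tree(text = "(A,B);")))
  eff <- data.frame(observation_id = c("o1", "o2"), study_id = c("s1", "s2"),
                    species = c("A", "B"), d = c(0.5, 0.5), var = c(0.3, 0.3))
  ds <- meta_dataset(eff, tree, rho = 0)
  fit <- fit_reml(ds, fix_sigma2 = c(phylogeny = 0, species = 0,
                                     study = 0, observation = 0))
  expect_equal(unname(fit$beta[1]), 0.5, tolerance = 1e-12)
})

test_that("the REML optimum is at least as good as a brute-force grid", {
  # a denser sweep runs in the acceptance suite; here a few instances
  for (i in 1:4) {
    ds <- make_tiny_dataset(k = sample(8:12, 1), seed = 300 + i, rho = 0)
    fit <- fit_reml(ds)
    grid_best <- oracle_grid_min(ds)
    expect_lte(fit$deviance, grid_best + 1e-4)
  }
})

test_that("estimates agree with an independent multilevel implementation", {
  skip_if_not_installed("metafor")
  cfg <- sim_config(seed = 42, n_species = 15, studies_per_species = 1:2,
                    effects_per_study = 1:2)
  ds <- simulate_effects(cfg)
  eff <- ds$effects
  eff$phylo <- eff$species
  eff$sp2 <- eff$species
  m <- metafor::rma.mv(d, V = ds$V,
                       random = list(~1 | phylo, ~1 | sp2, ~1 | study_id,
                                     ~1 | observation_id),
                       R = list(phylo = vcv_from_tree(ds$tree)),
                       data = eff, method = "REML")
  fit <- fit_reml(ds)
  expect_equal(unname(fit$beta[1]), unname(coef(m)), tolerance = 1e-4)
  expect_equal(unname(fit$se_beta[1]), unname(m$se), tolerance = 1e-4)
  expect_equal(unname(fit$sigma2), unname(m$sigma2), tolerance = 1e-3)
})

test_that("heterogeneity partition follows the multilevel I2 definition", {
  ds <- make_tiny_dataset(k = 10, seed = 41, rho = 0)
  # all components zero: no heterogeneity
  fit0 <- fit_reml(ds, fix_sigma2 = c(phylogeny = 0, species = 0,
                                      study = 0, observation = 0))
  expect_equal(i2_partition(fit0)$I2_total, 0)

  # equal sampling variances v: typical s2 = v, so one component equal to v
  # gives I2 = 50%
  tree <- grafen_transform(unit_branch_lengths(ape::rtree(4)))
  tree$tip.label <- paste0("sp", 1:4)
  eff <- data.frame(observation_id = paste0("o", 1:8), study_id = paste0("s", 1:8),
                    species = rep(tree$tip.label, 2),
                    d = rnorm(8), var = 0.25)
  dse <- meta_dataset(eff, tree, rho = 0)
  fit50 <- fit_reml(dse, fix_sigma2 = c(phylogeny = 0, species = 0,
                                        study = 0, observation = 0.25))
  het <- i2_partition(fit50)
  expect_equal(het$s2, 0.25, tolerance = 1e-12)
  expect_equal(het$I2_total, 50, tolerance = 1e-10)
  expect_equal(unname(het$I2_partition[["observation"]]), 50, tolerance = 1e-10)

  # partition entries are nonnegative and sum exactly to the total
  fit <- fit_reml(ds)
  h <- i2_partition(fit)
  expect_true(all(h$I2_partition >= 0))
  expect_equal(sum(h$I2_partition), h$I2_total, tolerance = 1e-6)
})

test_that("meta-regression: Q_M, level filtering and level means", {
  cfg <- sim_config(seed = 55, n_species = 20, studies_per_species = 2,
                    effects_per_study = 2)
  ds <- simulate_effects(cfg)

  fit <- meta_regression(ds, "taxon_group", type = "categorical")
  expect_true(is.finite(fit$QM))
  expect_gte(fit$QM_df, 1)
  expect_true(fit$R2_marginal >= 0 && fit$R2_marginal <= 1)

  # levels with fewer than five effects are dropped before fitting
  eff <- ds$effects
  eff$rare_mod <- eff$taxon_group
  eff$rare_mod[1:3] <- "rare_level"
  eff$rare_mod[-(1:3)] <- "common_level"
  ds2 <- meta_dataset(eff, ds$tree, rho = 0.5)
  expect_error(meta_regression(ds2, "rare_mod", type = "categorical"),
               "fewer than two levels")

  lv <- level_means(ds, "taxon_group")
  expect_true(all(lv$k >= 5))
  expect_true(all(lv$ci_low < lv$mean_d & lv$mean_d < lv$ci_high))
  expect_equal(sum(lv$k), attr(meta_regression(ds, "taxon_group"), "data_k"))

  expect_error(meta_regression(ds, "no_such_column"), "not found")
})

test_that("a null moderator shows no association; shuffling preserves that", {
  # moderator assigned independently of y: QM should not be extreme, and a
  # continuous moderator with an injected slope is recovered
  cfg <- sim_config(seed = 77, n_species = 25, studies_per_species = 2,
                    effects_per_study = 2,
                    beta = list(intercept = 0.1, slope = 0.8, moderator = "x"))
  ds <- simulate_effects(cfg)
  fit <- meta_regression(ds, "moderator_x", type = "continuous")
  expect_lt(abs(unname(fit$beta["moderator_x"]) - 0.8),
            2.5 * unname(fit$se_beta["moderator_x"]))

  # destroying the association by permutation drops the slope toward zero
  set.seed(1)
  eff <- ds$effects
  eff$moderator_x <- sample(eff$moderator_x)
  ds_perm <- meta_dataset(eff, ds$tree, rho = 0.5)
  fit_perm <- meta_regression(ds_perm, "moderator_x", type = "continuous")
  expect_lt(abs(unname(fit_perm$beta["moderator_x"])),
            abs(unname(fit$beta["moderator_x"])))
})

test_that("sneaker-frequency models fit quadratic then linear", {
  cfg <- sim_config(seed = 88, n_species = 25, studies_per_species = 2,
                    effects_per_study = 2)
  ds <- simulate_effects(cfg)
  res <- sneaker_frequency_models(ds)
  expect_s3_class(res$quadratic, "meta_fit")
  expect_s3_class(res$linear, "meta_fit")
  expect_true(is.finite(res$quadratic_term$z))
  expect_equal(res$quadratic_term$p,
               2 * pnorm(-abs(res$quadratic_term$z)), tolerance = 1e-12)
  expect_equal(res$linear$p, 2)   # intercept + slope

  # fewer than 3 distinct frequencies: quadratic impossible
  eff <- ds$effects
  eff$sneaker_freq <- rep(c(0.2, 0.6), length.out = nrow(eff))
  ds2 <- meta_dataset(eff, ds$tree, rho = 0.5)
  expect_error(meta_regression(ds2, "sneaker_freq", type = "quadratic"),
               "3 distinct")
})

test_that("sensitivity variants behave as the data dictate", {
  # no directionless rows and no shared experiments: variant (i) and the
  # rho profile all equal the base fit
  ds <- make_tiny_dataset(k = 12, seed = 91, rho = 0.5, shared_experiments = FALSE)
  ds$effects$directionless <- FALSE
  tab <- sensitivity_suite(ds)
  base <- tab[tab$variant == "base", ]
  expect_equal(tab[tab$variant == "no_directionless", "mean_d"], base$mean_d)
  for (v in c("rho_0.25", "rho_0.50", "rho_0.75")) {
    expect_equal(tab[tab$variant == v, "mean_d"], base$mean_d, tolerance = 1e-6)
  }

  # dropping directionless zeros changes k
  ds2 <- make_tiny_dataset(k = 12, seed = 92, rho = 0)
  ds2$effects$directionless <- rep(c(TRUE, FALSE), each = 6)
  ds2 <- meta_dataset(ds2$effects, ds2$tree, rho = 0)
  tab2 <- sensitivity_suite(ds2)
  expect_equal(tab2[tab2$variant == "no_directionless", "k"], 6)

  # species exclusion variant appears when requested
  sp <- ds2$effects$species[1]
  tab3 <- sensitivity_suite(ds2, exclude_species = sp)
  expect_true("species_excluded" %in% tab3$variant)
  expect_lt(tab3[tab3$variant == "species_excluded", "k"], 12)
})
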