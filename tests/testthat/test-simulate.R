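test_that("simulated trees meet the pipeline tree contract", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_error(simulate_tree(1), ">= 2")

  tr <- simulate_tree(12, seed = 3)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  v <- vcv_from_tree(tr)  # passes validation
  expect_equal(unname(diag(v)), rep(1, 12))

  # same seed, same Newick string
  expect_identical(ape::write.tree(simulate_tree(12, seed = 3)),
                   ape::write.tree(tr))
})

test_that("the effect generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, n_species = 10)
  a <- simulate_effects(cfg)
  b <- simulate_effects(cfg)
  expect_identical(a$effects, b$effects)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("pure noise: with all components zero the sample moments match", {
  cfg <- sim_config(seed = 12, n_species = 40, studies_per_species = 3,
                    effects_per_study = 3, beta = 0,
                    sigma2 = c(phylogeny = 0, species = 0, study = 0, observation = 0),
                    v_range = c(0.2, 0.2), prop_multi_effect_experiments = 0)
  ds <- simulate_effects(cfg)
  expect_lt(abs(mean(ds$effects$d)), 3 * sqrt(0.2 / ds$k))
  expect_equal(stats::var(ds$effects$d), 0.2, tolerance = 0.35)
})

test_that("strong phylogenetic signal correlates sister-species effects", {
  # fully pectinate tree: compare sister pairs against distant pairs over
  # replicates
  cfg <- sim_config(seed = NULL, n_species = 20, studies_per_species = 1,
                    effects_per_study = 1, beta = 0,
                    sigma2 = c(phylogeny = 1, species = 0, study = 0, observation = 0),
                    v_range = c(0.01, 0.01))
  set.seed(13)
  comb <- grafen_transform(unit_branch_lengths(
    ape::stree(20, type = "left")))
  comb$tip.label <- sprintf("sp%02d", 1:20)
  A <- vcv_from_tree(comb)
  # most correlated tip pair anywhere in the tree, and the tip least
  # correlated with the first member of that pair
  Au <- A; Au[lower.tri(Au, diag = TRUE)] <- -Inf
  idx <- which(Au == max(Au), arr.ind = TRUE)[1, ]
  t1 <- rownames(A)[idx[1]]; t2 <- colnames(A)[idx[2]]
  far_tip <- names(which.min(A[t1, setdiff(rownames(A), c(t1, t2))]))
  x1 <- x2 <- xfar <- numeric(60)
  for (r in 1:60) {
    ds <- simulate_effects(cfg, tree = comb)
    eff <- ds$effects
    x1[r] <- eff$d[eff$species == t1]
    x2[r] <- eff$d[eff$species == t2]
    xfar[r] <- eff$d[eff$species == far_tip]
  }
  expect_gt(cor(x1, x2), 0.3)
  expect_gt(cor(x1, x2), cor(x1, xfar))
})

test_that("allometry generator: scale-free case and negative-allometry sign", {
  cfg <- sim_config(seed = 14)
  cfg$allometry$slope <- 1
  cfg$allometry$dimorphism <- 1
  tab_iso <- simulate_allometry(cfg, seed = 14)
  g <- gsi(tab_iso$testes_mass, soma_mass(tab_iso$body_mass, tab_iso$testes_mass))
  m <- tapply(g, tab_iso$tactic, mean)
  expect_lt(abs(m[["sneaker"]] - m[["guarder"]]),
            3 * stats::sd(g) / sqrt(nrow(tab_iso) / 2) * sqrt(2))

  # slope 0.5, guarders twice the body mass: GSI of the smaller morph higher
  cfg2 <- sim_config(seed = 15)
  gm <- sapply(1:20, function(i) {
    tab <- simulate_allometry(cfg2, seed = 500 + i)
    g <- gsi(tab$testes_mass, soma_mass(tab$body_mass, tab$testes_mass))
    diff(tapply(g, tab$tactic, mean)[c("guarder", "sneaker")])
  })
  expect_gt(mean(gm), 0)

  expect_identical(simulate_allometry(cfg2, seed = 9), simulate_allometry(cfg2, seed = 9))
  cfg_bad <- sim_config(seed = 16)
  cfg_bad$allometry$intercept <- 5   # testes would exceed body mass
  expect_error(simulate_allometry(cfg_bad, seed = 1), "testes mass")
})

test_that("fixture bundles round-trip losslessly and regenerate byte-identically", {
  dir1 <- withr::local_tempdir()
  cfg <- sim_config(seed = 17, n_species = 8)
  paths <- write_fixtures(dir1, cfg, n_allometry = 2)

  eff <- read_effects_table(paths$effects)
  tree <- ape::read.tree(paths$tree)
  ds <- meta_dataset(eff, tree, rho = 0.5)   # loads cleanly through the readers
  expect_equal(ds$k, nrow(eff))
  tab <- read_allometry_table(paths$allometry[1])
  expect_true(all(c("tactic", "body_mass", "testes_mass") %in% names(tab)))

  man <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(man$seed, 17)
  dir2 <- withr::local_tempdir()
  cfg2 <- sim_config(seed = man$seed, n_species = man$n_species)
  write_fixtures(dir2, cfg2, n_allometry = 2)
  for (f in c("effects.csv", "tree.nwk", file.path("allometry", "allometry_01.csv"))) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})
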