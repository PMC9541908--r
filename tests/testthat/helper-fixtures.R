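# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# A small random meta-analytic instance assembled directly (not via
# simulate_effects), so model-fitting tests do not depend on the generator.
make_tiny_dataset <- function(k = 10, n_species = 4, seed = 1, rho = 0,
                              shared_experiments = FALSE) {
  set.seed(seed)
  tree <- grafen_transform(unit_branch_lengths(ape::rtree(n_species)))
  tree$tip.label <- paste0("sp", seq_len(n_species))
  species <- sample(tree$tip.label, k, replace = TRUE)
  study <- paste0("st", sample(ceiling(k / 2), k, replace = TRUE))
  exper <- if (shared_experiments) {
    paste0(study, "_e1")
  } else {
    paste0("e", seq_len(k))
  }
  eff <- data.frame(
    observation_id = paste0("o", seq_len(k)),
    study_id = study,
    experiment_id = exper,
    species = species,
    d = stats::rnorm(k, 0.3, 0.6),
    var = stats::runif(k, 0.05, 0.5),
    stringsAsFactors = FALSE
  )
  meta_dataset(eff, tree, rho = rho)
}

# Independent REML deviance used by the grid-search oracle: written from the
# restricted-likelihood definition, separate from the package's evaluator.
oracle_reml_deviance <- function(sigma2, dataset, X) {
  Sigma <- dataset$V
  nm <- names(dataset$structures)
  for (i in seq_along(sigma2)) {
    Sigma <- Sigma + sigma2[i] * dataset$structures[[nm[i]]]
  }
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) return(Inf)
  y <- dataset$effects$d
  Ly <- backsolve(L, y, transpose = TRUE)
  LX <- backsolve(L, X, transpose = TRUE)
  XtSiX <- crossprod(LX)
  b <- solve(XtSiX, crossprod(LX, Ly))
  2 * sum(log(diag(L))) + determinant(XtSiX)$modulus[1] +
    sum(Ly^2) - sum(crossprod(LX, Ly) * b) +
    (length(y) - ncol(X)) * log(2 * pi)
}

# Exhaustive grid minimum of the REML deviance over the four variance
# components, resolution 0.05 on [0, hi].
oracle_grid_min <- function(dataset, X = NULL, hi = 0.5, by = 0.05) {
  if (is.null(X)) X <- matrix(1, dataset$k, 1, dimnames = list(NULL, "intercept"))
  g <- seq(0, hi, by = by)
  best <- Inf
  for (s1 in g) for (s2 in g) for (s3 in g) for (s4 in g) {
    val <- oracle_reml_deviance(c(s1, s2, s3, s4), dataset, X)
    if (val < best) best <- val
  }
  best
}

# Textbook paired t-test, coded independently of stats::t.test.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Brute-force sums of squares for the common-slope ANCOVA, via explicit
# least-squares projections (independent of stats::anova).
oracle_ancova_eta2 <- function(table) {
  soma <- table$body_mass - table$testes_mass
  y <- table$testes_mass
  g <- as.numeric(factor(table$tactic)) - 1
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  rss_reduced <- rss(cbind(1, soma))
  rss_full <- rss(cbind(1, soma, g))
  ss_tactic <- rss_reduced - rss_full
  ss_tactic / (ss_tactic + rss_full)
}
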