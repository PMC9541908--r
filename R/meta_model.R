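## 0/1 indicator matrix for a factor; robust to single-level factors.
indicator_matrix <- function(f) {
  out <- vapply(levels(f), function(l) as.numeric(f == l),
                numeric(length(f)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(f))
  colnames(out) <- levels(f)
  out
}

#' Bind effect sizes and a phylogeny into a dataset for model fitting
#'
#' Checks that every species appears in the tree, prunes the tree to the
#' species present, and precomputes the random-effect design: the
#' phylogenetic correlation matrix A (from the pruned, Grafen-transformed
#' tree), species/study/experiment indicator structures, and the sampling
#' (co)variance matrix V. V has the reported sampling variances on the
#' diagonal and, for effect sizes from the same experiment (the same sample
#' of males), off-diagonal entries \code{rho * sqrt(v_i v_j)}.
#'
#' @param effects Data frame with at least \code{d}, \code{var},
#'   \code{species}, \code{study_id}, \code{observation_id}; optionally
#'   \code{experiment_id} and moderator columns.
#' @param tree A rooted \code{phylo} object covering all species (may be
#'   larger; it is pruned). Branch lengths are replaced by unit lengths and
#'   the Grafen transform before the correlation matrix is computed.
#' @param rho Assumed correlation between effect sizes from the same
#'   experiment (default 0.5; conventional when the trait correlation is
#'   unreported).
#' @return An object of class \code{meta_dataset}.
#' @export
meta_dataset <- function(effects, tree, rho = 0.5) {
  stopifnot(is.data.frame(effects), inherits(tree, "phylo"))
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  need <- c("d", "var", "species", "study_id", "observation_id")
  if (!all(need %in% names(effects))) {
    stop("effects needs columns: ", paste(need, collapse = ", "))
  }
  k <- nrow(effects)
  if (k < 2) stop("need at least two effect sizes")
  if (any(effects$var <= 0)) stop("sampling variances must be > 0")
  missing_sp <- setdiff(unique(effects$species), tree$tip.label)
  if (length(missing_sp) > 0) {
    stop("species missing from tree: ", paste(missing_sp, collapse = ", "))
  }
  sub <- prune_tree(tree, unique(effects$species))
  sub <- grafen_transform(unit_branch_lengths(sub))
  A <- vcv_from_tree(sub)

  sp <- factor(effects$species, levels = rownames(A))
  Zsp <- indicator_matrix(sp)
  st <- factor(effects$study_id)
  Zst <- indicator_matrix(st)
  exper <- if ("experiment_id" %in% names(effects)) as.character(effects$experiment_id) else rep(NA_character_, k)
  exper[is.na(exper) | exper == ""] <- paste0(".solo", seq_len(k))[is.na(exper) | exper == ""]
  ex <- factor(exper)
  Zex <- indicator_matrix(ex)

  se <- sqrt(effects$var)
  V <- diag(effects$var, nrow = k)
  same_exp <- tcrossprod(Zex) > 0
  off <- same_exp & !diag(TRUE, k)
  V[off] <- rho * (se %o% se)[off]

  structures <- list(
    phylogeny = Zsp %*% A %*% t(Zsp),
    species = tcrossprod(Zsp),
    study = tcrossprod(Zst),
    observation = diag(1, k)
  )
  structure(list(
    effects = effects, tree = sub, A = A, rho = rho, k = k,
    structures = structures, experiment = ex, Zexp = Zex, V = V
  ), class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("meta_dataset:", x$k, "effect sizes,",
      length(unique(x$effects$species)), "species,",
      length(unique(x$effects$study_id)), "studies; rho =", x$rho, "\n")
  invisible(x)
}

#' Assemble the marginal covariance matrix of the effect sizes
#'
#' \code{Sigma(theta) = sigma2_phylo Z A Z' + sigma2_species Z Z' +
#' sigma2_study Z_t Z_t' + sigma2_obs I [+ sigma2_exp Z_e Z_e'] + V}.
#'
#' @param dataset A \code{\link{meta_dataset}}.
#' @param sigma2 Named numeric vector of variance components (names from
#'   \code{phylogeny, species, study, observation, experiment}; missing
#'   components are treated as zero).
#' @return The k-by-k covariance matrix.
#' @export
build_covariance <- function(dataset, sigma2) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (any(sigma2 < 0)) stop("variance components must be >= 0")
  Sigma <- dataset$V
  for (nm in names(sigma2)) {
    M <- if (nm == "experiment") tcrossprod(dataset$Zexp) else dataset$structures[[nm]]
    if (is.null(M)) stop("unknown variance component: ", nm)
    if (sigma2[[nm]] > 0) Sigma <- Sigma + sigma2[[nm]] * M
  }
  Sigma
}

## -2 * restricted log-likelihood given component values (vector theta in the
## order of `mats`), fixed structures and data. Returns +Inf when Sigma is
## not positive definite.
reml_deviance <- function(theta, mats, V, X, y) {
  k <- length(y)
  Sigma <- V
  for (i in seq_along(mats)) {
    if (theta[i] > 0) Sigma <- Sigma + theta[i] * mats[[i]]
  }
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) return(Inf)
  Ly <- backsolve(L, y, transpose = TRUE)
  LX <- backsolve(L, X, transpose = TRUE)
  XtSiX <- crossprod(LX)
  Lx <- tryCatch(chol(XtSiX), error = function(e) NULL)
  if (is.null(Lx)) return(Inf)
  XtSiy <- crossprod(LX, Ly)
  beta <- backsolve(Lx, backsolve(Lx, XtSiy, transpose = TRUE))
  quad <- sum(Ly^2) - sum(XtSiy * beta)
  2 * sum(log(diag(L))) + 2 * sum(log(diag(Lx))) + quad +
    (k - ncol(X)) * log(2 * pi)
}

#' Fit the multilevel random-effects meta-analytic model by REML
#'
#' Estimates the variance components of the model
#' \code{y ~ N(X beta, Sigma(theta))} (see \code{\link{build_covariance}})
#' by restricted maximum likelihood, then \code{beta} by generalised least
#' squares at the REML solution. The optimiser works on log-variance
#' parameters (so components stay nonnegative and may shrink to zero),
#' using Nelder-Mead from several starts followed by an L-BFGS-B polish.
#' Confidence intervals are normal (Wald) intervals; an effect is declared
#' significant when its CI excludes zero. When \code{X} contains moderator
#' columns, the omnibus Q_M Wald chi-square over those columns and the
#' marginal R-squared (variance of the fitted moderator values over that
#' plus the summed variance components) are reported.
#'
#' @param dataset A \code{\link{meta_dataset}}.
#' @param X Fixed-effect design matrix (default: intercept only). Columns
#'   named \code{"intercept"} (or \code{"(Intercept)"}) are excluded from
#'   Q_M; all other columns are treated as moderators.
#' @param fix_sigma2 Optional named numeric vector: fix these components at
#'   the given values instead of estimating them (use 0 to drop a level).
#'   When all components are fixed no optimisation is performed.
#' @param include_experiment Add an experiment-level random intercept in
#'   addition to the within-experiment correlation carried by V.
#' @param ci_level Confidence level (default 0.95).
#' @param n_starts Number of optimiser starts (default 3).
#' @return An object of class \code{meta_fit}.
#' @export
fit_reml <- function(dataset, X = NULL, fix_sigma2 = NULL,
                     include_experiment = FALSE, ci_level = 0.95,
                     n_starts = 3) {
  stopifnot(inherits(dataset, "meta_dataset"))
  y <- dataset$effects$d
  k <- dataset$k
  if (is.null(X)) {
    X <- matrix(1, k, 1, dimnames = list(NULL, "intercept"))
  }
  X <- as.matrix(X)
  if (k <= ncol(X)) stop("need more effect sizes than fixed-effect columns")

  comp_names <- c("phylogeny", "species", "study", "observation")
  mats <- dataset$structures[comp_names]
  if (include_experiment) {
    mats$experiment <- tcrossprod(dataset$Zexp)
    comp_names <- c(comp_names, "experiment")
  }
  fixed <- rep(NA_real_, length(comp_names)); names(fixed) <- comp_names
  if (!is.null(fix_sigma2)) {
    bad <- setdiff(names(fix_sigma2), comp_names)
    if (length(bad) > 0) stop("unknown components in fix_sigma2: ", paste(bad, collapse = ", "))
    fixed[names(fix_sigma2)] <- fix_sigma2
  }
  free <- which(is.na(fixed))

  dev_free <- function(gamma) {
    theta <- fixed
    theta[free] <- exp(gamma)
    reml_deviance(unname(theta), mats, dataset$V, X, y)
  }

  if (length(free) == 0) {
    theta_hat <- fixed
    deviance <- reml_deviance(unname(theta_hat), mats, dataset$V, X, y)
    conv <- TRUE
  } else {
    tau0 <- max(stats::var(y) - mean(dataset$effects$var), 0.05 * stats::var(y), 1e-3)
    starts <- list(rep(log(tau0 / length(free)), length(free)),
                   rep(log(1e-3), length(free)),
                   rep(log(max(stats::var(y), 1e-3)), length(free)))
    starts <- starts[seq_len(min(n_starts, length(starts)))]
    best <- NULL
    for (g0 in starts) {
      nm <- stats::optim(g0, dev_free, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-12))
      pol <- tryCatch(
        stats::optim(nm$par, dev_free, method = "L-BFGS-B",
                     lower = rep(-30, length(free)), upper = rep(10, length(free)),
                     control = list(factr = 1e3, maxit = 200)),
        error = function(e) nm)
      cand <- if (is.finite(pol$value) && pol$value <= nm$value) pol else nm
      if (is.null(best) || cand$value < best$value) best <- cand
    }
    if (!is.finite(best$value)) stop("REML optimisation failed to find a finite criterion")
    theta_hat <- fixed
    theta_hat[free] <- exp(best$par)
    theta_hat[free][theta_hat[free] < 1e-8] <- 0   # collapse numerically-zero components
    deviance <- reml_deviance(unname(theta_hat), mats, dataset$V, X, y)
    conv <- TRUE
  }

  # GLS at the REML solution
  Sigma <- dataset$V
  for (i in seq_along(mats)) {
    if (theta_hat[i] > 0) Sigma <- Sigma + theta_hat[i] * mats[[i]]
  }
  L <- chol(Sigma)
  Ly <- backsolve(L, y, transpose = TRUE)
  LX <- backsolve(L, X, transpose = TRUE)
  XtSiX <- crossprod(LX)
  vb <- solve(XtSiX)
  beta <- drop(vb %*% crossprod(LX, Ly))
  names(beta) <- colnames(X)
  se <- sqrt(diag(vb))
  names(se) <- colnames(X)
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  mod_idx <- which(!(colnames(X) %in% c("intercept", "(Intercept)")))
  QM <- QM_df <- QM_p <- R2 <- NA_real_
  if (length(mod_idx) > 0) {
    bm <- beta[mod_idx]
    QM <- drop(t(bm) %*% solve(vb[mod_idx, mod_idx, drop = FALSE]) %*% bm)
    QM_df <- length(mod_idx)
    QM_p <- stats::pchisq(QM, df = QM_df, lower.tail = FALSE)
    fitted_fix <- drop(X %*% beta)
    var_fix <- mean((fitted_fix - mean(fitted_fix))^2)
    R2 <- var_fix / (var_fix + sum(theta_hat))
  }

  structure(list(
    beta = beta, se_beta = se, zval = zval, pval = pval,
    ci_low = beta - zc * se, ci_high = beta + zc * se, ci_level = ci_level,
    sigma2 = theta_hat, loglik_reml = -0.5 * deviance, deviance = deviance,
    QM = QM, QM_df = QM_df, QM_p = QM_p, R2_marginal = R2,
    k = k, p = ncol(X), X = X, vb = vb, vi = dataset$effects$var,
    converged = conv, method = "REML", test = "z"
  ), class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic model (REML), k =", x$k, "\n\n")
  tab <- data.frame(estimate = x$beta, se = x$se_beta,
                    ci.lb = x$ci_low, ci.ub = x$ci_high, p = x$pval)
  print(round(tab, digits))
  cat("\nVariance components:\n")
  print(round(x$sigma2, digits))
  if (is.finite(x$QM)) {
    cat(sprintf("\nQ_M(df = %d) = %.*f, p = %.4g; marginal R2 = %.*f\n",
                x$QM_df, digits, x$QM, x$QM_p, digits, x$R2_marginal))
  }
  invisible(x)
}

#' Heterogeneity partition across random-effect levels
#'
#' Multilevel I-squared: the typical sampling variance is
#' \code{s2 = (k - 1) sum(w) / ((sum w)^2 - sum(w^2))} with weights
#' \code{w_i = 1 / v_i}; each level's I-squared is its variance component
#' over the total (components plus \code{s2}), in percent. The per-level
#' values sum exactly to the total. Benchmarks: 25, 50 and 75 percent are
#' conventionally read as low, medium and high heterogeneity.
#'
#' @param fit A \code{meta_fit}.
#' @return List with \code{I2_total} (percent), \code{I2_partition} (named
#'   percent vector) and \code{s2} (typical sampling variance).
#' @export
i2_partition <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  if (fit$k < 2) stop("need k >= 2")
  w <- 1 / fit$vi
  s2 <- ((fit$k - 1) * sum(w)) / (sum(w)^2 - sum(w^2))
  denom <- sum(fit$sigma2) + s2
  part <- 100 * fit$sigma2 / denom
  list(I2_total = sum(part), I2_partition = part, s2 = s2)
}

## Rebuild a meta_dataset on a row subset (tree re-pruned).
subset_dataset <- function(dataset, idx) {
  meta_dataset(dataset$effects[idx, , drop = FALSE], dataset$tree, rho = dataset$rho)
}

#' Moderator meta-regression
#'
#' Fits the multilevel model with one moderator as a fixed effect. Rows with
#' a missing moderator value are dropped; for categorical moderators, levels
#' carrying fewer than \code{min_k} effect sizes are excluded before fitting
#' (small levels give unstable level means). The omnibus Q_M statistic tests
#' the moderator's coefficients (intercept excluded) against a chi-square
#' reference; marginal R-squared reports the proportion of variance
#' explained by the moderator.
#'
#' @param dataset A \code{\link{meta_dataset}}.
#' @param moderator Name of a column of the effects table.
#' @param type \code{"categorical"}, \code{"continuous"} or
#'   \code{"quadratic"} (continuous plus its square).
#' @param min_k Minimum effect sizes per retained categorical level
#'   (default 5).
#' @param center Center a continuous moderator at its mean before fitting
#'   (stabilises the intercept; slope unchanged).
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return A \code{meta_fit} with attributes \code{moderator} and
#'   \code{data_k}.
#' @export
meta_regression <- function(dataset, moderator,
                            type = c("categorical", "continuous", "quadratic"),
                            min_k = 5, center = FALSE, ...) {
  stopifnot(inherits(dataset, "meta_dataset"))
  type <- match.arg(type)
  if (!moderator %in% names(dataset$effects)) {
    stop("moderator not found: ", moderator)
  }
  xvals <- dataset$effects[[moderator]]
  keep <- !is.na(xvals) & (!is.character(xvals) | xvals != "")
  if (type == "categorical") {
    tab <- table(xvals[keep])
    ok_levels <- names(tab)[tab >= min_k]
    if (length(ok_levels) < 2) stop("moderator '", moderator,
                                    "' has fewer than two levels with >= ", min_k, " effects")
    keep <- keep & xvals %in% ok_levels
  }
  ds <- if (all(keep)) dataset else subset_dataset(dataset, which(keep))
  x <- ds$effects[[moderator]]
  if (type == "categorical") {
    f <- factor(x)
    X <- stats::model.matrix(~ f)
    colnames(X) <- c("intercept", paste0(moderator, "_", levels(f)[-1]))
  } else {
    x <- as.numeric(x)
    if (length(unique(x)) < 2) stop("continuous moderator is constant")
    if (center) x <- x - mean(x)
    if (type == "quadratic") {
      if (length(unique(x)) < 3) stop("need >= 3 distinct values for a quadratic term")
      X <- cbind(intercept = 1, linear = x, quadratic = x^2)
      colnames(X) <- c("intercept", moderator, paste0(moderator, "^2"))
    } else {
      X <- cbind(intercept = 1, x)
      colnames(X) <- c("intercept", moderator)
    }
  }
  fit <- fit_reml(ds, X = X, ...)
  attr(fit, "moderator") <- moderator
  attr(fit, "type") <- type
  attr(fit, "data_k") <- ds$k
  attr(fit, "dataset") <- ds
  fit
}

#' Per-level mean effect sizes for a categorical moderator
#'
#' Refits the moderator model with the intercept dropped so that each
#' coefficient is the mean effect size of one level (in effect a separate
#' meta-analysis per level sharing the variance components), with Wald CIs.
#'
#' @param dataset A \code{\link{meta_dataset}}.
#' @param moderator Name of a categorical column.
#' @param min_k Minimum effect sizes per retained level.
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return Data frame with \code{level, k, mean_d, ci_low, ci_high}.
#' @export
level_means <- function(dataset, moderator, min_k = 5, ...) {
  xvals <- dataset$effects[[moderator]]
  keep <- !is.na(xvals) & xvals != ""
  tab <- table(xvals[keep])
  ok_levels <- names(tab)[tab >= min_k]
  keep <- keep & xvals %in% ok_levels
  if (sum(keep) < 2) stop("too few rows after level filtering")
  ds <- subset_dataset(dataset, which(keep))
  f <- factor(ds$effects[[moderator]])
  X <- indicator_matrix(f)
  fit <- fit_reml(ds, X = X, ...)
  data.frame(
    moderator = moderator, level = levels(f),
    k = as.integer(table(f)), mean_d = unname(fit$beta),
    ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
    stringsAsFactors = FALSE
  )
}

#' Sneaker-frequency meta-regressions
#'
#' Theory predicts the tactic difference in post-mating investment peaks at
#' intermediate sneaker frequencies, so a quadratic model in the proportion
#' of sneaker males is fitted first and the quadratic term's z-test
#' reported; a linear model is fitted and reported alongside (it is the
#' model of interest when the quadratic term is not significant).
#'
#' @param dataset A \code{\link{meta_dataset}} whose effects carry a
#'   \code{sneaker_freq} column (proportions in [0, 1]).
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return List with \code{quadratic}, \code{linear} (both \code{meta_fit}),
#'   and \code{quadratic_term} (estimate, z, p for the squared term).
#' @export
sneaker_frequency_models <- function(dataset, ...) {
  quad <- meta_regression(dataset, "sneaker_freq", type = "quadratic", ...)
  lin <- meta_regression(dataset, "sneaker_freq", type = "continuous", ...)
  qn <- "sneaker_freq^2"
  list(
    quadratic = quad,
    linear = lin,
    quadratic_term = list(estimate = unname(quad$beta[qn]),
                          z = unname(quad$zval[qn]),
                          p = unname(quad$pval[qn]))
  )
}

#' Sensitivity analyses for the pooled mean
#'
#' Refits the intercept-only model (i) excluding directionless zero effects,
#' (ii) at each within-experiment correlation in \code{rhos}, and (iii)
#' excluding caller-specified species, and tabulates the pooled mean, its
#' CI and k for each variant alongside the base fit. Variants that would
#' leave fewer than two effects are skipped with a warning.
#'
#' @param dataset A \code{\link{meta_dataset}}.
#' @param exclude_species Optional character vector of species to drop in a
#'   dedicated variant.
#' @param rhos Within-experiment correlations to profile (default
#'   \code{c(0.25, 0.5, 0.75)}).
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return Data frame with one row per variant: \code{variant, k, mean_d,
#'   ci_low, ci_high}.
#' @export
sensitivity_suite <- function(dataset, exclude_species = NULL,
                              rhos = c(0.25, 0.5, 0.75), ...) {
  row_of <- function(name, ds) {
    fit <- fit_reml(ds, ...)
    data.frame(variant = name, k = ds$k, mean_d = unname(fit$beta[1]),
               ci_low = unname(fit$ci_low[1]), ci_high = unname(fit$ci_high[1]),
               stringsAsFactors = FALSE)
  }
  out <- list(row_of("base", dataset))
  dl <- dataset$effects$directionless
  if (!is.null(dl) && any(dl, na.rm = TRUE)) {
    idx <- which(!dl | is.na(dl))
    if (length(idx) >= 2) {
      out <- c(out, list(row_of("no_directionless", subset_dataset(dataset, idx))))
    } else {
      warning("skipping no_directionless variant: fewer than two effects left")
    }
  } else {
    out <- c(out, list(row_of("no_directionless", dataset)))
  }
  for (r in rhos) {
    ds_r <- meta_dataset(dataset$effects, dataset$tree, rho = r)
    out <- c(out, list(row_of(sprintf("rho_%.2f", r), ds_r)))
  }
  if (!is.null(exclude_species)) {
    idx <- which(!dataset$effects$species %in% exclude_species)
    if (length(idx) >= 2) {
      out <- c(out, list(row_of("species_excluded", subset_dataset(dataset, idx))))
    } else {
      warning("skipping species-exclusion variant: fewer than two effects left")
    }
  }
  do.call(rbind, out)
}
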