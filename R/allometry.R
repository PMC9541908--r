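#' Soma mass
#'
#' Body mass with the testes removed, used as the ANCOVA covariate so that
#' the testes do not appear on both sides of the model.
#'
#' @param body_mass,testes_mass Masses in the same units;
#'   \code{body_mass > testes_mass}.
#' @return \code{body_mass - testes_mass}.
#' @export
soma_mass <- function(body_mass, testes_mass) {
  out <- body_mass - testes_mass
  if (any(out <= 0)) stop("soma mass must be positive (body_mass > testes_mass)")
  out
}

#' Gonadosomatic index
#'
#' GSI = 100 * testes mass / soma mass. A ratio measure of gonadal
#' investment that only removes body-size effects when testes scale
#' isometrically with soma mass; under negative allometry it inflates the
#' apparent investment of the smaller morph.
#'
#' @param testes_mass,soma_mass Masses in the same units; \code{soma_mass > 0}.
#' @export
gsi <- function(testes_mass, soma_mass) {
  if (any(soma_mass <= 0)) stop("soma mass must be > 0")
  100 * testes_mass / soma_mass
}

#' Validate an individual-level allometry table
#'
#' @param table Data frame with columns \code{individual_id}, \code{tactic},
#'   \code{body_mass}, \code{testes_mass} (one study, two tactics).
#' @return The table, invisibly, after validation.
#' @export
validate_allometry <- function(table) {
  need <- c("tactic", "body_mass", "testes_mass")
  if (!all(need %in% names(table))) {
    stop("allometry table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(table$testes_mass <= 0) || any(table$body_mass <= table$testes_mass)) {
    stop("each row must satisfy body_mass > testes_mass > 0")
  }
  if (length(unique(table$tactic)) != 2) {
    stop("allometry table must contain exactly two tactic labels")
  }
  invisible(table)
}

#' Read an allometry table from delimited text
#'
#' @param path CSV file with columns \code{individual_id, tactic, body_mass,
#'   testes_mass}.
#' @export
read_allometry_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_allometry(x)
  x
}

#' Effect size from the GSI route
#'
#' Computes each individual's GSI, then the tactic difference as Hedges' d
#' from the two group summaries, signed by the direction rule.
#'
#' @param table Allometry table (see \code{\link{validate_allometry}}).
#' @param rule \code{\link{direction_rule}} naming the two tactics.
#' @param ... Metadata passed through to the effect-size record.
#' @return One-row effect-size data frame with \code{measurement = "GSI"}.
#' @export
gsi_effect <- function(table, rule, ...) {
  validate_allometry(table)
  g <- gsi(table$testes_mass, soma_mass(table$body_mass, table$testes_mass))
  split_g <- split(g, table$tactic)
  if (any(lengths(split_g) < 2)) stop("need >= 2 individuals per tactic")
  tactics <- names(split_g)
  es <- hedges_d_from_summary(
    n1 = length(split_g[[1]]), m1 = mean(split_g[[1]]), sd1 = stats::sd(split_g[[1]]),
    n2 = length(split_g[[2]]), m2 = mean(split_g[[2]]), sd2 = stats::sd(split_g[[2]]),
    measurement = "GSI", ...
  )
  apply_direction(es, rule, observed_order = tactics)
}

#' Effect size from the ANCOVA route
#'
#' Fits testes mass on soma mass, tactic, and their interaction. When the
#' interaction (tactic-specific allometric slopes) is not significant at
#' \code{alpha} it is dropped and partial eta-squared for tactic is computed
#' from the common-slope model with tactic entered after soma
#' (\code{SS_tactic / (SS_tactic + SS_residual)}). Partial eta-squared is
#' converted to Cohen's d, signed by the adjusted (equal-soma) group means,
#' Hedges-corrected, and oriented by the direction rule. If the interaction
#' is significant the effect is still computed from the main-effects model
#' but flagged as slope-heterogeneous.
#'
#' @param table Allometry table.
#' @param rule \code{\link{direction_rule}}.
#' @param alpha Significance level for the interaction-drop rule (default 0.05).
#' @param log_scale Analyse masses on the log scale (off by default; the
#'   conventional re-analysis works on raw masses).
#' @param ... Metadata passed through to the effect-size record.
#' @return A list with elements \code{result} (interaction p, drop flag,
#'   partial eta-squared, common slope, tactic-term p) and \code{effect}
#'   (one-row effect-size data frame, \code{measurement = "ANCOVA"}).
#' @export
ancova_effect <- function(table, rule, alpha = 0.05, log_scale = FALSE, ...) {
  validate_allometry(table)
  dat <- data.frame(
    testes = table$testes_mass,
    soma = soma_mass(table$body_mass, table$testes_mass),
    tactic = factor(table$tactic)
  )
  if (log_scale) {
    dat$testes <- log(dat$testes)
    dat$soma <- log(dat$soma)
  }
  if (any(table(dat$tactic) < 3)) stop("need >= 3 individuals per tactic")

  full <- stats::lm(testes ~ soma + tactic + soma:tactic, data = dat)
  a_full <- stats::anova(full)
  interaction_p <- a_full["soma:tactic", "Pr(>F)"]

  main <- stats::lm(testes ~ soma + tactic, data = dat)
  a_main <- stats::anova(main)   # sequential; tactic entered after soma
  ss_tactic <- a_main["tactic", "Sum Sq"]
  ss_resid <- a_main["Residuals", "Sum Sq"]
  eta2 <- ss_tactic / (ss_tactic + ss_resid)
  tactic_p <- a_main["tactic", "Pr(>F)"]

  # adjusted means at the grand-mean soma mass carry the direction
  lev <- levels(dat$tactic)
  nd <- data.frame(soma = mean(dat$soma), tactic = factor(lev, levels = lev))
  adj <- stats::predict(main, newdata = nd)
  sgn <- if (adj[1] >= adj[2]) 1 else -1

  ns <- table(dat$tactic)
  es <- d_from_partial_eta2(eta2, n1 = ns[[1]], n2 = ns[[2]], sign = sgn,
                            measurement = "ANCOVA", ...)
  es <- apply_direction(es, rule, observed_order = lev)

  result <- list(
    interaction_p = interaction_p,
    interaction_dropped = is.na(interaction_p) || interaction_p >= alpha,
    slope_heterogeneous = !is.na(interaction_p) && interaction_p < alpha,
    partial_eta2 = eta2,
    tactic_p = tactic_p,
    slope_common = stats::coef(main)[["soma"]],
    d = es$d
  )
  list(result = result, effect = es)
}

#' Paired comparison of GSI and ANCOVA effect sizes
#'
#' Paired t-test on Hedges' d values obtained from the same raw data by the
#' two routes; a significantly positive mean difference indicates that the
#' GSI route inflates the apparent tactic difference.
#'
#' @param d_gsi,d_ancova Numeric vectors of paired effect sizes.
#' @return List with \code{t}, \code{df}, \code{p}, \code{mean_diff}, \code{n}.
#' @export
compare_methods <- function(d_gsi, d_ancova) {
  if (length(d_gsi) != length(d_ancova)) stop("paired vectors must have equal length")
  if (length(d_gsi) < 2) stop("need >= 2 pairs")
  diffs <- d_gsi - d_ancova
  if (stats::sd(diffs) == 0) stop("differences have zero variance: paired t-test degenerate")
  tt <- stats::t.test(d_gsi, d_ancova, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = length(diffs))
}

#' Count significant tactic differences under each route
#'
#' For each study table, evaluates a two-sample t-test on individual GSI
#' values and the ANCOVA tactic term at level \code{alpha}, and counts how
#' often each route declares a significant tactic difference. Per-table fit
#' failures are recorded, not fatal.
#'
#' @param tables List of allometry tables.
#' @param rule \code{\link{direction_rule}}.
#' @param alpha Significance level.
#' @return List with \code{count_gsi_sig}, \code{count_ancova_sig},
#'   \code{n_tables}, \code{errors}.
#' @export
significance_counts <- function(tables, rule, alpha = 0.05) {
  gsi_sig <- 0L; anc_sig <- 0L; errs <- character(0); n_ok <- 0L
  for (i in seq_along(tables)) {
    res <- tryCatch({
      tab <- tables[[i]]
      validate_allometry(tab)
      g <- gsi(tab$testes_mass, soma_mass(tab$body_mass, tab$testes_mass))
      p_gsi <- stats::t.test(g ~ tab$tactic, var.equal = TRUE)$p.value
      p_anc <- ancova_effect(tab, rule, alpha = alpha)$result$tactic_p
      c(p_gsi, p_anc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("table %d: %s", i, conditionMessage(res)))
    } else {
      n_ok <- n_ok + 1L
      if (res[1] < alpha) gsi_sig <- gsi_sig + 1L
      if (res[2] < alpha) anc_sig <- anc_sig + 1L
    }
  }
  list(count_gsi_sig = gsi_sig, count_ancova_sig = anc_sig,
       n_tables = n_ok, errors = errs)
}

#' Run the GSI-versus-ANCOVA comparison over a set of studies
#'
#' @param tables Named list of allometry tables (one per study).
#' @param rule \code{\link{direction_rule}}.
#' @param alpha Significance level for the interaction rule and the counts.
#' @return List with the per-study comparison data frame (\code{per_study}),
#'   the paired test (\code{paired_test}) and the significance counts
#'   (\code{counts}).
#' @export
gsi_compare <- function(tables, rule, alpha = 0.05) {
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    dg <- gsi_effect(tab, rule)
    anc <- ancova_effect(tab, rule, alpha = alpha)
    data.frame(
      study = if (!is.null(names(tables))) names(tables)[i] else as.character(i),
      d_gsi = dg$d, d_ancova = anc$effect$d,
      partial_eta2 = anc$result$partial_eta2,
      interaction_dropped = anc$result$interaction_dropped,
      stringsAsFactors = FALSE
    )
  })
  per_study <- do.call(rbind, rows)
  list(
    per_study = per_study,
    paired_test = compare_methods(per_study$d_gsi, per_study$d_ancova),
    counts = significance_counts(tables, rule, alpha = alpha)
  )
}
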