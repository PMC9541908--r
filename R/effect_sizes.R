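#' Small-sample correction factor for the standardized mean difference
#'
#' Hedges' J shrinks the uncorrected standardized mean difference towards
#' zero to remove small-sample bias. J is always below 1 for finite degrees
#' of freedom and approaches 1 as \code{df} grows.
#'
#' @param df Degrees of freedom, usually \code{n1 + n2 - 2}.
#' @return The correction factor \code{1 - 3 / (4 * df - 1)}.
#' @export
hedges_j <- function(df) {
  if (any(df < 1)) stop("degrees of freedom must be >= 1")
  1 - 3 / (4 * df - 1)
}

## Hedges-Olkin large-sample sampling variance, applied to the corrected d.
d_sampling_var <- function(d, n1, n2) {
  (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
}

check_group_n <- function(n1, n2) {
  if (!is.numeric(n1) || !is.numeric(n2) || n1 < 2 || n2 < 2 ||
      n1 != round(n1) || n2 != round(n2)) {
    stop("group sample sizes must be integers >= 2")
  }
}

#' Construct an effect-size record
#'
#' One standardized mean difference (Hedges' d) with its sampling variance
#' and the grouping labels used by the multilevel meta-analytic model.
#' Returned as a one-row data frame so records can be stacked with
#' \code{rbind} into an effect-size table.
#'
#' @param d Hedges' d.
#' @param var Sampling variance of d (> 0).
#' @param species,study_id,experiment_id,observation_id Grouping labels.
#'   \code{experiment_id} groups effects computed from the same sample of
#'   males; such effects are treated as correlated by the model.
#' @param trait_category One of \code{"testes_size"}, \code{"sperm_quantity"},
#'   \code{"sperm_trait"}.
#' @param measurement Sub-measure label (e.g. \code{"GSI"},
#'   \code{"relative_testes"}, \code{"sperm_number"}, \code{"length"}).
#' @param directionless Logical; \code{TRUE} for effects reported without a
#'   direction and assigned d = 0.
#' @param method Label recording the conversion route that produced d.
#' @param ... Further moderator columns (e.g. \code{taxon_group},
#'   \code{fert_mode}, \code{tactic_type}, \code{sneaker_freq},
#'   \code{pub_year}).
#' @return A one-row \code{data.frame} with at least columns \code{d},
#'   \code{var}, \code{se}.
#' @export
effect_size <- function(d, var, species = NA_character_, study_id = NA_character_,
                        experiment_id = NA_character_, observation_id = NA_character_,
                        trait_category = NA_character_, measurement = NA_character_,
                        directionless = FALSE, method = NA_character_, ...) {
  if (!is.finite(d)) stop("d must be finite")
  if (!is.finite(var) || var <= 0) stop("sampling variance must be > 0")
  out <- data.frame(
    observation_id = observation_id, study_id = study_id,
    experiment_id = experiment_id, species = species,
    trait_category = trait_category, measurement = measurement,
    d = d, var = var, se = sqrt(var),
    directionless = directionless, method = method,
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Hedges' d from group means and standard deviations
#'
#' The standardized mean difference between two tactic groups, computed from
#' reported means and variances, with Hedges' small-sample correction.
#' \code{g_high} is the group expected (or observed) to carry the larger
#' trait value in the orientation of the computation: d is positive when
#' \code{g_high} has the larger mean. Use \code{\link{apply_direction}} to
#' enforce the sperm-competition-risk sign convention afterwards.
#'
#' @param n1,m1,sd1 Sample size, mean, SD of the first group.
#' @param n2,m2,sd2 Sample size, mean, SD of the second group.
#' @param se1,se2 Optionally, standard errors instead of \code{sd1}/\code{sd2};
#'   converted via \code{sd = se * sqrt(n)}.
#' @param ... Metadata passed to \code{\link{effect_size}}.
#' @return A one-row effect-size data frame; d oriented as group 1 minus
#'   group 2.
#' @export
hedges_d_from_summary <- function(n1, m1, sd1 = NULL, n2, m2, sd2 = NULL,
                                  se1 = NULL, se2 = NULL, ...) {
  check_group_n(n1, n2)
  if (is.null(sd1)) sd1 <- se1 * sqrt(n1)
  if (is.null(sd2)) sd2 <- se2 * sqrt(n2)
  if (is.null(sd1) || is.null(sd2) || sd1 < 0 || sd2 < 0) {
    stop("supply nonnegative sd (or se) for both groups")
  }
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  if (s_pooled == 0) {
    if (m1 == m2) {
      d <- 0
    } else {
      stop("pooled SD is zero with unequal means: effect size undefined")
    }
  } else {
    d <- hedges_j(df) * (m1 - m2) / s_pooled
  }
  effect_size(d = d, var = d_sampling_var(d, n1, n2),
              method = "summary", ...)
}

#' Hedges' d from a two-sample t statistic
#'
#' Converts an independent-samples t statistic to the standardized mean
#' difference (\code{d = t * sqrt(1/n1 + 1/n2)}), then applies Hedges'
#' correction and the usual sampling variance. Agrees exactly with
#' \code{\link{hedges_d_from_summary}} when t is computed from the same
#' group summaries.
#'
#' @param t Two-sample t statistic (positive when group 1 exceeds group 2).
#' @param n1,n2 Group sample sizes.
#' @param ... Metadata passed to \code{\link{effect_size}}.
#' @export
d_from_t <- function(t, n1, n2, ...) {
  check_group_n(n1, n2)
  d <- hedges_j(n1 + n2 - 2) * t * sqrt(1 / n1 + 1 / n2)
  effect_size(d = d, var = d_sampling_var(d, n1, n2), method = "t", ...)
}

#' Hedges' d from a paired t statistic
#'
#' Fallback conversion when the correlation between paired measurements is
#' unreported: \code{d = t / sqrt(n_pairs)} with variance
#' \code{1/n + d^2/(2n)}. Rows produced this way carry
#' \code{method = "paired_t"} so they can be audited or excluded.
#'
#' @param t Paired t statistic.
#' @param n_pairs Number of pairs (>= 2).
#' @param ... Metadata passed to \code{\link{effect_size}}.
#' @export
d_from_paired_t <- function(t, n_pairs, ...) {
  if (n_pairs < 2 || n_pairs != round(n_pairs)) stop("n_pairs must be an integer >= 2")
  d <- hedges_j(n_pairs - 1) * t / sqrt(n_pairs)
  effect_size(d = d, var = 1 / n_pairs + d^2 / (2 * n_pairs),
              method = "paired_t", ...)
}

#' Hedges' d from a Mann-Whitney U statistic
#'
#' Normal-approximation chain without continuity correction:
#' z from U, the rank-biserial-style correlation \code{r = z / sqrt(n1 + n2)},
#' then \code{d = 2 r / sqrt(1 - r^2)}, followed by Hedges' correction and
#' the standard sampling variance. d carries the sign of
#' \code{U - n1 n2 / 2}, i.e. positive when group 1 tends to exceed group 2.
#'
#' @param U Mann-Whitney U statistic for group 1, in \code{[0, n1 * n2]}.
#' @param n1,n2 Group sample sizes.
#' @param ... Metadata passed to \code{\link{effect_size}}.
#' @export
d_from_mwu <- function(U, n1, n2, ...) {
  check_group_n(n1, n2)
  if (U < 0 || U > n1 * n2) stop("U must lie in [0, n1 * n2]")
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  r <- z / sqrt(n1 + n2)
  if (abs(r) >= 1) stop("|r| >= 1: U too extreme for the normal approximation")
  d <- hedges_j(n1 + n2 - 2) * 2 * r / sqrt(1 - r^2)
  effect_size(d = d, var = d_sampling_var(d, n1, n2), method = "mwu", ...)
}

#' Hedges' d from partial eta-squared
#'
#' Converts partial eta-squared for a two-group term (e.g. the tactic term
#' of an ANCOVA) to Cohen's d via \code{d = 2 sqrt(eta2 / (1 - eta2))},
#' attaches the supplied sign (eta-squared is unsigned; direction comes from
#' the adjusted group difference), and applies Hedges' correction with
#' \code{df = n1 + n2 - 2}.
#'
#' @param eta2 Partial eta-squared in \code{[0, 1)}.
#' @param n1,n2 Group sample sizes.
#' @param sign +1 or -1, the sign of the adjusted group difference
#'   (group 1 minus group 2).
#' @param ... Metadata passed to \code{\link{effect_size}}.
#' @export
d_from_partial_eta2 <- function(eta2, n1, n2, sign = 1, ...) {
  check_group_n(n1, n2)
  if (eta2 < 0 || eta2 >= 1) stop("eta2 must lie in [0, 1)")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  d_cohen <- sign * 2 * sqrt(eta2 / (1 - eta2))
  d <- hedges_j(n1 + n2 - 2) * d_cohen
  effect_size(d = d, var = d_sampling_var(d, n1, n2), method = "eta2", ...)
}

#' Direction rule for a pair of alternative reproductive tactics
#'
#' Encodes the sign convention: the effect size is positive when the tactic
#' facing the greater sperm competition risk (or with reduced pre-mating
#' investment) has the larger trait value — e.g. "sneaker > guarder".
#'
#' @param high Tactic label expected to carry the higher post-mating
#'   investment (e.g. \code{"sneaker"}).
#' @param low The alternative tactic label (e.g. \code{"guarder"}).
#' @param rationale Optional free-text justification.
#' @return A \code{direction_rule} object.
#' @export
direction_rule <- function(high, low, rationale = NULL) {
  if (identical(high, low)) stop("the two tactic labels must differ")
  structure(list(high = high, low = low, rationale = rationale),
            class = "direction_rule")
}

#' Orient an effect size by the tactic sign convention
#'
#' Flips the sign of d iff the order in which the two groups entered the
#' computation disagrees with the rule's expected order. \code{|d|} and the
#' sampling variance are never changed, and applying the same rule twice
#' returns the original value.
#'
#' @param es A one-row effect-size data frame (d oriented as
#'   \code{observed_order[1]} minus \code{observed_order[2]}).
#' @param rule A \code{\link{direction_rule}}.
#' @param observed_order Character vector of the two tactic labels in the
#'   order they entered the d computation.
#' @export
apply_direction <- function(es, rule, observed_order) {
  stopifnot(inherits(rule, "direction_rule"), length(observed_order) == 2)
  if (!setequal(observed_order, c(rule$high, rule$low))) {
    stop("observed tactic labels do not match the direction rule: ",
         paste(observed_order, collapse = ", "))
  }
  if (observed_order[1] == rule$low) es$d <- -es$d
  es$se <- sqrt(es$var)
  es
}

#' Zero effect size for a directionless report
#'
#' Studies sometimes report a non-significant difference without its
#' direction. Excluding such results biases the dataset towards significant
#' effects, so they are retained as d = 0 with the sampling variance
#' evaluated at d = 0 (\code{(n1 + n2) / (n1 n2)}), which preserves
#' weighting by sample size. The \code{directionless} flag lets sensitivity
#' analyses drop these rows.
#'
#' @param n1,n2 Group sample sizes.
#' @param ... Metadata passed to \code{\link{effect_size}}.
#' @export
directionless_zero <- function(n1, n2, ...) {
  check_group_n(n1, n2)
  effect_size(d = 0, var = (n1 + n2) / (n1 * n2), directionless = TRUE,
              method = "directionless", ...)
}

effects_columns <- c("observation_id", "study_id", "experiment_id", "species",
                     "trait_category", "measurement", "d", "var",
                     "directionless", "taxon_group", "fert_mode",
                     "tactic_type", "sneaker_freq", "pub_year")

#' Read or write an effect-size table
#'
#' The interchange format is a UTF-8 comma-separated file with a header row
#' and columns \code{observation_id, study_id, experiment_id, species,
#' trait_category, measurement, d, var, directionless, taxon_group,
#' fert_mode, tactic_type, sneaker_freq, pub_year}. Missing moderators are
#' empty fields.
#'
#' @param path File path.
#' @return \code{read_effects_table}: a data frame with an added \code{se}
#'   column.
#' @export
read_effects_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sneaker_freq = "numeric"))
  missing <- setdiff(effects_columns, names(x))
  if (length(missing) > 0) {
    stop("effect-size table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(x$var)) || any(x$var <= 0)) stop("all sampling variances must be > 0")
  bad <- !is.na(x$sneaker_freq) & (x$sneaker_freq < 0 | x$sneaker_freq > 1)
  if (any(bad)) stop("sneaker_freq must lie in [0, 1]")
  x$directionless <- as.logical(x$directionless)
  x$se <- sqrt(x$var)
  x
}

#' @rdname read_effects_table
#' @param effects Data frame of effect sizes.
#' @export
write_effects_table <- function(effects, path) {
  out <- effects[, effects_columns]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
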