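#' Funnel-asymmetry (study precision) meta-regression
#'
#' Regresses effect sizes on their inverse standard error (study precision)
#' within the full multilevel model. A slope whose CI excludes zero signals
#' funnel asymmetry — the "small-study effect" expected when small,
#' non-significant effects are missing from the literature. This is an
#' ordinary moderator meta-regression with covariate \code{1 / se_i}.
#'
#' @param dataset A \code{\link{meta_dataset}}.
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return A list of class \code{bias_report}: \code{covariate},
#'   \code{slope}, \code{ci_low}, \code{ci_high}, \code{QM}, \code{p},
#'   \code{flagged}, and the underlying \code{fit}.
#' @export
precision_regression <- function(dataset, ...) {
  stopifnot(inherits(dataset, "meta_dataset"))
  if (dataset$k < 3) stop("need k >= 3")
  prec <- 1 / sqrt(dataset$effects$var)
  if (stats::sd(prec) == 0) stop("precision is constant across effects")
  ds <- dataset
  ds$effects$inverse_se <- prec
  fit <- meta_regression(ds, "inverse_se", type = "continuous", ...)
  report_bias(fit, "inverse_se")
}

#' Time-lag (publication year) meta-regression
#'
#' Regresses effect sizes on publication year (centered at its mean, which
#' stabilises the intercept and leaves the slope unchanged) within the full
#' multilevel model. A slope whose CI is entirely negative flags a decline
#' effect: early publications reporting larger effects than later ones.
#'
#' @param dataset A \code{\link{meta_dataset}} whose effects carry
#'   \code{pub_year}.
#' @param ... Passed to \code{\link{fit_reml}}.
#' @return A \code{bias_report} (see \code{\link{precision_regression}}),
#'   with an extra \code{decline} flag.
#' @export
time_lag_regression <- function(dataset, ...) {
  stopifnot(inherits(dataset, "meta_dataset"))
  yrs <- dataset$effects$pub_year
  if (length(unique(yrs[!is.na(yrs)])) < 2) stop("need >= 2 distinct publication years")
  fit <- meta_regression(dataset, "pub_year", type = "continuous",
                         center = TRUE, ...)
  out <- report_bias(fit, "pub_year")
  out$decline <- out$ci_high < 0
  out
}

report_bias <- function(fit, covariate) {
  structure(list(
    covariate = covariate,
    slope = unname(fit$beta[covariate]),
    ci_low = unname(fit$ci_low[covariate]),
    ci_high = unname(fit$ci_high[covariate]),
    QM = fit$QM, p = fit$QM_p,
    flagged = unname(fit$ci_low[covariate] > 0 | fit$ci_high[covariate] < 0),
    fit = fit
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, digits = 4, ...) {
  cat(sprintf("Bias meta-regression on %s: slope = %.*f [%.*f, %.*f], Q_M = %.*f, p = %.4g%s\n",
              x$covariate, digits, x$slope, digits, x$ci_low, digits, x$ci_high,
              digits, x$QM, x$p,
              if (isTRUE(x$flagged)) " (flagged)" else ""))
  invisible(x)
}
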