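---
title: "Methods: phylogenetic multilevel meta-analysis of tactic differences in post-mating investment"
author: "artmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic multilevel meta-analysis of tactic differences in post-mating investment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Many species harbour discrete male alternative reproductive tactics (ARTs):
"guarder" or "bourgeois" males that monopolise matings, and "sneaker" males
that parasitise the spawnings of others. Sperm-competition theory predicts
that sneakers — who almost always release sperm in competition — should
invest more in post-mating traits: relatively larger testes, more sperm, and
faster, longer-lived or better-provisioned sperm. `artmeta` implements the
statistical machinery needed to test this prediction across species: an
effect-size engine, a phylogenetic multilevel meta-analytic model,
moderator meta-regressions, publication-bias diagnostics, and a paired
comparison of two ways of measuring relative testes investment (the
gonadosomatic index versus ANCOVA).

The package ships a synthetic-data generator that produces every input the
pipeline consumes, so that the whole analysis runs, and can be validated,
without any external download.

## Effect sizes

All comparisons are expressed as Hedges' *d*, the small-sample-corrected
standardized mean difference between the two tactic groups, with

$$d = J \cdot \frac{\bar x_1 - \bar x_2}{s_\text{pooled}},\qquad
J = 1 - \frac{3}{4\,\mathrm{df} - 1},\qquad
v = \frac{n_1 + n_2}{n_1 n_2} + \frac{d^2}{2(n_1 + n_2)}.$$

The engine converts group summaries, *t* statistics, Mann–Whitney *U*
statistics (via the normal approximation, `z` → `r` → `d`, without
continuity correction) and partial $\eta^2$ from ANCOVA
($d_\text{Cohen} = 2\sqrt{\eta^2/(1-\eta^2)}$, signed by the adjusted group
difference). The sampling variance above is the conventional Hedges–Olkin
large-sample form, applied to the corrected *d* in every route; the Hedges
correction is applied before the variance is computed. Paired *t*
statistics use the fallback $d = t/\sqrt{n}$ with variance $1/n + d^2/2n$
when the pre–post correlation is unreported; such rows are tagged
`method = "paired_t"` so they can be audited.

Sign convention: *d* is positive when the tactic facing the greater sperm
competition risk (e.g. the sneaker) has the larger trait value.
`direction_rule()` + `apply_direction()` enforce this; the operation is an
involution and never touches $|d|$ or $v$.

Reports of "no significant difference" without a direction are retained as
*d* = 0 with variance $(n_1+n_2)/(n_1 n_2)$ — the same formula evaluated at
*d* = 0, which preserves weighting by sample size (no convention exists for
this variance; this is the package's choice). These rows carry a
`directionless` flag and the sensitivity suite refits without them.

## The GSI versus ANCOVA contrast

The gonadosomatic index, $\mathrm{GSI} = 100\,\times$ testes mass / soma
mass (soma = body − testes), only removes body size when testes scale
isometrically with the soma. Under negative allometry (log–log slope
$b < 1$), $\mathrm{GSI} \propto \text{body}^{\,b-1}$ falls with body size,
so the smaller morph *looks* like the heavier investor even when the two
morphs share one allometric line. The recommended alternative is an ANCOVA
of testes mass on tactic with soma mass as the covariate.

`ancova_effect()` first fits the interaction (tactic-specific slopes); when
its *p* ≥ 0.05 the interaction is dropped (0.05 being the operative
convention throughout; the slope-heterogeneous case is still computed from
the main-effects model but flagged). Partial $\eta^2$ for tactic uses
sums of squares with tactic entered after the covariate
($SS_\text{tactic}/(SS_\text{tactic}+SS_\text{res})$) — the standard
treatment for a one-covariate ANCOVA, equivalent to Type-II SS for this
design. The sign comes from the adjusted (equal-soma) group means. Masses
are analysed on the raw scale by default (`log_scale = TRUE` exists but is
off), matching how such re-analyses are conventionally run.

`gsi_compare()` runs both routes on the same raw tables, pairs the
estimates, and tests the mean difference with a paired *t*-test, alongside
counts of how often each route declares a significant tactic difference.

## The multilevel model

Each effect size is modelled as

$$y_i = \mathbf{x}_i^\top\boldsymbol\beta + a_{sp(i)} + b_{sp(i)} +
c_{st(i)} + e_i + \varepsilon_i,$$

with $\mathbf a \sim N(0, \sigma^2_\text{phylo}\mathbf A)$ correlated
through the phylogenetic correlation matrix $\mathbf A$, and species,
study and observation effects iid normal. Phylogeny and species are two
random effects over the same index, distinguished only by their correlation
structure ($\mathbf A$ versus $\mathbf I$); the pair is weakly identified —
on small datasets the optimiser may trade one off against the other, which
is why the validation below focuses on their sum and on the fixed effects.
Sampling errors have known variances $v_i$ on the diagonal of
$\mathbf V$; effect sizes computed from the same sample of males (the same
`experiment_id`) are given covariance $\rho\sqrt{v_iv_j}$, with $\rho = 0.5$
by default — halfway between independence and perfect correlation, the
usual assumption when the trait correlation is unreported — and
$\rho \in \{0.25, 0.75\}$ profiled in the sensitivity suite.

$\mathbf A$ is built from the input tree by setting every branch length to
1, applying Grafen's transform (node height ∝ descendant tips − 1,
normalised, power $\rho_G = 1$ — the method's conventional default, since
the relevant supertrees carry no meaningful branch lengths) and scaling to
unit depth, so $\mathbf A$ has exactly unit diagonal. Trees are re-pruned
(and re-transformed) for every data subset.

### Estimation and inference

Variance components are estimated by REML. The optimiser works on
$\log\sigma^2$ (components stay nonnegative and may shrink to zero),
running Nelder–Mead from three starts with an L-BFGS-B polish; components
below $10^{-8}$ are collapsed to zero. $\boldsymbol\beta$ is the GLS
estimate at the REML solution, with normal (Wald, *z*) 95% CIs — the
default of the standard multilevel meta-analytic toolchain — and an effect
is called significant when its CI excludes zero. The omnibus moderator
statistic $Q_M$ is the Wald chi-square on the moderator coefficients
(intercept excluded; a chi-square rather than F reference, recorded in the
output). Marginal $R^2$ is
$\operatorname{var}(\mathbf X\hat{\boldsymbol\beta}) /
(\operatorname{var}(\mathbf X\hat{\boldsymbol\beta}) + \sum\hat\sigma^2)$
with the population variance of the fitted values.

Heterogeneity uses the multilevel I² with the typical sampling variance
$s^2 = (k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$, $w_i = 1/v_i$;
each level's I² is $100\,\sigma^2_\ell/(\sum\sigma^2 + s^2)$, so the
partition sums exactly to the total.

Meta-regressions test one moderator at a time (joint moderator models are
deliberately not offered — one-at-a-time testing is enforced structurally).
Categorical levels with fewer than five effect sizes are dropped before
fitting; per-level means come from the no-intercept refit. Sneaker
frequency enters as a proportion in [0, 1]; the quadratic model (the
theoretical prediction of a peak at intermediate frequencies) is fitted
first and its squared term's *z*-test reported, with the linear model
alongside. Publication-bias checks are the same machinery with covariate
1/SE (precision; funnel asymmetry) or mean-centered publication year
(decline effect) — they are thin wrappers over `meta_regression()` and
agree with it exactly.

## What the generator emulates — and what it does not

`simulate_effects()` draws data from exactly the model above: a Yule tree
(unit branches + Grafen, so the tree contract holds by construction),
phylogeny-correlated species effects, iid species/study/observation
effects, within-experiment correlated sampling errors, and moderators
attached at the level where they live in real data (taxonomy, fertilisation
mode, tactic type and sneaker frequency per species; year per study).
Defaults describe a realistic synthesis: 40 species, 1–3 studies per
species, 1–3 effects per study (k ≈ 160), variance components
(0.2, 0.1, 0.1, 0.05), sampling variances uniform on [0.05, 0.5] (typical
of *d*-based effects), ~70% of species fish, sneaker frequency
Beta(2, 3) (mean 0.4, matching the empirical spread of sneaker
proportions), years 1990–2020. `simulate_allometry()` draws log-normal body
masses with a 2× guarder:sneaker dimorphism and testes from a log-linear
allometry with slope 0.5 and residual SD 0.15 — the regime in which the GSI
artefact operates — with `tactic_effect` adding a true intercept shift when
one is wanted.

Because the generator *is* the assumed model, passing recovery tests shows
the estimator is correct under its own assumptions — not that real data
meet them. Real datasets add missingness correlated with moderators,
non-normal effect distributions, measurement error in sneaker frequency,
and trees with soft polytomies; none of these are emulated.

## Validation design

The test suite checks, among others:

* **Closed-form reduction** — with all components fixed at zero the fit
  equals the inverse-variance weighted mean to 1e-10.
* **Brute-force oracle** — on 50 random instances (k ≤ 12) the REML
  optimum is never beaten by an exhaustive grid over the four components
  (resolution 0.05 on [0, 0.5]) by more than 1e-4.
* **Cross-implementation agreement** — estimates match an independent
  multilevel meta-analytic implementation (metafor) on a shared instance.
* **Parameter recovery** — k = 300 (50 species × 3 studies × 2 effects),
  true mean 0.4, components (0.2, 0.1, 0.1, 0.05), 200 replicates: the
  median estimate is within 15% and CI coverage within [90%, 98%]. The
  replicate counts here and below were chosen as the smallest that hold
  Monte-Carlo error comfortably inside the acceptance bands.
* **Test size** — a null two-level moderator at k = 60 over 1000
  replicates rejects at close to the nominal 5%. Wald z-based tests with
  estimated variance components are known to run slightly liberal at
  moderate k; the observed rate (≈5–6%) reflects that.
* **GSI inflation** — 500 replicates at slope 0.5, 2× dimorphism, no true
  effect: the GSI route averages d > 0.5 while the ANCOVA route stays
  within ±0.1, and the gap grows monotonically as the slope drops through
  {1.0, 0.8, 0.6, 0.4}.

## Numerical choices and degenerate inputs

* Zero pooled SD with equal means returns d = 0; with unequal means it is
  an error (the effect is undefined).
* A Mann–Whitney *U* so extreme that $|r| \ge 1$ is rejected rather than
  extrapolated.
* Ultrametricity is checked with relative tolerance 1e-8 before a tree is
  converted to a correlation matrix.
* Paired comparisons with zero variance of differences raise a
  degenerate-test error instead of returning an infinite *t*.
* Variants of the sensitivity suite that would leave fewer than two
  effects are skipped with a warning, not an error.
* Species with a single effect keep all their random-effect levels;
  degenerate components are simply allowed to estimate to zero.

## Known limitations

* The phylogeny/species split is weakly identified (by design: it is what
  the four-factor model implies); interpret the two components jointly.
* Wald z intervals run slightly anti-conservative at small k; a
  Knapp–Hartung-style t correction is not currently offered.
* No robust variance estimation, Bayesian estimation, trim-and-fill or
  selection models; reduced-major-axis allometry fitting is out of scope.
* The GSI/ANCOVA comparison is within-study only; no phylogenetic ANCOVA
  across species is attempted.
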