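test_that("Hedges' d from group summaries matches hand-computed values", {
  # identical groups: zero effect, variance reduces to (n1+n2)/(n1 n2)
  es0 <- hedges_d_from_summary(n1 = 10, m1 = 5, sd1 = 1, n2 = 10, m2 = 5, sd2 = 1)
  expect_equal(es0$d, 0)
  expect_equal(es0$var, 0.2)

  # unit mean difference, unit SDs, n = 10 per group: J = 1 - 3/71
  es <- hedges_d_from_summary(n1 = 10, m1 = 1, sd1 = 1, n2 = 10, m2 = 0, sd2 = 1)
  J <- 1 - 3 / 71
  expect_equal(es$d, J * 1, tolerance = 1e-12)
  expect_equal(es$d, 0.9577, tolerance = 1e-4)
  expect_equal(es$var, 0.2 + es$d^2 / 40, tolerance = 1e-12)
  expect_equal(es$var, 0.2229, tolerance = 1e-3)

  # standard errors are accepted in place of SDs (sd = se * sqrt(n))
  es_se <- hedges_d_from_summary(n1 = 10, m1 = 1, se1 = 1 / sqrt(10),
                                 n2 = 10, m2 = 0, se2 = 1 / sqrt(10))
  expect_equal(es_se$d, es$d)

  expect_error(hedges_d_from_summary(n1 = 10, m1 = 1, sd1 = 0, n2 = 10, m2 = 0, sd2 = 0),
               "pooled SD")
  expect_error(hedges_d_from_summary(n1 = 1, m1 = 1, sd1 = 1, n2 = 10, m2 = 0, sd2 = 1),
               "sample sizes")
})

test_that("small-sample correction is below 1 and increases with df", {
  dfs <- c(2, 5, 10, 50, 500, 5000)
  J <- hedges_j(dfs)
  expect_true(all(J < 1))
  expect_true(all(diff(J) > 0))
  expect_equal(hedges_j(1e8), 1, tolerance = 1e-7)
})

test_that("t-statistic conversion round-trips with the summary route", {
  expect_equal(d_from_t(0, 12, 15)$d, 0)
  expect_equal(d_from_t(0, 12, 15)$var, 27 / (12 * 15))

  # t = 2, n = 20 per group: d = J * 2 * sqrt(0.1)
  es <- d_from_t(2, 20, 20)
  expect_equal(es$d, (1 - 3 / (4 * 38 - 1)) * 2 * sqrt(0.1), tolerance = 1e-12)

  # computing t from random group summaries and converting it reproduces
  # the direct summary computation exactly
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.3, 2); s2 <- runif(1, 0.3, 2)
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    expect_equal(d_from_t(t, n1, n2)$d,
                 hedges_d_from_summary(n1, m1, s1, n2, m2, s2)$d,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney conversion follows the z -> r -> d chain", {
  # U at the null midpoint gives d = 0
  expect_equal(d_from_mwu(50, 10, 10)$d, 0)

  # U = 80, n = 10 per group: z = 30/sqrt(175), r = z/sqrt(20),
  # uncorrected d = 2r/sqrt(1 - r^2) ~ 1.1767
  es <- d_from_mwu(80, 10, 10)
  z <- 30 / sqrt(175)
  r <- z / sqrt(20)
  expect_equal(es$d / hedges_j(18), 2 * r / sqrt(1 - r^2), tolerance = 1e-12)
  expect_equal(es$d / hedges_j(18), 1.1767, tolerance = 1e-4)

  # sign of d follows the side of U relative to n1 n2 / 2
  expect_lt(d_from_mwu(20, 10, 10)$d, 0)
  expect_gt(d_from_mwu(80, 10, 10)$d, 0)
  expect_error(d_from_mwu(101, 10, 10), "U must lie")
})

test_that("partial eta-squared converts through Cohen's d", {
  expect_equal(d_from_partial_eta2(0, 10, 10)$d, 0)

  # eta2 = 0.5 gives Cohen's d = 2 exactly before the Hedges correction
  es <- d_from_partial_eta2(0.5, 10, 10)
  expect_identical(es$d / hedges_j(18), 2)

  # eta2 = 0.2, n = 20 per group: Cohen's d = 1, Hedges' d = 1 - 3/151
  es2 <- d_from_partial_eta2(0.2, 20, 20)
  expect_equal(es2$d, 1 - 3 / 151, tolerance = 1e-12)

  # the supplied sign carries the direction
  expect_equal(d_from_partial_eta2(0.2, 20, 20, sign = -1)$d, -es2$d)
  expect_error(d_from_partial_eta2(1, 10, 10), "eta2")
})

test_that("direction rule flips sign without touching magnitude or variance", {
  rule <- direction_rule(high = "sneaker", low = "guarder")
  es <- hedges_d_from_summary(10, 1, 1, 10, 0, 1)

  kept <- apply_direction(es, rule, c("sneaker", "guarder"))
  expect_equal(kept$d, es$d)
  flipped <- apply_direction(es, rule, c("guarder", "sneaker"))
  expect_equal(flipped$d, -es$d)
  expect_equal(flipped$var, es$var)

  # involution
  twice <- apply_direction(apply_direction(es, rule, c("guarder", "sneaker")),
                           rule, c("guarder", "sneaker"))
  expect_equal(twice$d, es$d)

  expect_error(apply_direction(es, rule, c("sneaker", "satellite")), "labels")
  expect_error(direction_rule("sneaker", "sneaker"), "differ")
})

test_that("directionless reports become zero effects weighted by sample size", {
  es <- directionless_zero(10, 10)
  expect_equal(es$d, 0)
  expect_equal(es$var, 0.2)
  expect_true(es$directionless)
  expect_equal(directionless_zero(5, 15)$var, 20 / 75)
})

test_that("sampling variance is positive and even in d", {
  set.seed(3)
  for (i in 1:20) {
    t <- rnorm(1, 0, 3)
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    expect_gt(d_from_t(t, n1, n2)$var, 0)
    expect_equal(d_from_t(t, n1, n2)$var, d_from_t(-t, n1, n2)$var)
  }
})

test_that("the effects table round-trips through the interchange CSV", {
  rule <- direction_rule("sneaker", "guarder")
  rows <- rbind(
    hedges_d_from_summary(10, 1.2, 0.8, 12, 0.7, 0.9,
                          observation_id = "o1", study_id = "s1",
                          experiment_id = "s1_e1", species = "spA",
                          trait_category = "testes_size", measurement = "GSI",
                          taxon_group = "fish", fert_mode = "external",
                          tactic_type = "fixed", sneaker_freq = 0.3,
                          pub_year = 2001),
    directionless_zero(8, 8, observation_id = "o2", study_id = "s2",
                       experiment_id = "s2_e1", species = "spB",
                       trait_category = "sperm_trait", measurement = "length",
                       taxon_group = "insect", fert_mode = "internal",
                       tactic_type = "plastic", sneaker_freq = NA_real_,
                       pub_year = 2015)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_effects_table(rows, path)
  back <- read_effects_table(path)
  expect_equal(back$d, rows$d, tolerance = 1e-12)
  expect_equal(back$var, rows$var, tolerance = 1e-12)
  expect_identical(back$directionless, rows$directionless)
  expect_identical(back$species, rows$species)
  expect_true(is.na(back$sneaker_freq[2]))
})
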