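# Propensity estimation modes, propensity-based weights, and balance
# diagnostics.

test_that("constant survey weights collapse the two estimation modes", {
  smp <- dplyr::mutate(small_sample(), weight = 1)
  suppressWarnings({
    p_cov <- estimate_propensity(smp, c("bmi", "age"), mode = "osw_covariate")
    p_wt <- estimate_propensity(smp, c("bmi", "age"), mode = "osw_weighted")
  })
  expect_equal(p_cov$e_hat, p_wt$e_hat, tolerance = 1e-8)
  # the constant weight column is aliased out of the covariate-mode fit
  expect_true("weight" %in% p_cov$fit$aliased)
})

test_that("a null exposure model yields the marginal exposure rate", {
  set.seed(61)
  d <- tibble::tibble(
    insomnia = rbinom(4000, 1, 0.3),
    bmi = rnorm(4000, 29, 5),
    weight = rep(1, 4000),
    stratum = 1L, bg_id = rep(1:40, each = 100)
  )
  ps <- estimate_propensity(d, "bmi", mode = "osw_covariate")
  expect_lt(max(abs(ps$e_hat - mean(d$insomnia))), 0.05)
})

test_that("propensity model recovers the generating exposure coefficients", {
  pop <- small_pop()
  smp <- draw_survey_sample(pop, 1, seed = 13, bg_prob = rep(0.9, 8),
                            hh_prob = 0.6)
  ps <- estimate_propensity(smp, c("bmi", "age"), mode = "osw_covariate")
  td <- tidy(ps$fit)
  a <- attr(pop, "config")$exposure_coefs
  bmi_row <- td[td$term == "bmi", ]
  age_row <- td[td$term == "age", ]
  expect_gt(a[["bmi"]], bmi_row$conf.low)
  expect_lt(a[["bmi"]], bmi_row$conf.high)
  expect_gt(a[["confounder"]], age_row$conf.low)
  expect_lt(a[["confounder"]], age_row$conf.high)
})

test_that("IPTW and odds weights follow their formulas", {
  e <- c(0.25, 0.25)
  z <- c(1L, 0L)
  expect_equal(propensity_weights(e, z, "iptw"), c(4, 4 / 3))
  expect_equal(propensity_weights(e, z, "odds"), c(1, 1 / 3))

  # symmetric case with balanced groups: IPTW-weighted exposed fraction
  # is exactly one half
  z2 <- rep(c(1L, 0L), 250)
  w <- propensity_weights(rep(0.5, 500), z2, "iptw")
  expect_equal(weighted.mean(z2, w), 0.5, tolerance = 1e-12)
})

test_that("absolute SMD matches its definition and detects balance", {
  d <- tibble::tibble(
    insomnia = rep(c(1L, 0L), each = 4),
    x = c(1.0, 1.2, 1.4, 1.2, 0.8, 1.0, 1.2, 1.0),
    weight = rep(1, 8)
  )
  bt <- balance_table(d, "x")
  s_exp <- sqrt(svycausal:::weighted_var(d$x[1:4], rep(1, 4)))
  expect_equal(bt$smd_before, abs(1.2 - 1.0) / s_exp)

  # identical groups balance exactly
  d2 <- tibble::tibble(insomnia = rep(c(1L, 0L), each = 3),
                       x = rep(c(1, 2, 3), 2), weight = rep(1, 6))
  expect_equal(balance_table(d2, "x")$smd_before, 0)

  # categorical covariates: one row per level
  d$g <- rep(c("a", "b"), 4)
  expect_equal(nrow(balance_table(d, "g")), 2)
})

test_that("weighting by the true propensity balances covariates", {
  set.seed(63)
  n <- 40000
  x <- rnorm(n)
  e <- plogis(-0.5 + 0.9 * x)
  z <- as.integer(runif(n) < e)
  d <- tibble::tibble(insomnia = z, x = x, weight = rep(1, n))
  w_iptw <- propensity_weights(e, z, "iptw")
  bt <- balance_table(d, "x", rows = seq_len(n), analysis_weights = w_iptw)
  expect_gt(bt$smd_before, 0.5)
  expect_lt(bt$smd_after, 0.05)
})

test_that("CEM weighting zeroes the SMD of a matched bin indicator", {
  smp <- small_sample()
  cem <- cem_match(smp, list(age = c(40, 55, 65)))
  smp$age_bin2 <- as.numeric(coarsen(smp$age, c(40, 55, 65)) == 2L)
  bt <- balance_table(smp, "age_bin2", rows = cem$row,
                      analysis_weights = cem$cemw)
  expect_equal(bt$smd_after, 0, tolerance = 1e-10)
})
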