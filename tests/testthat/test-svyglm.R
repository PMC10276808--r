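# Pseudo-likelihood GLM engine: closed-form point estimates, weight-scale
# invariance, and the design-based linearized covariance against
# independent oracles.

test_that("intercept-only fits match their closed forms", {
  d <- tibble::tibble(y = c(1, 0, 1, 0))
  fit <- svy_glm(d, y ~ 1, family = "binomial")
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(unname(fit$fitted[1]), 0.5, tolerance = 1e-8)

  # weighted poisson rate with offset: log(sum(w y) / sum(w t))
  d2 <- tibble::tibble(y = c(3L, 1L, 0L, 2L), t = c(2, 1, 3, 1),
                       w = c(1, 2, 1, 0.5))
  fit2 <- svy_glm(d2, y ~ 1, family = "poisson", weights = "w",
                  offset = log(d2$t))
  expect_equal(unname(coef(fit2)),
               log(sum(d2$w * d2$y) / sum(d2$w * d2$t)), tolerance = 1e-8)
})

test_that("coefficients are invariant to rescaling the weights", {
  smp <- small_sample()
  f1 <- svy_glm(smp, mci ~ insomnia + bmi, family = "binomial",
                weights = smp$weight)
  f2 <- svy_glm(smp, mci ~ insomnia + bmi, family = "binomial",
                weights = smp$weight * 10)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("linearized covariance equals the textbook sandwich for iid PSUs", {
  set.seed(21)
  n <- 120
  d <- tibble::tibble(
    x = rnorm(n), w = runif(n, 0.5, 2),
    y = rbinom(n, 1, plogis(-0.3 + 0.8 * rnorm(n))),
    stratum = 1L, psu = seq_len(n)
  )
  fit <- svy_glm(d, y ~ x, family = "binomial", weights = "w",
                 design = svy_design("stratum", "psu"))
  X <- cbind(1, d$x)
  V_oracle <- textbook_sandwich(X, d$y, fit$fitted, d$w, "binomial")
  expect_equal(unname(fit$vcov), unname(V_oracle), tolerance = 1e-8)

  # hand-sized poisson check on five points
  d5 <- tibble::tibble(y = c(0L, 2L, 1L, 3L, 1L), x = c(-1, 0, 1, 2, 0.5),
                       stratum = 1L, psu = 1:5)
  f5 <- svy_glm(d5, y ~ x, family = "poisson",
                design = svy_design("stratum", "psu"))
  X5 <- cbind(1, d5$x)
  V5 <- textbook_sandwich(X5, d5$y, f5$fitted, rep(1, 5), "poisson")
  expect_equal(unname(f5$vcov), unname(V5), tolerance = 1e-8)
})

test_that("replicating every PSU leaves point estimates unchanged", {
  smp <- small_sample()
  doubled <- dplyr::bind_rows(smp, dplyr::mutate(smp, stratum = stratum + 100L,
                                                 bg_id = bg_id + 10000L))
  f1 <- svy_glm(smp, mci ~ insomnia + bmi, family = "binomial",
                weights = "weight", design = svy_design())
  f2 <- svy_glm(doubled, mci ~ insomnia + bmi, family = "binomial",
                weights = "weight", design = svy_design())
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("lonely-PSU strata are handled with a warning", {
  set.seed(31)
  d <- tibble::tibble(
    y = rbinom(40, 1, 0.4), x = rnorm(40),
    stratum = c(rep(1L, 36), rep(2L, 4)),
    psu = c(rep(1:9, each = 4), rep(10L, 4))
  )
  expect_warning(
    fit <- svy_glm(d, y ~ x, family = "binomial", weights = rep(1, 40),
                   design = svy_design("stratum", "psu")),
    "single PSU")
  expect_equal(fit$lonely_strata, 1L)
  expect_true(all(is.finite(fit$se)))
})

test_that("wald intervals follow the normal quantile", {
  fit <- structure(list(coefficients = c(x = 0), se = c(x = 1),
                        converged = TRUE), class = "svy_glm")
  ci <- wald_interval(fit, "x")
  expect_equal(unname(ci), c(-1, 1) * qnorm(0.975), tolerance = 1e-9)
  expect_equal(unname(wald_interval(fit, "x", exponentiate = TRUE)),
               exp(c(-1, 1) * qnorm(0.975)), tolerance = 1e-9)

  fit0 <- structure(list(coefficients = c(x = 2), se = c(x = 0),
                         converged = TRUE), class = "svy_glm")
  expect_equal(unname(wald_interval(fit0, "x")), c(2, 2))
})

test_that("aliased covariates are dropped with their names recorded", {
  smp <- small_sample()
  smp$const <- 1.7
  fit <- svy_glm(smp, insomnia ~ bmi + const, family = "binomial")
  expect_equal(fit$aliased, "const")
  ref <- svy_glm(smp, insomnia ~ bmi, family = "binomial")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
})

test_that("design-based SEs exceed naive ones under informative clustered sampling", {
  pop <- small_pop()
  ratios <- vapply(1:10, function(r) {
    s <- draw_survey_sample(pop, 1, seed = r)
    fd <- suppressWarnings(
      svy_glm(s, mci ~ insomnia, family = "binomial", weights = "weight",
              design = svy_design()))
    fm <- svy_glm(s, mci ~ insomnia, family = "binomial", weights = "weight")
    fd$se[["insomnia"]] / fm$se[["insomnia"]]
  }, numeric(1))
  expect_gt(mean(ratios), 1)
})

test_that("linearized SEs agree with a PSU-bootstrap oracle", {
  set.seed(77)
  n_psu <- 60
  psu_eff <- rnorm(n_psu, 0, 0.4)
  d <- tibble::tibble(
    psu = rep(seq_len(n_psu), each = 12),
    stratum = rep(rep(1:2, each = n_psu / 2), each = 12),
    x = rnorm(n_psu * 12),
    w = rep(runif(n_psu, 0.5, 2), each = 12)
  )
  d$y <- rbinom(nrow(d), 1, plogis(-0.2 + 0.5 * d$x + psu_eff[d$psu]))
  fit <- svy_glm(d, y ~ x, family = "binomial", weights = "w",
                 design = svy_design("stratum", "psu"))
  # within-stratum with-replacement resampling of whole PSUs
  boot <- vapply(1:400, function(b) {
    idx <- unlist(lapply(1:2, function(h) {
      ids <- unique(d$psu[d$stratum == h])
      pick <- sample(ids, length(ids), replace = TRUE)
      unlist(lapply(pick, function(p) which(d$psu == p)))
    }))
    db <- d[idx, ]
    coef(svy_glm(db, y ~ x, family = "binomial", weights = "w"))[["x"]]
  }, numeric(1))
  expect_lt(abs(sd(boot) / fit$se[["x"]] - 1), 0.10)
})

test_that("wald coverage is nominal for an intercept-only logistic model", {
  set.seed(55)
  p_true <- 0.3
  theta <- qlogis(p_true)
  covered <- vapply(1:1000, function(r) {
    y <- rbinom(400, 1, p_true)
    fit <- svy_glm(tibble::tibble(y = y), y ~ 1, family = "binomial")
    ci <- wald_interval(fit, "(Intercept)")
    ci[1] <= theta && theta <= ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("input validation rejects malformed specifications", {
  d <- tibble::tibble(y = c(0, 1, 2), x = 1:3, t = c(1, 1, 1))
  expect_error(svy_glm(d, y ~ x, family = "binomial"), "binary")
  expect_error(svy_glm(d, y ~ x, family = "binomial", offset = log(d$t)),
               "offset")
  expect_error(svy_glm(dplyr::mutate(d, y = c(0.5, 1, 2)), y ~ x,
                       family = "poisson"), "integer")
  expect_error(svy_glm(dplyr::mutate(d, y = c(0, 1, 1)), y ~ x,
                       family = "binomial", weights = rep(0, 3)),
               "weights")
})
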