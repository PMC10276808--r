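# Population generator: covariate distributions, association models,
# potential-outcome bookkeeping, and reproducibility.

test_that("truncated normal draws respect bounds and symmetry", {
  set.seed(1)
  x <- rtruncnorm(1e5, 40, 15, 23, 69)
  expect_gte(min(x), 23)
  expect_lte(max(x), 69)

  set.seed(2)
  y <- rtruncnorm(1e5, 0, 1, -10, 10)
  expect_lt(abs(mean(y)), 3 / sqrt(1e5))

  # degenerate-scale limit collapses on the mean
  set.seed(3)
  expect_equal(rtruncnorm(1, 6, 1e-10, 3, 9), 6, tolerance = 1e-6)

  expect_error(rtruncnorm(1, NaN, 1, 0, 1), "finite")
  expect_error(rtruncnorm(1, 0, -1, 0, 1), "finite|sd")
  expect_error(rtruncnorm(1, 0, 1, 2, 1), "lo < hi")
})

test_that("exposure model matches its closed form", {
  cfg <- pop_config()
  # spot value computed directly from the printed odds ratios
  p <- expit(svycausal:::exposure_lp(29, 40, cfg$exposure_coefs))
  expect_equal(p, plogis(log(0.109) + 29 * log(1.025) + 40 * log(1.019)))
  expect_equal(round(p, 3), 0.321)

  # intercept-only model gives probability 1/2 everywhere
  cfg0 <- pop_config(exposure_coefs = c(intercept = 0, bmi = 0, confounder = 0),
                     n_bg = 16, hh_per_bg_mean = 5)
  pop0 <- generate_population(cfg0, seed = 1)
  expect_true(all(pop0$p_insomnia == 0.5))
})

test_that("population frame satisfies its structural invariants", {
  pop <- small_pop()
  cfg <- attr(pop, "config")

  # observed outcome equals the potential outcome selected by exposure
  expect_identical(pop$mci,
                   pop$insomnia * pop$mci_pot1 + (1L - pop$insomnia) * pop$mci_pot0)
  expect_identical(pop$htn_v2,
                   pop$insomnia * pop$htn_v2_pot1 + (1L - pop$insomnia) * pop$htn_v2_pot0)

  # households: two members sharing ids and random effects, ages within
  # the half-width of the household mean age
  expect_true(all(table(pop$hh_id) == 2))
  by_hh <- split(pop$hh_effect, pop$hh_id)
  expect_true(all(vapply(by_hh, function(x) x[1] == x[2], logical(1))))
  age_by_hh <- split(pop$age, pop$hh_id)
  spread <- vapply(age_by_hh, function(a) abs(a[1] - a[2]), numeric(1))
  expect_true(all(spread <= 2 * cfg$age_halfwidth))

  # covariate truncation bounds and probability range
  expect_true(all(pop$bmi >= 15 & pop$bmi <= 63))
  expect_true(all(pop$years_between >= 3 & pop$years_between <= 9))
  expect_true(all(pop$p_insomnia > 0 & pop$p_insomnia < 1))

  # strata cover all BGs and are nonempty
  expect_identical(sort(unique(pop$stratum)), 1:8)
})

test_that("same seed reproduces the frame exactly", {
  cfg <- pop_config(n_bg = 24, hh_per_bg_mean = 10)
  a <- generate_population(cfg, seed = 99)
  b <- generate_population(cfg, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_population(cfg, seed = 100)
  expect_false(identical(a$bmi, c$bmi))
})

test_that("zero random effects reduce prevalence to the expit of the linear predictor", {
  cfg <- pop_config(n_bg = 40, hh_per_bg_mean = 120,
                    hh_re_sd = 0, bg_re_sd = 0,
                    bmi = list(mean = 29, sd = 1e-9, lo = 15, hi = 63),
                    hh_mean_age = list(mean = 40, sd = 1e-9, lo = 23, hi = 69),
                    age_halfwidth = 0)
  pop <- generate_population(cfg, seed = 4)
  p_expected <- plogis(svycausal:::outcome_lp(0, 29, 40, 0, 0, cfg$mci_coefs))
  expect_lt(abs(mean(pop$mci_pot0) - p_expected), 0.01)
})

test_that("education calibration hits the target correlation", {
  set.seed(10)
  ages <- round(rtruncnorm(1e5, 40, 15, 23, 69)) +
    sample(-10:10, 1e5, replace = TRUE)

  set.seed(11)
  e <- generate_education(ages, rho = 0.75)
  expect_equal(cor(e$education, ages), 0.75, tolerance = 0.02)
  expect_gt(e$q, 0)
  expect_lt(e$q, 1)

  set.seed(12)
  e2 <- generate_education(ages, rho = 0.25)
  expect_equal(cor(e2$education, ages), 0.25, tolerance = 0.02)
  expect_gt(e$q, e2$q)

  expect_error(generate_education(rep(40, 10), 0.5), "zero variance")
})

test_that("education mode swaps the confounder in all association models", {
  cfg <- pop_config(n_bg = 40, hh_per_bg_mean = 40,
                    confounder_mode = "education", education_rho = 0.5)
  pop <- generate_population(cfg, seed = 6)
  expect_true("education" %in% names(pop))
  expect_equal(cor(pop$education, pop$age), 0.5, tolerance = 0.05)
  # exposure probability is a function of bmi and education, not age
  p <- expit(svycausal:::exposure_lp(pop$bmi, pop$education, cfg$exposure_coefs))
  expect_equal(pop$p_insomnia, p)
})

test_that("intercept calibration reaches targets and is monotone", {
  cfg <- pop_config(n_bg = 40, hh_per_bg_mean = 40)
  targets <- list(exposure = 0.15, mci = 0.25)
  cal <- calibrate_intercepts(cfg, targets, seed = 2)
  expect_equal(unname(cal$achieved["exposure"]), 0.15, tolerance = 0.005)
  expect_equal(unname(cal$achieved["mci"]), 0.25, tolerance = 0.005)

  pop <- generate_population(cal$config, seed = 2)
  expect_lt(abs(mean(pop$insomnia) - 0.15), 0.02)
  expect_lt(abs(mean(pop$mci) - 0.25), 0.02)

  # a higher target demands a strictly larger intercept
  cal_hi <- calibrate_intercepts(cfg, list(exposure = 0.35), seed = 2)
  expect_gt(cal_hi$intercepts[["exposure"]], cal$intercepts[["exposure"]])

  # degenerate slope-free logistic: target 1/2 needs intercept 0
  cfg0 <- pop_config(n_bg = 16, hh_per_bg_mean = 5,
                     exposure_coefs = c(intercept = 2, bmi = 0, confounder = 0))
  cal0 <- calibrate_intercepts(cfg0, list(exposure = 0.5), seed = 1)
  expect_equal(cal0$intercepts[["exposure"]], 0, tolerance = 1e-6)
})

test_that("null exposure effects make the potential outcomes exchangeable", {
  cfg <- pop_config(
    n_bg = 60, hh_per_bg_mean = 60,
    mci_coefs = c(intercept = log(0.03), exposure = 0, bmi = log(1.018),
                  confounder = log(1.056)),
    htn1_coefs = c(intercept = log(0.002), exposure = 0, bmi = log(1.088),
                   confounder = log(1.082)),
    htn2_coefs = c(intercept = log(0.001), exposure = 0, bmi = log(1.082),
                   confounder = log(1.092), years = log(1.098)))
  pop <- generate_population(cfg, seed = 8)
  te <- true_effects(pop)
  expect_true(all(abs(log(te$estimate)) < 0.1))
})
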