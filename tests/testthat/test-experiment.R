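# Replicate driver: aggregation arithmetic, determinism, robustness
# classification.

make_fake_reps <- function(est, lo, hi, n = length(est)) {
  dplyr::bind_cols(
    method_config("psm", scheme = "osw")[rep(1, n), ],
    tibble::tibble(estimand = "att", scale = "OR", estimate = est,
                   conf.low = lo, conf.high = hi, log_se = 0.1,
                   n_used = 100L, rep = seq_len(n))
  )
}

test_that("bias and coverage aggregation matches direct computation", {
  te <- tibble::tibble(outcome = "mci", estimand = "att", scale = "OR",
                       estimate = 1.15)

  # estimates identical to the truth: zero bias, full coverage
  m0 <- svycausal:::aggregate_metrics(
    make_fake_reps(rep(1.15, 5), rep(1.0, 5), rep(1.3, 5)), te)
  expect_equal(m0$bias, 0)
  expect_equal(m0$cover, 1)

  # hand-counted coverage: two of three intervals contain 1.15
  m1 <- svycausal:::aggregate_metrics(
    make_fake_reps(c(1.05, 1.25, 0.9), c(0.9, 1.1, 0.8), c(1.2, 1.4, 1.0)), te)
  expect_equal(m1$cover, 2 / 3, tolerance = 1e-12)
  expect_equal(m1$bias, mean(c(1.05, 1.25, 0.9) - 1.15), tolerance = 1e-12)
  expect_equal(m1$mc_se_cover, sqrt((2 / 3) * (1 / 3) / 3), tolerance = 1e-12)

  # failed replicates are excluded and counted
  reps <- make_fake_reps(c(1.1, NA, 1.2), c(1, NA, 1.1), c(1.2, NA, 1.3))
  m2 <- svycausal:::aggregate_metrics(reps, te)
  expect_equal(m2$n_fail, 1L)
  expect_equal(m2$n_reps_used, 2L)
  # a third of the replicates failed, above the 10% validity threshold
  expect_false(m2$valid)
})

test_that("the replicate driver is deterministic in its seed", {
  pop <- small_pop()
  cfg <- method_config("psm", scheme = "osw")
  m1 <- suppressWarnings(run_replicates(pop, cfg, n_reps = 4, seed = 31))
  m2 <- suppressWarnings(run_replicates(pop, cfg, n_reps = 4, seed = 31))
  expect_equal(m1$bias, m2$bias)
  expect_equal(m1$cover, m2$cover)
  m3 <- suppressWarnings(run_replicates(pop, cfg, n_reps = 4, seed = 32))
  expect_false(isTRUE(all.equal(m1$bias, m3$bias)))
})

test_that("robustness classification applies the closed coverage band", {
  key <- method_config("psm", scheme = "osw")[
    , c("family", "ps_mode", "cem_bin_osw", "adjusted", "scheme", "outcome")]
  cells <- function(covers) {
    dplyr::bind_cols(
      key[rep(1, 3), ],
      tibble::tibble(scenario = c(1L, 2L, 1L),
                     specification = c("correct", "correct", "under"),
                     cover = covers)
    )
  }
  expect_true(classify_robust(cells(c(0.95, 0.95, 0.95)))$robust)
  expect_false(classify_robust(cells(c(0.95, 0.95, 0.413)))$robust)
  # band endpoints are inside (closed band)
  expect_true(classify_robust(cells(c(0.93, 0.97, 0.95)))$robust)
  # missing cells leave the flag undetermined
  incomplete <- cells(c(0.95, 0.95, 0.95))[1:2, ]
  expect_true(is.na(classify_robust(incomplete)$robust))
})

test_that("plot methods return ggplot objects", {
  pop <- small_pop()
  cfgs <- dplyr::bind_rows(method_config("psm", scheme = "osw"),
                           method_config("iptw", scheme = "psw_osw"))
  m <- suppressWarnings(run_replicates(pop, cfgs, n_reps = 3, seed = 41))
  expect_s3_class(ggplot2::autoplot(m), "ggplot")

  smp <- small_sample()
  bt <- balance_table(smp, c("bmi", "age"))
  expect_s3_class(plot_balance(bt), "ggplot")
})

test_that("sensitivity-analysis branches run end to end at toy scale", {
  base <- pop_config(n_bg = 40, hh_per_bg_mean = 40)
  cfg <- method_config("psm", ps_mode = "osw_covariate", scheme = "osw",
                       specification = "under")

  mu <- suppressWarnings(run_sensitivity(
    "unmeasured_confounder", base_config = base, n_reps = 3, seed = 51,
    configs = dplyr::bind_rows(cfg, dplyr::mutate(cfg, scenario = 2L))))
  expect_equal(sort(unique(mu$scenario)), c(1L, 2L))
  expect_true(all(mu$specification == "under"))

  me <- suppressWarnings(run_sensitivity(
    "education_correlation", base_config = base, n_reps = 3, seed = 52,
    configs = cfg, rho_values = c(0.3, 0.7)))
  expect_equal(sort(unique(me$rho)), c(0.3, 0.7))

  mp <- suppressWarnings(run_sensitivity(
    "prevalence_grid", base_config = base, n_reps = 3, seed = 53,
    configs = method_config("psm", ps_mode = "osw_covariate", scheme = "osw"),
    prevalences = 0.25))
  expect_equal(mp$prev_exposure, 0.25)
  expect_true(all(is.finite(mp$cover)))
})
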