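# Scenario execution, the stability-exclusion rule, and performance measures
# with their Monte Carlo standard errors.

fake_results <- function(psi, se, theta = 0) {
  z <- 1.96
  tibble::tibble(
    rep = seq_along(psi), seed = seq_along(psi), psi = psi, se = se,
    ci_low = psi - z * se, ci_high = psi + z * se, error = NA_character_
  )
}

test_that("the scenario registry enumerates the full design", {
  grid <- scenario_grid()
  expect_equal(nrow(grid), 20)
  expect_equal(sort(unique(grid$n)), c(200L, 500L, 1000L, 2000L))
  expect_setequal(unique(grid$dgm_name), dgm_names())
  expect_equal(sum(grid$p == 87L), 8)
})

test_that("replicate tables are deterministic and datasets independent of estimator settings", {
  params <- tiny_dgm()
  sp <- scenario_spec("simple-1", n = 60, method = "aipw", folds = "none",
                      n_reps = 3, base_seed = 5)
  nf <- parametric_nuisance_fn(params)
  r1 <- run_scenario(sp, params, nuisance_fn = nf)
  r2 <- run_scenario(sp, params, nuisance_fn = nf)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 3)

  # seed isolation: estimator settings must not change generated data
  sp_cf <- scenario_spec("simple-1", n = 60, method = "aipw", folds = 2,
                         n_reps = 2, base_seed = 5)
  seeds_plain <- run_scenario(sp, params, nuisance_fn = nf)$seed
  seeds_cf <- run_scenario(sp_cf, params, nuisance_fn = nf)$seed
  expect_identical(seeds_plain[1:2], seeds_cf)

  # estimator failures are recorded, not raised
  failing <- function(train, newdata, seed) stop("boom")
  r3 <- run_scenario(sp, params, nuisance_fn = failing)
  expect_true(all(!is.na(r3$error)))
  expect_true(all(is.na(r3$psi)))
})

test_that("the stability filter applies the two exclusion rules", {
  # identical replicates: nothing excluded
  res <- fake_results(rep(0.5, 10), rep(1, 10))
  expect_equal(stability_filter(res)$n_excluded, 0)

  # a single SE eleven times the median is excluded; ten times is not
  res <- fake_results(rep(0.5, 101), c(rep(1, 100), 11))
  filt <- stability_filter(res)
  expect_equal(filt$n_excluded, 1)
  expect_equal(filt$excluded$se, 11)
  res_edge <- fake_results(rep(0.5, 101), c(rep(1, 100), 10))
  expect_equal(stability_filter(res_edge)$n_excluded, 0)

  # heavy-tailed fixture: exclusions match the two-rule oracle
  psi <- withr::with_seed(8L, rcauchy(200, location = 0.4, scale = 0.05))
  se <- withr::with_seed(9L, 0.1 * exp(rnorm(200, sd = 1.2)))
  res <- fake_results(psi, se)
  filt <- stability_filter(res)
  flags <- oracle_stability_flags(psi, se)
  expect_equal(filt$n_excluded, sum(flags))
  expect_setequal(filt$excluded$rep, which(flags))
  # conservation
  expect_equal(nrow(filt$kept) + nrow(filt$excluded), 200)

  # scale equivariance
  res_scaled <- fake_results(7 * psi, 7 * se)
  expect_equal(stability_filter(res_scaled)$n_excluded, sum(flags))
})

test_that("performance measures match a spreadsheet-style recomputation", {
  theta <- 0.4
  psi <- withr::with_seed(10L, rnorm(50, 0.45, 0.12))
  se <- withr::with_seed(11L, runif(50, 0.08, 0.16))
  res <- fake_results(psi, se)
  perf <- performance(res, theta)

  expect_equal(perf$bias, mean(psi) - theta)
  expect_equal(perf$relative_bias_pct, 100 * (mean(psi) - theta) / theta)
  expect_equal(perf$empirical_se, sd(psi))
  expect_equal(perf$model_se, sqrt(mean(se^2)))
  expect_equal(
    perf$relative_error_model_se_pct,
    100 * (sqrt(mean(se^2)) / sd(psi) - 1)
  )
  expect_equal(
    perf$coverage_pct,
    100 * mean(psi - 1.96 * se <= theta & theta <= psi + 1.96 * se)
  )
  expect_equal(perf$power_pct, 100 * mean(abs(psi) > qnorm(0.975) * se))
  expect_equal(perf$bias_mcse, sd(psi) / sqrt(50))
  expect_equal(perf$empirical_se_mcse, sd(psi) / sqrt(2 * 49))
  cov <- mean(psi - 1.96 * se <= theta & theta <= psi + 1.96 * se)
  expect_equal(perf$coverage_pct_mcse, 100 * sqrt(cov * (1 - cov) / 50))

  # degenerate case: psi always equal to theta
  res0 <- fake_results(rep(theta, 10), rep(0.1, 10))
  perf0 <- performance(res0, theta)
  expect_equal(perf0$bias, 0)
  expect_equal(perf0$relative_bias_pct, 0)
  expect_equal(perf0$coverage_pct, 100)

  # theta = 0: relative bias undefined, not infinite
  perf_null <- performance(res, 0)
  expect_true(is.na(perf_null$relative_bias_pct))
})

test_that("MCSEs halve when replications quadruple", {
  psi_big <- withr::with_seed(12L, rnorm(2000, 0.4, 0.1))
  se_big <- rep(0.1, 2000)
  p1 <- performance(fake_results(psi_big[1:500], se_big[1:500]), 0.4)
  p4 <- performance(fake_results(psi_big, se_big), 0.4)
  expect_equal(p4$bias_mcse / p1$bias_mcse, 0.5, tolerance = 0.15)
  expect_equal(p4$empirical_se_mcse / p1$empirical_se_mcse, 0.5, tolerance = 0.15)
})

test_that("summarize_grid emits one row per measure with MCSEs attached", {
  res <- fake_results(withr::with_seed(13L, rnorm(30, 0.4, 0.1)),
                      rep(0.1, 30))
  rows <- list(a = performance(res, 0.4), b = performance(res, 0.5))
  long <- summarize_grid(rows, id = data.frame(scenario = c("a", "b")))
  expect_equal(nrow(long), 2 * 7)
  expect_true(all(c("measure", "value", "mcse") %in% names(long)))
  # undefined relative bias comes through as NA
  rows_na <- list(performance(res, 0))
  long_na <- summarize_grid(rows_na)
  expect_true(is.na(long_na$value[long_na$measure == "relative_bias_pct"]))
})
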