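# Synthetic data-generating mechanisms: generation contracts, design
# expansion against brute-force oracles, and the nesting/collapsibility
# properties.

test_that("confounder generation honours the stated families and dimensions", {
  small <- generate_confounders(dgm_params("simple-1"), 200, seed = 1)
  expect_equal(ncol(small), 14)
  expect_equal(sum(apply(small, 2, function(v) length(unique(v)) > 2)), 13)

  large <- generate_confounders(dgm_params("simple-2"), 200, seed = 1)
  expect_equal(ncol(large), 87)
  expect_equal(sum(apply(large, 2, function(v) length(unique(v)) > 2)), 78)

  # determinism
  expect_identical(
    generate_confounders(dgm_params("complex-1a"), 50, seed = 9),
    generate_confounders(dgm_params("complex-1a"), 50, seed = 9)
  )
})

test_that("independence case: column means match model intercepts", {
  # all cross-variable coefficients zero -> each column marginal
  params <- tiny_dgm()
  params$confounders[[2]]$coefs <- c(1.5, 0) # N(1.5, 1), no dependence
  W <- generate_confounders(params, 1e5, seed = 4)
  se_bin <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(mean(W[, 1]) - 0.3), 4 * se_bin)
  expect_lt(abs(mean(W[, 2]) - 1.5), 4 / sqrt(1e5))
})

test_that("exposure generation matches the expanded-design oracle", {
  params <- dgm_params("complex-1a")
  W <- generate_confounders(params, 500, seed = 21)
  x <- generate_exposure(W, params, seed = 22)
  lp <- oracle_exposure_lp(params, W)
  x_oracle <- withr::with_seed(22L, rbinom(nrow(W), 1L, plogis(lp)))
  expect_identical(x, x_oracle)

  # degenerate logit: huge negative intercept -> all unexposed
  params$exposure$intercept <- -50
  expect_true(all(generate_exposure(W, params, seed = 1) == 0))
})

test_that("all-zero exposure coefficients give 50% exposure", {
  params <- tiny_dgm(a_main = c(0, 0))
  params$exposure$intercept <- 0
  W <- generate_confounders(params, 1e5, seed = 2)
  x <- generate_exposure(W, params, seed = 3)
  expect_lt(abs(mean(x) - 0.5), 4 * sqrt(0.25 / 1e5))
})

test_that("outcome generation matches the multiplier-4 oracle expansion", {
  params <- dgm_params("complex-1b")
  expect_equal(params$interaction_multiplier, 4)
  W <- generate_confounders(params, 400, seed = 31)
  X <- generate_exposure(W, params, seed = 32)
  y <- generate_outcome(W, X, params, seed = 33)
  mu <- oracle_outcome_mean(params, W, X)
  y_oracle <- withr::with_seed(33L, mu + rnorm(nrow(W), 0, params$outcome$sd))
  expect_equal(y, y_oracle, tolerance = 1e-12)
})

test_that("outcome with zero coefficients is standard noise; noiseless case recovers the effect", {
  params <- tiny_dgm(beta_x = 0, b_main = c(0, 0))
  W <- generate_confounders(params, 1e5, seed = 5)
  X <- generate_exposure(W, params, seed = 6)
  y <- generate_outcome(W, X, params, seed = 7)
  expect_lt(abs(mean(y)), 4 / sqrt(1e5))
  expect_lt(abs(sd(y) - 1), 0.02)

  quiet <- tiny_dgm(beta_x = 0.7, sd = 1e-10)
  y2 <- generate_outcome(W, X, quiet, seed = 8)
  expect_equal(
    mean(y2[X == 1]) - mean(y2[X == 0]) -
      (mean(W[X == 1, ] %*% quiet$outcome$main) -
        mean(W[X == 0, ] %*% quiet$outcome$main)),
    0.7,
    tolerance = 1e-6
  )
})

test_that("complex mechanisms with zeroed extras reproduce their simple counterparts byte-for-byte", {
  cx <- dgm_params("complex-1a")
  cx$exposure$ww_coefs[] <- 0
  cx$exposure$nl_coefs[] <- 0
  cx$outcome$ww_coefs[] <- 0
  cx$outcome$xw_coefs[] <- 0
  cx$outcome$nl_coefs[] <- 0
  d_cx <- generate_dataset(cx, 300, seed = 77)
  d_s <- generate_dataset(dgm_params("simple-1"), 300, seed = 77)
  expect_identical(d_cx$W, d_s$W)
  expect_identical(d_cx$X, d_s$X)
  expect_identical(d_cx$Y, d_s$Y)
})

test_that("configuration errors name the offending variable", {
  params <- tiny_dgm()
  params$confounders[[2]]$coefs <- c(0, 0.4, 0.9) # one coefficient too many
  expect_error(generate_confounders(params, 10, 1), "confounder 2")
  params2 <- tiny_dgm()
  params2$confounders[[1]]$family <- "poisson"
  expect_error(generate_confounders(params2, 10, 1), "family")
})

test_that("interaction multipliers follow the mechanism definitions", {
  mults <- vapply(dgm_names(), function(nm) dgm_params(nm)$interaction_multiplier, 1)
  expect_equal(unname(mults), c(1, 2, 4, 1, 1))
  # simple variants carry all-zero interaction and non-linear coefficients
  for (nm in c("simple-1", "simple-2")) {
    p <- dgm_params(nm)
    expect_true(all(p$outcome$ww_coefs == 0) && all(p$outcome$xw_coefs == 0))
    expect_true(all(p$exposure$ww_coefs == 0) && all(p$exposure$nl_coefs == 0))
  }
})
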