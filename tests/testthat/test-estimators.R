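# AIPW, TMLE, fold construction and cross-fitting.

read_nuisance_fixture <- function(file) {
  df <- read.csv(fixture_path(file))
  list(
    data = observed_data(matrix(0, nrow(df), 1), df$x, df$y),
    nuis = nuisance_estimates(df$e1, df$e0, df$g)
  )
}

test_that("AIPW reproduces the zero-residual and pure-IPW reductions", {
  fx <- read_nuisance_fixture("zero_residual.csv")
  est <- aipw(fx$data, fx$nuis)
  expect_equal(est$psi, 1)
  expect_equal(est$se, 0)

  # zero outcome predictions, g = 1/2: psi reduces to mean(2 (2X - 1) Y)
  y <- withr::with_seed(1L, rnorm(40))
  x <- withr::with_seed(2L, rbinom(40, 1, 0.5))
  d <- observed_data(matrix(0, 40, 1), x, y)
  nuis <- nuisance_estimates(rep(0, 40), rep(0, 40), rep(0.5, 40))
  expect_equal(aipw(d, nuis)$psi, mean(2 * (2 * x - 1) * y), tolerance = 1e-12)

  # zero residual terms: psi equals the g-computation contrast
  e1 <- withr::with_seed(3L, rnorm(40))
  e0 <- withr::with_seed(4L, rnorm(40))
  yy <- ifelse(x == 1, e1, e0)
  d2 <- observed_data(matrix(0, 40, 1), x, yy)
  nuis2 <- nuisance_estimates(e1, e0, withr::with_seed(5L, runif(40, 0.2, 0.8)))
  expect_equal(aipw(d2, nuis2)$psi, mean(e1 - e0), tolerance = 1e-12)
})

test_that("AIPW matches the straight-line oracle on the 6-record fixture", {
  df <- read.csv(fixture_path("aipw_oracle_6.csv"))
  fx <- read_nuisance_fixture("aipw_oracle_6.csv")
  est <- aipw(fx$data, fx$nuis)
  oracle <- oracle_aipw(df$y, df$x, df$e1, df$e0, df$g)
  expect_equal(est$psi, oracle$psi, tolerance = 1e-10)
  expect_equal(est$se, oracle$se, tolerance = 1e-10)
  expect_equal(est$eif, oracle$terms - oracle$psi, tolerance = 1e-10)
  # Wald construction
  expect_equal(est$ci_high - est$ci_low, 2 * 1.96 * est$se, tolerance = 1e-10)
})

test_that("propensity scores at the boundary raise a positivity error", {
  expect_error(
    nuisance_estimates(rep(0, 3), rep(0, 3), c(0.5, 1, 0.2)),
    "positivity"
  )
})

test_that("TMLE solves the EIF score equation and respects outcome bounds", {
  params <- tiny_dgm()
  for (s in 1:6) {
    d <- generate_dataset(params, 150, seed = s)
    pr <- parametric_nuisance_fn(params)(d, d, 1)
    nuis <- nuisance_estimates(pr$e1, pr$e0, truncate_ps(pr$g))
    est <- tmle(d, nuis)
    expect_lt(abs(mean(est$eif)), 1e-8)
    rng <- range(d$Y)
    expect_true(all(est$e1_star >= rng[1] & est$e1_star <= rng[2]))
    expect_true(all(est$e0_star >= rng[1] & est$e0_star <= rng[2]))
    expect_true(abs(est$psi) <= diff(rng))
  }
})

test_that("TMLE targeting leaves zero-residual predictions unchanged", {
  fx <- read_nuisance_fixture("zero_residual.csv")
  est <- tmle(fx$data, fx$nuis)
  expect_equal(est$psi, 1, tolerance = 1e-6)
})

test_that("TMLE agrees with an optimizer-based targeting oracle", {
  params <- tiny_dgm()
  d <- generate_dataset(params, 50, seed = 42)
  pr <- parametric_nuisance_fn(params)(d, d, 1)
  nuis <- nuisance_estimates(pr$e1, pr$e0, truncate_ps(pr$g))
  est <- tmle(d, nuis)
  psi_oracle <- oracle_tmle_psi(d$Y, d$X, nuis$e1, nuis$e0, nuis$g)
  expect_equal(est$psi, psi_oracle, tolerance = 1e-6)
  expect_lt(abs(mean(est$eif)), 1e-8)
})

test_that("fold assignment partitions exactly with near-equal, stratified sizes", {
  fa <- make_folds(10, 2, seed = 1)
  expect_equal(sort(as.integer(table(fa$fold))), c(5L, 5L))
  expect_setequal(seq_len(10), which(fa$fold %in% 1:2))

  fa2 <- make_folds(101, 5, seed = 2)
  expect_true(all(table(fa2$fold) %in% c(20, 21)))
  expect_equal(sum(table(fa2$fold)), 101)

  # determinism and stratification
  x <- withr::with_seed(3L, rbinom(200, 1, 0.25))
  f1 <- make_folds(200, 4, seed = 7, strata = x)
  f2 <- make_folds(200, 4, seed = 7, strata = x)
  expect_identical(f1$fold, f2$fold)
  per_fold_exposed <- tapply(x, f1$fold, sum)
  expect_lte(diff(range(per_fold_exposed)), 1)
  expect_lte(diff(range(table(f1$fold))), 1)

  expect_error(make_folds(8, 5, seed = 1), "2K")
  expect_error(make_folds(100, 1, seed = 1), "at least 2")
})

test_that("cross-fitting with data-independent nuisances equals pooled AIPW", {
  params <- tiny_dgm()
  d <- generate_dataset(params, 120, seed = 5)
  truth_fn <- function(train, newdata, seed) {
    W <- newdata$W
    list(
      e1 = outcome_mean(params, W, 1),
      e0 = outcome_mean(params, W, 0),
      g = plogis(drcfit:::exposure_lp(params, W))
    )
  }
  cf <- crossfit(d, K = 2, method = "aipw", seed = 3, truncate = "none",
                 nuisance_fn = truth_fn)
  pooled <- aipw(d, nuisance_estimates(
    outcome_mean(params, d$W, 1), outcome_mean(params, d$W, 0),
    plogis(drcfit:::exposure_lp(params, d$W))
  ))
  expect_equal(cf$psi, pooled$psi, tolerance = 1e-12)
  expect_equal(cf$se, pooled$se, tolerance = 1e-12)
})

test_that("cross-fitted estimates are deterministic and carry metadata", {
  params <- tiny_dgm()
  d <- generate_dataset(params, 100, seed = 6)
  e1 <- estimate_ace(d, "tmle", folds = 2, library = c("glm", "lasso"),
                     seed = 4, v_folds = 5)
  e2 <- estimate_ace(d, "tmle", folds = 2, library = c("glm", "lasso"),
                     seed = 4, v_folds = 5)
  expect_identical(e1$psi, e2$psi)
  expect_identical(e1$se, e2$se)
  expect_equal(e1$folds, 2L)
  expect_equal(e1$method, "tmle")
  expect_lt(abs(mean(e1$eif)), 0.2) # out-of-fold EIF mean is small, not exact
})

test_that("sparse exposure in a training complement is refused with advice", {
  W <- matrix(rnorm(60), 60, 1)
  X <- c(1, rep(0, 59))
  d <- observed_data(W, X, rnorm(60))
  expect_error(
    crossfit(d, K = 2, method = "aipw", library = "glm", seed = 1, v_folds = 5),
    "fewer folds"
  )
})

test_that("analyze validates inputs and reports overlap diagnostics", {
  res <- analyze(fixture_path("demo_simple1.csv"), method = "tmle",
                 library = c("glm", "lasso"), seed = 1)
  expect_s3_class(res$estimate, "effect_estimate")
  expect_true(is.finite(res$estimate$psi) && res$estimate$se > 0)
  expect_equal(nrow(res$ps_summary), 2)
  expect_true(all(res$ps_summary$min > 0 & res$ps_summary$max < 1))

  df <- read.csv(fixture_path("demo_simple1.csv"))
  df$y[3] <- NA
  expect_error(analyze(df, seed = 1), "missing")
  df2 <- read.csv(fixture_path("demo_simple1.csv"))
  df2$x <- df2$x + 1 # coded {1, 2}
  expect_error(analyze(df2, seed = 1), "0/1")
})
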