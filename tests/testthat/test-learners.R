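# Super Learner: meta-weight optimality on the simplex, ensemble invariants,
# prediction plumbing, and propensity-score truncation.

make_xy <- function(n = 120, p = 4, seed = 1, noise = 0.5, binary = FALSE) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    eta <- x[, 1] - 0.5 * x[, 2] + 0.25 * x[, 3]^2
    y <- if (binary) rbinom(n, 1, plogis(eta)) else eta + rnorm(n, 0, noise)
    list(x = x, y = y)
  })
}

test_that("a single-learner library gets weight 1", {
  d <- make_xy()
  fit <- fit_super_learner(d$x, d$y, library = "glm", seed = 1)
  expect_equal(unname(fit$weights), 1)
})

test_that("ensemble CV loss never exceeds any single learner's CV risk", {
  for (s in 1:3) {
    d <- make_xy(seed = s)
    fit <- fit_super_learner(d$x, d$y, library = c("glm", "lasso", "boost"),
                             v_folds = 5, seed = s)
    expect_true(all(fit$ensemble_cv_loss <= fit$cv_risks + 1e-8))
  }
  # classification loss too
  d <- make_xy(seed = 9, binary = TRUE, n = 150)
  fit <- fit_super_learner(d$x, d$y, library = c("glm", "lasso"),
                           v_folds = 5, loss = "binomial", seed = 4)
  expect_true(all(fit$ensemble_cv_loss <= fit$cv_risks + 1e-8))
})

test_that("noiseless linear data: ensemble matches or beats the correctly specified glm", {
  d <- make_xy(seed = 2, noise = 0)
  d$y <- d$x[, 1] - 0.5 * d$x[, 2] # exactly linear
  fit <- fit_super_learner(d$x, d$y, library = c("glm", "boost"), v_folds = 5,
                           seed = 2)
  expect_lte(fit$ensemble_cv_loss, fit$cv_risks[["glm"]] + 1e-8)
  expect_gt(fit$weights[["glm"]], 0.9)
})

test_that("meta-weights solve the simplex program (grid-search oracle)", {
  for (cfg in list(
    list(seed = 5, loss = "squared", binary = FALSE, lib = c("glm", "lasso", "boost")),
    list(seed = 6, loss = "binomial", binary = TRUE, lib = c("glm", "lasso", "ridge"))
  )) {
    d <- make_xy(seed = cfg$seed, binary = cfg$binary, n = 160)
    fit <- fit_super_learner(d$x, d$y, library = cfg$lib, v_folds = 5,
                             loss = cfg$loss, seed = cfg$seed)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
    expect_true(all(fit$weights >= -1e-12))
    oracle <- oracle_simplex_loss(fit$cv_predictions, fit$cv_response, cfg$loss)
    expect_lte(fit$ensemble_cv_loss, oracle + 1e-4)
  }
})

test_that("weights are reproducible to 1e-12 given the seed", {
  d <- make_xy(seed = 7)
  f1 <- fit_super_learner(d$x, d$y, library = c("glm", "lasso", "mlp"),
                          v_folds = 5, seed = 11)
  f2 <- fit_super_learner(d$x, d$y, library = c("glm", "lasso", "mlp"),
                          v_folds = 5, seed = 11)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-12)
  expect_identical(predict(f1, d$x), predict(f2, d$x))
})

test_that("ensemble predictions are convex combinations of learner predictions", {
  d <- make_xy(seed = 8, binary = TRUE, n = 150)
  fit <- fit_super_learner(d$x, d$y, library = c("glm", "ridge", "boost"),
                           v_folds = 5, loss = "binomial", seed = 3)
  per_learner <- vapply(fit$learners, function(f) drcfit:::predict_learner(f, d$x),
                        numeric(nrow(d$x)))
  pred <- predict_ensemble(fit, d$x)
  expect_true(all(pred <= apply(per_learner, 1, max) + 1e-12))
  expect_true(all(pred >= apply(per_learner, 1, min) - 1e-12))
  expect_true(all(pred >= 0 & pred <= 1))
  # direct recomputation of the weighted sum
  expect_equal(pred, drop(per_learner %*% fit$weights), tolerance = 1e-12)
})

test_that("failing learners are dropped with a warning and weights renormalized", {
  d <- make_xy(n = 30, p = 10, seed = 10) # pairwise expansion too wide for n
  expect_warning(
    fit <- fit_super_learner(d$x, d$y, library = c("glm", "glm-interactions"),
                             v_folds = 5, seed = 1),
    "dropped"
  )
  expect_equal(fit$dropped, "glm-interactions")
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("schema mismatches are reported with the missing columns", {
  d <- make_xy(seed = 12)
  fit <- fit_super_learner(d$x, d$y, library = "glm", seed = 1)
  bad <- d$x[, 1:2]
  expect_error(predict_ensemble(fit, bad), "f3")
})

test_that("the full library contains every reduced-library learner", {
  expect_true(all(names(sl_library("reduced")) %in% names(sl_library("full"))))
})

test_that("propensity truncation pins values to the 5th/95th percentiles", {
  expect_equal(truncate_ps(rep(0.5, 20)), rep(0.5, 20))

  ps <- (1:100) / 101
  tr <- truncate_ps(ps)
  expect_equal(min(tr), unname(quantile(ps, 0.05)))
  expect_equal(max(tr), unname(quantile(ps, 0.95)))

  # oracle comparison on uniform draws
  ps <- withr::with_seed(3L, runif(1000))
  q <- quantile(ps, c(0.05, 0.95), type = 7, names = FALSE)
  oracle <- pmin(pmax(ps, q[1]), q[2])
  expect_equal(truncate_ps(ps), oracle)
  expect_equal(mean(abs(truncate_ps(ps) - ps)), mean(abs(oracle - ps)))

  expect_error(truncate_ps(numeric(0)), "empty")
})
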