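# Calibration of the outcome-model intercept (marginal mean of Y at 0) and of
# the exposure main effect (80% rejection power at a given sample size), plus
# the empirical computation of the true average causal effect.

# Marginal mean of Y under a mechanism, by chunked simulation of the
# noise-free conditional mean (the Gaussian residual has mean zero, so
# omitting it removes residual Monte Carlo noise at identical expectation).
sim_mean_y <- function(params, n_sim, seed, chunk = 1e5) {
  total <- 0
  done <- 0
  i <- 0L
  while (done < n_sim) {
    i <- i + 1L
    m <- min(chunk, n_sim - done)
    total <- total + with_seed(child_seed(seed, i, stream = 1L), {
      W <- gen_confounders_impl(params, m)
      X <- rbinom(m, 1L, plogis(exposure_lp(params, W)))
      sum(outcome_mean(params, W, X))
    })
    done <- done + m
  }
  total / n_sim
}

#' Calibrate the outcome-model intercept so that E[Y] = 0
#'
#' The marginal mean of the outcome is linear in the intercept with unit
#' slope, so a single large simulated draw yields the exact correction up to
#' Monte Carlo error; the routine iterates measure-correct-verify until a
#' fresh draw has `|mean(Y)| < tol`.
#'
#' @param params a [dgm_params()] object.
#' @param n_cal size of the calibration sample (default 1e6).
#' @param seed integer seed.
#' @param tol tolerance on the marginal mean (default 0.005).
#' @param chunk simulation chunk size (bounds memory for the large set).
#' @param max_iter maximum measure-correct cycles before failing.
#' @return The input `params` with the adjusted intercept; the achieved
#'   residual mean is attached as attribute `"residual_mean"`.
#' @export
calibrate_intercept <- function(params, n_cal = 1e6, seed = 1, tol = 0.005,
                                chunk = 1e5, max_iter = 5) {
  params <- validate_dgm_params(params)
  m <- NA_real_
  for (iter in seq_len(max_iter)) {
    m <- sim_mean_y(params, n_cal, child_seed(seed, iter), chunk = chunk)
    if (abs(m) < tol) {
      attr(params, "residual_mean") <- m
      return(params)
    }
    params$outcome$intercept <- params$outcome$intercept - m
  }
  stop(sprintf(
    "intercept calibration did not converge in %d iterations (residual mean %.4g)",
    max_iter, m
  ))
}

#' Empirical true average causal effect of a mechanism
#'
#' Simulates a single very large confounder sample and averages the
#' difference of the noise-free potential-outcome conditional means
#' `E[Y | W, X = 1] - E[Y | W, X = 0]`. For simple mechanisms (no
#' exposure-confounder interaction) this equals the exposure main effect to
#' numerical precision.
#'
#' @param params a calibrated [dgm_params()] object.
#' @param n_truth truth-evaluation sample size (default 1e6).
#' @param seed integer seed.
#' @param chunk simulation chunk size.
#' @return A `scenario_truth` object: list with `theta`, `n_truth`, `seed`.
#' @export
true_ace <- function(params, n_truth = 1e6, seed = 1, chunk = 1e5) {
  params <- validate_dgm_params(params)
  total <- 0
  done <- 0
  i <- 0L
  while (done < n_truth) {
    i <- i + 1L
    m <- min(chunk, n_truth - done)
    total <- total + with_seed(child_seed(seed, i, stream = 2L), {
      W <- gen_confounders_impl(params, m)
      sum(outcome_mean(params, W, 1) - outcome_mean(params, W, 0))
    })
    done <- done + m
  }
  structure(
    list(theta = total / n_truth, n_truth = n_truth, seed = seed),
    class = "scenario_truth"
  )
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf(
    "<scenario_truth> theta = %.6f (n_truth = %g, seed = %d)\n",
    x$theta, x$n_truth, x$seed
  ))
  invisible(x)
}

# ---- correctly specified parametric analysis (calibration oracle) ----------

# Nuisance estimates from correctly specified parametric models: linear
# regression on the mechanism's true outcome design, logistic regression on
# its true exposure design, with the study-wide 5th/95th-percentile
# propensity truncation (untruncated extreme weights give the power curve
# heavy tails that would dominate the calibration error). Used for power
# calibration and as an internal baseline; never part of the Super Learner
# path.
fit_parametric_nuisance <- function(data, params) {
  W <- data$W
  D <- cbind(1, dgm_outcome_design(params, W, data$X))
  fit <- lm.fit(D, data$Y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  e1 <- drop(cbind(1, dgm_outcome_design(params, W, rep(1, data$n))) %*% beta)
  e0 <- drop(cbind(1, dgm_outcome_design(params, W, rep(0, data$n))) %*% beta)
  Dx <- cbind(1, dgm_exposure_design(params, W))
  g <- suppressWarnings(
    glm.fit(Dx, data$X, family = binomial())$fitted.values
  )
  nuisance_estimates(e1 = e1, e0 = e0, g = truncate_ps(g))
}

# One replicate of the correctly specified parametric AIPW analysis.
parametric_aipw_once <- function(params, n, seed) {
  data <- generate_dataset(params, n, seed)
  est <- aipw(data, fit_parametric_nuisance(data, params))
  c(psi = est$psi, se = est$se)
}

#' Rejection rate of H0: ACE = 0 under a mechanism
#'
#' Simulates `reps` datasets of size `n` and analyses each with the
#' correctly specified parametric AIPW estimator (the calibration oracle),
#' returning the proportion of replicates whose Wald test rejects the null of
#' no average causal effect.
#'
#' @param params a [dgm_params()] object.
#' @param n sample size per replicate.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param alpha test level (default 0.05).
#' @return Proportion of replicates rejecting H0.
#' @export
rejection_rate <- function(params, n, reps = 400, seed = 1, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  rej <- vapply(seq_len(reps), function(r) {
    est <- parametric_aipw_once(params, n, child_seed(seed, r, stream = 3L))
    abs(est["psi"]) > z * est["se"]
  }, logical(1))
  mean(rej)
}

#' Calibrate the exposure main effect to a target rejection power
#'
#' Finds the exposure main effect (`beta_x >= 0`) at which the null
#' hypothesis of zero average causal effect is rejected (Wald test at level
#' `alpha`, correctly specified parametric AIPW analysis) in approximately
#' `target_power` of `reps` simulated datasets of size `n`.
#'
#' Because the analysis model contains the exposure main effect, adding `d`
#' to `beta_x` shifts every replicate's estimate by exactly `d` and leaves
#' its standard error unchanged, so a single batch of replicates (simulated
#' at a reference effect of 1) traces the entire empirical power curve. A
#' monotone bisection is run on a smoothed (normal-approximation) power
#' estimate built from the replicate-level estimation errors and standard
#' errors; if the smoothed solution's raw empirical rejection proportion
#' deviates from the target by more than `tol`, the bisection falls back to
#' the empirical step curve, guaranteeing the contract. The outcome intercept
#' is recalibrated for the returned effect (the rejection test is invariant
#' to the intercept, so recalibrating once at the solution is equivalent to
#' recalibrating at every update).
#'
#' @param params a [dgm_params()] object.
#' @param n sample size the power targets.
#' @param target_power target rejection proportion (default 0.80).
#' @param alpha test level (default 0.05).
#' @param reps number of calibration replicates (default 400).
#' @param seed integer seed.
#' @param tol acceptable deviation of the achieved rejection proportion from
#'   `target_power` (default 0.03).
#' @param beta_max upper bound of the bisection bracket (default 20).
#' @param n_cal_intercept sample size for the final intercept recalibration.
#' @return `params` with calibrated `beta_x` (and intercept); calibration
#'   diagnostics are attached as attribute `"calibration"` (a list with the
#'   achieved empirical and smoothed power, `reps`, `n`, `seed`).
#' @export
calibrate_effect <- function(params, n, target_power = 0.80, alpha = 0.05,
                             reps = 400, seed = 1, tol = 0.03, beta_max = 20,
                             n_cal_intercept = 1e6) {
  params <- validate_dgm_params(params)
  stopifnot(target_power > 0, target_power < 1)
  z <- qnorm(1 - alpha / 2)
  ref <- params
  ref$outcome$beta_x <- 1
  sims <- vapply(
    seq_len(reps),
    function(r) parametric_aipw_once(ref, n, child_seed(seed, r, stream = 4L)),
    numeric(2)
  )
  psi_ref <- sims["psi", ]
  se_ref <- sims["se", ]
  mu_ref <- mean(psi_ref)
  sigma <- sd(psi_ref)

  pow_emp <- function(b) mean(abs(psi_ref + (b - 1)) > z * se_ref)
  pow_smooth <- function(b) {
    mu <- mu_ref + (b - 1)
    mean(pnorm((mu - z * se_ref) / sigma) + pnorm((-mu - z * se_ref) / sigma))
  }

  bisect <- function(f) {
    lo <- 0
    hi <- 1
    while (f(hi) < target_power) {
      hi <- hi * 2
      if (hi > beta_max) {
        stop(sprintf(
          "target power %.2f unreachable for beta_x in [0, %g]: achieved range [%.3f, %.3f]",
          target_power, beta_max, f(0), f(beta_max)
        ))
      }
    }
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < target_power) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  beta_star <- bisect(pow_smooth)
  if (abs(pow_emp(beta_star) - target_power) > tol) {
    beta_star <- bisect(pow_emp)
  }
  achieved <- pow_emp(beta_star)
  if (abs(achieved - target_power) > tol) {
    stop(sprintf(
      "power calibration failed: achieved rejection proportion %.3f vs target %.2f",
      achieved, target_power
    ))
  }
  params$outcome$beta_x <- beta_star
  params <- calibrate_intercept(
    params,
    n_cal = n_cal_intercept, seed = child_seed(seed, 1L, stream = 5L)
  )
  attr(params, "calibration") <- list(
    beta_x = beta_star, achieved_power = achieved,
    smoothed_power = pow_smooth(beta_star),
    target_power = target_power, reps = reps, n = n, seed = seed
  )
  params
}
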