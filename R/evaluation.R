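# Monte Carlo evaluation: scenario grid, replicate execution, the stability
# exclusion rule for extreme replicates, and performance measures with Monte
# Carlo standard errors.

#' The scenario registry: mechanisms by sample sizes
#'
#' The study design crosses the five data-generating mechanisms with four
#' sample sizes, giving exactly 20 scenarios; estimator variants (method,
#' library, folds) multiply within each scenario.
#'
#' @return A tibble with columns `scenario`, `dgm_name`, `n`, `p`.
#' @examples
#' nrow(scenario_grid())
#' @export
scenario_grid <- function() {
  grid <- tidyr::expand_grid(
    dgm_name = dgm_names(),
    n = c(200L, 500L, 1000L, 2000L)
  )
  grid$p <- ifelse(grid$dgm_name %in% c("simple-2", "complex-2"), 87L, 14L)
  grid$scenario <- paste0(grid$dgm_name, "_n", grid$n)
  grid[, c("scenario", "dgm_name", "n", "p")]
}

#' Specify one simulation scenario
#'
#' @param dgm_name one of [dgm_names()].
#' @param n sample size per replicate (design values: 200, 500, 1000, 2000).
#' @param method `"aipw"` or `"tmle"`.
#' @param folds `"none"` or a fold count (2, 5, 10 in the study design).
#' @param library Super Learner library preset (see [sl_library()]).
#' @param n_reps number of Monte Carlo replicates (2000 in the full design,
#'   chosen so the coverage MCSE at 95% nominal is at most 0.5%).
#' @param base_seed integer; replicate r uses a seed derived from
#'   `(base_seed, r)`, independent of estimator settings.
#' @param v_folds internal Super Learner cross-validation folds.
#' @param truncate propensity-score truncation mode passed to
#'   [estimate_ace()] (`"fold"`, `"pooled"` or `"none"`).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(dgm_name, n, method = "tmle", folds = "none",
                          library = "reduced", n_reps = 2000,
                          base_seed = 1, v_folds = 10, truncate = "fold") {
  dgm_name <- match.arg(dgm_name, dgm_names())
  method <- match.arg(method, c("aipw", "tmle"))
  if (!identical(folds, "none")) {
    folds <- as.integer(folds)
    stopifnot(folds >= 2)
  }
  structure(
    list(
      dgm_name = dgm_name, n = as.integer(n), method = method, folds = folds,
      library = library, n_reps = as.integer(n_reps),
      base_seed = as.integer(base_seed), v_folds = v_folds,
      truncate = match.arg(truncate, c("fold", "pooled", "none"))
    ),
    class = "scenario_spec"
  )
}

#' Run the Monte Carlo replicates of one scenario
#'
#' For replicate `r = 1..n_reps` a dataset is generated with a seed derived
#' from `(base_seed, r)` (independent of estimator settings, so different
#' estimator variants see identical datasets) and analysed with the specified
#' estimator. Estimator errors are recorded as failed replicates, not raised.
#'
#' @param spec a [scenario_spec()].
#' @param params the calibrated [dgm_params()] for `(dgm_name, n)`; defaults
#'   to the uncalibrated preset (fine for smoke tests; calibrate with
#'   [calibrate_effect()] for performance runs).
#' @param nuisance_fn optional nuisance override passed to [estimate_ace()]
#'   (e.g. [parametric_nuisance_fn()] for a correctly specified parametric
#'   analysis).
#' @param workers number of parallel workers (forked; replicates are
#'   independent and per-replicate seeded, so results are invariant to the
#'   worker count).
#' @return A tibble with one row per replicate: `rep`, `seed`, `psi`, `se`,
#'   `ci_low`, `ci_high`, `error`.
#' @export
run_scenario <- function(spec, params = dgm_params(spec$dgm_name),
                         nuisance_fn = NULL, workers = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  one_rep <- function(r) {
    seed_r <- child_seed(spec$base_seed, r, stream = 40L)
    data <- generate_dataset(params, spec$n, seed_r)
    est <- try(
      estimate_ace(
        data,
        method = spec$method, folds = if (identical(spec$folds, "none")) NULL else spec$folds,
        library = spec$library, seed = seed_r, v_folds = spec$v_folds,
        truncate = spec$truncate %||% "fold", nuisance_fn = nuisance_fn
      ),
      silent = TRUE
    )
    if (inherits(est, "try-error")) {
      tibble::tibble(
        rep = r, seed = seed_r, psi = NA_real_, se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        error = conditionMessage(attr(est, "condition"))
      )
    } else {
      tibble::tibble(
        rep = r, seed = seed_r, psi = est$psi, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high, error = NA_character_
      )
    }
  }
  reps <- seq_len(spec$n_reps)
  rows <- if (workers > 1) {
    parallel::mclapply(reps, one_rep, mc.cores = workers)
  } else {
    lapply(reps, one_rep)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  out
}

#' Correctly specified parametric nuisance models for a mechanism
#'
#' Returns a nuisance-fitting function (usable as `nuisance_fn` in
#' [estimate_ace()] / [run_scenario()]) that fits linear and logistic
#' regressions on the mechanism's true design expansion.
#'
#' @param params a [dgm_params()] object.
#' @return A function `(train, newdata, seed) -> list(e1, e0, g)`.
#' @export
parametric_nuisance_fn <- function(params) {
  params <- validate_dgm_params(params)
  function(train, newdata, seed) {
    D <- cbind(1, dgm_outcome_design(params, train$W, train$X))
    beta <- lm.fit(D, train$Y)$coefficients
    beta[is.na(beta)] <- 0
    m <- nrow(newdata$W)
    Dx <- cbind(1, dgm_exposure_design(params, train$W))
    ps_fit <- suppressWarnings(glm.fit(Dx, train$X, family = binomial()))
    gamma <- ps_fit$coefficients
    gamma[is.na(gamma)] <- 0
    list(
      e1 = drop(cbind(1, dgm_outcome_design(params, newdata$W, rep(1, m))) %*% beta),
      e0 = drop(cbind(1, dgm_outcome_design(params, newdata$W, rep(0, m))) %*% beta),
      g = plogis(drop(cbind(1, dgm_exposure_design(params, newdata$W)) %*% gamma))
    )
  }
}

#' Flag unstable replicates (the AIPW stability-exclusion rule)
#'
#' A replicate is flagged when its standard error exceeds 10 times the median
#' standard error, or the absolute point estimate exceeds 5 times the
#' absolute median point estimate (medians over the scenario's non-failed
#' replicates). Both rules are scale-equivariant. In the evaluation pipeline
#' the rule is applied to AIPW results by default (TMLE, a bounded
#' substitution estimator, does not produce such replicates).
#'
#' @param results a replicate-level results tibble from [run_scenario()].
#' @param se_factor,psi_factor rule thresholds (defaults 10 and 5).
#' @return A list with `kept` and `excluded` tibbles and `n_excluded`.
#' @export
stability_filter <- function(results, se_factor = 10, psi_factor = 5) {
  ok <- is.na(results$error) | results$error == ""
  done <- results[ok & !is.na(results$psi), , drop = FALSE]
  if (nrow(done) < 3) stop("stability filter needs at least 3 replicates")
  med_se <- median(done$se)
  med_psi <- median(done$psi)
  flag <- done$se > se_factor * med_se | abs(done$psi) > psi_factor * abs(med_psi)
  list(
    kept = done[!flag, , drop = FALSE],
    excluded = done[flag, , drop = FALSE],
    n_excluded = sum(flag)
  )
}

# Monte Carlo SE helpers (Morris, White & Crowther conventions).
mcse_coverage <- function(c, R) sqrt(c * (1 - c) / R)

#' Monte Carlo performance measures for one scenario
#'
#' Computes bias, relative bias (%), empirical SE, model-based SE (square
#' root of the mean estimated variance), relative error of the model SE
#' versus the empirical SE (%), coverage of the 95% Wald interval (%), and
#' power (% rejecting H0: ACE = 0 at `alpha`), each with its Monte Carlo
#' standard error.
#'
#' @param results replicate-level tibble (already stability-filtered if
#'   desired) with columns `psi`, `se`, `ci_low`, `ci_high`.
#' @param theta true ACE (from [true_ace()]); relative bias is reported as
#'   `NA` when `theta == 0` rather than infinity.
#' @param alpha rejection level for the power measure (default 0.05).
#' @param n_excluded count of stability-excluded replicates, carried into the
#'   output row.
#' @return A one-row tibble (`performance_row`) with each measure and its
#'   `*_mcse` companion, plus `n_reps`, `n_excluded`.
#' @export
performance <- function(results, theta, alpha = 0.05, n_excluded = 0) {
  results <- results[is.na(results$error) | results$error == "", , drop = FALSE]
  psi <- results$psi
  se <- results$se
  R <- length(psi)
  if (R < 2) stop("need at least 2 replicates to compute performance measures")
  stopifnot(is.finite(theta))
  z <- qnorm(1 - alpha / 2)

  bias <- mean(psi) - theta
  bias_mcse <- sd(psi) / sqrt(R)
  emp_se <- sd(psi)
  emp_se_mcse <- emp_se / sqrt(2 * (R - 1))
  mean_var <- mean(se^2)
  mod_se <- sqrt(mean_var)
  mod_se_mcse <- sqrt(var(se^2) / (4 * R * mean_var))
  rel_err <- 100 * (mod_se / emp_se - 1)
  rel_err_mcse <- 100 * (mod_se / emp_se) *
    sqrt(var(se^2) / (4 * R * mod_se^4) + 1 / (2 * (R - 1)))
  cover <- mean(results$ci_low <= theta & theta <= results$ci_high)
  power <- mean(abs(psi) > z * se)

  if (theta != 0) {
    rel_bias <- 100 * bias / theta
    rel_bias_mcse <- 100 * bias_mcse / abs(theta)
  } else {
    rel_bias <- NA_real_
    rel_bias_mcse <- NA_real_
  }

  out <- tibble::tibble(
    n_reps = R, n_excluded = as.integer(n_excluded),
    bias = bias, bias_mcse = bias_mcse,
    relative_bias_pct = rel_bias, relative_bias_pct_mcse = rel_bias_mcse,
    empirical_se = emp_se, empirical_se_mcse = emp_se_mcse,
    model_se = mod_se, model_se_mcse = mod_se_mcse,
    relative_error_model_se_pct = rel_err,
    relative_error_model_se_pct_mcse = rel_err_mcse,
    coverage_pct = 100 * cover,
    coverage_pct_mcse = 100 * mcse_coverage(cover, R),
    power_pct = 100 * power,
    power_pct_mcse = 100 * mcse_coverage(power, R)
  )
  class(out) <- c("performance_row", class(out))
  out
}

#' Long-format summary of performance rows
#'
#' Stacks performance rows (one per scenario x estimator variant) into a
#' tidy long table with one row per measure, suitable for CSV export and for
#' the panel plots.
#'
#' @param rows a named list of `performance_row` tibbles, or one tibble with
#'   identifying columns already attached.
#' @param id optional tibble/data.frame of identifying columns (one row per
#'   element of `rows`).
#' @return A tibble with identifying columns plus `measure`, `value`, `mcse`.
#' @export
summarize_grid <- function(rows, id = NULL) {
  if (inherits(rows, "data.frame")) rows <- list(rows)
  tab <- dplyr::bind_rows(rows, .id = ".row")
  if (!is.null(id)) {
    id <- as.data.frame(id)
    stopifnot(nrow(id) == nrow(tab))
    tab <- dplyr::bind_cols(id, tab)
  }
  measures <- c(
    "bias", "relative_bias_pct", "empirical_se", "model_se",
    "relative_error_model_se_pct", "coverage_pct", "power_pct"
  )
  vals <- tidyr::pivot_longer(
    tab[, setdiff(names(tab), paste0(measures, "_mcse"))],
    cols = dplyr::all_of(measures),
    names_to = "measure", values_to = "value"
  )
  mcses <- tidyr::pivot_longer(
    tab[, c(".row", paste0(measures, "_mcse"))],
    cols = -".row", names_to = "measure", values_to = "mcse"
  )
  mcses$measure <- sub("_mcse$", "", mcses$measure)
  out <- dplyr::left_join(vals, mcses, by = c(".row", "measure"))
  out$.row <- NULL
  out
}

#' Panel plot of a performance measure across scenarios
#'
#' Mirrors the simulation-report layout: one panel per mechanism, sample size
#' on the x axis, estimator variants distinguished by colour and linetype.
#'
#' @param summary_long output of [summarize_grid()] including columns
#'   `dgm_name`, `n`, `method`, `folds`, `measure`, `value`.
#' @param measure which measure to plot (e.g. `"coverage_pct"`).
#' @return A ggplot object.
#' @export
plot_performance <- function(summary_long, measure = "coverage_pct") {
  df <- summary_long[summary_long$measure == measure, , drop = FALSE]
  df$folds <- factor(df$folds, levels = c("none", "2", "5", "10"))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$n), y = .data$value,
      colour = .data$method, group = interaction(.data$method, .data$folds),
      linetype = .data$folds
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~dgm_name) +
    ggplot2::labs(x = "sample size", y = measure) +
    ggplot2::theme_bw()
}
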