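# Doubly robust estimators of the average causal effect: AIPW and TMLE,
# with and without K-fold cross-fitting.

#' Bundle nuisance estimates
#'
#' @param e1 per-record predictions of `E[Y | X = 1, W]`.
#' @param e0 per-record predictions of `E[Y | X = 0, W]`.
#' @param g per-record propensity scores `P(X = 1 | W)`, strictly inside
#'   (0, 1) (truncate first if needed; see [truncate_ps()]).
#' @param out_of_fold logical flag: were these predictions made out-of-fold
#'   (cross-fitting) or in-sample?
#' @return A `nuisance_estimates` object.
#' @export
nuisance_estimates <- function(e1, e0, g, out_of_fold = FALSE) {
  n <- length(g)
  stopifnot(length(e1) == n, length(e0) == n)
  bad <- which(g <= 0 | g >= 1)
  if (length(bad)) {
    stop(
      "propensity scores at 0 or 1 (positivity violation) for record(s): ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  structure(
    list(e1 = as.double(e1), e0 = as.double(e0), g = as.double(g),
         out_of_fold = isTRUE(out_of_fold)),
    class = "nuisance_estimates"
  )
}

effect_estimate <- function(psi, se, eif, method, folds = NULL,
                            library = NA_character_, seed = NA_integer_,
                            n = length(eif), extra = list()) {
  out <- c(
    list(
      psi = psi, se = se,
      ci_low = psi - 1.96 * se, ci_high = psi + 1.96 * se,
      eif = eif, method = method, folds = folds, library = library,
      seed = seed, n = n
    ),
    extra
  )
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "<effect_estimate> %s%s: ACE = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], n = %d\n",
    toupper(x$method),
    if (is.null(x$folds)) "" else paste0(" + ", x$folds, "-fold CF"),
    x$psi, x$se, x$ci_low, x$ci_high, x$n
  ))
  invisible(x)
}

# EIF-based variance of the mean: sample variance of the per-record terms
# divided by n.
eif_se <- function(terms, center) {
  n <- length(terms)
  sqrt(sum((terms - center)^2) / ((n - 1) * n))
}

#' Augmented inverse probability weighting estimate of the ACE
#'
#' One-step doubly robust estimator: the g-computation contrast plus an
#' inverse-probability-weighted residual correction,
#' `psi = mean( e1 - e0 + X (Y - e1) / g - (1 - X)(Y - e0) / (1 - g) )`.
#' The standard error is the square root of the sample variance of the
#' per-record terms divided by n, and the per-record efficient influence
#' function values (terms centred at `psi`) are returned.
#'
#' @param data an [observed_data()] object.
#' @param nuis a [nuisance_estimates()] object aligned with `data`.
#' @return An `effect_estimate` (fields `psi`, `se`, `ci_low`, `ci_high`,
#'   `eif`, `method`, ...).
#' @export
aipw <- function(data, nuis) {
  stopifnot(inherits(data, "observed_data"), inherits(nuis, "nuisance_estimates"))
  if (length(nuis$g) != data$n) stop("nuisance estimates not aligned with data")
  X <- data$X
  Y <- data$Y
  terms <- nuis$e1 - nuis$e0 +
    X * (Y - nuis$e1) / nuis$g -
    (1 - X) * (Y - nuis$e0) / (1 - nuis$g)
  psi <- mean(terms)
  effect_estimate(
    psi = psi, se = eif_se(terms, psi), eif = terms - psi,
    method = "aipw", n = data$n
  )
}

# Logistic fluctuation of scaled outcome predictions along the clever
# covariate; shared by the plain and cross-fitted TMLE paths.
# Returns targeted predictions on the original outcome scale.
tmle_target <- function(Y, X, e1, e0, g, bounds) {
  a <- bounds[1]
  b <- bounds[2]
  span <- b - a
  if (span <= 0) stop("degenerate outcome range; cannot scale for targeting")
  sc <- function(v) pmin(pmax((v - a) / span, 1e-4), 1 - 1e-4)
  ys <- (Y - a) / span # in [0, 1] whenever `bounds` covers the data range
  q1 <- sc(e1)
  q0 <- sc(e0)
  qx <- ifelse(X == 1, q1, q0)
  H <- X / g - (1 - X) / (1 - g)
  fit <- suppressWarnings(glm(
    ys ~ -1 + H + offset(qlogis(qx)),
    family = quasibinomial(),
    control = list(epsilon = 1e-12, maxit = 200)
  ))
  if (!fit$converged) stop("TMLE fluctuation did not converge")
  eps <- coef(fit)[["H"]]
  # polish the fluctuation MLE by Newton steps so the EIF score equation is
  # solved to near machine precision (the IRLS tolerance alone leaves a
  # mean-EIF residual of ~1e-7)
  off <- qlogis(qx)
  for (i in 1:50) {
    q <- plogis(off + eps * H)
    score <- sum(H * (ys - q))
    if (abs(score) < 1e-12 * length(ys)) break
    info <- sum(H^2 * q * (1 - q))
    if (info <= 0) break
    eps <- eps + score / info
  }
  q1s <- plogis(qlogis(q1) + eps / g)
  q0s <- plogis(qlogis(q0) - eps / (1 - g))
  list(
    e1_star = a + span * q1s,
    e0_star = a + span * q0s,
    eps = eps,
    H = H,
    bounds = c(a, b)
  )
}

#' Targeted maximum likelihood estimate of the ACE
#'
#' Substitution estimator with a targeting step: the outcome and predictions
#' are scaled to `[0, 1]` using the observed outcome range, the initial
#' predictions are fluctuated by an intercept-free logistic regression of the
#' scaled outcome on the clever covariate `H = X/g - (1-X)/(1-g)` with the
#' scaled prediction as offset, and the ACE is the mean difference of the
#' back-transformed targeted predictions. Because it is a substitution
#' estimator, the estimate always respects the bounds implied by the observed
#' outcome range (the source of TMLE's extra stability relative to AIPW).
#' The fluctuation solves the EIF score equation, so the per-record EIF
#' values returned have mean zero (up to the fluctuation solver tolerance),
#' and the standard error is computed from them exactly as for AIPW.
#'
#' @inheritParams aipw
#' @return An `effect_estimate`; `extra` fields: `eps` (fluctuation
#'   coefficient), `e1_star`, `e0_star` (targeted predictions) and
#'   `outcome_bounds`.
#' @export
tmle <- function(data, nuis) {
  stopifnot(inherits(data, "observed_data"), inherits(nuis, "nuisance_estimates"))
  if (length(nuis$g) != data$n) stop("nuisance estimates not aligned with data")
  bounds <- range(data$Y)
  tg <- tmle_target(data$Y, data$X, nuis$e1, nuis$e0, nuis$g, bounds)
  psi <- mean(tg$e1_star) - mean(tg$e0_star)
  ex_star <- ifelse(data$X == 1, tg$e1_star, tg$e0_star)
  d <- tg$H * (data$Y - ex_star) + tg$e1_star - tg$e0_star
  effect_estimate(
    psi = psi, se = eif_se(d, psi), eif = d - psi,
    method = "tmle", n = data$n,
    extra = list(
      eps = tg$eps, e1_star = tg$e1_star, e0_star = tg$e0_star,
      outcome_bounds = bounds
    )
  )
}

#' Random folds of roughly equal size
#'
#' Partition `1..n` into `K` folds whose sizes differ by at most one,
#' optionally stratified (cross-fitting stratifies on the exposure so that
#' sparse exposure cannot produce single-class training complements at small
#' n). Deterministic given `seed`.
#'
#' @param n number of records (must be at least `2 K`).
#' @param K number of folds (at least 2).
#' @param seed integer seed.
#' @param strata optional stratification vector of length `n`.
#' @return A `fold_assignment` object: list with `K`, `fold` (length-n index
#'   vector) and `seed`.
#' @export
make_folds <- function(n, K, seed, strata = NULL) {
  if (K < 2) stop("K must be at least 2")
  if (n < 2 * K) stop("need n >= 2K records to form K folds")
  fold <- with_seed(child_seed(seed, 0L, stream = 20L),
                    fold_indices(n, K, strata))
  structure(list(K = as.integer(K), fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

# Super Learner nuisance fits on one training set, predicting on `newdata`
# records. The outcome ensemble regresses Y on (X, W); the exposure ensemble
# is a probability model for X given W.
sl_nuisance_fitter <- function(library, v_folds = 10) {
  library # force
  function(train, newdata, seed) {
    xtr <- cbind(x = train$X, train$W)
    sl_y <- fit_super_learner(
      xtr, train$Y,
      library = library, v_folds = v_folds,
      loss = "squared", seed = child_seed(seed, 1L, stream = 30L)
    )
    sl_g <- fit_super_learner(
      train$W, train$X,
      library = library, v_folds = v_folds,
      loss = "binomial", seed = child_seed(seed, 2L, stream = 30L)
    )
    m <- nrow(newdata$W)
    list(
      e1 = predict_ensemble(sl_y, cbind(x = rep(1, m), newdata$W)),
      e0 = predict_ensemble(sl_y, cbind(x = rep(0, m), newdata$W)),
      g = predict_ensemble(sl_g, newdata$W),
      fits = list(outcome = sl_y, exposure = sl_g)
    )
  }
}

#' Fit nuisance models on the full sample (no cross-fitting)
#'
#' @param data an [observed_data()] object.
#' @param library Super Learner library (see [sl_library()]).
#' @param v_folds internal Super Learner cross-validation folds.
#' @param seed integer seed.
#' @param truncate truncate the propensity scores at their empirical 5th and
#'   95th percentiles (default TRUE).
#' @return A [nuisance_estimates()] object (attribute `"fits"` carries the
#'   two `super_learner` objects).
#' @export
fit_nuisance <- function(data, library = "reduced", v_folds = 10, seed = 1,
                         truncate = TRUE) {
  pr <- sl_nuisance_fitter(library, v_folds)(data, data, seed)
  g <- if (truncate) truncate_ps(pr$g) else pr$g
  out <- nuisance_estimates(e1 = pr$e1, e0 = pr$e0, g = g)
  attr(out, "fits") <- pr$fits
  out
}

#' Cross-fitted doubly robust estimation
#'
#' K-fold cross-fitting: the sample is split into `K` exposure-stratified
#' folds; for each fold the two nuisance ensembles are fitted on the
#' complement and evaluated on the held-out fold, with propensity-score
#' truncation applied within each held-out prediction vector. For AIPW the
#' estimate is the mean of the pooled out-of-fold per-record terms; for TMLE
#' the targeting step runs within each held-out fold (using the full-sample
#' outcome range for scaling) and the estimate is the fold-size-weighted mean
#' of the fold-specific substitution estimates. For both, the standard error
#' is the sample variance of the pooled out-of-fold EIF values centred at the
#' overall estimate, divided by n.
#'
#' @param data an [observed_data()] object.
#' @param K number of folds (>= 2; `n >= 2K` required).
#' @param method `"aipw"` or `"tmle"`.
#' @param library Super Learner library (see [sl_library()]).
#' @param seed integer seed controlling the split and all learner randomness.
#' @param v_folds internal Super Learner cross-validation folds.
#' @param truncate one of `"fold"` (default: truncate propensity scores
#'   within each held-out fold), `"pooled"` (truncate the pooled out-of-fold
#'   vector) or `"none"`.
#' @param nuisance_fn optional function `(train, newdata, seed)` returning
#'   `list(e1, e0, g)`, replacing the Super Learner (used for testing and for
#'   oracle analyses).
#' @return An `effect_estimate` with `folds = K`.
#' @export
crossfit <- function(data, K, method = c("aipw", "tmle"), library = "reduced",
                     seed = 1, v_folds = 10,
                     truncate = c("fold", "pooled", "none"),
                     nuisance_fn = NULL) {
  method <- match.arg(method)
  truncate <- match.arg(truncate)
  stopifnot(inherits(data, "observed_data"))
  fa <- make_folds(data$n, K, seed, strata = data$X)
  fitter <- nuisance_fn %||% sl_nuisance_fitter(library, v_folds)
  n <- data$n
  e1 <- e0 <- g <- rep(NA_real_, n)
  for (k in seq_len(fa$K)) {
    test_idx <- which(fa$fold == k)
    train_idx <- which(fa$fold != k)
    n_exposed <- sum(data$X[train_idx])
    if (n_exposed == 0 || n_exposed == length(train_idx)) {
      stop(
        "fold ", k, ": training complement has a single exposure class; ",
        "use fewer folds (sparse exposure)"
      )
    }
    train <- observed_data(
      data$W[train_idx, , drop = FALSE], data$X[train_idx], data$Y[train_idx]
    )
    test <- list(W = data$W[test_idx, , drop = FALSE])
    pr <- fitter(train, test, child_seed(seed, k, stream = 31L))
    e1[test_idx] <- pr$e1
    e0[test_idx] <- pr$e0
    g[test_idx] <- if (truncate == "fold") truncate_ps(pr$g) else pr$g
  }
  if (truncate == "pooled") g <- truncate_ps(g)
  nuis <- nuisance_estimates(e1, e0, g, out_of_fold = TRUE)
  lib_label <- if (is.character(library) && length(library) == 1) {
    library
  } else {
    "custom"
  }
  if (method == "aipw") {
    est <- aipw(data, nuis)
    est$folds <- as.integer(K)
    est$library <- lib_label
    est$seed <- as.integer(seed)
    est$ps <- g
    return(est)
  }
  # cross-fitted TMLE: held-out targeting per fold, global outcome bounds
  bounds <- range(data$Y)
  psi_k <- numeric(fa$K)
  n_k <- integer(fa$K)
  d <- rep(NA_real_, n)
  eps_k <- numeric(fa$K)
  for (k in seq_len(fa$K)) {
    idx <- which(fa$fold == k)
    tg <- tmle_target(
      data$Y[idx], data$X[idx], e1[idx], e0[idx], g[idx], bounds
    )
    psi_k[k] <- mean(tg$e1_star) - mean(tg$e0_star)
    n_k[k] <- length(idx)
    eps_k[k] <- tg$eps
    ex_star <- ifelse(data$X[idx] == 1, tg$e1_star, tg$e0_star)
    d[idx] <- tg$H * (data$Y[idx] - ex_star) + tg$e1_star - tg$e0_star
  }
  psi <- sum(psi_k * n_k) / n
  effect_estimate(
    psi = psi, se = eif_se(d, psi), eif = d - psi,
    method = "tmle", folds = as.integer(K), library = lib_label,
    seed = as.integer(seed), n = n,
    extra = list(fold_estimates = psi_k, fold_sizes = n_k, eps = eps_k,
                 outcome_bounds = bounds, ps = g)
  )
}

#' Estimate the ACE with a single call
#'
#' Dispatcher used by the applied-analysis and simulation paths: fits the
#' nuisance models (full-sample or cross-fitted) and applies the requested
#' doubly robust estimator.
#'
#' @inheritParams crossfit
#' @param folds `NULL` (or `"none"`) for no cross-fitting, otherwise the
#'   number of folds K >= 2.
#' @return An `effect_estimate`.
#' @export
estimate_ace <- function(data, method = c("aipw", "tmle"), folds = NULL,
                         library = "reduced", seed = 1, v_folds = 10,
                         truncate = c("fold", "pooled", "none"),
                         nuisance_fn = NULL) {
  method <- match.arg(method)
  truncate <- match.arg(truncate)
  if (is.character(folds) && identical(folds, "none")) folds <- NULL
  if (!is.null(folds)) {
    return(crossfit(
      data, K = folds, method = method, library = library, seed = seed,
      v_folds = v_folds, truncate = truncate, nuisance_fn = nuisance_fn
    ))
  }
  nuis <- if (is.null(nuisance_fn)) {
    fit_nuisance(data, library, v_folds, seed, truncate = truncate != "none")
  } else {
    pr <- nuisance_fn(data, data, seed)
    g <- if (truncate != "none") truncate_ps(pr$g) else pr$g
    nuisance_estimates(pr$e1, pr$e0, g)
  }
  est <- if (method == "aipw") aipw(data, nuis) else tmle(data, nuis)
  est$library <- if (is.character(library) && length(library) == 1) library else "custom"
  est$seed <- as.integer(seed)
  est$ps <- nuis$g
  est
}

#' Applied analysis of a tabular dataset
#'
#' Runs the full pipeline on user data (CSV path or data frame with columns
#' `y, x, w1..wp`): validation (binary exposure, no missing values),
#' Super Learner nuisance estimation, the requested doubly robust estimator
#' with or without cross-fitting, and a propensity-score overlap summary by
#' exposure group.
#'
#' @param x CSV path, data frame, or [observed_data()] object.
#' @inheritParams estimate_ace
#' @return A list of class `drcfit_analysis`: `estimate` (an
#'   `effect_estimate`), `ps_summary` (tibble of propensity-score summaries
#'   by exposure group) and `n`.
#' @export
analyze <- function(x, method = c("aipw", "tmle"), folds = NULL,
                    library = "reduced", seed = 1, v_folds = 10) {
  method <- match.arg(method)
  data <- as_observed_data(x)
  est <- estimate_ace(
    data,
    method = method, folds = folds, library = library,
    seed = seed, v_folds = v_folds
  )
  # overlap diagnostics from the propensity scores the estimator actually used
  g <- est$ps
  ps_summary <- dplyr::group_by(
    tibble::tibble(exposed = data$X, ps = g), .data$exposed
  )
  ps_summary <- dplyr::summarise(
    ps_summary,
    n = dplyr::n(),
    min = min(.data$ps), q25 = quantile(.data$ps, 0.25),
    median = median(.data$ps), q75 = quantile(.data$ps, 0.75),
    max = max(.data$ps),
    .groups = "drop"
  )
  structure(
    list(estimate = est, ps_summary = ps_summary, n = data$n),
    class = "drcfit_analysis"
  )
}

#' @export
print.drcfit_analysis <- function(x, ...) {
  print(x$estimate)
  cat("Propensity-score distribution by exposure group:\n")
  print(as.data.frame(x$ps_summary), row.names = FALSE)
  invisible(x)
}
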