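# From-scratch Super Learner: V-fold cross-validated stacking over a library
# of base learners, with meta-weights found by minimizing the cross-validated
# loss over the probability simplex.

# Fold labels 1..K of near-equal size; if `strata` is given the assignment is
# stratified (per-stratum remainders are allocated to the currently smallest
# folds, keeping overall fold sizes within one of each other).
fold_indices <- function(n, K, strata = NULL) {
  fold <- integer(n)
  sizes <- integer(K)
  groups <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  for (idx in groups) {
    m <- length(idx)
    idx <- idx[sample.int(m)]
    q <- m %/% K
    r <- m - q * K
    take <- rep(q, K)
    if (r > 0) {
      extras <- order(sizes, sample.int(K))[seq_len(r)]
      take[extras] <- take[extras] + 1L
    }
    fold[idx] <- rep.int(seq_len(K), take)
    sizes <- sizes + take
  }
  fold
}

cv_loss <- function(pred, y, loss) {
  if (loss == "squared") {
    mean((pred - y)^2)
  } else {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

# Minimize the cross-validated loss over the probability simplex by
# accelerated projected gradient with backtracking; the best single-learner
# vertex is a feasible fallback, so the returned weights never do worse than
# the best learner.
simplex_weights <- function(Z, y, loss, max_iter = 20000, tol = 1e-13) {
  L <- ncol(Z)
  if (L == 1) return(1)
  f <- function(w) cv_loss(drop(Z %*% w), y, loss)
  grad <- function(w) {
    pred <- drop(Z %*% w)
    n <- length(y)
    if (loss == "squared") {
      drop(crossprod(Z, pred - y)) * 2 / n
    } else {
      p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
      drop(crossprod(Z, -y / p + (1 - y) / (1 - p))) / n
    }
  }
  run_fista <- function(w) {
    v <- w
    t_acc <- 1
    step <- 1
    f_w <- f(w)
    for (i in seq_len(max_iter)) {
      g <- grad(v)
      f_v <- f(v)
      repeat {
        w_new <- project_simplex(v - step * g)
        d <- w_new - v
        if (f(w_new) <= f_v + sum(g * d) + sum(d^2) / (2 * step) ||
          step < 1e-14) {
          break
        }
        step <- step / 2
      }
      t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
      v <- w_new + ((t_acc - 1) / t_new) * (w_new - w)
      v <- project_simplex(v)
      f_new <- f(w_new)
      if (abs(f_w - f_new) < tol * max(1, abs(f_w)) && i > 10) {
        w <- w_new
        break
      }
      w <- w_new
      f_w <- f_new
      t_acc <- t_new
      step <- step * 2
    }
    w
  }
  w <- run_fista(rep(1 / L, L))
  vertex_losses <- vapply(seq_len(L), function(l) f(replace(numeric(L), l, 1)),
                          numeric(1))
  best_vertex <- which.min(vertex_losses)
  if (f(w) > vertex_losses[best_vertex]) {
    w2 <- run_fista(replace(numeric(L), best_vertex, 1))
    if (f(w2) <= vertex_losses[best_vertex]) {
      w <- w2
    } else {
      w <- replace(numeric(L), best_vertex, 1)
    }
  }
  w / sum(w)
}

# Euclidean projection onto the probability simplex (Duchi et al. algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Fit a Super Learner ensemble
#'
#' Cross-validated stacking: every base learner is fitted on each of
#' `v_folds` fold-complements, the out-of-fold predictions are assembled into
#' a matrix, and non-negative meta-weights summing to one are chosen to
#' minimize the cross-validated loss (mean squared error for regression,
#' mean negative Bernoulli log-likelihood for probability prediction) over
#' the probability simplex. Surviving learners are then refitted on the full
#' data. Base learners that error anywhere are dropped with a warning and the
#' weights are renormalized over the remainder; if every learner fails, an
#' error is raised.
#'
#' @param x feature matrix (or data frame coercible to a numeric matrix).
#' @param y response: real-valued for `loss = "squared"`, 0/1 for
#'   `loss = "binomial"`.
#' @param library library specification passed to [sl_library()].
#' @param v_folds number of internal cross-validation folds (default 10).
#' @param loss `"squared"` or `"binomial"`.
#' @param seed integer seed; fold assignment and any learner-internal
#'   randomness derive from it, so refits are exactly reproducible.
#' @return A `super_learner` object: list with `learners` (full-data fits),
#'   `weights`, `cv_risks`, `ensemble_cv_loss`, `v_folds`, `loss`, `dropped`.
#' @examples
#' x <- matrix(rnorm(600), 200, 3)
#' y <- x[, 1] - x[, 2] + rnorm(200, 0, 0.5)
#' fit <- fit_super_learner(x, y, library = c("glm", "lasso"), seed = 1)
#' fit$weights
#' @export
fit_super_learner <- function(x, y, library = "reduced", v_folds = 10,
                              loss = c("squared", "binomial"), seed = 1) {
  loss <- match.arg(loss)
  task <- if (loss == "squared") "regression" else "classification"
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (n < 2 * v_folds) {
    stop("need at least 2 * v_folds records to cross-validate the library")
  }
  if (task == "classification" && !all(y %in% c(0, 1))) {
    stop("binomial loss requires a 0/1 response")
  }
  library <- sl_library(library)
  library <- with_seed(
    child_seed(seed, 0L, stream = 10L),
    freeze_lasso_lambda(library, x, y, task)
  )
  L <- length(library)
  strata <- if (task == "classification") y else NULL
  fold <- with_seed(child_seed(seed, 0L, stream = 11L),
                    fold_indices(n, v_folds, strata))
  Z <- matrix(NA_real_, n, L, dimnames = list(NULL, names(library)))
  failed <- setNames(rep(FALSE, L), names(library))
  for (k in seq_len(v_folds)) {
    train <- fold != k
    for (l in seq_len(L)) {
      if (failed[l]) next
      fit_k <- try(
        with_seed(
          child_seed(seed, l * 100L + k, stream = 12L),
          fit_learner(library[[l]], x[train, , drop = FALSE], y[train], task)
        ),
        silent = TRUE
      )
      if (inherits(fit_k, "try-error")) {
        failed[l] <- TRUE
        next
      }
      Z[!train, l] <- predict_learner(fit_k, x[!train, , drop = FALSE])
    }
  }
  if (any(failed)) {
    warning(
      "dropped learner(s) that failed during cross-validation: ",
      paste(names(library)[failed], collapse = ", ")
    )
  }
  keep <- which(!failed)
  if (!length(keep)) stop("all base learners failed")
  Zk <- Z[, keep, drop = FALSE]
  cv_risks <- vapply(seq_along(keep), function(j) cv_loss(Zk[, j], y, loss),
                     numeric(1))
  names(cv_risks) <- names(library)[keep]
  weights <- simplex_weights(Zk, y, loss)
  full_fits <- lapply(keep, function(l) {
    with_seed(
      child_seed(seed, l * 100L, stream = 12L),
      fit_learner(library[[l]], x, y, task)
    )
  })
  names(full_fits) <- names(library)[keep]
  structure(
    list(
      learners = full_fits,
      weights = setNames(weights, names(library)[keep]),
      cv_risks = cv_risks,
      ensemble_cv_loss = cv_loss(drop(Zk %*% weights), y, loss),
      cv_predictions = Zk,
      cv_response = y,
      v_folds = v_folds,
      loss = loss,
      dropped = names(library)[failed],
      feature_names = colnames(x),
      seed = seed
    ),
    class = "super_learner"
  )
}

#' @export
print.super_learner <- function(x, ...) {
  cat("<super_learner>", x$loss, "loss,", x$v_folds, "fold CV\n")
  info <- data.frame(weight = round(x$weights, 4), cv_risk = signif(x$cv_risks, 5))
  print(info)
  if (length(x$dropped)) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.super_learner <- function(object, newdata, ...) {
  predict_ensemble(object, newdata)
}

#' Predict from a fitted Super Learner ensemble
#'
#' Weighted combination of the base-learner predictions; probability
#' predictions stay within `[0, 1]` because the weights are a convex
#' combination.
#'
#' @param model a `super_learner` object.
#' @param features feature matrix with the training columns.
#' @return Numeric prediction vector.
#' @export
predict_ensemble <- function(model, features) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!is.null(colnames(features))) {
    missing_cols <- setdiff(model$feature_names, colnames(features))
    if (length(missing_cols)) {
      stop(
        "feature columns missing from newdata: ",
        paste(missing_cols, collapse = ", ")
      )
    }
    features <- features[, model$feature_names, drop = FALSE]
  } else if (ncol(features) != length(model$feature_names)) {
    stop("newdata has ", ncol(features), " columns; model expects ",
         length(model$feature_names))
  }
  preds <- vapply(
    model$learners, function(f) predict_learner(f, features),
    numeric(nrow(features))
  )
  if (nrow(features) == 1) preds <- matrix(preds, nrow = 1)
  drop(preds %*% model$weights)
}

#' Truncate propensity scores at their empirical 5th and 95th percentiles
#'
#' Entries below the 5th percentile of the input vector are set to that
#' percentile, entries above the 95th to the 95th. Percentiles use the
#' linear-interpolation convention (`quantile(type = 7)`), fixed for
#' reproducibility.
#'
#' @param ps vector of propensity scores in `[0, 1]`.
#' @param lower,upper percentile bounds (defaults 0.05 and 0.95).
#' @return Truncated vector of the same length.
#' @examples
#' truncate_ps(seq(0.01, 0.99, length.out = 100))[1:6]
#' @export
truncate_ps <- function(ps, lower = 0.05, upper = 0.95) {
  if (!length(ps)) stop("cannot truncate an empty propensity-score vector")
  q <- quantile(ps, c(lower, upper), type = 7, names = FALSE)
  pmin(pmax(ps, q[1]), q[2])
}
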