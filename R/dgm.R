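#' Data-generating mechanism parameters
#'
#' A `dgm_params` object fully describes one synthetic data-generating
#' mechanism: the sequential models for the confounders, the logistic exposure
#' model, and the Gaussian outcome model. Five presets emulating the
#' confounding structure of an early-life birth cohort are shipped (see
#' [dgm_names()]): `simple-1`, `complex-1a`, `complex-1b` use the small
#' confounder set (p = 14, 13 continuous), `simple-2` and `complex-2` the
#' large set (p = 87, 78 continuous). Simple variants have main-effects-only,
#' linear exposure and outcome models; complex variants add two-way
#' interactions (confounder-confounder in both models, exposure-confounder in
#' the outcome model) and non-linear terms (squares and `log(|z|+1)`) for
#' designated continuous confounders. `complex-1a` and `complex-1b` multiply
#' all interaction coefficients by 2 and 4 respectively.
#'
#' Confounders are generated sequentially: each variable's model may only
#' reference previously generated columns, so the implied graph is acyclic.
#' Supported families are `gaussian` (linear model, residual sd per variable),
#' `bernoulli` (logistic model) and `categorical` (multinomial logit, emitted
#' as `k - 1` indicator columns; not used by the shipped presets so that the
#' generated matrix has exactly `p` columns).
#'
#' @param name one of [dgm_names()].
#' @param overrides optional named list merged recursively into the preset
#'   (e.g. `list(outcome = list(beta_x = 0.3))`).
#' @return A validated `dgm_params` object.
#' @examples
#' params <- dgm_params("simple-1")
#' params$p
#' @export
dgm_params <- function(name = dgm_names(), overrides = NULL) {
  name <- match.arg(name)
  params <- dgm_preset(name)
  if (!is.null(overrides)) {
    params <- utils::modifyList(params, overrides)
    class(params) <- "dgm_params"
  }
  validate_dgm_params(params)
}

#' Names of the shipped data-generating mechanisms
#' @return Character vector of the five mechanism names.
#' @export
dgm_names <- function() {
  c("simple-1", "complex-1a", "complex-1b", "simple-2", "complex-2")
}

#' @export
print.dgm_params <- function(x, ...) {
  cat(
    "<dgm_params>", x$name, "-", x$complexity,
    sprintf(
      "(p = %d, %d continuous, interaction multiplier = %g)\n",
      x$p, x$n_continuous, x$interaction_multiplier
    ),
    sprintf(
      "  exposure intercept %.3f; outcome: beta0 = %.4f, beta_x = %.4f, sd = %.2f\n",
      x$exposure$intercept, x$outcome$intercept, x$outcome$beta_x, x$outcome$sd
    )
  )
  invisible(x)
}

validate_dgm_params <- function(params) {
  if (!inherits(params, "dgm_params")) class(params) <- "dgm_params"
  req <- c(
    "name", "complexity", "p", "n_continuous", "interaction_multiplier",
    "confounders", "exposure", "outcome"
  )
  missing_fields <- setdiff(req, names(params))
  if (length(missing_fields)) {
    abort_config("dgm_params missing field(s): ", paste(missing_fields, collapse = ", "))
  }
  if (!params$complexity %in% c("simple", "complex")) {
    abort_config("complexity must be 'simple' or 'complex'")
  }
  ncols <- 0L
  for (j in seq_along(params$confounders)) {
    cm <- params$confounders[[j]]
    if (!cm$family %in% c("gaussian", "bernoulli", "categorical")) {
      abort_config("confounder ", j, ": unknown family '", cm$family, "'")
    }
    expected <- ncols + 1L
    if (cm$family == "categorical") {
      if (is.null(cm$k) || cm$k < 2) {
        abort_config("confounder ", j, ": categorical family needs k >= 2 levels")
      }
      if (!is.matrix(cm$coefs) || nrow(cm$coefs) != cm$k - 1 ||
        ncol(cm$coefs) != expected) {
        abort_config(
          "confounder ", j, ": coefficient matrix must be (k-1) x ",
          expected, " (intercept + previously generated columns)"
        )
      }
      ncols <- ncols + cm$k - 1L
    } else {
      if (length(cm$coefs) != expected) {
        abort_config(
          "confounder ", j, ": expected ", expected,
          " coefficients (intercept + previously generated columns), got ",
          length(cm$coefs)
        )
      }
      if (cm$family == "gaussian" && (is.null(cm$sd) || cm$sd < 0)) {
        abort_config("confounder ", j, ": gaussian family needs a non-negative sd")
      }
      ncols <- ncols + 1L
    }
  }
  params$n_cols <- ncols
  for (side in c("exposure", "outcome")) {
    m <- params[[side]]
    if (length(m$main) != ncols) {
      abort_config(side, " model: 'main' must have one coefficient per confounder column")
    }
    if (length(m$ww_coefs) != nrow_or_zero(m$ww_pairs)) {
      abort_config(side, " model: ww_coefs length must match ww_pairs rows")
    }
    if (length(m$nl_coefs) != length(m$nl_terms)) {
      abort_config(side, " model: nl_coefs length must match nl_terms")
    }
  }
  if (length(params$outcome$xw_coefs) != length(params$outcome$xw_cols)) {
    abort_config("outcome model: xw_coefs length must match xw_cols")
  }
  if (params$complexity == "simple") {
    zero <- function(z) length(z) == 0 || all(z == 0)
    if (!zero(params$exposure$ww_coefs) || !zero(params$exposure$nl_coefs) ||
      !zero(params$outcome$ww_coefs) || !zero(params$outcome$xw_coefs) ||
      !zero(params$outcome$nl_coefs)) {
      abort_config("simple mechanisms must have all interaction and non-linear coefficients zero")
    }
  }
  params
}

nrow_or_zero <- function(m) if (is.null(m)) 0L else nrow(m)

# ---- generation (internal cores assume the RNG state is already set) -------

gen_confounders_impl <- function(params, n) {
  W <- matrix(0, n, params$n_cols %||% count_cols(params))
  nms <- character(ncol(W))
  col <- 0L
  for (j in seq_along(params$confounders)) {
    cm <- params$confounders[[j]]
    prev <- if (col > 0) W[, seq_len(col), drop = FALSE] else matrix(0, n, 0)
    if (cm$family == "categorical") {
      # multinomial logit against the first level as reference
      eta <- cbind(0, tcrossprod(cbind(1, prev), cm$coefs))
      pr <- exp(eta - apply(eta, 1, max))
      pr <- pr / rowSums(pr)
      u <- runif(n)
      lev <- max.col(u < t(apply(pr, 1, cumsum)), ties.method = "first")
      for (l in 2:cm$k) {
        col <- col + 1L
        W[, col] <- as.double(lev == l)
        nms[col] <- paste0("w", j, "_l", l)
      }
    } else {
      lp <- drop(cbind(1, prev) %*% cm$coefs)
      col <- col + 1L
      W[, col] <- if (cm$family == "gaussian") {
        rnorm(n, lp, cm$sd)
      } else {
        as.double(rbinom(n, 1L, plogis(lp)))
      }
      nms[col] <- paste0("w", j)
    }
  }
  colnames(W) <- nms
  W
}

count_cols <- function(params) {
  sum(vapply(
    params$confounders,
    function(cm) if (cm$family == "categorical") cm$k - 1L else 1L, integer(1)
  ))
}

# Non-linear basis value for one column: squared or log(|z| + 1) transform.
nl_value <- function(W, term) {
  z <- W[, term$col]
  switch(term$type,
    sq = z^2,
    log = log(abs(z) + 1),
    abort_config("unknown non-linear term type '", term$type, "'")
  )
}

# Linear predictor of the exposure model; interaction coefficients carry the
# mechanism's interaction multiplier.
exposure_lp <- function(params, W) {
  m <- params$exposure
  lp <- m$intercept + drop(W %*% m$main)
  mult <- params$interaction_multiplier
  if (length(m$ww_coefs)) {
    for (r in seq_along(m$ww_coefs)) {
      lp <- lp + mult * m$ww_coefs[r] * W[, m$ww_pairs[r, 1]] * W[, m$ww_pairs[r, 2]]
    }
  }
  if (length(m$nl_coefs)) {
    for (r in seq_along(m$nl_coefs)) {
      lp <- lp + m$nl_coefs[r] * nl_value(W, m$nl_terms[[r]])
    }
  }
  lp
}

#' Conditional mean of the outcome given confounders and exposure
#'
#' Evaluates the noise-free outcome model `E[Y | W, X = x]` for a fixed
#' exposure value or vector. Used internally for intercept calibration and for
#' the empirical computation of the true average causal effect.
#'
#' @param params a [dgm_params()] object.
#' @param W confounder matrix.
#' @param X exposure value (scalar 0/1) or vector.
#' @return Numeric vector of conditional means.
#' @export
outcome_mean <- function(params, W, X) {
  m <- params$outcome
  if (length(X) == 1) X <- rep(X, nrow(W))
  mu <- m$intercept + m$beta_x * X + drop(W %*% m$main)
  mult <- params$interaction_multiplier
  if (length(m$ww_coefs)) {
    for (r in seq_along(m$ww_coefs)) {
      mu <- mu + mult * m$ww_coefs[r] * W[, m$ww_pairs[r, 1]] * W[, m$ww_pairs[r, 2]]
    }
  }
  if (length(m$xw_coefs)) {
    for (r in seq_along(m$xw_coefs)) {
      mu <- mu + mult * m$xw_coefs[r] * X * W[, m$xw_cols[r]]
    }
  }
  if (length(m$nl_coefs)) {
    for (r in seq_along(m$nl_coefs)) {
      mu <- mu + m$nl_coefs[r] * nl_value(W, m$nl_terms[[r]])
    }
  }
  mu
}

#' Generate confounders from a data-generating mechanism
#'
#' Draws `n` records of the confounder matrix, variable by variable in the
#' declared generation order, each from its stated family conditional on the
#' previously generated columns. Pure function of `(params, n, seed)`.
#'
#' @param params a [dgm_params()] object.
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @return An `n x p` numeric matrix with columns `w1..wp`.
#' @export
generate_confounders <- function(params, n, seed) {
  params <- validate_dgm_params(params)
  stopifnot(n >= 1)
  with_seed(seed, gen_confounders_impl(params, n))
}

#' Generate exposure from the logistic exposure model
#'
#' Bernoulli draws with logit equal to the exposure-model linear predictor
#' (main effects, plus interaction and non-linear basis terms for complex
#' mechanisms).
#'
#' @param W confounder matrix generated under the same mechanism.
#' @param params a [dgm_params()] object.
#' @param seed integer seed.
#' @return Integer 0/1 vector of length `nrow(W)`.
#' @export
generate_exposure <- function(W, params, seed) {
  params <- validate_dgm_params(params)
  if (ncol(W) != params$n_cols) {
    abort_config(
      "W has ", ncol(W), " columns; mechanism expects ", params$n_cols
    )
  }
  lp <- exposure_lp(params, W)
  if (!all(is.finite(lp))) stop("non-finite exposure linear predictor")
  with_seed(seed, rbinom(nrow(W), 1L, plogis(lp)))
}

#' Generate outcomes from the Gaussian outcome model
#'
#' `Y = E[Y | W, X] + N(0, sd)`, where the conditional mean includes main
#' effects and (for complex mechanisms) interaction terms scaled by the
#' interaction multiplier plus non-linear terms.
#'
#' @param W confounder matrix.
#' @param X 0/1 exposure vector.
#' @param params a [dgm_params()] object.
#' @param seed integer seed.
#' @return Numeric outcome vector.
#' @export
generate_outcome <- function(W, X, params, seed) {
  params <- validate_dgm_params(params)
  if (length(X) != nrow(W)) stop("length(X) must equal nrow(W)")
  mu <- outcome_mean(params, W, X)
  if (!all(is.finite(mu))) stop("non-finite outcome linear predictor")
  with_seed(seed, mu + rnorm(nrow(W), 0, params$outcome$sd))
}

#' Generate a complete analysis dataset
#'
#' Draws confounders, exposure and outcome in a single RNG stream, so the
#' dataset is a pure function of `(params, n, seed)` and is byte-identical
#' across complexity variants whose extra coefficients are all zero.
#'
#' @inheritParams generate_confounders
#' @return An [observed_data()] object.
#' @examples
#' d <- generate_dataset(dgm_params("simple-1"), n = 100, seed = 1)
#' d
#' @export
generate_dataset <- function(params, n, seed) {
  params <- validate_dgm_params(params)
  stopifnot(n >= 1)
  with_seed(seed, {
    W <- gen_confounders_impl(params, n)
    X <- rbinom(n, 1L, plogis(exposure_lp(params, W)))
    Y <- outcome_mean(params, W, X) + rnorm(n, 0, params$outcome$sd)
    observed_data(W, X, Y)
  })
}

# ---- design expansions for correctly specified parametric analyses ---------

# Design matrix (no intercept column) of the exposure model's terms:
# raw confounder columns, then interaction products, then non-linear bases.
dgm_exposure_design <- function(params, W) {
  m <- params$exposure
  blocks <- list(W)
  if (nrow_or_zero(m$ww_pairs)) {
    ww <- W[, m$ww_pairs[, 1], drop = FALSE] * W[, m$ww_pairs[, 2], drop = FALSE]
    colnames(ww) <- paste0("ww", seq_len(ncol(ww)))
    blocks <- c(blocks, list(ww))
  }
  if (length(m$nl_terms)) {
    nl <- vapply(m$nl_terms, function(t) nl_value(W, t), numeric(nrow(W)))
    colnames(nl) <- paste0("nl", seq_along(m$nl_terms))
    blocks <- c(blocks, list(nl))
  }
  do.call(cbind, blocks)
}

# Outcome-model design: exposure, confounders, WW products, XW products,
# non-linear bases.
dgm_outcome_design <- function(params, W, X) {
  m <- params$outcome
  blocks <- list(x = matrix(X, ncol = 1, dimnames = list(NULL, "x")), W)
  if (nrow_or_zero(m$ww_pairs)) {
    ww <- W[, m$ww_pairs[, 1], drop = FALSE] * W[, m$ww_pairs[, 2], drop = FALSE]
    colnames(ww) <- paste0("ww", seq_len(ncol(ww)))
    blocks <- c(blocks, list(ww))
  }
  if (length(m$xw_cols)) {
    xw <- X * W[, m$xw_cols, drop = FALSE]
    colnames(xw) <- paste0("xw", seq_along(m$xw_cols))
    blocks <- c(blocks, list(xw))
  }
  if (length(m$nl_terms)) {
    nl <- vapply(m$nl_terms, function(t) nl_value(W, t), numeric(nrow(W)))
    colnames(nl) <- paste0("nl", seq_along(m$nl_terms))
    blocks <- c(blocks, list(nl))
  }
  do.call(cbind, blocks)
}
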