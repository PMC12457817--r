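# Independent oracle implementations and tiny mechanisms used across tests.
# Oracles are deliberately written as straight-line / brute-force code, not
# through the package's own computational paths.

# Straight-line evaluation of the AIPW estimator and its variance from the
# per-record formula, term by term.
oracle_aipw <- function(y, x, e1, e0, g) {
  n <- length(y)
  terms <- numeric(n)
  for (i in seq_len(n)) {
    terms[i] <- e1[i] - e0[i] +
      x[i] * (y[i] - e1[i]) / g[i] -
      (1 - x[i]) * (y[i] - e0[i]) / (1 - g[i])
  }
  psi <- sum(terms) / n
  v <- sum((terms - psi)^2) / (n - 1) / n
  list(psi = psi, se = sqrt(v), terms = terms)
}

# TMLE targeting via a generic optimizer maximizing the fluctuation
# likelihood (instead of solving the score equation).
oracle_tmle_psi <- function(y, x, e1, e0, g) {
  a <- min(y)
  b <- max(y)
  sc <- function(v) pmin(pmax((v - a) / (b - a), 1e-4), 1 - 1e-4)
  ys <- (y - a) / (b - a)
  q1 <- sc(e1)
  q0 <- sc(e0)
  qx <- ifelse(x == 1, q1, q0)
  H <- x / g - (1 - x) / (1 - g)
  negll <- function(eps) {
    q <- plogis(qlogis(qx) + eps * H)
    -sum(ys * log(q) + (1 - ys) * log(1 - q))
  }
  eps <- optimize(negll, c(-5, 5), tol = 1e-12)$minimum
  q1s <- plogis(qlogis(q1) + eps / g)
  q0s <- plogis(qlogis(q0) - eps / (1 - g))
  mean(a + (b - a) * q1s) - mean(a + (b - a) * q0s)
}

# Grid search over the probability simplex at a fixed resolution.
oracle_simplex_loss <- function(Z, y, loss, step = 0.01) {
  L <- ncol(Z)
  lossfun <- function(w) {
    p <- drop(Z %*% w)
    if (loss == "squared") {
      mean((p - y)^2)
    } else {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
  }
  grid <- seq(0, 1, by = step)
  best <- Inf
  if (L == 2) {
    for (w1 in grid) best <- min(best, lossfun(c(w1, 1 - w1)))
  } else if (L == 3) {
    for (w1 in grid) {
      for (w2 in seq(0, 1 - w1, by = step)) {
        best <- min(best, lossfun(c(w1, w2, 1 - w1 - w2)))
      }
    }
  } else {
    stop("oracle supports 2 or 3 learners")
  }
  best
}

# Two-line oracle for the stability-exclusion rule.
oracle_stability_flags <- function(psi, se) {
  se > 10 * median(se) | abs(psi) > 5 * abs(median(psi))
}

# Brute-force linear predictor of a mechanism's exposure model, looping over
# every term in the parameter object.
oracle_exposure_lp <- function(params, W) {
  m <- params$exposure
  n <- nrow(W)
  lp <- rep(m$intercept, n)
  for (j in seq_along(m$main)) lp <- lp + m$main[j] * W[, j]
  if (length(m$ww_coefs)) {
    for (r in seq_along(m$ww_coefs)) {
      lp <- lp + params$interaction_multiplier * m$ww_coefs[r] *
        W[, m$ww_pairs[r, 1]] * W[, m$ww_pairs[r, 2]]
    }
  }
  if (length(m$nl_coefs)) {
    for (r in seq_along(m$nl_coefs)) {
      t <- m$nl_terms[[r]]
      z <- W[, t$col]
      basis <- if (t$type == "sq") z^2 else log(abs(z) + 1)
      lp <- lp + m$nl_coefs[r] * basis
    }
  }
  lp
}

# Same for the outcome conditional mean, with the interaction multiplier
# applied explicitly.
oracle_outcome_mean <- function(params, W, X) {
  m <- params$outcome
  mult <- params$interaction_multiplier
  n <- nrow(W)
  mu <- rep(m$intercept, n) + m$beta_x * X
  for (j in seq_along(m$main)) mu <- mu + m$main[j] * W[, j]
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
      t <- m$nl_terms[[r]]
      z <- W[, t$col]
      basis <- if (t$type == "sq") z^2 else log(abs(z) + 1)
      mu <- mu + m$nl_coefs[r] * basis
    }
  }
  mu
}

# A tiny custom mechanism (p = 2: one binary, one continuous) for fast unit
# tests of the calibration contracts.
tiny_dgm <- function(beta_x = 0.4, b_main = c(0.5, -0.4), a_main = c(0.6, 0.5),
                     sd = 1) {
  params <- list(
    name = "custom", complexity = "simple", p = 2L, n_continuous = 1L,
    interaction_multiplier = 1,
    confounders = list(
      list(family = "bernoulli", coefs = qlogis(0.3)),
      list(family = "gaussian", coefs = c(0, 0.4), sd = 1)
    ),
    exposure = list(
      intercept = qlogis(0.3), main = a_main,
      ww_pairs = NULL, ww_coefs = numeric(0),
      nl_terms = list(), nl_coefs = numeric(0)
    ),
    outcome = list(
      intercept = 0, beta_x = beta_x, main = b_main,
      ww_pairs = NULL, ww_coefs = numeric(0),
      xw_cols = integer(0), xw_coefs = numeric(0),
      nl_terms = list(), nl_coefs = numeric(0),
      sd = sd
    )
  )
  class(params) <- "dgm_params"
  drcfit:::validate_dgm_params(params)
}

# Nuisance table fixtures shipped under extdata.
fixture_path <- function(file) {
  system.file("extdata", file, package = "drcfit", mustWork = TRUE)
}
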