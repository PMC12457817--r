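# Shipped default parameterizations for the five data-generating mechanisms.
#
# The generation *structure* (sequential mixed-type confounders with mutual
# dependence, logistic exposure, Gaussian outcome, simple/complex variants,
# small p = 14 and large p = 87 confounder sets) emulates the motivating
# birth-cohort study; the *coefficient values* are package defaults, fixed
# once by drawing from the distributions below under the constant seed
# `.dgm_build_seed` so they behave as versioned constants:
#
#   * continuous confounders: Gaussian-linear, intercept 0, residual sd 1,
#     dependence on up to 3 earlier variables with coefficients U(-0.3, 0.3);
#   * binary confounders: Bernoulli-logistic with marginal prevalence drawn
#     from U(0.05, 0.5), dependence coefficients U(-0.5, 0.5);
#   * exposure model: intercept logit(0.25) (~25% exposure prevalence, as in
#     the motivating cohort), main effects (1.73 / sqrt(p)) * U(-1, 1) so the
#     linear-predictor sd is ~1 regardless of p;
#   * outcome model: residual sd 0.8 (outcome standardized), main effects
#     (0.6 * sqrt(3 / p)) * U(-1, 1) giving a confounder-explained sd ~0.6,
#     exposure main effect 0.5 before power calibration;
#   * complex variants: round(10 p / 14) confounder-confounder pairs (both
#     models) and round(5 p / 14) exposure-confounder columns (outcome model),
#     base interaction coefficients at 0.3x the main-effect scale before the
#     mechanism's interaction multiplier; round(4 p / 14) squared and
#     round(4 p / 14) log(|z| + 1) terms on designated continuous confounders
#     in both models, also at 0.3x the main-effect scale (not multiplied).
#
# All defaults are overridable through dgm_params(overrides = ...).

.dgm_build_seed <- 20250901L

.dgm_cache <- new.env(parent = emptyenv())

dgm_preset <- function(name) {
  if (!is.null(.dgm_cache[[name]])) return(.dgm_cache[[name]])
  set <- if (name %in% c("simple-1", "complex-1a", "complex-1b")) "small" else "large"
  base <- dgm_base_structure(set)
  complexity <- if (startsWith(name, "simple")) "simple" else "complex"
  mult <- switch(name,
    "complex-1a" = 2, "complex-1b" = 4, 1
  )
  params <- base
  params$name <- name
  params$complexity <- complexity
  params$interaction_multiplier <- mult
  if (complexity == "simple") {
    params$exposure$ww_coefs <- rep(0, length(params$exposure$ww_coefs))
    params$exposure$nl_coefs <- rep(0, length(params$exposure$nl_coefs))
    params$outcome$ww_coefs <- rep(0, length(params$outcome$ww_coefs))
    params$outcome$xw_coefs <- rep(0, length(params$outcome$xw_coefs))
    params$outcome$nl_coefs <- rep(0, length(params$outcome$nl_coefs))
  }
  class(params) <- "dgm_params"
  params <- validate_dgm_params(params)
  .dgm_cache[[name]] <- params
  params
}

# Base structure shared by the simple and complex variants of a confounder
# set; complex-specific coefficients are drawn here so that zeroing them in
# the simple variant leaves everything else identical (nesting property).
dgm_base_structure <- function(set = c("small", "large")) {
  set <- match.arg(set)
  key <- paste0("base_", set)
  if (!is.null(.dgm_cache[[key]])) return(.dgm_cache[[key]])
  p <- if (set == "small") 14L else 87L
  n_binary <- if (set == "small") 1L else 9L
  out <- with_seed(.dgm_build_seed + (set == "large"), {
    confounders <- vector("list", p)
    for (j in seq_len(p)) {
      n_prev <- j - 1L
      n_dep <- min(3L, n_prev)
      dep <- if (n_dep > 0) sort(sample.int(n_prev, n_dep)) else integer(0)
      if (j <= n_binary) {
        coefs <- numeric(n_prev + 1L)
        coefs[1] <- qlogis(runif(1, 0.05, 0.5))
        coefs[dep + 1L] <- runif(n_dep, -0.5, 0.5)
        confounders[[j]] <- list(family = "bernoulli", coefs = coefs)
      } else {
        coefs <- numeric(n_prev + 1L)
        coefs[dep + 1L] <- runif(n_dep, -0.3, 0.3)
        confounders[[j]] <- list(family = "gaussian", coefs = coefs, sd = 1)
      }
    }
    cx <- 1.73 / sqrt(p)
    cy <- 0.6 * sqrt(3 / p)
    n_ww <- round(10 * p / 14)
    n_xw <- round(5 * p / 14)
    n_sq <- round(4 * p / 14)
    n_log <- round(4 * p / 14)
    ww_pairs <- unique_pairs(p, n_ww)
    xw_cols <- sort(sample.int(p, n_xw))
    cont_cols <- which(seq_len(p) > n_binary)
    nl_cols <- sample(cont_cols, n_sq + n_log)
    nl_terms <- c(
      lapply(nl_cols[seq_len(n_sq)], function(cc) list(col = cc, type = "sq")),
      lapply(nl_cols[n_sq + seq_len(n_log)], function(cc) list(col = cc, type = "log"))
    )
    list(
      p = p,
      n_continuous = p - n_binary,
      confounders = confounders,
      exposure = list(
        intercept = qlogis(0.25),
        main = cx * runif(p, -1, 1),
        ww_pairs = ww_pairs,
        ww_coefs = 0.3 * cx * runif(n_ww, -1, 1),
        nl_terms = nl_terms,
        nl_coefs = 0.3 * cx * runif(n_sq + n_log, -1, 1)
      ),
      outcome = list(
        intercept = 0,
        beta_x = 0.5,
        main = cy * runif(p, -1, 1),
        ww_pairs = ww_pairs,
        ww_coefs = 0.3 * cy * runif(n_ww, -1, 1),
        xw_cols = xw_cols,
        xw_coefs = 0.3 * cy * runif(n_xw, -1, 1),
        nl_terms = nl_terms,
        nl_coefs = 0.3 * cy * runif(n_sq + n_log, -1, 1),
        sd = 0.8
      )
    )
  })
  .dgm_cache[[key]] <- out
  out
}

# n distinct unordered pairs i < j from 1..p.
unique_pairs <- function(p, n) {
  all_pairs <- p * (p - 1) / 2
  stopifnot(n <= all_pairs)
  seen <- character(0)
  pairs <- matrix(0L, n, 2)
  r <- 0L
  while (r < n) {
    ij <- sort(sample.int(p, 2))
    key <- paste(ij, collapse = "-")
    if (key %in% seen) next
    r <- r + 1L
    seen <- c(seen, key)
    pairs[r, ] <- ij
  }
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}
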