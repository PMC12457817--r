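#' @importFrom stats plogis qlogis rnorm rbinom runif glm glm.fit lm.fit
#'   predict quantile sd var median binomial gaussian quasibinomial coef
#'   pnorm qnorm as.formula model.matrix setNames
#' @importFrom utils head modifyList
NULL

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit
# integer range (R integers). Deterministic and collision-poor for the
# index ranges used here (reps <= ~1e5, streams < 100).
child_seed <- function(seed, index, stream = 0L) {
  s <- (as.double(seed) * 48271 + as.double(index) * 1009 + stream * 97) %%
    2147483629
  as.integer(s) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_config <- function(..., class = "drcfit_config_error") {
  stop(rlang::error_cnd(class = class, message = paste0(...)))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_config(name, " must be a single finite number")
  }
  invisible(x)
}
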