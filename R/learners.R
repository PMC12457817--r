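#' Specify a base learner for the Super Learner library
#'
#' @param name unique identifier within a library.
#' @param family learner family; one of `"glm"`, `"glm-interactions"`,
#'   `"ridge"` (a ridge-penalized GLM standing in for a Bayesian GLM),
#'   `"gam"`, `"lasso"`, `"boost"` (gradient-boosted depth-1 trees) or
#'   `"mlp"` (single-hidden-layer neural network). Random-forest and
#'   MARS-style families are not available in this build: no implementation
#'   exists in the supported dependency set.
#' @param hyper named list of hyperparameters; missing entries are filled
#'   with the family defaults (see [learner_defaults()]).
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name, family = name, hyper = list()) {
  family <- match.arg(family, names(.learner_families))
  hyper <- utils::modifyList(learner_defaults(family), hyper)
  structure(
    list(name = name, family = family, hyper = hyper),
    class = "learner_spec"
  )
}

#' Default hyperparameters per learner family
#' @param family learner family name.
#' @return Named list of defaults.
#' @export
learner_defaults <- function(family) {
  switch(family,
    "glm" = list(),
    "glm-interactions" = list(max_ratio = 0.9),
    "ridge" = list(lambda = 0.01),
    "gam" = list(k = 4, max_ratio = 0.9),
    "lasso" = list(alpha = 1, nfolds = 5, nlambda = 50, lambda = NULL,
                   freeze_lambda = TRUE),
    "boost" = list(n_trees = 100, shrinkage = 0.1, n_splits = 20,
                   subsample = 1),
    "mlp" = list(size = 5, decay = 0.1, maxit = 200),
    abort_config("unknown learner family '", family, "'")
  )
}

#' Assemble a Super Learner library
#'
#' Two presets are shipped. `"reduced"` holds the less flexible (parametric
#' and additive) approaches: GLM, GLM with pairwise interactions, ridge GLM,
#' GAM, and lasso-regularized GLM. `"full"` is a superset adding the flexible
#' non-parametric learners (gradient-boosted stumps and a single-hidden-layer
#' neural network), i.e. learners more prone to biased standard errors when
#' cross-fitting is not used. A character vector of family names builds a
#' custom library.
#'
#' @param library `"reduced"`, `"full"`, a character vector of family names,
#'   or a list of [learner_spec()] objects (returned unchanged).
#' @return A named list of `learner_spec` objects.
#' @examples
#' names(sl_library("reduced"))
#' names(sl_library(c("glm", "lasso")))
#' @export
sl_library <- function(library = "reduced") {
  if (is.list(library)) {
    stopifnot(all(vapply(library, inherits, logical(1), "learner_spec")))
    names(library) <- vapply(library, `[[`, character(1), "name")
    if (anyDuplicated(names(library))) stop("learner names must be unique")
    return(library)
  }
  families <- if (identical(library, "reduced")) {
    c("glm", "glm-interactions", "ridge", "gam", "lasso")
  } else if (identical(library, "full")) {
    c("glm", "glm-interactions", "ridge", "gam", "lasso", "boost", "mlp")
  } else {
    library
  }
  specs <- lapply(families, function(f) learner_spec(f, f))
  names(specs) <- families
  specs
}

# ---- learner fitting registry ----------------------------------------------

# Each family entry is list(fit = function(x, y, task, hyper) -> model,
# predict = function(model, x) -> numeric). `task` is "regression" or
# "classification"; classification predictions are probabilities in [0, 1].

fit_learner <- function(spec, x, y, task) {
  fam <- .learner_families[[spec$family]]
  model <- fam$fit(x, y, task, spec$hyper)
  structure(
    list(model = model, family = spec$family, name = spec$name, task = task,
         cols = colnames(x)),
    class = "drcfit_learner_fit"
  )
}

predict_learner <- function(fit, x) {
  pred <- .learner_families[[fit$family]]$predict(fit$model, x, fit$task)
  if (fit$task == "classification") pred <- pmin(pmax(pred, 1e-6), 1 - 1e-6)
  pred
}

lin_fit <- function(x, y, task) {
  D <- cbind(1, x)
  beta <- if (task == "regression") {
    lm.fit(D, y)$coefficients
  } else {
    suppressWarnings(glm.fit(D, y, family = binomial())$coefficients)
  }
  beta[is.na(beta)] <- 0
  beta
}

lin_predict <- function(beta, x, task) {
  eta <- drop(cbind(1, x) %*% beta)
  if (task == "classification") plogis(eta) else eta
}

expand_pairwise <- function(x) {
  p <- ncol(x)
  if (p < 2) return(x)
  pairs <- utils::combn(p, 2)
  inter <- x[, pairs[1, ], drop = FALSE] * x[, pairs[2, ], drop = FALSE]
  colnames(inter) <- paste0(colnames(x)[pairs[1, ]], ":", colnames(x)[pairs[2, ]])
  cbind(x, inter)
}

.learner_families <- list(
  "glm" = list(
    fit = function(x, y, task, hyper) lin_fit(x, y, task),
    predict = function(model, x, task) lin_predict(model, x, task)
  ),
  "glm-interactions" = list(
    fit = function(x, y, task, hyper) {
      xx <- expand_pairwise(x)
      if (ncol(xx) + 1 > hyper$max_ratio * nrow(x)) {
        stop("glm-interactions: expanded design wider than the sample supports")
      }
      lin_fit(xx, y, task)
    },
    predict = function(model, x, task) lin_predict(model, expand_pairwise(x), task)
  ),
  "ridge" = list(
    fit = function(x, y, task, hyper) {
      glmnet::glmnet(
        x, y,
        family = if (task == "regression") "gaussian" else "binomial",
        alpha = 0, lambda = hyper$lambda
      )
    },
    predict = function(model, x, task) {
      drop(predict(model, x, type = "response"))
    }
  ),
  "gam" = list(
    fit = function(x, y, task, hyper) {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      smooth <- vapply(df, function(v) length(unique(v)) >= 10, logical(1))
      n_par <- sum(smooth) * (hyper$k - 1) + sum(!smooth) + 1
      if (n_par > hyper$max_ratio * nrow(x)) {
        stop("gam: smooth basis wider than the sample supports")
      }
      terms <- ifelse(
        smooth, sprintf("s(%s, k = %d, bs = 'cr')", names(df), hyper$k),
        names(df)
      )
      df$.y <- y
      mgcv::gam(
        as.formula(paste(".y ~", paste(terms, collapse = " + "))),
        data = df,
        family = if (task == "regression") gaussian() else binomial(),
        method = "REML"
      )
    },
    predict = function(model, x, task) {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      as.numeric(predict(model, newdata = df, type = "response"))
    }
  ),
  "lasso" = list(
    fit = function(x, y, task, hyper) {
      fam <- if (task == "regression") "gaussian" else "binomial"
      if (is.null(hyper$lambda)) {
        cv <- glmnet::cv.glmnet(
          x, y,
          family = fam, alpha = hyper$alpha,
          nfolds = hyper$nfolds, nlambda = hyper$nlambda
        )
        structure(list(fit = cv$glmnet.fit, lambda = cv$lambda.min),
                  class = "drcfit_lasso")
      } else {
        structure(
          list(
            fit = glmnet::glmnet(x, y, family = fam, alpha = hyper$alpha,
                                 lambda = hyper$lambda),
            lambda = hyper$lambda
          ),
          class = "drcfit_lasso"
        )
      }
    },
    predict = function(model, x, task) {
      drop(predict(model$fit, x, s = model$lambda, type = "response"))
    }
  ),
  "boost" = list(
    fit = function(x, y, task, hyper) fit_boost(x, y, task, hyper),
    predict = function(model, x, task) predict_boost(model, x, task)
  ),
  "mlp" = list(
    fit = function(x, y, task, hyper) fit_mlp(x, y, task, hyper),
    predict = function(model, x, task) predict_mlp(model, x, task)
  )
)

# Pre-select the lasso penalty once per training set so that the Super
# Learner's internal cross-validation refits a single-lambda glmnet (the
# documented default; see the methods vignette for rationale).
freeze_lasso_lambda <- function(library, x, y, task) {
  for (i in seq_along(library)) {
    spec <- library[[i]]
    if (spec$family == "lasso" && isTRUE(spec$hyper$freeze_lambda) &&
      is.null(spec$hyper$lambda)) {
      fam <- if (task == "regression") "gaussian" else "binomial"
      cv <- glmnet::cv.glmnet(
        x, y,
        family = fam, alpha = spec$hyper$alpha,
        nfolds = spec$hyper$nfolds, nlambda = spec$hyper$nlambda
      )
      library[[i]]$hyper$lambda <- cv$lambda.min
    }
  }
  library
}
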