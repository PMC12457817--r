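# Hand-rolled flexible learners. No gradient-boosting, random-forest or
# neural-network package is available in the supported dependency set, so the
# two flexible non-parametric members of the full library are implemented
# here directly: gradient-boosted depth-1 regression trees (stumps) and a
# single-hidden-layer neural network trained by BFGS.

# ---- gradient-boosted stumps ----------------------------------------------

# Candidate split points per feature: interior quantiles, so split search is
# O(n_splits) per feature per boosting round.
boost_split_grid <- function(x, n_splits) {
  lapply(seq_len(ncol(x)), function(j) {
    q <- unique(quantile(x[, j], probs = seq_len(n_splits) / (n_splits + 1),
                         type = 7, names = FALSE))
    q[q < max(x[, j])] # a split must leave the right node non-empty
  })
}

# Best stump for working response r: minimizes SSE over (feature, split).
fit_stump <- function(x, r, grid) {
  best <- list(sse = Inf)
  n <- length(r)
  sum_r <- sum(r)
  for (j in seq_along(grid)) {
    splits <- grid[[j]]
    if (!length(splits)) next
    xj <- x[, j]
    for (s in splits) {
      left <- xj <= s
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      sl <- sum(r[left])
      # SSE reduction maximized <=> sl^2/nl + (sum-sl)^2/(n-nl) maximized
      score <- sl^2 / nl + (sum_r - sl)^2 / (n - nl)
      if (-score < best$sse) {
        best <- list(
          sse = -score, j = j, split = s,
          left = sl / nl, right = (sum_r - sl) / (n - nl)
        )
      }
    }
  }
  best
}

stump_predict <- function(st, x) {
  ifelse(x[, st$j] <= st$split, st$left, st$right)
}

fit_boost <- function(x, y, task, hyper) {
  n <- length(y)
  grid <- boost_split_grid(x, hyper$n_splits)
  if (task == "regression") {
    f0 <- mean(y)
    f <- rep(f0, n)
  } else {
    f0 <- qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
    f <- rep(f0, n)
  }
  trees <- vector("list", hyper$n_trees)
  for (t in seq_len(hyper$n_trees)) {
    # negative gradient: residual (squared error) or y - p (Bernoulli)
    r <- if (task == "regression") y - f else y - plogis(f)
    idx <- if (hyper$subsample < 1) {
      sample.int(n, max(2, floor(hyper$subsample * n)))
    } else {
      seq_len(n)
    }
    st <- fit_stump(x[idx, , drop = FALSE], r[idx], grid)
    if (!is.finite(st$sse)) break
    trees[[t]] <- st
    f <- f + hyper$shrinkage * stump_predict(st, x)
  }
  list(f0 = f0, trees = trees[!vapply(trees, is.null, logical(1))],
       shrinkage = hyper$shrinkage)
}

predict_boost <- function(model, x, task) {
  f <- rep(model$f0, nrow(x))
  for (st in model$trees) {
    f <- f + model$shrinkage * stump_predict(st, x)
  }
  if (task == "classification") plogis(f) else f
}

# ---- single-hidden-layer neural network -----------------------------------

# Weights packed as [W1 (p x size), b1 (size), w2 (size), b2]. Inputs are
# standardized internally; tanh hidden activation; identity (regression) or
# logistic (classification) output; L2 penalty `decay` on all weights.
mlp_unpack <- function(theta, p, size) {
  i1 <- p * size
  list(
    W1 = matrix(theta[seq_len(i1)], p, size),
    b1 = theta[i1 + seq_len(size)],
    w2 = theta[i1 + size + seq_len(size)],
    b2 = theta[i1 + 2 * size + 1]
  )
}

fit_mlp <- function(x, y, task, hyper) {
  p <- ncol(x)
  size <- hyper$size
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  n <- nrow(xs)
  npar <- p * size + 2 * size + 1
  loss_grad <- function(theta) {
    w <- mlp_unpack(theta, p, size)
    Z <- tanh(sweep(xs %*% w$W1, 2, w$b1, "+"))
    eta <- drop(Z %*% w$w2) + w$b2
    if (task == "regression") {
      resid <- eta - y
      loss <- mean(resid^2) / 2
      dout <- resid / n
    } else {
      pr <- plogis(eta)
      loss <- -mean(y * log(pmax(pr, 1e-12)) +
                      (1 - y) * log(pmax(1 - pr, 1e-12)))
      dout <- (pr - y) / n
    }
    gw2 <- drop(crossprod(Z, dout)) + hyper$decay * w$w2
    gb2 <- sum(dout)
    dhid <- outer(dout, w$w2) * (1 - Z^2)
    gW1 <- crossprod(xs, dhid) + hyper$decay * w$W1
    gb1 <- colSums(dhid)
    list(
      value = loss + hyper$decay / 2 * (sum(w$W1^2) + sum(w$w2^2)),
      grad = c(as.vector(gW1), gb1, gw2, gb2)
    )
  }
  theta0 <- runif(npar, -0.5, 0.5) / sqrt(p)
  opt <- stats::optim(
    theta0,
    fn = function(th) loss_grad(th)$value,
    gr = function(th) loss_grad(th)$grad,
    method = "BFGS",
    control = list(maxit = hyper$maxit, reltol = 1e-10)
  )
  list(theta = opt$par, p = p, size = size, mu = mu, sd = sdev)
}

predict_mlp <- function(model, x, task) {
  xs <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
  w <- mlp_unpack(model$theta, model$p, model$size)
  Z <- tanh(sweep(xs %*% w$W1, 2, w$b1, "+"))
  eta <- drop(Z %*% w$w2) + w$b2
  if (task == "classification") plogis(eta) else eta
}
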