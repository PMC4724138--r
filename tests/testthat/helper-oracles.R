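# Independent oracles, written from the definitions, never calling the
# package's fitting code.

# Logistic regression MLE by plain Newton-Raphson on the score equations.
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(score)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  se <- unname(sqrt(diag(solve(crossprod(X * (mu * (1 - mu)), X)))))
  list(coef = unname(beta), se = se)
}

# OLS by the closed-form normal equations.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = as.vector(beta), se = unname(sqrt(sigma2 * diag(solve(XtX)))))
}

# AUC by brute-force enumeration of all case-control pairs.
oracle_auc <- function(cases, controls) {
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(cases) * length(controls))
}

# Pearson contingency chi-square from first principles.
oracle_chisq <- function(counts) {
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - expected)^2 / expected)
}

# draw a random small logistic dataset that is clearly non-separated;
# regenerates until the oracle fit is well-behaved
draw_logistic_instance <- function(n = 60) {
  repeat {
    d <- stats::rbinom(n, 2, runif(1, 0.2, 0.8))
    x <- stats::rnorm(n)
    eta <- -0.2 + runif(1, -0.6, 0.6) * d + 0.3 * x
    y <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
    if (length(unique(y)) < 2 || var(d) == 0) next
    X <- cbind(1, d, x)
    fit <- tryCatch(oracle_logistic(X, y), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coef)) || max(abs(fit$coef)) > 8) next
    return(list(d = d, x = x, y = y, oracle = fit))
  }
}
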