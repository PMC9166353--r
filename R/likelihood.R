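## Shared Gaussian-likelihood machinery. Every trait model is a multivariate
## normal with mean X beta and covariance sigma2 * V(theta); beta and sigma2
## have closed-form ML solutions given V, so only the covariance parameters
## are searched numerically. Solves go through a Cholesky factor of V, with
## the log-determinant read off the factor diagonal (stable at n = 836);
## a factorization failure is an error, never a silent pseudo-inverse.

## Profile ML of a Gaussian model y ~ N(X beta, sigma2 * V).
## Returns logLik maximized over beta and sigma2, plus the pieces callers
## need (GLS coefficients, whitened design, RSS).
profile_mvn <- function(V, y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite (Cholesky failed)",
         call. = FALSE))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw))
    stop("design matrix is rank deficient (collinear predictors)",
         call. = FALSE)
  beta <- qr.coef(qx, yw)
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  logdetV <- 2 * sum(log(diag(R)))
  if (rss <= n * 1e-12 * max(1, mean(y)^2)) {
    return(list(loglik = Inf, beta = beta, sigma2 = 0, rss = rss,
                R = R, Xw = Xw, yw = yw, logdetV = logdetV,
                degenerate = TRUE))
  }
  sigma2 <- rss / n
  loglik <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2) -
    0.5 * logdetV - 0.5 * n
  list(loglik = loglik, beta = beta, sigma2 = sigma2, rss = rss,
       R = R, Xw = Xw, yw = yw, logdetV = logdetV, degenerate = FALSE)
}

## Exact Gaussian log-likelihood at fixed mean vector and covariance.
mvn_loglik <- function(y, mean, Sigma) {
  n <- length(y)
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is not positive definite (Cholesky failed)",
         call. = FALSE))
  z <- backsolve(R, y - mean, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

## Evaluate a scalar profile log-likelihood on a bounded interval with a
## deterministic multi-start (optimize over subintervals + endpoints).
## Returns the arg max, the max, and whether it sits at a bound.
optimize_profile <- function(f, lower, upper, n_starts = 5L, tol = 1e-8) {
  cuts <- seq(lower, upper, length.out = n_starts + 1L)
  best <- list(par = lower, value = f(lower))
  for (i in seq_len(n_starts)) {
    o <- stats::optimize(f, c(cuts[i], cuts[i + 1L]), maximum = TRUE,
                         tol = tol)
    if (o$objective > best$value)
      best <- list(par = o$maximum, value = o$objective)
  }
  vu <- f(upper)
  if (vu > best$value) best <- list(par = upper, value = vu)
  btol <- max(1e-6, 1e-4 * (upper - lower))
  best$at_lower <- best$par - lower < btol
  best$at_upper <- upper - best$par < btol
  ## snap to the bound when the optimizer stops within tolerance of it
  if (best$at_lower) best$par <- lower
  if (best$at_upper) best$par <- upper
  best
}

## Run code with a temporary RNG state seeded from `seed`; restores the
## caller's stream so package functions never clobber user RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
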