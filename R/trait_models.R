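## Maximum-likelihood fitting of the seven continuous trait-evolution models
## (Brownian motion, white noise, Pagel's lambda, Ornstein-Uhlenbeck,
## Early-Burst, trend diffusion, drift) and their comparison by AIC and
## likelihood-ratio tests. ML (not REML) throughout, so log-likelihoods are
## comparable across models and valid for LRTs.

new_evo_fit <- function(model, params, loglik, k, n, y, tips,
                        converged = TRUE, boundary = character(),
                        notes = character()) {
  structure(list(
    model = model, params = params, loglik = loglik, k = k,
    AIC = 2 * k - 2 * loglik, n = n, y = unname(y), tips = tips,
    converged = converged, boundary = boundary, notes = notes),
    class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat("Trait-evolution model fit:", x$model, "\n")
  cat(sprintf("  n = %d tips, logLik = %.4f, k = %d, AIC = %.4f\n",
              x$n, x$loglik, x$k, x$AIC))
  cat("  parameters:\n")
  for (p in names(x$params))
    cat(sprintf("    %-8s %.6g%s\n", p, x$params[[p]],
                if (p %in% x$boundary) "  [at bound]" else ""))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
logLik.evo_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

check_fit_data <- function(tree, y) {
  validate_tree(tree)
  if (is.null(names(y))) {
    if (length(y) != ape::Ntip(tree))
      stop("`y` has no names and its length differs from the tip count",
           call. = FALSE)
    names(y) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(y)))
    stop("`y` is missing values for some tips", call. = FALSE)
  y <- y[tree$tip.label]
  if (length(y) < 2L) stop("need at least 2 tips", call. = FALSE)
  if (anyNA(y) || !all(is.finite(y)))
    stop("`y` contains missing or non-finite values", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate data: trait is constant across tips", call. = FALSE)
  y
}

#' Fit the Brownian-motion model
#'
#' Closed-form ML fit: trait covariance `sigma2 * C` with `C` the path-sum
#' covariance of [phylo_vcv()], mean equal to the GLS phylogenetic mean
#' (the root-state estimate).
#'
#' @param tree A rooted `phylo` object.
#' @param y Named trait vector (one value per tip).
#' @return An `evo_fit` with parameters `sigma2` and `z0`; `k = 2`.
#' @export
fit_bm <- function(tree, y) {
  y <- check_fit_data(tree, y)
  C <- phylo_vcv(tree)
  pf <- profile_mvn(C, y)
  if (pf$degenerate)
    stop("degenerate data: zero phylogenetic residual variance", call. = FALSE)
  new_evo_fit("BM", list(sigma2 = pf$sigma2, z0 = unname(pf$beta[1L])),
              pf$loglik, k = 2L, n = length(y), y = y, tips = names(y))
}

#' Fit the white-noise (non-phylogenetic) model
#'
#' Ignores the tree: tips are iid normal. ML estimates are the sample mean
#' and the population variance.
#'
#' @inheritParams fit_bm
#' @return An `evo_fit` with parameters `sigma2` and `z0`; `k = 2`.
#' @export
fit_white_noise <- function(tree, y) {
  y <- check_fit_data(tree, y)
  n <- length(y)
  pf <- profile_mvn(diag(n), y)
  new_evo_fit("white-noise",
              list(sigma2 = pf$sigma2, z0 = unname(pf$beta[1L])),
              pf$loglik, k = 2L, n = n, y = y, tips = names(y))
}

#' Fit Pagel's lambda model
#'
#' Optimizes the off-diagonal multiplier `lambda` in `[0, lambda_max]` of the
#' profile log-likelihood; `lambda = 1` recovers Brownian motion and
#' `lambda = 0` a star-like model with the original tip heights.
#'
#' @inheritParams fit_bm
#' @param lambda_max Upper bound for lambda (default 1).
#' @return An `evo_fit` with parameters `sigma2`, `z0`, `lambda`; `k = 3`.
#' @export
fit_lambda <- function(tree, y, lambda_max = 1) {
  y <- check_fit_data(tree, y)
  C <- phylo_vcv(tree)
  f <- function(l) profile_mvn(transform_lambda(C, l, lambda_max), y)$loglik
  opt <- optimize_profile(f, 0, lambda_max)
  pf <- profile_mvn(transform_lambda(C, opt$par, lambda_max), y)
  bnd <- c(if (opt$at_lower) "lambda", if (opt$at_upper) "lambda")
  fit <- new_evo_fit("lambda",
                     list(sigma2 = pf$sigma2, z0 = unname(pf$beta[1L]),
                          lambda = opt$par),
                     opt$value, k = 3L, n = length(y), y = y,
                     tips = names(y), boundary = unique(bnd))
  fit$profile <- f      # profile logLik in lambda, used for CIs / LRTs
  fit
}

#' Fit the Ornstein-Uhlenbeck model
#'
#' Optimizes the attraction strength `alpha > 0` over a log-spaced range;
#' the `alpha -> 0` boundary is the Brownian model, so the OU log-likelihood
#' never drops below BM's beyond numerical tolerance.
#'
#' @inheritParams fit_bm
#' @param alpha_range Search interval for alpha (default `c(1e-6, 100)`).
#' @return An `evo_fit` with parameters `sigma2`, `z0`, `alpha`; `k = 3`.
#' @export
fit_ou <- function(tree, y, alpha_range = c(1e-6, 100)) {
  y <- check_fit_data(tree, y)
  S <- phylo_vcv(tree)
  h <- diag(S)
  D <- outer(h, h, "+") - 2 * S
  vrel <- function(a) exp(-a * D) * (-expm1(-2 * a * S)) / (2 * a)
  f <- function(la) tryCatch(profile_mvn(vrel(exp(la)), y)$loglik,
                             error = function(e) -1e10)
  opt <- optimize_profile(f, log(alpha_range[1L]), log(alpha_range[2L]),
                          n_starts = 6L)
  alpha <- exp(opt$par)
  pf <- profile_mvn(vrel(alpha), y)
  bnd <- c(if (opt$at_lower || opt$at_upper) "alpha")
  ## sigma2 of the process: profiled scalar multiplies vrel, which already
  ## carries the 1/(2 alpha) stationary factor
  new_evo_fit("OU", list(sigma2 = pf$sigma2, z0 = unname(pf$beta[1L]),
                         alpha = alpha),
              opt$value, k = 3L, n = length(y), y = y, tips = names(y),
              boundary = bnd,
              notes = if (opt$at_lower)
                "alpha at lower bound: indistinguishable from Brownian motion")
}

#' Fit the Early-Burst model
#'
#' Optimizes the rate-decay exponent `a` in `[a_min, 0]`; `a = 0` collapses
#' exactly to Brownian motion and is reported with a boundary flag.
#'
#' @inheritParams fit_bm
#' @param a_min Lower bound for the exponent (default -10 per unit branch
#'   length).
#' @return An `evo_fit` with parameters `sigma2`, `z0`, `a`; `k = 3`.
#' @export
fit_eb <- function(tree, y, a_min = -10) {
  y <- check_fit_data(tree, y)
  S <- phylo_vcv(tree)
  vrel <- function(a) if (a == 0) S else expm1(a * S) / a
  f <- function(a) tryCatch(profile_mvn(vrel(a), y)$loglik,
                            error = function(e) -1e10)
  opt <- optimize_profile(f, a_min, 0)
  pf <- profile_mvn(vrel(opt$par), y)
  bnd <- c(if (opt$at_lower || opt$at_upper) "a")
  new_evo_fit("EB", list(sigma2 = pf$sigma2, z0 = unname(pf$beta[1L]),
                         a = opt$par),
              opt$value, k = 3L, n = length(y), y = y, tips = names(y),
              boundary = bnd,
              notes = if (opt$at_upper)
                "a = 0: Early-Burst collapses to Brownian motion")
}

#' Fit the trend-diffusion model
#'
#' Brownian motion whose rate changes linearly with time from the root,
#' `r(t) = sigma0^2 + slope * t`, constrained non-negative over the tree
#' depth. Covariance `V[i,j] = sigma0^2 s_ij + slope s_ij^2 / 2` with `s_ij`
#' the shared root-path length. The rate-change `slope` is bounded to
#' `[-100, 100]`; a bound hit is flagged.
#'
#' @inheritParams fit_bm
#' @param slope_bound Symmetric bound on the slope (default 100).
#' @return An `evo_fit` with parameters `sigma0sq`, `z0`, `slope`; `k = 3`.
#' @export
fit_trend <- function(tree, y, slope_bound = 100) {
  y <- check_fit_data(tree, y)
  S <- phylo_vcv(tree)
  smax <- max(S)
  ## ratio parametrization r = slope / sigma0^2 with sigma0^2 profiled out,
  ## searched on a log-warped axis u with r = (exp(u) - 1) / smax so the
  ## Brownian point (r = 0, u = 0) and its neighbourhood stay well resolved
  ## even though r spans many orders of magnitude. The |slope| <= bound
  ## constraint is enforced inside the profile: when the freely profiled
  ## scale would push the slope past the bound, the scale is capped at
  ## bound/|r| and the likelihood evaluated at that fixed covariance.
  vrel <- function(r) S + (r / 2) * S * S
  eval_at <- function(u) {
    r <- expm1(u) / smax
    pf <- tryCatch(profile_mvn(vrel(r), y), error = function(e) NULL)
    if (is.null(pf) || pf$degenerate)
      return(list(loglik = -1e10, sigma0sq = NA_real_, slope = NA_real_,
                  z0 = NA_real_, clamped = FALSE))
    slope <- r * pf$sigma2
    if (abs(slope) > slope_bound) {
      s0 <- slope_bound / abs(r)
      V <- s0 * vrel(r)
      ll <- tryCatch(fixed_cov_loglik(V, y), error = function(e) -1e10)
      return(list(loglik = ll, sigma0sq = s0, slope = sign(r) * slope_bound,
                  z0 = gls_mean(V, y), clamped = TRUE))
    }
    list(loglik = pf$loglik, sigma0sq = pf$sigma2, slope = slope,
         z0 = unname(pf$beta[1L]), clamped = FALSE)
  }
  f <- function(u) eval_at(u)$loglik
  u_min <- log(1e-9)                   # r -> -(1 - 1e-9)/smax: rate hits 0
  u_max <- log1p(1e4 * smax)
  opt <- optimize_profile(f, u_min, u_max, n_starts = 8L)
  if (f(0) > opt$value) {              # never undercut the nested BM fit
    opt$par <- 0
    opt$value <- f(0)
    opt$at_lower <- opt$at_upper <- FALSE
  }
  at <- eval_at(opt$par)
  boundary <- character()
  if (at$clamped || opt$at_lower) boundary <- "slope"
  new_evo_fit("trend", list(sigma0sq = at$sigma0sq, z0 = at$z0,
                            slope = at$slope),
              at$loglik, k = 3L, n = length(y), y = y, tips = names(y),
              boundary = boundary)
}

## logLik with covariance fully specified (no scalar profiled), mean profiled
fixed_cov_loglik <- function(V, y) {
  mu <- gls_mean(V, y)
  mvn_loglik(y, rep(mu, length(y)), V)
}

gls_mean <- function(V, y) {
  R <- chol(V)
  yw <- backsolve(R, y, transpose = TRUE)
  ow <- backsolve(R, rep(1, length(y)), transpose = TRUE)
  sum(ow * yw) / sum(ow * ow)
}

#' Fit the drift model
#'
#' Brownian covariance with a directional mean trend:
#' `E[y_i] = z0 + drift * h_i` with `h_i` the root-to-tip distance. On
#' (near-)ultrametric trees all `h_i` coincide, drift is confounded with the
#' root state, and the fit falls back to Brownian motion with a warning.
#'
#' @inheritParams fit_bm
#' @param drift_bound Symmetric bound on the drift coefficient (default 100).
#' @return An `evo_fit` with parameters `sigma2`, `z0`, `drift`; `k = 3`.
#' @export
fit_drift <- function(tree, y, drift_bound = 100) {
  y <- check_fit_data(tree, y)
  C <- phylo_vcv(tree)
  h <- diag(C)
  n <- length(y)
  if (diff(range(h)) < 1e-8 * max(h)) {
    warning("all root-to-tip distances are equal: drift is unidentifiable ",
            "(confounded with the root state); returning the Brownian fit",
            call. = FALSE)
    bm <- fit_bm(tree, y)
    return(new_evo_fit("drift",
                       list(sigma2 = bm$params$sigma2, z0 = bm$params$z0,
                            drift = 0),
                       bm$loglik, k = 3L, n = n, y = y, tips = names(y),
                       boundary = "drift",
                       notes = "drift unidentifiable on an ultrametric tree"))
  }
  X <- cbind("(Intercept)" = 1, h = h)
  pf <- profile_mvn(C, y, X)
  drift <- unname(pf$beta[2L])
  boundary <- character()
  if (abs(drift) > drift_bound) {
    drift <- sign(drift) * drift_bound
    pf <- profile_mvn(C, y - drift * h)
    boundary <- "drift"
    z0 <- unname(pf$beta[1L])
  } else z0 <- unname(pf$beta[1L])
  new_evo_fit("drift", list(sigma2 = pf$sigma2, z0 = z0, drift = drift),
              pf$loglik, k = 3L, n = n, y = y, tips = names(y),
              boundary = boundary)
}

#' Fit a set of trait-evolution models
#'
#' Convenience wrapper running any subset of the seven models on one
#' tree/trait pair.
#'
#' @inheritParams fit_bm
#' @param models Character vector among `"bm"`, `"white"`, `"lambda"`,
#'   `"ou"`, `"eb"`, `"trend"`, `"drift"`.
#' @return Named list of `evo_fit` objects.
#' @export
fit_models <- function(tree, y,
                       models = c("bm", "white", "lambda", "ou", "eb",
                                  "trend", "drift")) {
  models <- match.arg(models, several.ok = TRUE)
  fitters <- list(bm = fit_bm, white = fit_white_noise, lambda = fit_lambda,
                  ou = fit_ou, eb = fit_eb, trend = fit_trend,
                  drift = fit_drift)
  lapply(stats::setNames(models, models), function(m) fitters[[m]](tree, y))
}

## nested-model map: child model -> parent it collapses to, with chi^2 df
NESTED_IN_BM <- c(lambda = 1L, OU = 1L, EB = 1L, trend = 1L, drift = 1L)

#' Compare fitted trait-evolution models
#'
#' Tabulates log-likelihood, parameter count, AIC (sorted ascending) and,
#' for models nested in Brownian motion (lambda, OU, EB, trend, drift),
#' the likelihood-ratio statistic `2 * dlogLik` against the BM fit with a
#' chi-squared p-value on the parameter-count difference.
#'
#' @param fits List of `evo_fit` objects on the same data.
#' @return A data frame, one row per model, AIC-best first and flagged.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "evo_fit")))
  y0 <- fits[[1L]]$y
  for (f in fits[-1L])
    if (!isTRUE(all.equal(y0, f$y)))
      stop("fits were computed on different data vectors; ",
           "likelihoods are not comparable", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    logLik = vapply(fits, `[[`, 0, "loglik"),
    k = vapply(fits, `[[`, 0L, "k"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    stringsAsFactors = FALSE)
  bm <- which(tab$model == "BM")
  tab$LRT_vs_BM <- tab$LRT_df <- tab$LRT_p <- NA_real_
  if (length(bm) == 1L) {
    for (i in seq_len(nrow(tab))) {
      df <- NESTED_IN_BM[tab$model[i]]
      if (is.na(df)) next
      stat <- max(0, 2 * (tab$logLik[i] - tab$logLik[bm]))
      tab$LRT_vs_BM[i] <- stat
      tab$LRT_df[i] <- df
      tab$LRT_p[i] <- stats::pchisq(stat, df, lower.tail = FALSE)
    }
  }
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$best <- tab$dAIC == 0
  tab[order(tab$AIC), , drop = FALSE]
}
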