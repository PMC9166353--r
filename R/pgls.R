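## Non-phylogenetic GLS (ordinary least squares with a Gaussian likelihood)
## and phylogenetic GLS with branch-length transforms estimated by joint ML.
## The residual covariance is built in the fixed composition order
## kappa (branch lengths) -> path-sum C -> delta (element-wise) -> lambda
## (off-diagonal); the overall residual variance is always profiled out.

TRANSFORM_BOUNDS <- list(kappa = c(0, 3), lambda = c(0, 1),
                         delta = c(1e-4, 3))
TRANSFORM_STARTS <- list(c(kappa = 1,    lambda = 1,    delta = 1),
                         c(kappa = 0.5,  lambda = 0.5,  delta = 1.5),
                         c(kappa = 0.24, lambda = 0.98, delta = 2.5))

new_reg_fit <- function(...) structure(list(...), class = "reg_fit")

#' @export
print.reg_fit <- function(x, ...) {
  cat(sprintf("%s regression: %s ~ %s  (n = %d)\n", x$method, x$response,
              paste(setdiff(names(x$coefficients), "(Intercept)"),
                    collapse = " + "), x$n))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t,
                    p = x$p_coef)
  print(signif(tab, 4))
  if (!is.null(x$transforms) && length(x$transforms)) {
    cat("Branch-length transforms:\n")
    for (nm in names(x$transforms)) {
      tr <- x$transforms[[nm]]
      cat(sprintf("  %-6s = %.4g%s", nm, tr$value,
                  if (tr$mode == "fixed") " (fixed)" else ""))
      if (!all(is.na(tr$ci)))
        cat(sprintf("  95%% CI (%.3g, %.3g)", tr$ci[1L], tr$ci[2L]))
      if (isTRUE(tr$boundary)) cat("  [at bound]")
      cat("\n")
    }
  }
  cat(sprintf("logLik = %.4f, AIC = %.4f, model p = %.4g\n",
              x$loglik, x$AIC, x$p_model))
  cat(sprintf("R2 (multiple, whitened) = %.4g; R2 (Nagelkerke) = %.4g\n",
              x$r2_multiple, x$r2_nagelkerke))
  invisible(x)
}

nagelkerke_r2 <- function(ll0, ll1, n) {
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

## shared finishing step: coefficient table, R2s, overall p, AIC
finish_reg <- function(method, response, y, X, V, pf, ll0, k, n_transform,
                       transforms = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (isTRUE(pf$degenerate)) {
    ## exact fit: slopes are recovered exactly, no residual variation
    return(new_reg_fit(
      method = method, response = response,
      coefficients = stats::setNames(as.numeric(pf$beta), colnames(X)),
      se = stats::setNames(rep(0, p), colnames(X)),
      t = stats::setNames(rep(Inf, p), colnames(X)),
      p_coef = stats::setNames(rep(0, p), colnames(X)),
      p_model = 0, loglik = Inf, k = p + 1L + n_transform, AIC = -Inf,
      n = n, rss = 0, sigma2 = 0, r2_multiple = 1, r2_nagelkerke = 1,
      transforms = transforms, y = unname(y), X = X, V = V))
  }
  XtX_inv <- chol2inv(qr.R(qr(pf$Xw)))
  s2 <- pf$rss / (n - p)
  se <- sqrt(diag(XtX_inv) * s2)
  tval <- pf$beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  ## whitened R2 against the intercept-only model under the same covariance
  pf0 <- profile_mvn(V, y)
  r2_mult <- 1 - pf$rss / pf0$rss
  p_model <- if (p > 1L)
    stats::pchisq(max(0, 2 * (pf$loglik - ll0)), df = p - 1L,
                  lower.tail = FALSE) else 1
  new_reg_fit(
    method = method, response = response,
    coefficients = stats::setNames(as.numeric(pf$beta), colnames(X)),
    se = stats::setNames(as.numeric(se), colnames(X)),
    t = stats::setNames(as.numeric(tval), colnames(X)),
    p_coef = stats::setNames(as.numeric(pval), colnames(X)),
    p_model = p_model, loglik = pf$loglik,
    k = p + 1L + n_transform, AIC = 2 * (p + 1L + n_transform) - 2 * pf$loglik,
    n = n, rss = pf$rss, sigma2 = pf$sigma2,
    r2_multiple = r2_mult,
    r2_nagelkerke = nagelkerke_r2(ll0, pf$loglik, n),
    transforms = transforms, y = unname(y), X = X, V = V)
}

#' Non-phylogenetic generalized least squares (ordinary least squares)
#'
#' Identity residual covariance; equivalent to OLS, reported with the
#' Gaussian ML log-likelihood so it is AIC-comparable with the phylogenetic
#' fits. The pseudo-R2 is Nagelkerke's, computed against the intercept-only
#' model.
#'
#' @param y Response vector.
#' @param X Design matrix including an intercept column.
#' @param response Response name used in printing.
#' @return A `reg_fit`.
#' @export
gls_fit <- function(y, X, response = "y") {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  n <- length(y)
  V <- diag(n)
  pf <- profile_mvn(V, y, X)
  ll0 <- profile_mvn(V, y)$loglik
  finish_reg("GLS", response, y, X, V, pf, ll0, k = ncol(X) + 1L,
             n_transform = 0L)
}

parse_transforms <- function(transforms) {
  allowed <- c("kappa", "lambda", "delta")
  if (is.null(transforms)) transforms <- list()
  transforms <- as.list(transforms)
  if (length(transforms) && (is.null(names(transforms)) ||
                             !all(names(transforms) %in% allowed)))
    stop("transforms must be named among kappa, lambda, delta", call. = FALSE)
  out <- stats::setNames(vector("list", 3L), allowed)
  for (nm in allowed) {
    v <- transforms[[nm]]
    if (is.null(v)) {
      out[[nm]] <- list(mode = "fixed", value = 1)
    } else if (identical(v, "ML") || identical(v, "ml")) {
      out[[nm]] <- list(mode = "ml", value = NA_real_)
    } else if (is.numeric(v) && length(v) == 1L) {
      b <- TRANSFORM_BOUNDS[[nm]]
      if (v < b[1L] || v > b[2L])
        stop(nm, " = ", v, " outside [", b[1L], ", ", b[2L], "]",
             call. = FALSE)
      out[[nm]] <- list(mode = "fixed", value = as.numeric(v))
    } else stop("transform '", nm, "' must be \"ML\" or a single number",
                call. = FALSE)
  }
  out
}

#' Phylogenetic generalized least squares
#'
#' GLS with residual covariance `V(kappa, lambda, delta)` built from the
#' tree in the fixed order kappa -> C -> delta -> lambda. Each transform is
#' either held at a value or estimated by joint maximum likelihood (bounded
#' multi-start optimization); ML transforms get 95% profile-likelihood
#' intervals (other ML transforms re-optimized at each profile point) and,
#' for lambda, LRT flags for "different from 0" and "different from 1".
#'
#' @param tree A rooted `phylo` object whose tips match `names(y)`.
#' @param y Named response vector.
#' @param X Design matrix (intercept included), rows in `names(y)` order.
#' @param transforms Named list/vector; each of `kappa`, `lambda`, `delta`
#'   may be `"ML"` or a fixed number. Omitted transforms are fixed at 1.
#' @param response Response name used in printing.
#' @param ci Compute profile-likelihood CIs for ML transforms (default TRUE;
#'   turn off to save time in simulation loops).
#' @return A `reg_fit` with coefficient tests on `n - p` degrees of freedom,
#'   transform estimates and intervals, log-likelihood, AIC and both
#'   pseudo-R2 variants.
#' @export
pgls_fit <- function(tree, y, X, transforms = list(kappa = "ML",
                                                   lambda = "ML",
                                                   delta = "ML"),
                     response = "y", ci = TRUE) {
  validate_tree(tree)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  if (is.null(names(y))) stop("`y` must be named by tip label", call. = FALSE)
  if (!identical(sort(names(y)), sort(tree$tip.label)))
    stop("tips of `y` and `tree` differ; align them first", call. = FALSE)
  y <- y[tree$tip.label]
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  tr <- parse_transforms(transforms)
  ml <- names(tr)[vapply(tr, function(t) t$mode == "ml", TRUE)]

  build_V <- function(th) {
    tt <- if (th[["kappa"]] != 1) transform_kappa(tree, th[["kappa"]])
          else tree
    C <- phylo_vcv(tt)
    if (th[["delta"]] != 1) C <- transform_delta(C, th[["delta"]])
    transform_lambda(C, th[["lambda"]])
  }
  theta_full <- function(par) {
    th <- vapply(tr, function(t) if (t$mode == "fixed") t$value else NA_real_,
                 0)
    th[ml] <- par
    th
  }
  obj <- function(par) {
    V <- tryCatch(build_V(theta_full(par)), error = function(e) NULL)
    if (is.null(V)) return(-1e10)
    tryCatch(profile_mvn(V, y, X)$loglik, error = function(e) -1e10)
  }

  boundary <- stats::setNames(rep(FALSE, length(ml)), ml)
  if (length(ml)) {
    lb <- vapply(TRANSFORM_BOUNDS[ml], `[`, 0, 1L)
    ub <- vapply(TRANSFORM_BOUNDS[ml], `[`, 0, 2L)
    best <- NULL
    for (st in TRANSFORM_STARTS) {
      p0 <- pmin(pmax(st[ml], lb), ub)
      o <- tryCatch(
        stats::optim(p0, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                     control = list(fnscale = -1, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value > best$value)) best <- o
    }
    if (is.null(best)) stop("transform optimization failed", call. = FALSE)
    par_hat <- pmin(pmax(best$par, lb), ub)
    btol <- 1e-4 * (ub - lb)
    at_lo <- par_hat - lb < btol
    at_hi <- ub - par_hat < btol
    par_hat[at_lo] <- lb[at_lo]
    par_hat[at_hi] <- ub[at_hi]
    boundary <- at_lo | at_hi
  } else par_hat <- numeric(0)

  th_hat <- theta_full(par_hat)
  V_hat <- build_V(th_hat)
  if (length(ml) == 0L) {
    ok <- tryCatch({chol(V_hat); TRUE}, error = function(e) FALSE)
    if (!ok) {
      bad <- names(tr)[vapply(tr, function(t)
        t$mode == "fixed" && t$value != 1, TRUE)]
      stop("covariance not positive definite at the requested fixed ",
           "transform(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  pf <- profile_mvn(V_hat, y, X)

  ## profile logLik of one ML transform, others re-optimized from the MLE
  prof_one <- function(nm) {
    others <- setdiff(ml, nm)
    function(v) {
      if (!length(others)) {
        par <- stats::setNames(v, nm)
        return(obj(par[ml]))
      }
      lb2 <- vapply(TRANSFORM_BOUNDS[others], `[`, 0, 1L)
      ub2 <- vapply(TRANSFORM_BOUNDS[others], `[`, 0, 2L)
      inner <- function(q) {
        par <- stats::setNames(numeric(length(ml)), ml)
        par[others] <- q
        par[nm] <- v
        obj(par[ml])
      }
      o <- tryCatch(
        stats::optim(pmin(pmax(par_hat[others], lb2), ub2), inner,
                     method = "L-BFGS-B", lower = lb2, upper = ub2,
                     control = list(fnscale = -1, factr = 1e6)),
        error = function(e) NULL)
      if (is.null(o)) -1e10 else o$value
    }
  }

  transforms_out <- list()
  for (nm in names(tr)) {
    if (tr[[nm]]$mode == "fixed") {
      if (nm %in% names(as.list(transforms)))  # only echo explicit fixes
        transforms_out[[nm]] <- list(value = tr[[nm]]$value, mode = "fixed",
                                     ci = c(NA_real_, NA_real_),
                                     boundary = FALSE)
      next
    }
    b <- TRANSFORM_BOUNDS[[nm]]
    entry <- list(value = unname(th_hat[[nm]]), mode = "ml",
                  ci = c(NA_real_, NA_real_),
                  boundary = unname(boundary[[nm]]))
    if (ci) {
      f <- prof_one(nm)
      entry$ci <- profile_ci(f, th_hat[[nm]], pf$loglik, b[1L], b[2L])
      if (nm == "lambda") {
        entry$p_vs_0 <- stats::pchisq(max(0, 2 * (pf$loglik - f(b[1L]))), 1,
                                      lower.tail = FALSE)
        entry$p_vs_1 <- stats::pchisq(max(0, 2 * (pf$loglik - f(1))), 1,
                                      lower.tail = FALSE)
        entry$diff_from_0 <- entry$p_vs_0 < 0.05
        entry$diff_from_1 <- entry$p_vs_1 < 0.05
      }
    }
    transforms_out[[nm]] <- entry
  }

  ## null model: intercept-only under the same transform treatment
  null_fit <- if (length(ml)) {
    obj0 <- function(par) {
      V <- tryCatch(build_V(theta_full(par)), error = function(e) NULL)
      if (is.null(V)) return(-1e10)
      tryCatch(profile_mvn(V, y)$loglik, error = function(e) -1e10)
    }
    lb <- vapply(TRANSFORM_BOUNDS[ml], `[`, 0, 1L)
    ub <- vapply(TRANSFORM_BOUNDS[ml], `[`, 0, 2L)
    o0 <- stats::optim(pmin(pmax(par_hat, lb), ub), obj0,
                       method = "L-BFGS-B", lower = lb, upper = ub,
                       control = list(fnscale = -1, factr = 1e4))
    o0$value
  } else profile_mvn(V_hat, y)$loglik
  out <- finish_reg("PGLS", response, y, X, V_hat, pf, ll0 = null_fit,
                    k = ncol(X) + 1L + length(ml), n_transform = length(ml),
                    transforms = transforms_out)
  out$tree <- tree
  out
}

#' PGLS with Brownian-motion residuals
#'
#' [pgls_fit()] with all three transforms fixed at 1 (pure Brownian residual
#' covariance) — appropriate when the residual lambda is not distinguishable
#' from 1.
#'
#' @inheritParams pgls_fit
#' @return A `reg_fit`.
#' @export
pgls_fit_bm <- function(tree, y, X, response = "y") {
  pgls_fit(tree, y, X,
           transforms = list(kappa = 1, lambda = 1, delta = 1),
           response = response)
}

#' Compare nested regression models
#'
#' F test on whitened residual sums of squares, with the smaller model
#' re-whitened under the larger model's fitted covariance so the two sums
#' are commensurable; a likelihood-ratio test on the fits' own
#' log-likelihoods is reported as a cross-check.
#'
#' @param fit_small,fit_big `reg_fit` objects on the same response with
#'   nested predictor sets.
#' @return List with `F`, `df1`, `df2`, `p_value`, plus `lrt` and `p_lrt`.
#' @export
anova_nested <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "reg_fit"), inherits(fit_big, "reg_fit"))
  if (!isTRUE(all.equal(fit_small$y, fit_big$y)))
    stop("models were fitted to different responses", call. = FALSE)
  small_terms <- colnames(fit_small$X)
  big_terms <- colnames(fit_big$X)
  if (!all(small_terms %in% big_terms))
    stop("predictor sets are not nested", call. = FALSE)
  n <- fit_big$n
  p_small <- ncol(fit_small$X)
  p_big <- ncol(fit_big$X)
  df1 <- p_big - p_small
  df2 <- n - p_big
  ## re-fit the small design under the big model's covariance
  rss_small <- profile_mvn(fit_big$V, fit_big$y, fit_small$X)$rss
  rss_big <- fit_big$rss
  Fstat <- if (df1 == 0L) 0 else ((rss_small - rss_big) / df1) / (rss_big / df2)
  p <- if (df1 == 0L) 1 else stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  lrt <- max(0, 2 * (fit_big$loglik - fit_small$loglik))
  df_lrt <- fit_big$k - fit_small$k
  p_lrt <- if (df_lrt <= 0L) 1
           else stats::pchisq(lrt, df_lrt, lower.tail = FALSE)
  list(F = Fstat, df1 = df1, df2 = df2, p_value = p,
       lrt = lrt, df_lrt = df_lrt, p_lrt = p_lrt)
}
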