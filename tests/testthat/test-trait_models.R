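# Model fitting: closed-form cases, first-principles likelihood oracle on a
# small tree, nesting inequalities, model comparison arithmetic, and scaled
# simulation-recovery checks.

test_that("BM fit matches the two-tip analytic solution", {
  tr <- parse_newick("(A:2,B:2);")
  y <- c(A = 1.3, B = 4.1)
  fit <- fit_bm(tr, y)
  expect_equal(fit$params$z0, mean(y))
  expect_equal(fit$params$sigma2, (y[["A"]] - y[["B"]])^2 / (4 * 2))
  expect_equal(fit$k, 2L)
  expect_equal(fit$AIC, 2 * 2 - 2 * fit$loglik)
})

test_that("constant traits raise a degenerate-data error", {
  tr <- small_tree()
  y <- setNames(rep(3, 5), tr$tip.label)
  expect_error(fit_bm(tr, y), "constant")
})

test_that("white-noise fit is the iid closed form and is exchangeable", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  y <- c(A = 0, B = 0, C = 0, D = 1)
  fit <- fit_white_noise(tr, y)
  expect_equal(fit$params$z0, 0.25)
  expect_equal(fit$params$sigma2, 0.1875)  # population variance
  yp <- setNames(y[c(4, 1, 2, 3)], names(y))
  fitp <- fit_white_noise(tr, yp)
  expect_equal(fitp$loglik, fit$loglik)
  expect_equal(fitp$params, fit$params)
})

test_that("every model's logLik matches a first-principles MVN oracle on a
           small tree", {
  tr <- small_tree()
  set.seed(42)
  y <- setNames(rnorm(5, 3, 1.5), tr$tip.label)
  fits <- list(fit_bm(tr, y), fit_white_noise(tr, y), fit_lambda(tr, y),
               fit_ou(tr, y), fit_eb(tr, y), fit_trend(tr, y),
               fit_drift(tr, y))
  for (fit in fits) {
    mo <- fit_moments_oracle(fit$model, fit$params, tr)
    expect_equal(fit$loglik, mvn_loglik_oracle(y, mo$mu, mo$V),
                 tolerance = 1e-6, info = fit$model)
  }
})

test_that("nesting inequalities hold across datasets", {
  for (seed in c(2, 17, 31)) {
    tr <- simulate_yule(60, 1, seed = seed, jitter_sd = 0.25)
    y <- simulate_trait(tr, "lambda",
                        list(sigma2 = 1, z0 = 0, lambda = 0.6),
                        seed = seed + 100)
    bm <- fit_bm(tr, y)
    expect_gte(fit_lambda(tr, y)$loglik, bm$loglik - 1e-8)
    expect_gte(fit_ou(tr, y)$loglik, bm$loglik - 1e-4)
    expect_gte(fit_eb(tr, y)$loglik, bm$loglik - 1e-6)
    expect_gte(fit_trend(tr, y)$loglik, bm$loglik - 1e-6)
    expect_gte(suppressWarnings(fit_drift(tr, y))$loglik, bm$loglik - 1e-6)
  }
})

test_that("lambda profile at 1 equals the BM fit exactly", {
  tr <- simulate_yule(40, 1, seed = 3)
  y <- simulate_trait(tr, "bm", list(sigma2 = 2, z0 = 1), seed = 4)
  fl <- fit_lambda(tr, y)
  expect_equal(fl$profile(1), fit_bm(tr, y)$loglik, tolerance = 1e-10)
})

test_that("EB at a = 0 and drift on ultrametric trees collapse to BM", {
  tr <- simulate_yule(50, 1, seed = 8)   # ultrametric
  y <- simulate_trait(tr, "bm", list(sigma2 = 1, z0 = 0), seed = 9)
  bm <- fit_bm(tr, y)
  eb <- fit_eb(tr, y)
  expect_equal(eb$loglik, bm$loglik, tolerance = 1e-5)
  expect_warning(dr <- fit_drift(tr, y), "unidentifiable")
  expect_equal(dr$loglik, bm$loglik)
  expect_equal(dr$k, 3L)
  expect_true("drift" %in% dr$boundary)
})

test_that("drift slope is recovered on a non-clock tree", {
  tr <- simulate_yule(120, 1, seed = 21, jitter_sd = 0.4)
  y <- simulate_trait(tr, "drift",
                      list(sigma2 = 1, z0 = 0, drift = 3), seed = 22)
  fd <- fit_drift(tr, y)
  expect_gt(fd$params$drift, 1)
  expect_lt(fd$params$drift, 5)
})

test_that("compare_models orders by AIC, does LRT arithmetic and rejects
           mixed data", {
  tr <- simulate_yule(80, 1, seed = 12)
  y <- simulate_trait(tr, "lambda", list(sigma2 = 1, z0 = 0, lambda = 0.5),
                      seed = 13)
  bm <- fit_bm(tr, y)
  lam <- fit_lambda(tr, y)
  tab <- compare_models(list(bm, lam))
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  expect_false(is.unsorted(tab$AIC))
  i <- which(tab$model == "lambda")
  expect_equal(tab$LRT_vs_BM[i], 2 * (lam$loglik - bm$loglik))
  expect_equal(tab$LRT_p[i],
               pchisq(2 * (lam$loglik - bm$loglik), 1, lower.tail = FALSE))
  expect_true(tab$best[which.min(tab$AIC)])

  # two fits with provably identical likelihood (drift on an ultrametric
  # tree collapses to BM): LRT statistic 0, p = 1
  y3 <- simulate_trait(tr, "bm", list(sigma2 = 1, z0 = 0), seed = 14)
  bm3 <- fit_bm(tr, y3)
  dr3 <- suppressWarnings(fit_drift(tr, y3))
  tab2 <- compare_models(list(bm3, dr3))
  expect_equal(tab2$LRT_vs_BM[tab2$model == "drift"], 0)
  expect_equal(tab2$LRT_p[tab2$model == "drift"], 1)

  y2 <- y + 1
  expect_error(compare_models(list(bm, fit_bm(tr, y2))), "different data")
})

test_that("trend fit honours the slope bound and flags it", {
  # rate must rise steeply: strong late-burst data push the slope up
  tr <- simulate_yule(60, 1, seed = 33)
  C <- phylo_vcv(tr)
  set.seed(34)
  V <- 0.001 * C + 50 * C * C   # slope/sigma0^2 ratio far past the bound
  y <- setNames(drop(crossprod(chol(V), rnorm(60))), tr$tip.label)
  ft <- fit_trend(tr, y, slope_bound = 10)
  expect_lte(abs(ft$params$slope), 10)
  expect_true("slope" %in% ft$boundary)
})

# scaled down from the 500-tip / 100-replicate design to fit the test
# budget: 150 tips, 40 replicates
test_that("lambda is recovered within its profile CI under simulation", {
  n_rep <- 40
  covered <- 0
  for (i in seq_len(n_rep)) {
    tr <- simulate_yule(150, 1, seed = 1000 + i)
    y <- simulate_trait(tr, "lambda",
                        list(sigma2 = 1, z0 = 0, lambda = 0.5),
                        seed = 2000 + i)
    ls <- lambda_signal(tr, y)
    if (ls$ci[1] <= 0.5 && 0.5 <= ls$ci[2]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.85)
})

test_that("OU attraction strength is recovered in simulation", {
  # scaled: 200 tips, 20 replicates; alpha = 2 should land near [1, 4]
  alphas <- vapply(seq_len(20), function(i) {
    tr <- simulate_yule(200, 1, seed = 3000 + i)
    y <- simulate_trait(tr, "ou", list(sigma2 = 1, z0 = 0, alpha = 2),
                        seed = 4000 + i)
    fit_ou(tr, y)$params$alpha
  }, 0)
  expect_gte(mean(alphas >= 1 & alphas <= 4), 0.7)
  expect_gt(median(alphas), 1)
  expect_lt(median(alphas), 4)
})

test_that("EB decay is detected in simulation", {
  # scaled: 150 tips, 20 replicates, true a = -2
  a_hat <- vapply(seq_len(20), function(i) {
    tr <- simulate_yule(150, 1, seed = 5000 + i)
    y <- simulate_trait(tr, "eb", list(sigma2 = 1, z0 = 0, a = -2),
                        seed = 6000 + i)
    fit_eb(tr, y)$params$a
  }, 0)
  expect_gte(mean(a_hat < 0), 0.8)
})

test_that("trend slope sign is recovered in simulation", {
  # scaled: 120 tips, 20 replicates, true slope = 1 with sigma0^2 = 0.5
  slopes <- vapply(seq_len(20), function(i) {
    tr <- simulate_yule(120, 1, seed = 7000 + i)
    y <- simulate_trait(tr, "trend",
                        list(sigma2 = 0.5, z0 = 0, slope = 1),
                        seed = 8000 + i)
    fit_trend(tr, y)$params$slope
  }, 0)
  expect_gte(mean(slopes > 0), 0.8)
})

test_that("BM simulations give calibrated sigma2 and AIC selection", {
  # scaled: 100-tip trees, 40 replicates (stated world: 200 tips / 200 reps
  # in the synthetic acceptance block)
  wins <- 0
  s2 <- numeric(40)
  for (i in seq_len(40)) {
    tr <- simulate_yule(100, 1, seed = 9000 + i)
    y <- simulate_trait(tr, "bm", list(sigma2 = 1, z0 = 0), seed = 9500 + i)
    bm <- fit_bm(tr, y)
    lam <- fit_lambda(tr, y)
    s2[i] <- bm$params$sigma2
    if (bm$AIC <= lam$AIC || lam$params$lambda > 0.9) wins <- wins + 1
  }
  expect_lt(abs(mean(s2) - 1), 0.1)
  expect_gte(wins / 40, 0.8)
})
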