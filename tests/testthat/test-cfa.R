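test_that("compound symmetry forces equal loadings and uniques", {
  v <- 1.2; cc <- 0.6
  S <- matrix(cc, 4, 4); diag(S) <- v
  colnames(S) <- rownames(S) <- paste0("y", 1:4)
  fit <- fit1f(S)
  expect_true(fit$converged)
  expect_equal(unname(drop(fit$lambda)), rep(sqrt(cc), 4), tolerance = 1e-6)
  expect_equal(unname(fit$theta), rep(v - cc, 4), tolerance = 1e-6)
})

test_that("just-identified 3-indicator fit matches the closed form exactly", {
  for (S in list(verbal_cov(), speed_cov())) {
    fit <- fit1f(S)
    cf <- spearman_three_indicator(S)
    expect_lt(fit$discrepancy, 1e-10)
    expect_equal(drop(fit$lambda), cf$loadings, tolerance = 1e-8)
    expect_equal(fit$theta, cf$uniques, tolerance = 1e-8)
    # implied covariance reproduces S (off-diagonals exactly by identity)
    expect_equal(model_implied_cov(fit), S, tolerance = 1e-7)
  }
})

test_that("closed-form loadings: equal-covariance case and printed speed values", {
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  expect_equal(unname(spearman_three_indicator(S)$loadings),
               rep(sqrt(0.5), 3))
  sp <- spearman_three_indicator(speed_cov())
  expect_equal(unname(sp$loadings), c(0.661, 0.801, 0.565), tolerance = 0.01)
  # algebraic identity on a random matrix with positive covariances
  R <- rand_pd_positive(3, seed = 5)
  cf <- spearman_three_indicator(R)
  implied <- tcrossprod(cf$loadings) + diag(cf$uniques)
  expect_equal(implied[upper.tri(implied)], R[upper.tri(R)])
  S[1, 2] <- S[2, 1] <- -0.2
  expect_error(spearman_three_indicator(S), "positive")
})

test_that("two-factor fit to the published six-test moments recovers the reported solution", {
  m <- hs_scaled_moments()
  spec <- cfa_spec(list(verbal = c("x06", "x07", "x09"),
                        speed = c("x10", "x12", "x13")))
  fit <- suppressWarnings(fit_cfa(m, spec))
  lam <- fit$lambda[cbind(rownames(fit$lambda),
                          rep(c("verbal", "speed"), each = 3))]
  expect_equal(unname(lam), c(0.98, 1.11, 0.91, 0.67, 0.78, 0.59),
               tolerance = 0.03)
  expect_equal(fit$phi["verbal", "speed"], 0.26, tolerance = 0.02)
  expect_equal(unname(fit$theta), c(0.38, 0.42, 0.37, 0.73, 0.42, 0.67),
               tolerance = 0.03)
})

test_that("constraint taxonomy yields the right degrees of freedom", {
  m <- sample_moments(hs_scaled_moments()$cov, n = 301)
  dfs <- vapply(c("congeneric", "tau_equivalent", "parallel"), function(cs)
    fit1f(m$cov, constraint = cs)$df, integer(1))
  expect_identical(unname(dfs), c(9L, 14L, 19L))
  spec2 <- function(cs) cfa_spec(list(verbal = c("x06", "x07", "x09"),
                                      speed = c("x10", "x12", "x13")),
                                 constraint = cs)
  dfs2 <- vapply(c("congeneric", "tau_equivalent", "parallel"), function(cs)
    suppressWarnings(fit_cfa(m, spec2(cs)))$df, integer(1))
  expect_identical(unname(dfs2), c(8L, 12L, 16L))
})

test_that("discrepancy is monotone over nested constraint sets", {
  for (s in 1:20) {
    S <- rand_pd_positive(5, seed = 1000 + s)
    f <- vapply(c("parallel", "tau_equivalent", "congeneric"), function(cs)
      fit1f(S, constraint = cs)$discrepancy, numeric(1))
    expect_true(f[1] >= f[2] - 1e-8 && f[2] >= f[3] - 1e-8,
                label = sprintf("nesting at seed %d (F = %s)", s,
                                paste(signif(f, 4), collapse = " >= ")))
  }
})

test_that("congeneric estimates are scale-equivariant", {
  S <- rand_pd_positive(4, seed = 9)
  fit <- fit1f(S)
  cc <- 2.5
  S2 <- S; S2[2, ] <- cc * S2[2, ]; S2[, 2] <- cc * S2[, 2]
  fit2 <- fit1f(S2)
  expect_equal(fit2$lambda[2, 1], cc * fit$lambda[2, 1], tolerance = 1e-5)
  expect_equal(unname(fit2$theta[2]), cc^2 * unname(fit$theta[2]),
               tolerance = 1e-4)
  expect_equal(fit2$lambda[-2, 1], fit$lambda[-2, 1], tolerance = 1e-5)
})

test_that("saturated and constrained models report correct fit indices", {
  m <- sample_moments(verbal_cov(), n = 301)
  fit <- fit1f(m$cov)
  fit$moments <- m
  idx <- fit_indices(fit, m)
  expect_identical(idx$df, 0L)
  expect_equal(idx$chisq, 0)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$cfi, 1)
  # constrained model on clearly non-parallel data misfits
  mp <- fit1f(m$cov, constraint = "parallel")
  idx_p <- fit_indices(mp, m)
  expect_gt(idx_p$chisq, 0)
  expect_identical(idx_p$df, 4L)  # 6 moments - 2 free parameters
  expect_equal(idx_p$chisq, 300 * mp$discrepancy)
  expect_true(idx_p$rmsea_ci90[1] <= idx_p$rmsea + 1e-12)
  expect_true(idx_p$rmsea_ci90[2] >= idx_p$rmsea - 1e-12)
  expect_true(idx_p$srmr >= 0)
})

test_that("chi-square statistic is calibrated under a true one-factor model", {
  lam <- c(0.8, 0.7, 0.6, 0.5); th <- 1 - lam^2
  chis <- vapply(1:200, function(r) {
    cfg <- sim_config(500, lam, th, seed = 40000 + r)
    x <- simulate_items(cfg)$items
    ft <- fit1f(cov(x))
    ft$moments <- sample_moments(cov(x), n = 500)
    fit_indices(ft)$chisq
  }, numeric(1))
  df <- 2  # p = 4 congeneric: 10 moments - 8 free parameters
  se_mean <- sqrt(2 * df / 200)
  expect_lt(abs(mean(chis) - df), 3 * se_mean)
})

test_that("regression factor scores have mean zero and known limiting behavior", {
  set.seed(77)
  x <- matrix(rnorm(300), 100, 3)
  colnames(x) <- c("a", "b", "c")
  # hand-built near-error-free single-indicator model: scores = centered item
  fit <- structure(list(
    lambda = matrix(1, 1, 1, dimnames = list("a", "f")),
    theta = c(a = 1e-10), phi = matrix(1, 1, 1),
    moments = sample_moments(matrix(1, 1, 1, dimnames = list("a", "a")))),
    class = "fitted_cfa")
  sc <- factor_scores_regression(fit, items = x[, "a", drop = FALSE])
  expect_equal(drop(sc$scores), x[, "a"] - mean(x[, "a"]))
  # fitted three-indicator model: per-factor score means are exactly zero
  fit3 <- fit1f(cov(x))
  fit3$moments <- sample_moments(cov(x))
  sc3 <- factor_scores_regression(fit3, items = x)
  expect_equal(unname(colMeans(sc3$scores)), 0, tolerance = 1e-12)
  # scoring a holdout with calibration weights and centering is reusable
  hold <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, colnames(x)))
  sc_h <- factor_scores_regression(fit3, items = hold, center = colMeans(x))
  manual <- sweep(hold, 2, colMeans(x)) %*% t(sc3$weights)
  expect_equal(unname(sc_h$scores), unname(manual))
})

test_that("squared correlation of estimated with true factor scores matches lambda' C^-1 lambda", {
  lam <- c(0.9, 0.7, 0.5, 0.6); th <- 1 - lam^2
  cfg <- sim_config(20000, lam, th, seed = 314)
  sim <- simulate_items(cfg)
  S <- cov(sim$items)
  fit <- fit1f(S)
  fit$moments <- sample_moments(S)
  sc <- factor_scores_regression(fit, items = sim$items)$scores[, 1]
  rho2_emp <- cor(sc, sim$factor_scores[, 1])^2
  rho2_th <- nicewander_quantities(drop(fit$lambda), S)$fs_reliability
  expect_equal(rho2_emp, rho2_th, tolerance = 0.01)
})

test_that("implied covariance matrix behaves at the edges", {
  fit0 <- list(lambda = matrix(0, 3, 1), theta = c(1, 2, 3),
               phi = matrix(1, 1, 1))
  expect_equal(model_implied_cov(fit0), diag(c(1, 2, 3)))
  set.seed(12)
  for (r in 1:5) {
    L <- matrix(rnorm(6), 3, 2)
    fitr <- list(lambda = L, theta = runif(3, 0.1, 1),
                 phi = diag(2))
    ev <- eigen(model_implied_cov(fitr), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("invalid moments and underidentified models are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # not PD
  expect_error(sample_moments(bad), "positive definite")
  S <- rand_pd_positive(2, seed = 3)
  expect_error(fit_cfa(sample_moments(S), cfa_spec(list(g = colnames(S)))),
               "at least 3 indicators")
  expect_error(cfa_spec(list(a = "x", a2 = "x")), "exactly one factor")
})
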