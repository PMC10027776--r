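# Shared simulated dataset: one latent factor (marker metric), true latent
# slope 0.5 on a standard-normal predictor.
latent_slope_sim <- function(n = 5000, seed = 42) {
  cfg <- sim_config(n = n, lambda = c(1, 0.9, 0.8),
                    theta = c(0.5, 0.5, 0.5),
                    criterion_validities = c(z = 0.5), seed = seed)
  sim <- simulate_items(cfg)
  list(items = sim$items, z = sim$criteria[, "z"],
       blocks = list(f = colnames(sim$items)))
}

test_that("sum-score regression recovers a constructed group difference exactly", {
  # two balanced groups, composite means 8 and 10, total-sample SD exactly 2
  k <- sqrt(2)
  dev <- c(-1.5, -0.5, 0.5, 1.5) * k
  y <- c(8 + dev, 10 + dev)
  z <- rep(c(0, 1), each = 4)
  items <- cbind(i1 = y / 2, i2 = y / 2)  # unit-weight sum rebuilds y
  res <- method_sum_regression(items, list(total = c("i1", "i2")), z)
  expect_equal(res$estimates$B, 2)
  expect_equal(sd(y), 2)
  expect_equal(res$estimates$d, 1)
  expect_equal(res$estimates$beta, 1 * sd(z))
  expect_true(res$estimates$ci_lo < 2 && res$estimates$ci_hi > 2)
})

test_that("sum-score regression is null-calibrated when groups do not differ", {
  set.seed(88)
  items <- matrix(rnorm(400 * 3), 400, 3,
                  dimnames = list(NULL, paste0("i", 1:3)))
  z <- rep(c(0, 1), each = 200)
  res <- method_sum_regression(items, list(s = paste0("i", 1:3)), z)
  expect_lt(abs(res$estimates$B), 3 * res$estimates$se)
  expect_error(method_sum_regression(items, list(s = paste0("i", 1:3)),
                                     rep(1, 400)), "constant")
})

test_that("Croon correction removes the attenuation of naive factor-score regression", {
  sim <- latent_slope_sim()
  croon <- croon_factor_score_regression(sim$items, sim$blocks, sim$z,
                                         n_boot = 0)
  naive <- naive_factor_score_regression(sim$items, sim$blocks, sim$z)
  expect_equal(croon$estimates$B, 0.5, tolerance = 0.05)
  # naive slope is attenuated by exactly the factor-score reliability
  S <- cov(sim$items)
  fit <- fit1f(S)
  rho2 <- nicewander_quantities(drop(fit$lambda), S)$fs_reliability
  expect_lt(naive$estimates$B, croon$estimates$B)
  expect_equal(naive$estimates$B / croon$estimates$B, rho2, tolerance = 1e-6)
})

test_that("corrected and naive estimates coincide as measurement error vanishes", {
  cfg <- sim_config(n = 2000, lambda = c(1, 0.9, 0.8),
                    theta = rep(1e-4, 3),
                    criterion_validities = c(z = 0.5), seed = 12)
  sim <- simulate_items(cfg)
  z <- sim$criteria[, "z"]
  blocks <- list(f = colnames(sim$items))
  croon <- croon_factor_score_regression(sim$items, blocks, z, n_boot = 0)
  naive <- naive_factor_score_regression(sim$items, blocks, z)
  expect_equal(croon$estimates$B, naive$estimates$B, tolerance = 1e-3)
  # and the simultaneous latent model matches the sum-score beta
  m4 <- simultaneous_latent_regression(sim$items, blocks, z)
  m2 <- method_sum_regression(sim$items, blocks, z)
  expect_equal(m4$estimates$beta, m2$estimates$beta, tolerance = 1e-3)
})

test_that("Croon slope is null when the predictor is independent of the items", {
  set.seed(9)
  cfg <- sim_config(n = 2000, lambda = c(1, 0.9, 0.8),
                    theta = c(0.5, 0.5, 0.5), seed = 55)
  sim <- simulate_items(cfg)
  z <- rnorm(2000)
  res <- croon_factor_score_regression(sim$items, list(f = colnames(sim$items)),
                                       z, n_boot = 100, seed = 2)
  expect_lt(abs(res$estimates$B), 3 * res$estimates$se)
})

test_that("simultaneous latent regression recovers the slope and agrees with Croon", {
  sim <- latent_slope_sim()
  m4 <- simultaneous_latent_regression(sim$items, sim$blocks, sim$z)
  croon <- croon_factor_score_regression(sim$items, sim$blocks, sim$z,
                                         n_boot = 0)
  expect_equal(m4$estimates$B, 0.5, tolerance = 0.05)
  expect_equal(m4$estimates$B, croon$estimates$B, tolerance = 0.02)
  expect_true(m4$extra$converged)
  # d and beta obey their definitions
  expect_equal(m4$estimates$beta,
               m4$estimates$d * sqrt(m4$extra$var_z))
})

test_that("latent regression CI covers zero at the nominal rate under the null", {
  covered <- vapply(1:100, function(r) {
    cfg <- sim_config(n = 500, lambda = c(1, 0.9, 0.8),
                      theta = c(0.5, 0.5, 0.5), seed = 7000 + r)
    sim <- simulate_items(cfg)
    set.seed(8000 + r)
    z <- rnorm(500)
    m4 <- simultaneous_latent_regression(sim$items,
                                         list(f = colnames(sim$items)), z)
    m4$estimates$ci_lo <= 0 && m4$estimates$ci_hi >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("latent-level effects are at least as large as composite-level effects", {
  d2 <- numeric(100); d4 <- numeric(100)
  for (r in 1:100) {
    cfg <- sim_config(n = 300, lambda = c(1, 0.9, 0.8),
                      theta = c(0.5, 0.5, 0.5),
                      criterion_validities = c(z = 0.3), seed = 200 + r)
    sim <- simulate_items(cfg)
    z <- sim$criteria[, "z"]
    blocks <- list(f = colnames(sim$items))
    d2[r] <- method_sum_regression(sim$items, blocks, z)$estimates$d
    d4[r] <- simultaneous_latent_regression(sim$items, blocks, z)$estimates$d
  }
  expect_gte(mean(abs(d4)), mean(abs(d2)))
})

test_that("bootstrap and observed-information standard errors agree", {
  sim <- latent_slope_sim(n = 1000, seed = 73)
  croon <- croon_factor_score_regression(sim$items, sim$blocks, sim$z,
                                         n_boot = 200, seed = 3)
  m4 <- simultaneous_latent_regression(sim$items, sim$blocks, sim$z)
  expect_lt(abs(croon$estimates$se - m4$estimates$se) / m4$estimates$se, 0.25)
  expect_true(croon$estimates$ci_lo < croon$estimates$B)
  expect_true(croon$estimates$ci_hi > croon$estimates$B)
  expect_identical(croon$extra$n_boot_failed, 0L)
})

test_that("two-block structural analyses keep outcomes in their own metrics", {
  lam <- cbind(c(1, 0.8, 0.9, 0, 0, 0), c(0, 0, 0, 1, 0.7, 1.1))
  phi <- matrix(c(1, 0.3, 0.3, 1), 2)
  cfg <- sim_config(n = 3000, lambda = lam, theta = rep(0.5, 6),
                    phi = phi, criterion_validities = c(z = 0.4),
                    criterion_factors = 1L, seed = 21)
  sim <- simulate_items(cfg)
  z <- sim$criteria[, "z"]
  blocks <- list(f1 = paste0("item", 1:3), f2 = paste0("item", 4:6))
  croon <- croon_factor_score_regression(sim$items, blocks, z, n_boot = 0)
  m4 <- simultaneous_latent_regression(sim$items, blocks, z)
  # factor 1 drives the criterion; factor 2 only via phi = 0.3
  expect_equal(croon$estimates$B[1], 0.4, tolerance = 0.06)
  expect_equal(croon$estimates$B[2], 0.3 * 0.4, tolerance = 0.06)
  expect_equal(m4$estimates$B, croon$estimates$B, tolerance = 0.03)
})
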