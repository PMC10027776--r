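# Predictor -> outcome analyses for scored scales: sum-score regression,
# Croon-corrected factor score regression, and simultaneous latent regression.
#
# All three latent-metric methods use marker-variable identification (first
# loading per block fixed at 1), so raw slopes share the metric of each
# block's first indicator and are directly comparable across methods.

structural_result <- function(method, outcomes, B, se, ci_lo, ci_hi, d, beta,
                              extra = list()) {
  res <- data.frame(outcome = outcomes, B = B, se = se,
                    ci_lo = ci_lo, ci_hi = ci_hi, d = d, beta = beta,
                    row.names = NULL)
  structure(list(method = method, estimates = res, extra = extra),
            class = "structural_result")
}

#' @export
print.structural_result <- function(x, digits = 3, ...) {
  cat("Structural method:", x$method, "\n")
  est <- x$estimates
  est[-1] <- lapply(est[-1], round, digits)
  print(est, row.names = FALSE)
  invisible(x)
}

check_predictor <- function(z, n) {
  z <- as.numeric(z)
  if (length(z) != n) stop_input("predictor length does not match item rows")
  if (anyNA(z)) stop_input("predictor contains missing values")
  if (sd(z) == 0) stop_input("predictor is constant")
  z
}

#' Sum-score regression (Methods 1 and 2)
#'
#' Regresses unit-weight composites on a single predictor by ordinary least
#' squares. One composite per block: a single block containing all items
#' gives the single-outcome analysis (Method 1); one block per subscale gives
#' separate outcomes (Method 2). `d` standardizes the slope by the
#' composite's sample SD; `beta` additionally multiplies by the predictor's
#' sample SD (both with denominator n-1). With a 0/1 group predictor, `B` is
#' the raw mean difference and `d` is Cohen's d against the residual SD.
#'
#' @param items persons x items data.
#' @param blocks named list: composite name -> item labels.
#' @param z predictor vector (0/1 group code or general numeric).
#' @return a `structural_result`.
#' @export
method_sum_regression <- function(items, blocks, z) {
  x <- as_item_matrix(items)
  z <- check_predictor(z, nrow(x))
  out <- lapply(names(blocks), function(bn) {
    cols <- blocks[[bn]]
    if (!all(cols %in% colnames(x)))
      stop_input("block '", bn, "' references unknown items")
    y <- composite_scores(x[, cols, drop = FALSE])
    fit <- lm(y ~ z)
    B <- unname(coef(fit)[2]); se <- unname(sqrt(diag(vcov(fit)))[2])
    ci <- B + c(-1, 1) * qnorm(0.975) * se
    d <- B / sd(y)
    c(B = B, se = se, ci_lo = ci[1], ci_hi = ci[2],
      d = d, beta = d * sd(z))
  })
  m <- do.call(rbind, out)
  structural_result(if (length(blocks) == 1L) 1L else 2L, names(blocks),
                    m[, "B"], m[, "se"], m[, "ci_lo"], m[, "ci_hi"],
                    m[, "d"], m[, "beta"])
}

# Fit each block's congeneric model and return marker-metric measurement
# matrices plus regression-method scoring weights W = Phi Lambda' Sigma^-1
# (Sigma the model-implied covariance matrix, per block).
block_measurement <- function(x, blocks, ...) {
  p <- ncol(x); k <- length(blocks)
  labels <- unlist(blocks, use.names = FALSE)
  Lambda <- matrix(0, length(labels), k,
                   dimnames = list(labels, names(blocks)))
  Theta <- numeric(length(labels)); names(Theta) <- labels
  W <- matrix(0, k, length(labels), dimnames = list(names(blocks), labels))
  psi <- numeric(k)
  for (m in seq_len(k)) {
    cols <- blocks[[m]]
    if (length(cols) < 3L)
      stop_input("each factor block needs at least 3 items")
    fit <- suppressWarnings(
      fit_cfa(sample_moments(cov(x[, cols, drop = FALSE])),
              cfa_spec(setNames(list(cols), names(blocks)[m])), ...))
    lam <- drop(fit$lambda)
    s <- lam[1L]                       # marker rescale: first loading -> 1
    lam_m <- lam / s; var_f <- s^2
    Sig <- model_implied_cov(fit)
    W[m, cols] <- var_f * (lam_m %*% solve(Sig))
    Lambda[cols, m] <- lam_m
    Theta[cols] <- fit$theta
    psi[m] <- var_f
  }
  list(Lambda = Lambda, Theta = Theta, W = W, psi = psi, labels = labels)
}

croon_point <- function(x, blocks, z, ...) {
  meas <- block_measurement(x, blocks, ...)
  x <- x[, meas$labels, drop = FALSE]
  S <- cov(x)
  c_xz <- cov(x, z)
  A <- meas$W %*% meas$Lambda
  if (abs(det(A)) < 1e-12)
    stop_input("scoring weights and loadings are singular (W Lambda)")
  Ainv <- solve(A)
  mid <- meas$W %*% S %*% t(meas$W) -
    meas$W %*% diag(meas$Theta, nrow = length(meas$Theta)) %*% t(meas$W)
  Psi <- Ainv %*% mid %*% t(Ainv)
  cov_fz <- drop(Ainv %*% (meas$W %*% c_xz))
  B <- cov_fz / var(z)
  sd_f <- sqrt(pmax(diag(Psi), 0))
  d <- B / sd_f
  list(B = B, d = d, beta = d * sd(z), psi = Psi)
}

#' Croon-corrected factor score regression (Method 3)
#'
#' Two-stage analysis: each factor block's congeneric measurement model is
#' fitted separately, regression-method scoring weights
#' \eqn{W = \Phi \Lambda' \Sigma^{-1}} are formed, and the slope of each
#' factor on the predictor is computed with Croon's method-of-moments
#' correction, which removes the attenuation bias of naive regression on
#' estimated factor scores: with \eqn{A = W\Lambda},
#' \eqn{\widehat{var}(f) = A^{-1}(W S W' - W \Theta W')A^{-T}} and
#' \eqn{\widehat{cov}(f, z) = A^{-1} W c_{xz}}. Standard errors and 95% CIs
#' come from a seeded nonparametric bootstrap over persons (normal-theory
#' interval \eqn{B \pm 1.96\,SE_{boot}}).
#'
#' @param items persons x items data.
#' @param blocks named list: factor name -> item labels (>= 3 each).
#' @param z predictor vector.
#' @param n_boot bootstrap resamples (0 skips the bootstrap; SE/CI are NA).
#' @param seed integer seed for the bootstrap (required when `n_boot > 0`).
#' @param ... passed to [fit_cfa()].
#' @return a `structural_result`; `extra$n_boot_failed` counts resamples whose
#'   measurement fit failed.
#' @export
croon_factor_score_regression <- function(items, blocks, z, n_boot = 499L,
                                          seed = NULL, ...) {
  x <- as_item_matrix(items)
  z <- check_predictor(z, nrow(x))
  pt <- croon_point(x, blocks, z, ...)
  k <- length(blocks)
  se <- rep(NA_real_, k); ci_lo <- rep(NA_real_, k); ci_hi <- rep(NA_real_, k)
  failed <- 0L
  if (n_boot > 0L) {
    boots <- with_seed(seed, {
      replicate(n_boot, {
        idx <- sample.int(nrow(x), replace = TRUE)
        tryCatch(croon_point(x[idx, , drop = FALSE], blocks, z[idx], ...)$B,
                 error = function(e) rep(NA_real_, k))
      })
    })
    boots <- matrix(boots, nrow = k)
    failed <- sum(colSums(is.na(boots)) > 0L)
    se <- apply(boots, 1, sd, na.rm = TRUE)
    ci_lo <- pt$B - qnorm(0.975) * se
    ci_hi <- pt$B + qnorm(0.975) * se
  }
  structural_result(3L, names(blocks), pt$B, se, ci_lo, ci_hi, pt$d, pt$beta,
                    extra = list(n_boot = n_boot, n_boot_failed = failed,
                                 psi = pt$psi))
}

#' Naive (uncorrected) factor score regression
#'
#' Regresses regression-method factor score estimates directly on the
#' predictor, with no correction for measurement error in the scores. Slopes
#' are attenuated by the factor-score reliability; provided as the comparison
#' baseline for [croon_factor_score_regression()].
#'
#' @inheritParams croon_factor_score_regression
#' @return a `structural_result` (method label `"naive_fsr"`).
#' @export
naive_factor_score_regression <- function(items, blocks, z, ...) {
  x <- as_item_matrix(items)
  z <- check_predictor(z, nrow(x))
  meas <- block_measurement(x, blocks, ...)
  scores <- sweep(x[, meas$labels, drop = FALSE], 2,
                  colMeans(x[, meas$labels, drop = FALSE])) %*% t(meas$W)
  out <- lapply(seq_len(ncol(scores)), function(m) {
    fit <- lm(scores[, m] ~ z)
    B <- unname(coef(fit)[2]); se <- unname(sqrt(diag(vcov(fit)))[2])
    d <- B / sd(scores[, m])
    c(B = B, se = se, ci_lo = B - qnorm(0.975) * se,
      ci_hi = B + qnorm(0.975) * se, d = d, beta = d * sd(z))
  })
  m <- do.call(rbind, out)
  structural_result("naive_fsr", names(blocks), m[, "B"], m[, "se"],
                    m[, "ci_lo"], m[, "ci_hi"], m[, "d"], m[, "beta"])
}

# ---- Method 4: simultaneous latent regression (MIMIC) ----------------------

mimic_parmap <- function(blocks) {
  labels <- unlist(blocks, use.names = FALSE)
  p <- length(labels); k <- length(blocks)
  fac_of <- rep(seq_len(k), lengths(blocks))
  marker <- match(vapply(blocks, `[`, "", 1L), labels)
  free_lam <- setdiff(seq_len(p), marker)
  n_psi <- k * (k + 1L) / 2L
  list(labels = labels, p = p, k = k, fac_of = fac_of, marker = marker,
       free_lam = free_lam,
       n_free = length(free_lam) + p + k + n_psi + 1L)
}

mimic_unpack <- function(par, map, floor = 1e-6) {
  par <- unname(par)
  p <- map$p; k <- map$k
  i <- 0L
  Lambda <- matrix(0, p, k)
  Lambda[cbind(map$marker, seq_len(k))] <- 1
  Lambda[cbind(map$free_lam, map$fac_of[map$free_lam])] <-
    par[i + seq_along(map$free_lam)]; i <- i + length(map$free_lam)
  theta <- floor + exp(par[i + seq_len(p)]); i <- i + p
  Gamma <- par[i + seq_len(k)]; i <- i + k
  Lch <- matrix(0, k, k)
  diag(Lch) <- exp(par[i + seq_len(k)]); i <- i + k
  if (k > 1L) {
    lower <- which(lower.tri(Lch), arr.ind = TRUE)
    Lch[lower] <- par[i + seq_len(nrow(lower))]; i <- i + nrow(lower)
  }
  Psi <- Lch %*% t(Lch)
  vz <- exp(par[i + 1L])
  list(Lambda = Lambda, theta = theta, Gamma = Gamma, Psi = Psi, vz = vz)
}

mimic_implied <- function(est, map) {
  Phif <- tcrossprod(est$Gamma) * est$vz + est$Psi
  Sxx <- est$Lambda %*% Phif %*% t(est$Lambda)
  diag(Sxx) <- diag(Sxx) + est$theta
  Sxz <- est$Lambda %*% est$Gamma * est$vz
  rbind(cbind(Sxx, Sxz), c(Sxz, est$vz))
}

mimic_objective <- function(par, map, SJ, logdetSJ, floor = 1e-6) {
  est <- mimic_unpack(par, map, floor)
  Sigma <- mimic_implied(est, map)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(1e10 + sum(par^2))
  2 * sum(log(diag(R))) + sum(chol2inv(R) * SJ) - logdetSJ - (map$p + 1)
}

#' Simultaneous latent-variable regression (Method 4)
#'
#' Joint maximum-likelihood fit over the items and the predictor: a
#' congeneric measurement model per block, with each latent outcome regressed
#' on the predictor (modeled as a single-indicator, error-free variable).
#' Marker-variable identification (first loading per block fixed at 1).
#' Standard errors come from the inverse observed information. `d`
#' standardizes the slope by the model-implied latent outcome SD
#' \eqn{\sqrt{(\Gamma \sigma_z^2 \Gamma' + \Psi)_{mm}}}; `beta` multiplies by
#' the model SD of the predictor.
#'
#' @inheritParams croon_factor_score_regression
#' @param ... passed to the per-block [fit_cfa()] used for start values.
#' @return a `structural_result`; `extra` carries the measurement estimates,
#'   discrepancy, and convergence record.
#' @export
simultaneous_latent_regression <- function(items, blocks, z, ...) {
  x <- as_item_matrix(items)
  z <- check_predictor(z, nrow(x))
  map <- mimic_parmap(blocks)
  xz <- cbind(x[, map$labels, drop = FALSE], .z = z)
  SJ <- cov(xz)
  logdetSJ <- determinant(SJ, logarithm = TRUE)$modulus[1]
  if (!is.finite(logdetSJ))
    stop_input("joint covariance matrix of items and predictor is singular")

  # start values: per-block measurement fits + naive score regression
  meas <- block_measurement(x, blocks, ...)
  scores <- sweep(x[, meas$labels, drop = FALSE], 2,
                  colMeans(x[, meas$labels, drop = FALSE])) %*% t(meas$W)
  g0 <- drop(cov(scores, z)) / var(z)
  psi0 <- pmax(meas$psi - g0^2 * var(z), 0.2 * meas$psi)
  par0 <- c(meas$Lambda[cbind(map$free_lam, map$fac_of[map$free_lam])],
            log(pmax(meas$Theta, 1e-4)),
            g0,
            0.5 * log(psi0),
            if (map$k > 1L) rep(0, map$k * (map$k - 1L) / 2L),
            log(var(z)))
  opt <- nlminb(par0, mimic_objective, map = map, SJ = SJ,
                logdetSJ = logdetSJ,
                control = list(iter.max = 2000L, eval.max = 4000L,
                               rel.tol = 1e-12))
  grad_at <- function(par) {
    vapply(seq_along(par), function(i) {
      h <- 1e-6 * max(1, abs(par[i]))
      pp <- par; pm <- par
      pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
      (mimic_objective(pp, map, SJ, logdetSJ) -
         mimic_objective(pm, map, SJ, logdetSJ)) / (2 * h)
    }, numeric(1))
  }
  # polish from the incumbent when nlminb's own code is picky; accept a
  # flat-gradient solution
  tries <- 0L
  while (opt$convergence != 0L && max(abs(grad_at(opt$par))) > 1e-3 &&
         tries < 2L) {
    tries <- tries + 1L
    opt <- nlminb(opt$par, mimic_objective, map = map, SJ = SJ,
                  logdetSJ = logdetSJ,
                  control = list(iter.max = 2000L, eval.max = 4000L,
                                 rel.tol = 1e-12))
  }
  if (opt$objective > 1e6)
    stop_convergence(paste0("latent regression did not converge: ",
                            opt$message), best = opt)
  gnum <- grad_at(opt$par)
  converged <- opt$convergence == 0L || max(abs(gnum)) < 1e-3
  if (!converged)
    stop_convergence(paste0("latent regression did not converge: ",
                            opt$message, " (max |gradient| ",
                            format(max(abs(gnum)), digits = 3), ")"),
                     best = opt)
  est <- mimic_unpack(opt$par, map)
  n <- nrow(x)
  H <- optimHess(opt$par, mimic_objective, map = map, SJ = SJ,
                 logdetSJ = logdetSJ)
  Vp <- tryCatch(2 / (n - 1) * solve(H), error = function(e)
    stop_convergence("observed information is singular", best = opt))
  g_pos <- length(map$free_lam) + map$p + seq_len(map$k)
  B <- est$Gamma
  se <- sqrt(pmax(diag(Vp)[g_pos], 0))
  Phif <- tcrossprod(est$Gamma) * est$vz + est$Psi
  sd_f <- sqrt(diag(Phif))
  d <- B / sd_f
  beta <- B * sqrt(est$vz) / sd_f
  rownames(est$Lambda) <- map$labels; colnames(est$Lambda) <- names(blocks)
  structural_result(4L, names(blocks), B, se,
                    B - qnorm(0.975) * se, B + qnorm(0.975) * se, d, beta,
                    extra = list(lambda = est$Lambda, theta = est$theta,
                                 psi = est$Psi, var_z = est$vz,
                                 discrepancy = opt$objective,
                                 converged = converged,
                                 n_iterations = opt$iterations))
}
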