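# Simulation of factor-model item pools, criterion variables, the
# split-sample cross-validation harness, and the weighted-vs-unit-weight
# composite convergence property.

#' Simulation configuration for a factor-model item pool
#'
#' Describes the generating model: items are
#' \eqn{x = \nu + \Lambda f + \varepsilon} with factors
#' \eqn{f \sim N(0, \Phi)} and independent normal unique parts. Optional
#' Likert discretization maps each item onto 1..L by equal-probability normal
#' thresholds of its own marginal distribution. Criterion variables are
#' generated at the factor level — criterion = r * factor + sqrt(1 - r^2) *
#' noise — so the configured validity is the true factor-level correlation
#' and attenuation arithmetic is exact.
#'
#' @param n persons.
#' @param lambda loadings: vector (one factor) or p x k matrix.
#' @param theta unique variances (length p, non-negative).
#' @param phi factor correlation matrix (default identity).
#' @param nu intercepts (default 0).
#' @param likert_levels optional number of response categories.
#' @param criterion_validities optional named vector of factor-level
#'   correlations in (-1, 1), one criterion each.
#' @param criterion_factors factor index or name each criterion attaches to
#'   (recycled; default the first factor).
#' @param seed integer seed; mandatory, every stochastic call is reproducible
#'   given (seed, config).
#' @param item_labels optional item names.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n, lambda, theta, phi = NULL, nu = NULL,
                       likert_levels = NULL, criterion_validities = NULL,
                       criterion_factors = 1L, seed,
                       item_labels = NULL) {
  lambda <- if (is.matrix(lambda)) lambda else matrix(lambda, ncol = 1L)
  p <- nrow(lambda); k <- ncol(lambda)
  if (length(theta) != p) stop_input("theta length must match item count")
  if (any(theta < 0)) stop_input("unique variances must be non-negative")
  phi <- phi %||% diag(k)
  phi <- check_symmetric(phi, what = "phi")
  if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_input("phi is not positive definite")
  nu <- nu %||% rep(0, p)
  if (length(nu) != p) stop_input("nu length must match item count")
  if (!is.null(criterion_validities)) {
    if (any(abs(criterion_validities) >= 1))
      stop_input("criterion validities must lie in (-1, 1)")
    if (is.null(names(criterion_validities)))
      names(criterion_validities) <-
        paste0("criterion", seq_along(criterion_validities))
    criterion_factors <- rep(criterion_factors,
                             length.out = length(criterion_validities))
  }
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  implied <- lambda %*% phi %*% t(lambda) + diag(theta, p)
  if (min(eigen(implied, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_input("implied covariance matrix is not positive definite")
  item_labels <- item_labels %||% paste0("item", seq_len(p))
  structure(list(n = as.integer(n), lambda = lambda, theta = theta,
                 phi = phi, nu = nu, likert_levels = likert_levels,
                 criterion_validities = criterion_validities,
                 criterion_factors = criterion_factors,
                 seed = as.integer(seed), item_labels = item_labels,
                 p = p, k = k, implied = implied),
            class = "sim_config")
}

#' Simulate an item pool (and criteria) from a factor model
#'
#' Draws latent factors from the configured multivariate normal, forms items
#' as \eqn{\nu + \Lambda f + \varepsilon}, optionally discretizes onto a
#' Likert scale, and attaches criterion variables with the configured
#' factor-level validities. True factor scores are returned for recovery
#' checks. Bit-reproducible for a given config.
#'
#' @param config a [sim_config()].
#' @return list with `items` (n x p matrix), `factor_scores` (n x k),
#'   `criteria` (n x c matrix or NULL), and the `config`.
#' @export
simulate_items <- function(config) {
  if (!inherits(config, "sim_config")) stop_input("config must be a sim_config")
  with_seed(config$seed, {
    f <- rmvnorm_chol(config$n, config$phi)
    eps <- matrix(rnorm(config$n * config$p), config$n, config$p) %*%
      diag(sqrt(config$theta), config$p)
    x <- sweep(f %*% t(config$lambda) + eps, 2, config$nu, `+`)
    colnames(x) <- config$item_labels
    if (!is.null(config$likert_levels)) {
      L <- config$likert_levels
      mu <- config$nu
      sds <- sqrt(diag(config$implied))
      for (j in seq_len(config$p)) {
        cuts <- qnorm(seq_len(L - 1L) / L, mean = mu[j], sd = sds[j])
        x[, j] <- findInterval(x[, j], cuts) + 1L
      }
    }
    crit <- NULL
    if (!is.null(config$criterion_validities)) {
      crit <- vapply(seq_along(config$criterion_validities), function(i) {
        r <- config$criterion_validities[i]
        fm <- f[, config$criterion_factors[i]]
        r * fm + sqrt(1 - r^2) * rnorm(config$n)
      }, numeric(config$n))
      colnames(crit) <- names(config$criterion_validities)
    }
    colnames(f) <- colnames(config$lambda) %||%
      paste0("factor", seq_len(config$k))
    list(items = x, factor_scores = f, criteria = crit, config = config)
  })
}

#' Split-sample cross-validated validity of factor scores versus sum scores
#'
#' For each replication: draw a calibration subset, fit a one-factor
#' congeneric model to the scale items, form regression scoring weights, score
#' the holdout sample with the calibration weights (and calibration means for
#' centering), also compute the unit-weight sum on the holdout, and correlate
#' both scores with every criterion. Replications whose calibration fit fails
#' are skipped and counted. The aggregate mean/min/max over replications is
#' the cross-validated validity profile of each scoring method.
#'
#' @param config a [sim_config()] with criterion validities; defines the data.
#' @param scale_items item labels forming the scale (default: all items).
#' @param n_calibration calibration sample size (must be below `config$n`).
#' @param n_replications number of random splits.
#' @param seed seed for the replication splits.
#' @param ... passed to [fit_cfa()].
#' @return object of class `crossval_report`: a data.frame per criterion and
#'   scorer with mean/min/max cross-validated correlation, plus the skipped
#'   replication count.
#' @export
crossval_validity <- function(config, scale_items = NULL,
                              n_calibration = 200L, n_replications = 100L,
                              seed, ...) {
  if (n_calibration >= config$n)
    stop_input("n_calibration must be below config$n")
  data <- simulate_items(config)
  if (is.null(data$criteria)) stop_input("config has no criterion variables")
  scale_items <- scale_items %||% config$item_labels
  x <- data$items[, scale_items, drop = FALSE]
  crit <- data$criteria
  spec <- cfa_spec(list(f = scale_items))
  res_fs <- vector("list", n_replications)
  res_sum <- vector("list", n_replications)
  skipped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replications)) {
      idx <- sample.int(config$n, n_calibration)
      cal <- x[idx, , drop = FALSE]
      hold <- x[-idx, , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(fit_cfa(sample_moments(cov(cal)), spec, ...)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { skipped <- skipped + 1L; next }
      sc <- factor_scores_regression(fit, items = hold,
                                     center = colMeans(cal))$scores[, 1L]
      sums <- rowSums(hold)
      res_fs[[r]] <- drop(cor(sc, crit[-idx, , drop = FALSE]))
      res_sum[[r]] <- drop(cor(sums, crit[-idx, , drop = FALSE]))
    }
  })
  agg <- function(lst) {
    m <- do.call(rbind, lst[!vapply(lst, is.null, TRUE)])
    data.frame(criterion = colnames(crit),
               mean = colMeans(m), min = apply(m, 2, min),
               max = apply(m, 2, max), row.names = NULL)
  }
  structure(list(factor_scores = agg(res_fs), sum_scores = agg(res_sum),
                 n_replications = n_replications, skipped = skipped,
                 n_calibration = n_calibration),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, digits = 3, ...) {
  cat("Cross-validated validities over", x$n_replications, "replications (",
      x$skipped, "skipped )\n")
  both <- merge(x$factor_scores, x$sum_scores, by = "criterion",
                suffixes = c("_fs", "_sum"))
  both[-1] <- lapply(both[-1], round, digits)
  print(both, row.names = FALSE)
  invisible(x)
}

#' Convergence of weighted and unit-weight composites with scale length
#'
#' For each item count p, draws random positive weight vectors and reports the
#' mean correlation between the differentially weighted composite and the
#' unit-weight composite of the same items, computed from the model-implied
#' covariance matrix of an exchangeable item pool (pairwise correlation `r`).
#' As p grows the two composites become indistinguishable; the mean
#' correlation is non-decreasing in p up to Monte-Carlo error, and equals 1
#' exactly at p = 1 or for constant weights.
#'
#' @param p_grid item counts to evaluate.
#' @param weight_draws random weight vectors per p.
#' @param seed integer seed.
#' @param r exchangeable inter-item correlation (positive).
#' @return data.frame with columns `p` and `mean_correlation`.
#' @export
wilks_convergence <- function(p_grid, weight_draws = 500L, seed, r = 0.3) {
  if (r <= 0) stop_input("inter-item correlation must be positive")
  with_seed(seed, {
    rows <- lapply(p_grid, function(p) {
      C <- matrix(r, p, p); diag(C) <- 1
      ones <- rep(1, p)
      v1 <- sum(C)
      cors <- replicate(weight_draws, {
        w <- runif(p)
        drop(t(w) %*% C %*% ones) / sqrt(drop(t(w) %*% C %*% w) * v1)
      })
      data.frame(p = p, mean_correlation = mean(cors))
    })
    do.call(rbind, rows)
  })
}
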