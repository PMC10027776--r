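#' Sample moments for covariance-structure analysis
#'
#' Bundles a covariance matrix with optional means and sample size. The matrix
#' must be symmetric (tolerance 1e-8; it is then exactly symmetrized) and
#' positive definite.
#'
#' @param cov p x p covariance matrix, ideally with dimnames.
#' @param means optional length-p mean vector.
#' @param n optional sample size (persons); required for fit statistics.
#' @return object of class `sample_moments`.
#' @export
sample_moments <- function(cov, means = NULL, n = NULL) {
  cov <- check_symmetric(cov)
  p <- ncol(cov)
  if (is.null(colnames(cov))) {
    colnames(cov) <- rownames(cov) <- paste0("item", seq_len(p))
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev))
    stop_input("covariance matrix is not positive definite")
  if (!is.null(means)) {
    if (length(means) != p) stop_input("means length does not match cov")
    means <- setNames(as.numeric(means), colnames(cov))
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (n < 2L) stop_input("n must be at least 2")
  }
  structure(list(cov = cov, means = means, n = n, p = p,
                 labels = colnames(cov)),
            class = "sample_moments")
}

#' Factor model specification
#'
#' Describes a simple-structure factor model: which items load on which
#' factor, and the classical-test-theory constraint level. `"congeneric"`
#' leaves loadings and unique variances free; `"tau_equivalent"` forces equal
#' loadings within each factor block (true-score variances equal);
#' `"parallel"` additionally forces equal unique variances. Without a mean
#' structure these are the "essentially" tau-equivalent / parallel models;
#' supplying means to [fit_cfa()] with `strict_means = TRUE` adds
#' equal-intercept constraints within blocks ("strictly" variants).
#'
#' @param pattern named list mapping factor names to character vectors of item
#'   labels; every item loads on exactly one factor.
#' @param constraint constraint level.
#' @param strict_means constrain intercepts to equality within blocks when a
#'   mean structure is fitted?
#' @return object of class `cfa_spec`.
#' @examples
#' cfa_spec(list(verbal = c("x06", "x07", "x09")))
#' @export
cfa_spec <- function(pattern,
                     constraint = c("congeneric", "tau_equivalent", "parallel"),
                     strict_means = FALSE) {
  constraint <- match.arg(constraint)
  if (!is.list(pattern) || is.null(names(pattern)) || any(names(pattern) == ""))
    stop_input("pattern must be a named list: factor -> item labels")
  items <- unlist(pattern, use.names = FALSE)
  if (anyDuplicated(items))
    stop_input("every item must load on exactly one factor")
  if (any(lengths(pattern) < 1L))
    stop_input("each factor needs at least one item")
  structure(list(pattern = pattern, constraint = constraint,
                 strict_means = isTRUE(strict_means),
                 factors = names(pattern), items = items),
            class = "cfa_spec")
}

# ---- parameter bookkeeping -------------------------------------------------

# Maps the free-parameter vector onto (Lambda, theta, Phi, nu). Equality
# constraints are encoded by items sharing a parameter index.
cfa_parmap <- function(spec, labels, with_means) {
  items <- spec$items
  if (!all(items %in% labels))
    stop_input("pattern items missing from moments: ",
               paste(setdiff(items, labels), collapse = ", "))
  p <- length(items)
  k <- length(spec$factors)
  fac_of <- rep(seq_len(k), lengths(spec$pattern))
  lam_idx <- switch(spec$constraint,
                    congeneric = seq_len(p),
                    tau_equivalent = fac_of,
                    parallel = fac_of)
  th_idx <- if (spec$constraint == "parallel") fac_of else seq_len(p)
  n_lam <- max(lam_idx); n_th <- max(th_idx)
  n_phi <- k * (k - 1L) / 2L
  nu_idx <- NULL; n_nu <- 0L
  if (with_means) {
    nu_idx <- if (spec$strict_means) fac_of else seq_len(p)
    n_nu <- max(nu_idx)
  }
  off <- c(lam = 0L, th = n_lam, phi = n_lam + n_th,
           nu = n_lam + n_th + n_phi)
  list(items = items, p = p, k = k, fac_of = fac_of,
       lam_idx = lam_idx, th_idx = th_idx, nu_idx = nu_idx,
       off = off, n_free = n_lam + n_th + n_phi + n_nu,
       phi_pairs = if (n_phi > 0) which(upper.tri(diag(k)), arr.ind = TRUE))
}

cfa_unpack <- function(par, map, floor) {
  p <- map$p; k <- map$k
  lam_par <- par[map$off["lam"] + seq_len(max(map$lam_idx))]
  Lambda <- matrix(0, p, k)
  Lambda[cbind(seq_len(p), map$fac_of)] <- lam_par[map$lam_idx]
  theta <- floor + exp(par[map$off["th"] + map$th_idx])
  Phi <- diag(k)
  if (k > 1L) {
    z <- par[map$off["phi"] + seq_len(nrow(map$phi_pairs))]
    r <- tanh(z)
    Phi[map$phi_pairs] <- r
    Phi[map$phi_pairs[, 2:1, drop = FALSE]] <- r
  }
  nu <- NULL
  if (!is.null(map$nu_idx))
    nu <- par[map$off["nu"] + map$nu_idx]
  list(Lambda = Lambda, theta = theta, Phi = Phi, nu = nu)
}

# ML discrepancy F = log|Sigma| + tr(S* Sigma^-1) - log|S| - p, where
# S* = S + dd' and d = xbar - nu when a mean structure is fitted.
cfa_objective <- function(par, map, S, logdetS, xbar, floor) {
  th <- cfa_unpack(par, map, floor)
  Sigma <- th$Lambda %*% th$Phi %*% t(th$Lambda)
  diag(Sigma) <- diag(Sigma) + th$theta
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(1e10 + sum(par^2))
  Sstar <- S
  if (!is.null(th$nu)) {
    d <- xbar - th$nu
    Sstar <- S + tcrossprod(d)
  }
  Sinv <- chol2inv(R)
  2 * sum(log(diag(R))) + sum(Sinv * Sstar) - logdetS - map$p
}

cfa_gradient <- function(par, map, S, logdetS, xbar, floor) {
  th <- cfa_unpack(par, map, floor)
  Sigma <- th$Lambda %*% th$Phi %*% t(th$Lambda)
  diag(Sigma) <- diag(Sigma) + th$theta
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(2 * par)  # gradient of the non-PD penalty
  Sinv <- chol2inv(R)
  Sstar <- S; d <- NULL
  if (!is.null(th$nu)) {
    d <- xbar - th$nu
    Sstar <- S + tcrossprod(d)
  }
  G <- Sinv - Sinv %*% Sstar %*% Sinv
  grad <- numeric(map$n_free)
  # loadings: dF/dLambda = 2 G Lambda Phi, pooled over tied parameters
  dL <- 2 * (G %*% th$Lambda %*% th$Phi)
  dl_item <- dL[cbind(seq_len(map$p), map$fac_of)]
  grad[map$off["lam"] + seq_len(max(map$lam_idx))] <-
    as.numeric(rowsum(dl_item, map$lam_idx))
  # unique variances on the log scale
  dth <- diag(G) * (th$theta - floor)
  grad[map$off["th"] + seq_len(max(map$th_idx))] <-
    as.numeric(rowsum(dth, map$th_idx))
  # factor correlations via tanh
  if (map$k > 1L) {
    M <- t(th$Lambda) %*% G %*% th$Lambda
    z <- par[map$off["phi"] + seq_len(nrow(map$phi_pairs))]
    grad[map$off["phi"] + seq_len(nrow(map$phi_pairs))] <-
      2 * M[map$phi_pairs] * (1 - tanh(z)^2)
  }
  if (!is.null(th$nu)) {
    dn <- as.numeric(-2 * Sinv %*% d)
    grad[map$off["nu"] + seq_len(max(map$nu_idx))] <-
      as.numeric(rowsum(dn, map$nu_idx))
  }
  grad
}

cfa_start <- function(map, S, xbar) {
  p <- map$p
  lam_item <- numeric(p)
  for (f in seq_len(map$k)) {
    in_f <- which(map$fac_of == f)
    Sf <- S[in_f, in_f, drop = FALSE]
    off <- Sf[upper.tri(Sf)]
    cbar <- if (length(off)) mean(off) else 0.5 * mean(diag(Sf))
    lam_item[in_f] <- sqrt(max(cbar, 0.1 * mean(diag(Sf))))
  }
  th_item <- log(pmax(diag(S) - lam_item^2, 0.2 * diag(S)))
  pool <- function(v, idx) as.numeric(rowsum(v, idx)) / tabulate(idx)
  par <- c(pool(lam_item, map$lam_idx), pool(th_item, map$th_idx))
  if (map$k > 1L) par <- c(par, rep(0.2, nrow(map$phi_pairs)))
  if (!is.null(map$nu_idx)) par <- c(par, pool(as.numeric(xbar), map$nu_idx))
  par
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \eqn{F_{ML} = \log|\Sigma| + tr(S\Sigma^{-1}) - \log|S| - p} over the free
#' parameters of a simple-structure factor model. Factor variances are fixed
#' at 1 and factor covariances are free. Unique variances are parameterized on
#' a log scale with a small positive floor; estimates at the floor are flagged
#' as Heywood cases. A mean structure (intercepts \eqn{\nu}) is fitted only
#' when `moments` carries means. Factor orientation is fixed by forcing the
#' first loading per factor to be positive.
#'
#' Optimization uses [stats::nlminb()] with analytic gradients from a
#' data-driven start; when the first attempt fails its convergence checks, up
#' to `n_restarts` deterministic jittered restarts are tried and the best
#' discrepancy kept.
#'
#' @param moments a [sample_moments()] object (or bare covariance matrix).
#' @param spec a [cfa_spec()].
#' @param n_restarts maximum number of jittered restarts.
#' @param theta_floor lower bound for unique variances.
#' @param grad_tol gradient tolerance declared to the optimizer.
#' @return object of class `fitted_cfa` with elements `lambda` (p x k),
#'   `theta` (named unique variances), `phi` (k x k, unit diagonal), `nu`
#'   (intercepts or NULL), `discrepancy`, `converged`, `n_iterations`,
#'   `n_free`, `df`, `heywood`, `warnings`, and the `spec`/`moments` used.
#' @export
fit_cfa <- function(moments, spec, n_restarts = 10L,
                    theta_floor = 1e-6, grad_tol = 1e-8) {
  if (is.matrix(moments)) moments <- sample_moments(moments)
  if (!inherits(moments, "sample_moments"))
    stop_input("moments must be a sample_moments object or matrix")
  if (!inherits(spec, "cfa_spec")) stop_input("spec must be a cfa_spec")
  with_means <- !is.null(moments$means)
  map <- cfa_parmap(spec, moments$labels, with_means)
  # identification: >= 3 indicators for a lone congeneric block
  if (map$k == 1L && spec$constraint == "congeneric" && map$p < 3L)
    stop_input("a single congeneric factor needs at least 3 indicators")
  S <- moments$cov[map$items, map$items, drop = FALSE]
  xbar <- if (with_means) moments$means[map$items]
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]

  run <- function(par0) {
    nlminb(par0, cfa_objective, gradient = cfa_gradient,
           map = map, S = S, logdetS = logdetS, xbar = xbar,
           floor = theta_floor,
           control = list(iter.max = 1000L, eval.max = 2000L,
                          rel.tol = 1e-12))
  }
  ok <- function(fit) {
    # converged if the gradient is flat at the solution; nlminb's own code
    # can report "singular convergence" at a perfectly good optimum when the
    # relative tolerance is tight
    g <- cfa_gradient(fit$par, map, S, logdetS, xbar, theta_floor)
    max(abs(g)) < max(grad_tol, 1e-6) ||
      (fit$convergence == 0L && max(abs(g)) < 1e-4)
  }
  par0 <- cfa_start(map, S, xbar)
  best <- run(par0)
  attempt <- 0L
  while (!ok(best) && attempt < n_restarts) {
    attempt <- attempt + 1L
    jitter <- 0.3 * sin(seq_along(par0) * attempt * 1.7)
    cand <- run(par0 * (1 + 0.2 * jitter) + 0.1 * jitter)
    if (cand$objective < best$objective) best <- cand
    if (ok(cand)) { best <- cand; break }
  }
  est <- cfa_unpack(best$par, map, theta_floor)
  # orient each factor so its first loading is positive
  for (f in seq_len(map$k)) {
    first <- which(map$fac_of == f)[1L]
    if (est$Lambda[first, f] < 0) {
      est$Lambda[, f] <- -est$Lambda[, f]
      if (map$k > 1L) {
        est$Phi[f, -f] <- -est$Phi[f, -f]
        est$Phi[-f, f] <- -est$Phi[-f, f]
      }
    }
  }
  dimnames(est$Lambda) <- list(map$items, spec$factors)
  names(est$theta) <- map$items
  dimnames(est$Phi) <- list(spec$factors, spec$factors)
  heywood <- est$theta <= theta_floor * 10
  warnings <- character()
  if (any(heywood))
    warnings <- c(warnings, paste0("Heywood case: unique variance at floor for ",
                                   paste(map$items[heywood], collapse = ", ")))
  converged <- ok(best)
  if (!converged)
    warnings <- c(warnings, "optimizer did not meet convergence criteria")
  n_moments <- map$p * (map$p + 1) / 2 + if (with_means) map$p else 0
  res <- structure(list(
    lambda = est$Lambda, theta = est$theta, phi = est$Phi,
    nu = if (with_means) setNames(est$nu, map$items),
    discrepancy = best$objective, converged = converged,
    n_iterations = best$iterations, n_free = map$n_free,
    df = as.integer(n_moments - map$n_free),
    heywood = heywood, warnings = warnings,
    spec = spec, moments = moments), class = "fitted_cfa")
  if (length(warnings)) for (w in warnings) warning(w, call. = FALSE)
  res
}

#' @export
print.fitted_cfa <- function(x, digits = 3, ...) {
  cat("Confirmatory factor model (", x$spec$constraint, ")\n", sep = "")
  cat("F_ML =", format(x$discrepancy, digits = 6),
      " df =", x$df,
      " converged:", x$converged, "\n\nLoadings:\n")
  print(round(x$lambda, digits))
  cat("\nUnique variances:\n")
  print(round(x$theta, digits))
  if (ncol(x$phi) > 1L) { cat("\nFactor correlations:\n"); print(round(x$phi, digits)) }
  if (length(x$warnings)) cat("\nWarnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Closed-form one-factor solution for three indicators
#'
#' For three indicators with strictly positive covariances the just-identified
#' one-factor model has the classical closed form
#' \eqn{\lambda_1 = \sqrt{c_{12} c_{13} / c_{23}}} (cyclically for the
#' others), with unique variances \eqn{\theta_j = s_{jj} - \lambda_j^2}. The
#' implied covariance matrix reproduces the off-diagonal entries exactly.
#'
#' @param cov3 3 x 3 symmetric covariance matrix with positive off-diagonals.
#' @return list with `loadings` and `uniques` (both named if `cov3` has
#'   dimnames).
#' @export
spearman_three_indicator <- function(cov3) {
  cov3 <- check_symmetric(cov3)
  if (ncol(cov3) != 3L) stop_input("cov3 must be 3 x 3")
  c12 <- cov3[1, 2]; c13 <- cov3[1, 3]; c23 <- cov3[2, 3]
  if (min(c12, c13, c23) <= 0)
    stop_input("closed form requires strictly positive covariances ",
               "(factor orientation is indeterminate otherwise)")
  l <- c(sqrt(c12 * c13 / c23), sqrt(c12 * c23 / c13), sqrt(c13 * c23 / c12))
  names(l) <- colnames(cov3)
  list(loadings = l, uniques = setNames(diag(cov3) - l^2, colnames(cov3)))
}

#' Model-implied covariance matrix
#'
#' \eqn{\Sigma = \Lambda \Phi \Lambda' + \Theta}, symmetric by construction.
#'
#' @param fitted a `fitted_cfa` object, or a list with `lambda`, `theta`,
#'   `phi`.
#' @return implied covariance matrix.
#' @export
model_implied_cov <- function(fitted) {
  L <- as.matrix(fitted$lambda)
  Phi <- fitted$phi %||% diag(ncol(L))
  Sigma <- L %*% Phi %*% t(L)
  diag(Sigma) <- diag(Sigma) + fitted$theta
  (Sigma + t(Sigma)) / 2
}

#' Regression-method factor scores
#'
#' Applies the regression (Thurstone) scoring weights
#' \eqn{W = \Phi \Lambda' S^{-1}} to item deviations from the sample means of
#' the supplied data, so the returned scores have mean exactly zero per
#' factor. The weight matrix is returned so that holdout samples can be scored
#' with calibration-sample weights (pass `center` to reuse calibration means).
#'
#' @param fitted a `fitted_cfa`.
#' @param moments the [sample_moments()] whose covariance defines the weights;
#'   defaults to the moments used in fitting.
#' @param items persons x items data to score.
#' @param center item means used for centering; defaults to the column means
#'   of `items`.
#' @return list with `scores` (n x k matrix) and `weights` (k x p matrix).
#' @export
factor_scores_regression <- function(fitted, moments = fitted$moments, items,
                                     center = NULL) {
  x <- as_item_matrix(items)
  labels <- rownames(fitted$lambda)
  if (!all(labels %in% colnames(x)))
    stop_input("items to score lack columns: ",
               paste(setdiff(labels, colnames(x)), collapse = ", "))
  x <- x[, labels, drop = FALSE]
  S <- moments$cov[labels, labels, drop = FALSE]
  Sinv <- tryCatch(solve(S), error = function(e)
    stop_numeric("sample covariance matrix is singular"))
  W <- fitted$phi %*% t(fitted$lambda) %*% Sinv
  rownames(W) <- colnames(fitted$lambda); colnames(W) <- labels
  if (is.null(center)) center <- colMeans(x)
  scores <- sweep(x, 2, center[labels]) %*% t(W)
  list(scores = scores, weights = W)
}
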