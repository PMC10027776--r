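#' Coefficient alpha
#'
#' Internal-consistency reliability of the unit-weight sum score,
#' \eqn{\alpha = \frac{p}{p-1}\left(1 - \frac{\sum_j \sigma_j^2}{\sigma_Y^2}\right)},
#' where \eqn{\sigma_Y^2} is the grand sum of the item covariance matrix.
#' Alpha is a model-based reliability only under (essential) tau-equivalence;
#' for pathological inputs (negative average covariance) it can be negative.
#'
#' @param cov item covariance matrix, p >= 2. Raw-score (covariance) metric;
#'   convert correlation input explicitly with supplied SDs first.
#' @return coefficient alpha.
#' @export
coefficient_alpha <- function(cov) {
  cov <- check_symmetric(cov)
  p <- ncol(cov)
  if (p < 2L) stop_input("coefficient alpha needs at least 2 items")
  total <- sum(cov)
  p / (p - 1) * (1 - sum(diag(cov)) / total)
}

#' Coefficient omega-total
#'
#' Model-based reliability of the unit-weight sum under a one-factor
#' congeneric model:
#' \eqn{\omega_T = (\sum_j \lambda_j)^2 / ((\sum_j \lambda_j)^2 + \sum_j \theta_j)}.
#' Equals alpha when the loadings are equal (essential tau-equivalence) and
#' the model reproduces the covariance matrix.
#'
#' @param lambda loadings from a single-factor fit (raw-score metric).
#' @param theta unique variances, non-negative.
#' @return coefficient omega-total.
#' @export
omega_total <- function(lambda, theta) {
  if (length(lambda) != length(theta))
    stop_input("lambda and theta lengths differ")
  if (all(lambda == 0)) stop_input("all loadings are zero")
  if (any(theta < 0)) stop_input("unique variances must be non-negative")
  s <- sum(lambda)^2
  s / (s + sum(theta))
}

#' Factor-score and sum-score reliabilities and their correlation
#'
#' Given single-factor loadings \eqn{\lambda} (factor variance 1) and the item
#' covariance matrix \eqn{C}, returns
#' \describe{
#'   \item{fs_reliability}{\eqn{\rho^2(\hat f, f) = \lambda' C^{-1} \lambda},
#'     the reliability (squared correlation with the true factor) of
#'     regression-method factor scores — also their determinacy squared.}
#'   \item{sum_reliability}{\eqn{\rho^2(1'x, f) = (1'\lambda)^2 / (1'C1)},
#'     the reliability of the unit-weight sum score.}
#'   \item{fs_sum_correlation}{\eqn{\rho(\hat f, 1'x) =
#'     (1'\lambda) / [\sqrt{\lambda' C^{-1} \lambda}\,\sqrt{1'C1}]}, the
#'     correlation between regression factor scores and sum scores.}
#' }
#' Replacing population quantities by sample estimates gives the plug-in
#' sample versions; the function is agnostic. Regression scores are the
#' optimal linear composite, so `fs_reliability >= sum_reliability` whenever
#' `lambda` comes from a model consistent with `C`.
#'
#' @param lambda single-factor loadings.
#' @param cov item covariance matrix (positive definite).
#' @return named list with the three quantities.
#' @export
nicewander_quantities <- function(lambda, cov) {
  cov <- check_symmetric(cov)
  p <- ncol(cov)
  if (length(lambda) != p) stop_input("lambda length does not match cov")
  Cinv <- tryCatch(solve(cov), error = function(e)
    stop_numeric("covariance matrix is singular"))
  lam <- as.numeric(lambda)
  fs <- drop(t(lam) %*% Cinv %*% lam)
  total <- sum(cov)
  sum_rel <- sum(lam)^2 / total
  r <- sum(lam) / (sqrt(fs) * sqrt(total))
  list(fs_reliability = fs, sum_reliability = sum_rel, fs_sum_correlation = r)
}

#' Composite reliability from component reliabilities
#'
#' Reliability of a sum of components, each with a known reliability
#' \eqn{r_{xx,j}}: in the \emph{reduced} covariance matrix each diagonal entry
#' is replaced by the component's variance times its reliability (an estimate
#' of its true-score variance), off-diagonals are unchanged. The composite
#' reliability is the grand sum of the reduced matrix divided by the grand sum
#' of the raw matrix.
#'
#' @param cov component covariance matrix.
#' @param reliabilities per-component reliabilities in \[0, 1\].
#' @param details return intermediate sums too?
#' @return the composite reliability, or (with `details = TRUE`) a list with
#'   `raw_sum`, `reduced_sum`, `reliability`, and the `reduced` matrix.
#' @export
rae_composite_reliability <- function(cov, reliabilities, details = FALSE) {
  cov <- check_symmetric(cov)
  if (length(reliabilities) != ncol(cov))
    stop_input("one reliability per component is required")
  if (any(reliabilities < 0 | reliabilities > 1))
    stop_input("component reliabilities must lie in [0, 1]")
  reduced <- cov
  diag(reduced) <- diag(cov) * reliabilities
  raw_sum <- sum(cov); reduced_sum <- sum(reduced)
  rel <- reduced_sum / raw_sum
  if (!details) return(rel)
  list(raw_sum = raw_sum, reduced_sum = reduced_sum,
       reliability = rel, reduced = reduced)
}

#' One-stop reliability report for a single scale
#'
#' Fits a one-factor congeneric model to the covariance matrix and collects
#' coefficient alpha, omega-total, the factor-score/sum-score reliabilities
#' and correlation, and (when component reliabilities are supplied) the
#' composite reliability. All coefficients are carried at full floating
#' precision; rounding happens only when the report is rendered.
#'
#' @param moments a [sample_moments()] or covariance matrix of the scale
#'   items.
#' @param reliabilities optional per-item reliabilities for the composite
#'   reliability.
#' @param ... passed to [fit_cfa()].
#' @return object of class `reliability_report`.
#' @export
reliability_report <- function(moments, reliabilities = NULL, ...) {
  if (is.matrix(moments)) moments <- sample_moments(moments)
  S <- moments$cov
  spec <- cfa_spec(list(f = moments$labels))
  fit <- fit_cfa(moments, spec, ...)
  lam <- drop(fit$lambda)
  nw <- nicewander_quantities(lam, S)
  comp <- if (!is.null(reliabilities))
    rae_composite_reliability(S, reliabilities, details = TRUE)
  structure(list(
    alpha = coefficient_alpha(S),
    omega_total = omega_total(lam, fit$theta),
    fs_reliability = nw$fs_reliability,
    sum_reliability = nw$sum_reliability,
    fs_sum_correlation = nw$fs_sum_correlation,
    composite_reliability = if (!is.null(comp)) comp$reliability,
    composite_detail = comp,
    fit = fit,
    inputs_digest = list(p = moments$p, labels = moments$labels,
                         n = moments$n,
                         has_component_reliabilities = !is.null(reliabilities))),
    class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat("Reliability report (", x$inputs_digest$p, " items)\n", sep = "")
  fmt <- function(v) formatC(round(v, digits), digits = digits, format = "f")
  cat("  alpha                  ", fmt(x$alpha), "\n")
  cat("  omega_total            ", fmt(x$omega_total), "\n")
  cat("  factor score reliability", fmt(x$fs_reliability), "\n")
  cat("  sum score reliability  ", fmt(x$sum_reliability), "\n")
  cat("  r(factor score, sum)   ", formatC(round(x$fs_sum_correlation, 4),
                                           digits = 4, format = "f"), "\n")
  if (!is.null(x$composite_reliability)) {
    cat("  composite reliability  ", fmt(x$composite_reliability),
        sprintf("  (raw sum %.3f, reduced sum %.3f)\n",
                x$composite_detail$raw_sum, x$composite_detail$reduced_sum))
  }
  invisible(x)
}
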