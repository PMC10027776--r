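# Chi-square based fit assessment for fitted covariance-structure models.

# Invert the noncentral chi-square CDF in the noncentrality parameter:
# find ncp such that pchisq(q, df, ncp) == prob, by bisection.
ncp_solve <- function(q, df, prob, tol = 1e-6) {
  if (pchisq(q, df) < prob) return(0)        # even ncp = 0 gives too little mass
  lo <- 0; hi <- max(q * 2, 10)
  while (pchisq(q, df, ncp = hi) > prob) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pchisq(q, df, ncp = mid) > prob) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fit indices for a fitted factor model
#'
#' Computes the likelihood-ratio test statistic \eqn{\chi^2 = (n-1) F_{ML}}
#' and the usual practical fit indices. RMSEA is
#' \eqn{\sqrt{\max(0, \chi^2 - df) / (df (n-1))}} with a 90% confidence
#' interval from noncentral chi-square inversion (bisection on the
#' noncentrality parameter at probabilities .95 and .05). CFI and TLI compare
#' against the independence baseline (diagonal implied covariance matrix).
#' SRMR is the root mean square of correlation-metric residuals
#' \eqn{(s_{ij} - \sigma_{ij}) / \sqrt{s_{ii} s_{jj}}}; the primary dialect
#' includes the diagonal terms, the `"off_diagonal"` dialect drops them.
#'
#' Saturated models (df = 0) are reported as chisq 0, RMSEA 0, CFI/TLI 1.
#'
#' @param fitted a `fitted_cfa`.
#' @param moments [sample_moments()] with `n` set; defaults to the fitting
#'   moments.
#' @param srmr_type residual summary dialect.
#' @return list of class `fit_indices`: `chisq`, `df`, `p_value`, `rmsea`,
#'   `rmsea_ci90`, `cfi`, `tli`, `srmr`.
#' @export
fit_indices <- function(fitted, moments = fitted$moments,
                        srmr_type = c("with_diagonal", "off_diagonal")) {
  srmr_type <- match.arg(srmr_type)
  if (is.null(moments$n))
    stop_input("fit statistics need the sample size: supply n in sample_moments")
  n <- moments$n
  labels <- rownames(fitted$lambda)
  p <- length(labels)
  if (n < p + 1L)
    stop_input("fit statistics need n >= p + 1")
  S <- moments$cov[labels, labels, drop = FALSE]
  Sigma <- model_implied_cov(fitted)
  df <- fitted$df

  # residuals on the correlation metric, sample-SD standardized
  dd <- sqrt(diag(S))
  E <- (S - Sigma) / tcrossprod(dd)
  resid <- if (srmr_type == "with_diagonal") E[upper.tri(E, diag = TRUE)]
           else E[upper.tri(E)]
  srmr <- sqrt(mean(resid^2))

  if (df <= 0L) {
    out <- list(chisq = 0, df = 0L, p_value = NA_real_, rmsea = 0,
                rmsea_ci90 = c(0, 0), cfi = 1, tli = 1, srmr = srmr)
    class(out) <- "fit_indices"
    return(out)
  }

  chisq <- (n - 1) * fitted$discrepancy
  p_value <- pchisq(chisq, df, lower.tail = FALSE)
  rmsea <- sqrt(max(0, chisq - df) / (df * (n - 1)))
  ncp_lo <- ncp_solve(chisq, df, 0.95)
  ncp_hi <- ncp_solve(chisq, df, 0.05)
  rmsea_ci90 <- sqrt(c(ncp_lo, ncp_hi) / (df * (n - 1)))

  # independence baseline: Sigma_b = diag(S)
  f_base <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
  chisq_b <- (n - 1) * f_base
  df_b <- p * (p - 1) / 2
  num <- max(chisq - df, 0)
  cfi <- 1 - num / max(chisq - df, chisq_b - df_b, 0, na.rm = TRUE)
  if (!is.finite(cfi)) cfi <- 1
  tli <- ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)

  out <- list(chisq = chisq, df = as.integer(df), p_value = p_value,
              rmsea = rmsea, rmsea_ci90 = rmsea_ci90,
              cfi = cfi, tli = tli, srmr = srmr)
  class(out) <- "fit_indices"
  out
}

#' @export
print.fit_indices <- function(x, digits = 3, ...) {
  cat(sprintf("chisq(%d) = %.3f, p = %s\n", x$df, x$chisq,
              format.pval(x$p_value, digits = 3)))
  cat(sprintf("RMSEA = %.3f [%.3f, %.3f], CFI = %.3f, TLI = %.3f, SRMR = %.3f\n",
              x$rmsea, x$rmsea_ci90[1], x$rmsea_ci90[2], x$cfi, x$tli, x$srmr))
  invisible(x)
}
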