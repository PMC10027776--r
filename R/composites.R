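#' Weighted composite scores
#'
#' Computes per-person weighted linear combinations of item scores,
#' \eqn{Y_i = \sum_j w_j x_{ij}}. Unit weights give the plain sum score.
#' Optionally each item is standardized first to mean 0, SD 1 using the
#' supplied sample's own mean and SD (denominator \eqn{n-1}); this mirrors the
#' sample-specific standardization implicit in estimated factor scores and is
#' exposed as an explicit flag, with no attempt to infer a default for
#' mixed-scale items.
#'
#' @param items persons x items numeric matrix or data frame.
#' @param weights numeric vector, one weight per item; not all zero. Defaults
#'   to unit weights (the sum score). Weights are used as given; no
#'   normalization is applied.
#' @param standardize_first standardize each item before weighting?
#' @param na_action `"fail"` (default) errors on any missing cell among items
#'   with non-zero weight; `"impute_person_mean"` replaces a person's missing
#'   cells by that person's mean over observed weighted items.
#' @return numeric vector of composite scores, one per person.
#' @examples
#' composite_scores(matrix(1:4, 2, byrow = TRUE))      # c(3, 7)
#' @export
composite_scores <- function(items, weights = NULL,
                             standardize_first = FALSE,
                             na_action = c("fail", "impute_person_mean")) {
  na_action <- match.arg(na_action)
  x <- as_item_matrix(items)
  p <- ncol(x)
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p)
    stop_input("length of weights (", length(weights),
               ") does not match item count (", p, ")")
  if (all(weights == 0)) stop_input("weights must not all be zero")
  active <- weights != 0
  xa <- x[, active, drop = FALSE]
  if (anyNA(xa)) {
    if (na_action == "fail")
      stop_input("missing values among weighted items; set na_action = ",
                 "\"impute_person_mean\" to mean-impute per person")
    pm <- rowMeans(xa, na.rm = TRUE)
    if (anyNA(pm))
      stop_input("some persons have no observed weighted items")
    idx <- which(is.na(xa), arr.ind = TRUE)
    xa[idx] <- pm[idx[, 1L]]
  }
  if (standardize_first) {
    sds <- apply(xa, 2, sd)
    if (any(sds == 0))
      stop_input("zero item SD: cannot standardize item(s) ",
                 paste(colnames(xa)[sds == 0], collapse = ", "))
    xa <- scale(xa, center = TRUE, scale = sds)
  }
  drop(xa %*% weights[active])
}

#' Exact moments of a weighted composite
#'
#' Given item means \eqn{\mu} and covariance matrix \eqn{C}, the composite
#' \eqn{Y = w'x} has mean \eqn{w'\mu} and variance \eqn{w'Cw}. With unit
#' weights the variance is the grand sum of all elements of the covariance
#' matrix.
#'
#' @param cov item covariance matrix (symmetric).
#' @param means optional item mean vector; composite mean is `NA` if omitted.
#' @param weights per-item weights; defaults to unit weights.
#' @return list with elements `mean` and `variance`.
#' @examples
#' composite_moments(matrix(c(1, .5, .5, 1), 2))$variance  # 3
#' @export
composite_moments <- function(cov, means = NULL, weights = NULL) {
  cov <- check_symmetric(cov)
  p <- ncol(cov)
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p)
    stop_input("length of weights does not match covariance dimension")
  if (!is.null(means) && length(means) != p)
    stop_input("length of means does not match covariance dimension")
  list(mean = if (is.null(means)) NA_real_ else drop(crossprod(weights, means)),
       variance = drop(t(weights) %*% cov %*% weights))
}
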