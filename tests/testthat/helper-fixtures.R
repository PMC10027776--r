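# Fixtures built in code: the printed Holzinger-Swineford scaled-score
# covariance blocks, and generators for random test matrices.

verbal_cov <- function() {
  m <- matrix(c(1.355, 1.101, 0.899,
                1.101, 1.665, 1.018,
                0.899, 1.018, 1.200), 3, 3,
              dimnames = list(c("x06", "x07", "x09"),
                              c("x06", "x07", "x09")))
  m
}

speed_cov <- function() {
  m <- matrix(c(1.187, 0.537, 0.375,
                0.537, 1.025, 0.459,
                0.375, 0.459, 1.018), 3, 3,
              dimnames = list(c("x10", "x12", "x13"),
                              c("x10", "x12", "x13")))
  m
}

# random positive-definite covariance matrix with positive off-diagonals,
# built from a one-factor-plus-noise structure so covariances stay positive
rand_pd_positive <- function(p, seed) {
  set.seed(seed)
  lam <- runif(p, 0.4, 0.9)
  th <- runif(p, 0.3, 0.8)
  S <- tcrossprod(lam) + diag(th)
  colnames(S) <- rownames(S) <- paste0("v", seq_len(p))
  S
}

# random dense PD matrix (off-diagonals of any sign)
rand_pd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p + diag(p) * 0.5
  colnames(S) <- rownames(S) <- paste0("v", seq_len(p))
  S
}

# two-cluster covariance structure that a single factor cannot explain:
# strong within-cluster covariances, near-zero across
two_cluster_cov <- function() {
  S <- matrix(0.02, 6, 6)
  S[1:3, 1:3] <- 0.81
  S[4:6, 4:6] <- 0.64
  diag(S) <- 1
  colnames(S) <- rownames(S) <- paste0("i", 1:6)
  S
}

fit1f <- function(S, constraint = "congeneric", ...) {
  suppressWarnings(
    fit_cfa(sample_moments(S), cfa_spec(list(g = colnames(S)),
                                        constraint = constraint), ...))
}
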