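# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("sumscores_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("sumscores_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_convergence <- function(msg, best = NULL) {
  stop(structure(class = c("sumscores_convergence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), best = best)))
}

check_symmetric <- function(m, tol = 1e-8, what = "covariance matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_input(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop_input(what, " is not symmetric (tolerance ", format(tol), ")")
  (m + t(m)) / 2
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop_input("a seed is required for stochastic operations")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw n samples from N(mean, sigma) via the Cholesky factor.
rmvnorm_chol <- function(n, sigma, mean = rep(0, ncol(sigma))) {
  L <- tryCatch(chol(sigma), error = function(e)
    stop_input("covariance matrix is not positive definite"))
  z <- matrix(rnorm(n * ncol(sigma)), n, ncol(sigma))
  sweep(z %*% L, 2, mean, `+`)
}

as_item_matrix <- function(items, what = "items") {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items) || !is.numeric(items))
    stop_input(what, " must be a numeric matrix or data frame")
  if (nrow(items) < 1L || ncol(items) < 1L)
    stop_input(what, " needs at least one person and one item")
  if (is.null(colnames(items)))
    colnames(items) <- paste0("item", seq_len(ncol(items)))
  if (anyDuplicated(colnames(items)))
    stop_input(what, " has duplicated column labels")
  items
}
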