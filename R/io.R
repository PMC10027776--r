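# Readers, writers, and report rendering. CSV is the single tabular dialect
# (comma, header, UTF-8).

#' Read a persons x items table from CSV
#'
#' Expects a header row of item labels and one row per person. Missing values
#' may be encoded as empty cells or `NA`. Any other non-numeric cell is a
#' parse error naming its row and column. Row order is preserved. Lines
#' starting with `#` (provenance comments written by the `simulate`
#' subcommand) are ignored.
#'
#' @param path CSV file path.
#' @return numeric matrix with item labels as column names; `NA` marks
#'   missing cells.
#' @export
read_item_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = c("", "NA"), comment.char = "#")
  if (ncol(raw) < 1L || nrow(raw) < 1L)
    stop_input("item table needs at least one person and one item")
  out <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(NULL, names(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad))
      stop_input("non-numeric cell at row ", bad[1L], ", column '",
                 names(raw)[j], "': \"", raw[bad[1L], j], "\"")
    out[, j] <- v
  }
  out
}

#' Write composite scores to CSV
#'
#' Single score column keyed by row index.
#'
#' @param scores numeric vector.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  write.csv(data.frame(row = seq_along(scores), score = scores),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled covariance matrix from CSV
#'
#' The file carries variable labels in the header and in the first column.
#' Symmetry is enforced with tolerance 1e-8, then the matrix is exactly
#' symmetrized, so reading a transposed file gives an identical result.
#'
#' @param path CSV file path.
#' @param means optional mean vector (same order as labels).
#' @param n optional sample size.
#' @return a [sample_moments()].
#' @export
read_cov_matrix <- function(path, means = NULL, n = NULL) {
  raw <- read.csv(path, check.names = FALSE)
  labels <- as.character(raw[[1L]])
  m <- as.matrix(raw[-1L])
  if (nrow(m) != ncol(m))
    stop_input("covariance CSV is not square: ", nrow(m), " x ", ncol(m))
  if (!setequal(labels, colnames(m)))
    stop_input("row and column labels of the covariance CSV disagree")
  rownames(m) <- labels
  m <- m[colnames(m), , drop = FALSE]  # align row order with header order
  storage.mode(m) <- "double"
  sample_moments(m, means = means, n = n)
}

#' Render an analysis report
#'
#' `format = "json"` gives a schema-stable machine-readable document
#' (full floating precision); `format = "text"` gives an aligned block with
#' 3-decimal rounding applied at render time only. Warnings, when present,
#' are always surfaced.
#'
#' @param results a `reliability_report`, `structural_result`,
#'   `crossval_report`, or plain named list.
#' @param format output format.
#' @return character scalar (the document).
#' @export
render_report <- function(results, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- report_payload(results)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }
  paste(utils::capture.output(print(results)), collapse = "\n")
}

report_payload <- function(results) {
  if (inherits(results, "reliability_report")) {
    out <- list(
      alpha = results$alpha,
      omega_total = results$omega_total,
      fs_reliability = results$fs_reliability,
      sum_reliability = results$sum_reliability,
      fs_sum_correlation = results$fs_sum_correlation,
      composite_reliability = results$composite_reliability,
      inputs = results$inputs_digest,
      warnings = results$fit$warnings)
    if (!is.null(results$composite_detail))
      out$composite_sums <- list(raw = results$composite_detail$raw_sum,
                                 reduced = results$composite_detail$reduced_sum)
    return(out)
  }
  if (inherits(results, "structural_result"))
    return(list(method = results$method, estimates = results$estimates))
  if (inherits(results, "fitted_cfa"))
    return(list(constraint = results$spec$constraint,
                lambda = results$lambda, theta = results$theta,
                phi = results$phi, nu = results$nu,
                discrepancy = results$discrepancy, df = results$df,
                converged = results$converged,
                n_iterations = results$n_iterations,
                warnings = results$warnings))
  if (inherits(results, "crossval_report"))
    return(list(factor_scores = results$factor_scores,
                sum_scores = results$sum_scores,
                n_replications = results$n_replications,
                skipped = results$skipped))
  results
}

#' Holzinger--Swineford covariance fixtures
#'
#' Labeled 3 x 3 covariance matrices of the scaled verbal tests (paragraph
#' comprehension, sentence completion, word meaning) and speed tests
#' (addition, counting dots, straight-curved capitals), shipped as plain CSV
#' under `inst/extdata`.
#'
#' @param block `"verbal"` or `"speed"`.
#' @return a [sample_moments()].
#' @export
hs_cov <- function(block = c("verbal", "speed")) {
  block <- match.arg(block)
  read_cov_matrix(system.file("extdata",
                              paste0("hs_", block, "_cov.csv"),
                              package = "sumscores", mustWork = TRUE))
}

#' Holzinger--Swineford per-test reliabilities
#'
#' Published reliability estimates of the individual tests (averaged over the
#' two schools), used for the composite reliability of the verbal and speed
#' sums.
#'
#' @param block `"verbal"` or `"speed"`.
#' @return named numeric vector of per-test reliabilities.
#' @export
hs_reliabilities <- function(block = c("verbal", "speed")) {
  block <- match.arg(block)
  tab <- read.csv(system.file("extdata", "hs_reliabilities.csv",
                              package = "sumscores", mustWork = TRUE))
  sel <- tab[tab$block == block, ]
  setNames(sel$r_xx, sel$variable)
}

#' Holzinger--Swineford six-test scaled-score moments
#'
#' Rebuilds the 6 x 6 covariance matrix of the scaled test scores from the
#' published correlations and standard deviations (both rounded to two
#' decimals, so downstream estimates carry that rounding).
#'
#' @return a [sample_moments()] for x06, x07, x09, x10, x12, x13.
#' @export
hs_scaled_moments <- function() {
  tab <- read.csv(system.file("extdata", "hs_scaled_summary.csv",
                              package = "sumscores", mustWork = TRUE))
  cors <- as.matrix(read.csv(system.file("extdata", "hs_scaled_cor.csv",
                                         package = "sumscores",
                                         mustWork = TRUE), row.names = 1))
  cors <- check_symmetric(cors, what = "correlation matrix")
  sds <- setNames(tab$sd, tab$variable)[colnames(cors)]
  cov <- cors * tcrossprod(sds)
  dimnames(cov) <- dimnames(cors)
  sample_moments(cov, means = setNames(tab$mean, tab$variable)[colnames(cors)])
}
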