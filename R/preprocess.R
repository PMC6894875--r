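#' Log2-transform a non-negative expression matrix
#'
#' Normalized RNA-seq abundance estimates can be exactly zero, so a
#' pseudocount (default 1) is added before taking logs: `log2(x + 1)`.
#'
#' @param raw non-negative numeric matrix, genes x samples, with gene ids as
#'   row names and sample ids as column names.
#' @param pseudocount non-negative offset added before the log (default 1).
#' @return Matrix of the same shape on the log2 scale.
#' @examples
#' log2_transform(matrix(c(0, 7, 1023, 3), 2, 2))
#' @export
log2_transform <- function(raw, pseudocount = 1) {
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  bad <- which(raw < 0, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0) {
    stopf("negative expression value at row %d, column %d (%g)",
          bad[1, 1], bad[1, 2], raw[bad[1, 1], bad[1, 2]])
  }
  if (anyNA(raw)) stopf("expression matrix contains missing values")
  log2(raw + pseudocount)
}

#' Remove constant and lowly expressed genes
#'
#' Two filtering rules are applied in order. First, genes whose standard
#' deviation across samples is exactly 0 are removed. Second, a gene is
#' removed when more than `low_expr_sample_frac` of its samples lie below
#' the `percentile`-th percentile of the pooled value distribution of the
#' remaining matrix (all entries pooled; percentile computed with the usual
#' linear-interpolation convention of [stats::quantile()], type 7). A gene
#' failing both rules is counted once, under the zero-SD rule.
#'
#' @param X numeric matrix, genes x samples, log scale.
#' @param low_expr_sample_frac fraction of samples that must be below the
#'   pooled percentile before a gene is dropped; strictly greater than
#'   (default 0.75).
#' @param percentile percentile (0-100) of the pooled value distribution
#'   used as the low-expression threshold (default 15).
#' @return A list with `expr`, the filtered matrix, and `report`, a
#'   `filter_report` with fields `n_input_genes`, `n_removed_zero_sd`,
#'   `n_removed_low_expression`, `n_retained`.
#' @export
filter_genes <- function(X, low_expr_sample_frac = 0.75, percentile = 15) {
  if (!is.matrix(X) || nrow(X) == 0 || ncol(X) == 0) {
    stopf("X must be a non-empty genes x samples matrix")
  }
  n_input <- nrow(X)
  sds <- apply(X, 1, sd)
  zero_sd <- sds == 0
  X1 <- X[!zero_sd, , drop = FALSE]
  if (nrow(X1) == 0) stopf("all %d genes removed by the zero-SD rule", n_input)
  thr <- quantile(X1, probs = percentile / 100, names = FALSE, type = 7)
  frac_below <- rowMeans(X1 < thr)
  low <- frac_below > low_expr_sample_frac
  out <- X1[!low, , drop = FALSE]
  if (nrow(out) == 0) {
    stopf("all genes removed (zero-SD: %d, low expression: %d)",
          sum(zero_sd), sum(low))
  }
  report <- structure(list(n_input_genes = n_input,
                           n_removed_zero_sd = sum(zero_sd),
                           n_removed_low_expression = sum(low),
                           n_retained = nrow(out)),
                      class = "filter_report")
  list(expr = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("gene filter: %d input, %d removed (zero SD), ",
                     "%d removed (low expression), %d retained\n"),
              x$n_input_genes, x$n_removed_zero_sd,
              x$n_removed_low_expression, x$n_retained))
  invisible(x)
}

#' Write a filter report as JSON
#' @param report a `filter_report` from [filter_genes()].
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read or write a gene-by-sample expression matrix
#'
#' Plain-text matrices with genes as rows: the first column holds gene
#' identifiers and the header row holds sample identifiers. The delimiter
#' is inferred from the file extension (`.csv` -> comma, otherwise tab).
#'
#' @param path file path.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) stopf("duplicated gene ids in %s", path)
  X <- as.matrix(d[, -1, drop = FALSE])
  if (anyDuplicated(colnames(X))) stopf("duplicated sample ids in %s", path)
  storage.mode(X) <- "double"
  if (anyNA(X)) stopf("missing values in expression matrix %s", path)
  rownames(X) <- ids
  X
}

#' @rdname read_expression
#' @param X genes x samples matrix with dimnames.
#' @export
write_expression <- function(X, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
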