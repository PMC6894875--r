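#' Selection and feature-extraction specifications
#'
#' Each clustering approach pairs a clustering method with one of five
#' canonical selection/extraction methods: the top 100 or top 1000 genes by
#' standard deviation, all genes, or the first 5 or 30 principal components.
#' Arbitrary `N`/`M` are allowed beyond the canonical five.
#'
#' @param kind one of `"top_sd"`, `"all_genes"`, `"pca"`.
#' @param N number of genes to keep (for `top_sd`).
#' @param M number of principal components (for `pca`).
#' @return A list of class `"selection_spec"`.
#' @export
selection_spec <- function(kind = c("top_sd", "all_genes", "pca"),
                           N = NULL, M = NULL) {
  kind <- match.arg(kind)
  if (kind == "top_sd" && (is.null(N) || N < 1)) stopf("top_sd requires N >= 1")
  if (kind == "pca" && (is.null(M) || M < 1)) stopf("pca requires M >= 1")
  structure(list(kind = kind, N = N, M = M), class = "selection_spec")
}

#' @rdname selection_spec
#' @return `canonical_selections()`: the named list of the five canonical
#'   specifications (`top100`, `top1000`, `all`, `pc5`, `pc30`).
#' @export
canonical_selections <- function() {
  list(top100  = selection_spec("top_sd", N = 100),
       top1000 = selection_spec("top_sd", N = 1000),
       all     = selection_spec("all_genes"),
       pc5     = selection_spec("pca", M = 5),
       pc30    = selection_spec("pca", M = 30))
}

# Parse "top100" / "pc5" style strings into selection_spec objects.
parse_selection <- function(x) {
  if (inherits(x, "selection_spec")) return(x)
  can <- canonical_selections()
  if (is.character(x) && x %in% names(can)) return(can[[x]])
  if (is.character(x) && grepl("^top[0-9]+$", x)) {
    return(selection_spec("top_sd", N = as.integer(sub("top", "", x))))
  }
  if (is.character(x) && grepl("^pc[0-9]+$", x)) {
    return(selection_spec("pca", M = as.integer(sub("pc", "", x))))
  }
  stopf("unknown selection specification: %s", deparse(x))
}

#' Select the N genes with the highest standard deviation
#'
#' Standard deviations use the n-1 denominator; ties are broken by original
#' row order (first occurrence wins), so the result is deterministic. The
#' matrix is transposed to samples x features for clustering.
#'
#' @param X genes x samples matrix.
#' @param N number of genes to keep, `1 <= N <= nrow(X)`.
#' @return samples x features numeric matrix.
#' @export
select_top_sd <- function(X, N) {
  if (N < 1 || N > nrow(X)) {
    stopf("N must lie in 1..%d (got %d)", nrow(X), N)
  }
  sds <- apply(X, 1, sd)
  ord <- order(-sds, seq_along(sds))[seq_len(N)]
  t(X[sort(ord), , drop = FALSE])
}

#' Principal-component scores of the samples
#'
#' Samples are the observations and genes the variables; variables are
#' centered but not scaled by default (as in [stats::prcomp()]). Score
#' columns are ordered by non-increasing explained variance and signs are
#' fixed so that each component's largest-magnitude loading is positive,
#' making results reproducible across platforms.
#'
#' @param X genes x samples matrix.
#' @param M number of leading components, `1 <= M <= min(samples - 1, genes)`.
#' @param scale. also scale variables to unit variance (default `FALSE`).
#' @return samples x M matrix of PC scores, columns `PC1..PCM`.
#' @export
pca_features <- function(X, M, scale. = FALSE) {
  n <- ncol(X)
  max_rank <- min(n - 1L, nrow(X))
  if (M < 1 || M > max_rank) {
    stopf("M must lie in 1..%d for %d samples and %d genes (got %d)",
          max_rank, n, nrow(X), M)
  }
  pc <- prcomp(t(X), center = TRUE, scale. = scale.)
  scores <- pc$x[, seq_len(M), drop = FALSE]
  for (j in seq_len(M)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(X)
  scores
}

#' Apply a selection specification to an expression matrix
#'
#' @param X genes x samples matrix.
#' @param spec a [selection_spec()] or a canonical name such as `"top100"`.
#' @return samples x features matrix.
#' @export
apply_selection <- function(X, spec) {
  spec <- parse_selection(spec)
  switch(spec$kind,
         top_sd = select_top_sd(X, spec$N),
         all_genes = t(X),
         pca = pca_features(X, spec$M))
}
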