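#' Cluster partitions
#'
#' A `partition` is an integer vector of cluster labels in `1..k`, named by
#' sample identifier. Clustering methods return partitions with labels
#' canonicalised by order of first appearance; a partition in which some of
#' the `k` clusters are empty is flagged degenerate rather than rejected,
#' because methods such as affinity propagation or a self-organizing map can
#' collapse on pathological data and downstream agreement scores are still
#' well defined.
#'
#' @param labels vector of cluster labels; coerced to integers `1..k` by
#'   first appearance unless already such.
#' @param sample_ids character vector of sample identifiers (defaults to
#'   `names(labels)`).
#' @param k number of clusters the partition was requested to have; defaults
#'   to the number of distinct labels.
#' @return An integer vector of class `"partition"` with attributes `k` and
#'   `degenerate`.
#' @examples
#' p <- partition(c(1, 1, 2, 2), sample_ids = paste0("s", 1:4))
#' attr(p, "k")
#' @export
partition <- function(labels, sample_ids = NULL, k = NULL) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- relabel_first_appearance(as.character(labels))
  }
  sample_ids <- sample_ids %||% names(labels)
  labels <- as.integer(labels)
  if (anyNA(labels)) stopf("partition labels contain NA")
  k <- as.integer(k %||% max(labels))
  if (any(labels < 1L | labels > k)) {
    stopf("partition labels must lie in 1..k (k = %d)", k)
  }
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != length(labels)) {
      stopf("sample_ids length (%d) does not match labels (%d)",
            length(sample_ids), length(labels))
    }
    if (anyDuplicated(sample_ids)) stopf("duplicated sample ids in partition")
    names(labels) <- sample_ids
  }
  degenerate <- length(unique(labels)) < k
  structure(labels, k = k, degenerate = degenerate, class = "partition")
}

#' @rdname partition
#' @param x object to coerce (vector, factor, or partition).
#' @export
as_partition <- function(x, sample_ids = NULL, k = NULL) {
  if (inherits(x, "partition") && is.null(sample_ids) && is.null(k)) return(x)
  partition(unclass(x), sample_ids = sample_ids %||% names(x), k = k)
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition of %d samples into k = %d clusters%s\n",
              length(x), attr(x, "k"),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate)" else ""))
  sizes <- tabulate(unclass(x), nbins = attr(x, "k"))
  cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a partition to a subset of samples
#'
#' Used, e.g., to score a mixed-sex clustering separately on the female and
#' male subsets. Labels are kept as-is; the result may be degenerate.
#'
#' @param p a [partition()] with sample ids.
#' @param ids sample identifiers to keep.
#' @export
subset_partition <- function(p, ids) {
  if (is.null(names(p))) stopf("partition has no sample ids to subset by")
  missing <- setdiff(ids, names(p))
  if (length(missing)) {
    stopf("samples not in partition: %s", paste(missing, collapse = ", "))
  }
  partition(relabel_first_appearance(unclass(p)[match(ids, names(p))]),
            sample_ids = ids)
}

# Align two partitions on a common sample ordering. If both carry sample ids
# they must name the same set; B is reordered to A's order. Unnamed
# partitions must simply have equal length.
align_partitions <- function(A, B) {
  a <- as_partition(A); b <- as_partition(B)
  if (!is.null(names(a)) && !is.null(names(b))) {
    only_a <- setdiff(names(a), names(b))
    only_b <- setdiff(names(b), names(a))
    if (length(only_a) || length(only_b)) {
      stopf("partitions cover different samples; only in A: {%s}; only in B: {%s}",
            paste(only_a, collapse = ","), paste(only_b, collapse = ","))
    }
    b <- b[match(names(a), names(b))]
  } else if (length(a) != length(b)) {
    stopf("partitions have different sizes (%d vs %d)", length(a), length(b))
  }
  list(a = as.integer(a), b = as.integer(b))
}

#' Read or write a partition as two-column TSV
#'
#' The on-disk format is `sample_id<TAB>cluster` with a header row.
#'
#' @param p a partition with sample ids.
#' @param path file path.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"), !is.null(names(p)))
  write.table(data.frame(sample_id = names(p), cluster = as.integer(p)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  partition(d$cluster, sample_ids = as.character(d$sample_id))
}
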