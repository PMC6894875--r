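#' Contingency table of two partitions
#'
#' Cell `n_ij` counts the samples that fall in cluster `i` of `B` (rows)
#' and cluster `j` of `A` (columns). Margins (`row_sums`, `col_sums`) and
#' the total `n` are attached.
#'
#' @param A,B partitions (or label vectors) over identical sample sets;
#'   when both carry sample ids, `B` is aligned to `A`'s ordering.
#' @return An integer matrix of class `"contingency_table"` with attributes
#'   `row_sums`, `col_sums` and `n`.
#' @export
contingency <- function(A, B) {
  al <- align_partitions(A, B)
  tab <- table(B = al$b, A = al$a)
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  structure(out, row_sums = rowSums(out), col_sums = colSums(out),
            n = sum(out), class = c("contingency_table", class(out)))
}

# Are the two partitions behind a contingency table identical up to
# relabeling? True iff every row and every column has at most one nonzero.
is_relabel_identical <- function(tab) {
  all(rowSums(tab > 0) <= 1) && all(colSums(tab > 0) <= 1)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}
#'  {\frac12\left[\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}\right] -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}}
#' where `n_ij` are contingency counts and `a_i`, `b_j` the margins. The
#' index is 1 iff the partitions are identical up to relabeling, has
#' expected value 0 under random labelings with fixed margins, and may be
#' negative. Binomial coefficients are accumulated before the single final
#' division so no cancellation occurs. When the denominator is exactly 0
#' (both partitions all singletons, or both one single cluster) the value
#' is 1 if the partitions coincide up to relabeling and 0 otherwise; this
#' convention is reported via the `degenerate` attribute.
#'
#' @param A,B partitions (or label vectors) over the same `n >= 2` samples.
#' @return A numeric scalar with attributes `measure = "ARI"`, `n`, and
#'   `degenerate`.
#' @examples
#' ari(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1
#' ari(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
ari <- function(A, B) {
  tab <- contingency(A, B)
  n <- attr(tab, "n")
  if (n < 2) stopf("ARI requires at least 2 samples")
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(as.numeric(tab)))
  sum_a <- sum(choose2(as.numeric(attr(tab, "col_sums"))))
  sum_b <- sum(choose2(as.numeric(attr(tab, "row_sums"))))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    value <- if (is_relabel_identical(tab)) 1 else 0
    degenerate <- TRUE
  } else {
    value <- (sum_ij - expected) / denom
    degenerate <- FALSE
  }
  structure(value, measure = "ARI", n = n, degenerate = degenerate)
}

#' Average pairwise adjusted Rand index
#'
#' Mean ARI over all unordered pairs of distinct partitions; used to
#' quantify how similarly a set of clustering approaches partitions the
#' same samples, independent of any gold standard.
#'
#' @param partitions list of at least 2 partitions over identical samples.
#' @return Numeric scalar with attribute `measure = "apARI"`.
#' @export
apari <- function(partitions) {
  m <- length(partitions)
  if (m < 2) stopf("apARI requires at least 2 partitions")
  pairs <- combn(m, 2)
  vals <- apply(pairs, 2, function(ij) {
    as.numeric(ari(partitions[[ij[1]]], partitions[[ij[2]]]))
  })
  structure(mean(vals), measure = "apARI", n_pairs = ncol(pairs))
}

#' Variation of information between two partitions
#'
#' The entropy-based distance `VI = H(A) + H(B) - 2 I(A; B)`, computed from
#' the contingency table with natural logarithms. VI is a metric on
#' partitions: non-negative, symmetric, zero iff the partitions coincide up
#' to relabeling, and satisfying the triangle inequality.
#'
#' @param A,B partitions over identical samples.
#' @return Numeric scalar with attribute `measure = "VI"`.
#' @export
variation_of_information <- function(A, B) {
  tab <- contingency(A, B)
  n <- attr(tab, "n")
  p <- tab / n
  pa <- attr(tab, "col_sums") / n
  pb <- attr(tab, "row_sums") / n
  ent <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pb[i] * pa[j]))
    }
  }
  vi <- ent(pa) + ent(pb) - 2 * mi
  structure(max(0, vi), measure = "VI", n = n)
}
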