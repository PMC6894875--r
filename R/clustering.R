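#' Pairwise sample dissimilarities
#'
#' Supported metrics: `"manhattan"` (sum of absolute coordinate
#' differences), `"abs_pearson"` (`1 - |rho|`, where `rho` is the Pearson
#' correlation between the two samples' feature vectors, so perfectly
#' correlated or anti-correlated samples are at distance 0), and
#' `"euclidean"`.
#'
#' @param F samples x features matrix.
#' @param metric one of `"manhattan"`, `"abs_pearson"`, `"euclidean"`.
#' @return A [stats::dist] object with attribute `metric`.
#' @export
dissimilarity <- function(F, metric = c("manhattan", "abs_pearson",
                                        "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(F) < 2) stopf("need at least 2 samples")
  if (metric == "abs_pearson") {
    if (ncol(F) < 2) stopf("correlation distance needs >= 2 features")
    sds <- apply(F, 1, sd)
    if (any(sds == 0)) {
      stopf("zero-variance feature vector for sample(s): %s",
            paste(rownames(F)[sds == 0] %||% which(sds == 0), collapse = ", "))
    }
    D <- as.dist(1 - abs(cor(t(F))))
  } else {
    D <- dist(F, method = metric)
  }
  attr(D, "metric") <- metric
  D
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with Ward's linkage, with the dendrogram cut
#' into `k` clusters. Two Ward variants exist in common use: `"ward.D2"`
#' (the default here) squares the dissimilarities inside the
#' Lance-Williams update, which is the textbook Ward criterion when the
#' input is a plain distance; `"ward.D"` applies the update to the
#' dissimilarities as given.
#'
#' @param D a [stats::dist] or [dissimilarity()] object.
#' @param k number of clusters (default 2).
#' @param variant `"ward.D2"` or `"ward.D"`.
#' @return A [partition()]; labels follow order of first appearance.
#' @export
hclust_ward <- function(D, k = 2, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  D <- as.dist(D)
  n <- attr(D, "Size")
  if (k > n) stopf("k (%d) exceeds number of samples (%d)", k, n)
  hc <- hclust(D, method = variant)
  labs <- cutree(hc, k = k)
  partition(relabel_first_appearance(labs),
            sample_ids = attr(D, "Labels"), k = k)
}

# Complete-linkage variant used by the simulation study.
hclust_complete <- function(D, k = 2) {
  D <- as.dist(D)
  hc <- hclust(D, method = "complete")
  labs <- cutree(hc, k = k)
  partition(relabel_first_appearance(labs),
            sample_ids = attr(D, "Labels"), k = k)
}

#' Multi-start Lloyd k-means clustering
#'
#' Runs [stats::kmeans()] with Lloyd iterations from `n_starts` random
#' initializations (initial centers drawn from the sample rows) and keeps
#' the run with the smallest within-cluster sum of squares. Starts that
#' collapse to an empty cluster are repaired by re-seeding the offending
#' center with the sample farthest from its assigned center.
#'
#' @param F samples x features matrix.
#' @param k number of clusters (default 2).
#' @param n_starts random starts (default 10).
#' @param seed integer seed.
#' @param iter_max Lloyd iteration cap per start (default 100).
#' @return A [partition()] with attributes `objective` (the minimized
#'   within-cluster sum of squares) and `start_objectives` (one per start).
#' @export
kmeans_cluster <- function(F, k = 2, n_starts = 10, seed = 1L,
                           iter_max = 100) {
  n <- nrow(F)
  n_distinct <- nrow(unique(F))
  if (k > n_distinct) {
    stopf("k (%d) exceeds number of distinct sample rows (%d)", k, n_distinct)
  }
  set.seed(seed)
  best <- NULL
  objectives <- numeric(0)
  for (s in seq_len(n_starts)) {
    centers <- F[sample.int(n, k), , drop = FALSE]
    fit <- NULL
    for (attempt in 1:20) {
      fit <- tryCatch(
        suppressWarnings(kmeans(F, centers = centers, iter.max = iter_max,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      # empty-cluster repair: replace the worst center with the farthest
      # sample from its current center, then retry this start
      if (!is.null(fit)) {
        far <- which.max(rowSums((F - fit$centers[fit$cluster, ,
                                                  drop = FALSE])^2))
      } else {
        far <- sample.int(n, 1)
      }
      centers <- F[unique(c(far, sample.int(n, k - 1))), , drop = FALSE]
      if (nrow(centers) < k) centers <- F[sample.int(n, k), , drop = FALSE]
    }
    if (is.null(fit)) next
    objectives <- c(objectives, fit$tot.withinss)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stopf("k-means failed in all %d starts", n_starts)
  p <- partition(relabel_first_appearance(best$cluster),
                 sample_ids = rownames(F), k = k)
  attr(p, "objective") <- best$tot.withinss
  attr(p, "start_objectives") <- objectives
  p
}

#' Self-organizing-map clustering on a 1 x m node grid
#'
#' Online SOM training: codebook vectors are initialized from randomly
#' chosen samples and updated for `rlen` presentations of the data set
#' (samples drawn at random each step) with a learning rate decaying
#' linearly from `alpha[1]` to `alpha[2]`. With a 2 x 1 grid the
#' neighborhood collapses to winner-only updates. Training is repeated
#' `restarts` times and the run with the lowest within-variation (sum of
#' squared sample-to-assigned-node distances) is kept; each sample joins
#' the cluster of its nearest codebook vector.
#'
#' @param F samples x features matrix.
#' @param grid_nodes number of map nodes (default 2, the 2 x 1 grid).
#' @param rlen number of presentations of the complete data set
#'   (default 1000).
#' @param restarts independent training runs (default 10).
#' @param seed integer seed.
#' @param alpha learning-rate range, linear decay (default `c(0.05, 0.01)`).
#' @return A [partition()] with attributes `objective` (within-variation of
#'   the kept run) and `codebook` (nodes x features matrix).
#' @export
som_cluster <- function(F, grid_nodes = 2, rlen = 1000, restarts = 10,
                        seed = 1L, alpha = c(0.05, 0.01)) {
  n <- nrow(F)
  if (n < 2) stopf("need at least 2 samples")
  set.seed(seed)
  storage.mode(F) <- "double"
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- F[sample.int(n, grid_nodes), , drop = FALSE]
    order <- sample.int(n, rlen * n, replace = TRUE)
    fit <- som_train_cpp(F, init, order, alpha[1], alpha[2])
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  p <- partition(relabel_first_appearance(best$assignment),
                 sample_ids = rownames(F), k = grid_nodes)
  attr(p, "objective") <- best$objective
  attr(p, "codebook") <- best$codebook
  p
}

#' Affinity propagation targeting a fixed number of clusters
#'
#' Standard responsibility/availability message passing with damping on
#' similarities defined as negative (unsquared) Euclidean distances between
#' sample rows, with no noise jitter, so the algorithm is deterministic.
#' The shared exemplar preference (the similarity-matrix diagonal) is not a
#' free parameter here: it is searched by bisection on
#' `[min(similarity), median(similarity)]` until exactly `k` exemplars
#' emerge.
#'
#' @param F samples x features matrix.
#' @param k desired number of exemplars (default 2).
#' @param damping message damping factor `lam` (default 0.9).
#' @param maxits maximum message-passing iterations (default 2000).
#' @param convits iterations of unchanged exemplar set declaring
#'   convergence (default 200).
#' @param squared use negative squared Euclidean similarities instead
#'   (default `FALSE`).
#' @param max_bisect bisection step cap (default 50).
#' @return A [partition()] with attribute `exemplars` (sample indices).
#' @export
affinity_propagation_k <- function(F, k = 2, damping = 0.9, maxits = 2000,
                                   convits = 200, squared = FALSE,
                                   max_bisect = 50) {
  n <- nrow(F)
  if (n < k) stopf("need at least k = %d samples (got %d)", k, n)
  if (k == n) {
    # every sample is its own exemplar
    p <- partition(seq_len(n), sample_ids = rownames(F), k = k)
    attr(p, "exemplars") <- seq_len(n)
    return(p)
  }
  d <- as.matrix(dist(F))
  S <- if (squared) -d^2 else -d
  off <- S[upper.tri(S)]
  lo <- min(off); hi <- median(off)
  run <- function(pref) {
    diag(S) <- pref
    ap_messages_cpp(S, damping, maxits, convits)
  }
  count_k <- function(res) length(res$exemplars)
  res_lo <- run(lo); res_hi <- run(hi)
  # the minimum similarity often still yields more than k exemplars; extend
  # the lower preference bound geometrically until k is bracketed
  span <- max(hi - lo, abs(lo), 1)
  for (ext in 1:20) {
    if (count_k(res_lo) <= k) break
    lo <- lo - span
    span <- span * 2
    res_lo <- run(lo)
  }
  res <- NULL
  if (count_k(res_lo) == k) res <- res_lo
  else if (count_k(res_hi) == k) res <- res_hi
  else if (count_k(res_lo) > k || count_k(res_hi) < k) {
    stopf(paste0("affinity propagation: %d clusters not bracketed by the ",
                 "preference range (K = %d at the lower bound, ",
                 "%d at the median); widen the bounds"),
          k, count_k(res_lo), count_k(res_hi))
  } else {
    for (step in seq_len(max_bisect)) {
      mid <- (lo + hi) / 2
      res_mid <- run(mid)
      km <- count_k(res_mid)
      if (km == k) { res <- res_mid; break }
      if (km < k) lo <- mid else hi <- mid
    }
    if (is.null(res)) {
      stopf(paste0("affinity propagation failed to reach exactly %d ",
                   "exemplars in %d bisection steps; widen the preference ",
                   "bounds"), k, max_bisect)
    }
  }
  ex <- res$exemplars
  # assign every sample to the exemplar with maximal similarity
  diag(S) <- 0
  sim_to_ex <- S[, ex, drop = FALSE]
  assign <- ex[max.col(sim_to_ex, ties.method = "first")]
  assign[ex] <- ex
  p <- partition(relabel_first_appearance(assign),
                 sample_ids = rownames(F), k = k)
  attr(p, "exemplars") <- ex
  p
}

#' Hard Euclidean least-squares consensus partition
#'
#' Finds a single hard partition minimizing the total squared Euclidean
#' distance between its membership matrix and each input partition's
#' membership matrix after optimal per-input label matching. Labels are
#' matched exactly: for `k = 2` both label swaps are tried, for general `k`
#' all label permutations are enumerated (k <= 8). The fixed point iterates
#' relabel-then-reassign until the partition stops changing; the search is
#' restarted from each input partition plus `n_starts` random partitions,
#' and the best objective is kept.
#'
#' @param partitions list of [partition()]s over identical sample sets.
#' @param k number of consensus clusters (default 2).
#' @param n_starts additional random restarts (default 10).
#' @param seed integer seed for the random restarts.
#' @param max_iter fixed-point iteration cap (default 100).
#' @return A [partition()] with attribute `objective`, the minimized sum of
#'   squared membership distances.
#' @export
consensus_partition <- function(partitions, k = 2, n_starts = 10, seed = 1L,
                                max_iter = 100) {
  if (length(partitions) < 2) stopf("need at least 2 input partitions")
  ids <- names(as_partition(partitions[[1]]))
  mats <- lapply(partitions, function(p) {
    al <- align_partitions(partitions[[1]], p)
    al$b
  })
  n <- length(mats[[1]])
  if (k > 8) stopf("label matching enumerates permutations; k <= 8 required")
  perms <- perms_of(k)

  align_to <- function(ref, lab) {
    # best permutation of lab's labels to agree with ref
    best_agree <- -1L; best <- lab
    for (p in seq_len(nrow(perms))) {
      cand <- perms[p, ][lab]
      agree <- sum(cand == ref)
      if (agree > best_agree) { best_agree <- agree; best <- cand }
    }
    best
  }

  objective_of <- function(ref) {
    # sum over inputs of squared Frobenius distance between hard membership
    # matrices after optimal matching = 2 * (n - best agreement)
    sum(vapply(mats, function(lab) {
      best_agree <- max(vapply(seq_len(nrow(perms)), function(p) {
        sum(perms[p, ][lab] == ref)
      }, integer(1)))
      2 * (n - best_agree)
    }, numeric(1)))
  }

  refine <- function(start) {
    cur <- start
    for (it in seq_len(max_iter)) {
      aligned <- vapply(mats, align_to, integer(n), ref = cur)
      votes <- apply(aligned, 1, function(row) tabulate(row, nbins = k))
      new <- apply(votes, 2, which.max)  # ties -> smallest label
      if (all(new == cur)) break
      cur <- new
    }
    cur
  }

  set.seed(seed)
  starts <- c(mats, lapply(seq_len(n_starts), function(i) {
    sample.int(k, n, replace = TRUE)
  }))
  best <- NULL; best_obj <- Inf
  for (st in starts) {
    st <- pmin(st, k)
    cand <- refine(st)
    obj <- objective_of(cand)
    if (obj < best_obj) { best_obj <- obj; best <- cand }
  }
  p <- partition(relabel_first_appearance(best), sample_ids = ids, k = k)
  attr(p, "objective") <- best_obj
  p
}

# All permutations of 1..k as a matrix, one per row.
perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}

#' Run one clustering method by name
#'
#' Dispatcher used by the evaluation designs. `"cluster_ensemble"` is not
#' dispatched here because it consumes the other five methods' partitions;
#' see [run_grid()].
#'
#' @param F samples x features matrix.
#' @param method one of `"hclust_manhattan"`, `"hclust_correlation"`,
#'   `"kmeans"`, `"som"`, `"affinity_propagation"`.
#' @param k number of clusters (default 2).
#' @param seed integer seed for stochastic methods.
#' @return A [partition()].
#' @export
cluster_samples <- function(F, method, k = 2, seed = 1L) {
  switch(method,
         hclust_manhattan = hclust_ward(dissimilarity(F, "manhattan"), k),
         hclust_correlation = hclust_ward(dissimilarity(F, "abs_pearson"), k),
         kmeans = kmeans_cluster(F, k, n_starts = 10, seed = seed),
         som = som_cluster(F, grid_nodes = k, rlen = 1000, restarts = 10,
                           seed = seed),
         affinity_propagation = affinity_propagation_k(F, k),
         stopf("unknown clustering method: %s", method))
}
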