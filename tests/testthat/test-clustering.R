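test_that("dissimilarities match hand values and a brute-force loop", {
  F <- rbind(x = c(0, 0), y = c(1, 2))
  expect_equal(as.matrix(dissimilarity(F, "manhattan"))["x", "y"], 3)

  x <- c(1, 3, 2, 5)
  F2 <- rbind(a = x, b = 2 * x + 1)  # perfectly correlated samples
  expect_equal(as.matrix(dissimilarity(F2, "abs_pearson"))["a", "b"], 0)

  set.seed(31)
  F3 <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("s", 1:4), NULL))
  for (metric in c("manhattan", "euclidean", "abs_pearson")) {
    D <- as.matrix(dissimilarity(F3, metric))
    oracle <- matrix(0, 4, 4)
    for (i in 1:4) {
      for (j in 1:4) {
        oracle[i, j] <- switch(metric,
          manhattan = sum(abs(F3[i, ] - F3[j, ])),
          euclidean = sqrt(sum((F3[i, ] - F3[j, ])^2)),
          abs_pearson = 1 - abs(cor(F3[i, ], F3[j, ])))
      }
    }
    expect_equal(unname(D), oracle, tolerance = 1e-12)
    expect_true(all(diag(unname(D)) == 0))
  }
  F4 <- rbind(s1 = c(1, 1, 1), s2 = c(0, 1, 2))
  expect_error(dissimilarity(F4, "abs_pearson"), "s1")
})

test_that("Ward clustering recovers planted blobs and handles edge cases", {
  blobs <- make_blobs(seed = 101)
  p <- hclust_ward(dissimilarity(blobs$F, "manhattan"), k = 2)
  expect_equal(as.numeric(ari(blobs$gold, p)), 1)
  expect_equal(attr(p, "k"), 2L)
  expect_equal(length(unique(as.integer(p))), 2L)

  F2 <- blobs$F[1:2, ]
  p2 <- hclust_ward(dissimilarity(F2, "euclidean"), k = 2)
  expect_equal(sort(unname(as.integer(p2))), c(1L, 2L))
  expect_error(hclust_ward(dissimilarity(F2, "euclidean"), k = 3), "exceeds")
})

test_that("Ward merges agree with a naive sum-of-squares agglomeration", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:12, 1)
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(paste0("s", seq_len(n)), NULL))
    D <- dissimilarity(X, "euclidean")
    for (k in 2:4) {
      ours <- hclust_ward(D, k = k, variant = "ward.D2")
      oracle <- naive_ward_partition(X, k)
      expect_equal(as.numeric(ari(ours, partition(oracle))), 1)
    }
  }
})

test_that("k-means attains the multi-start minimum and recovers blobs", {
  F <- rbind(a = c(0, 0), b = c(5, 5))
  p <- kmeans_cluster(F, k = 2, n_starts = 3, seed = 1)
  expect_equal(sort(unname(as.integer(p))), c(1L, 2L))
  expect_equal(attr(p, "objective"), 0)

  blobs <- make_blobs(seed = 102)
  p2 <- kmeans_cluster(blobs$F, k = 2, seed = 4)
  expect_equal(as.numeric(ari(blobs$gold, p2)), 1)
  expect_true(attr(p2, "objective") <= min(attr(p2, "start_objectives")) +
                1e-8)
  expect_error(kmeans_cluster(rbind(F, a2 = c(0, 0)), k = 3), "distinct")
})

test_that("the SOM assigns samples to their nearest codebook vector", {
  blobs <- make_blobs(seed = 103)
  p <- som_cluster(blobs$F, seed = 5)
  expect_equal(as.numeric(ari(blobs$gold, p)), 1)
  W <- attr(p, "codebook")
  d2 <- function(x, w) sum((x - w)^2)
  raw_assign <- apply(blobs$F, 1, function(x) {
    which.min(c(d2(x, W[1, ]), d2(x, W[2, ])))
  })
  expect_equal(unname(as.integer(p)),
               match(raw_assign, unique(raw_assign)))
})

test_that("affinity propagation elects one exemplar per blob", {
  F <- rbind(a = c(0, 0), b = c(4, 4))
  p <- affinity_propagation_k(F, k = 2)
  expect_equal(sort(attr(p, "exemplars")), c(1L, 2L))
  expect_equal(sort(unname(as.integer(p))), c(1L, 2L))

  blobs <- make_blobs(seed = 104)
  p2 <- affinity_propagation_k(blobs$F, k = 2)
  expect_equal(as.numeric(ari(blobs$gold, p2)), 1)
  # every sample's exemplar maximizes its similarity among the exemplars
  ex <- attr(p2, "exemplars")
  S <- -as.matrix(dist(blobs$F))
  best_ex <- ex[apply(S[, ex], 1, which.max)]
  # each sample carries the label of its most similar exemplar
  expect_equal(unname(as.integer(p2)), unname(as.integer(p2))[best_ex])
})

test_that("consensus reproduces unanimity and majority", {
  ids <- paste0("s", 1:8)
  base <- partition(c(1, 1, 1, 1, 2, 2, 2, 2), sample_ids = ids)
  unanimous <- consensus_partition(rep(list(base), 5), seed = 1)
  expect_equal(as.numeric(ari(base, unanimous)), 1)

  divergent <- partition(c(1, 2, 1, 2, 1, 2, 1, 2), sample_ids = ids)
  cons <- consensus_partition(c(rep(list(base), 4), list(divergent)),
                              seed = 1)
  expect_equal(as.numeric(ari(base, cons)), 1)
  # exhaustive enumeration confirms the global optimum
  inputs <- c(rep(list(as.integer(base)), 4), list(as.integer(divergent)))
  expect_equal(attr(cons, "objective"), consensus_enumeration_min(inputs))

  other <- partition(1:2, sample_ids = c("x", "y"))
  expect_error(consensus_partition(list(base, other)), "different samples")
})

test_that("partitions are stable under sample permutation", {
  blobs <- make_blobs(seed = 105)
  perm <- sample(nrow(blobs$F))
  for (m in c("hclust_manhattan", "hclust_correlation", "kmeans")) {
    p1 <- cluster_samples(blobs$F, m, seed = 6)
    p2 <- cluster_samples(blobs$F[perm, ], m, seed = 6)
    expect_equal(as.numeric(ari(p1, p2)), 1)
  }
})
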