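# Fixtures and independent oracles used across the suite.

# Two planted sample blobs whose centers differ both in location and in
# correlation profile (random center directions), so that every distance in
# use -- Manhattan, Euclidean, absolute Pearson -- separates them. With the
# default amplitude the between/within separation ratio is >= 10.
make_blobs <- function(n = 60, d = 20, amplitude = 10, noise_sd = 1,
                       seed = 42) {
  set.seed(seed)
  c1 <- rnorm(d) * amplitude
  c2 <- rnorm(d) * amplitude
  n1 <- n %/% 2
  F <- rbind(
    matrix(rnorm(n1 * d, sd = noise_sd), n1, d, byrow = TRUE) +
      matrix(c1, n1, d, byrow = TRUE),
    matrix(rnorm((n - n1) * d, sd = noise_sd), n - n1, d, byrow = TRUE) +
      matrix(c2, n - n1, d, byrow = TRUE))
  rownames(F) <- sprintf("s%02d", seq_len(n))
  gold <- partition(rep(1:2, c(n1, n - n1)), sample_ids = rownames(F))
  list(F = F, gold = gold)
}

random_labels <- function(n, k) {
  # at least one sample per cluster, rest uniform
  labs <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  sample(labs)
}

# Brute-force ARI oracle: classify every unordered sample pair as together
# or apart in each partition and apply the chance-corrected Rand formula to
# the pair counts. Independent of the contingency-table implementation.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n * (n - 1) / 2
  pairs_a <- n11 + n10
  pairs_b <- n11 + n01
  expected <- pairs_a * pairs_b / total
  maximum <- (pairs_a + pairs_b) / 2
  if (maximum == expected) {
    if (n10 == 0 && n01 == 0) 1 else 0
  } else {
    (n11 - expected) / (maximum - expected)
  }
}

# Naive Ward agglomeration: track cluster members and merge the pair whose
# union minimizes the increase in within-cluster sum of squares, computed
# directly from the coordinates. Ties broken by the lexicographically
# smallest pair. Returns the k-cluster partition labels.
naive_ward_partition <- function(X, k) {
  ess <- function(members) {
    M <- X[members, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  while (length(clusters) > k) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labs <- integer(nrow(X))
  for (ci in seq_along(clusters)) labs[clusters[[ci]]] <- ci
  labs
}

# Consensus oracle: exhaustive minimum of the hard Euclidean least-squares
# objective over every 2-group labelling of n samples (including the
# degenerate one-cluster labellings), with optimal label swap per input.
consensus_objective <- function(labs, inputs) {
  n <- length(labs)
  sum(vapply(inputs, function(b) {
    agree <- max(sum(b == labs), sum((3L - b) == labs))
    2 * (n - agree)
  }, numeric(1)))
}

consensus_enumeration_min <- function(inputs) {
  n <- length(inputs[[1]])
  best <- Inf
  for (code in 0:(2^n - 1)) {
    labs <- as.integer(intToBits(code)[1:n]) + 1L
    obj <- consensus_objective(labs, inputs)
    if (obj < best) best <- obj
  }
  best
}
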