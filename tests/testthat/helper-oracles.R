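# Independent oracles used across the suite. These deliberately use naive
# enumeration / brute force, never the package's own code paths.

# Exhaustive-permutation two-sample KS p-value: the probability, over all
# C(n+m, n) assignments of the pooled values, of a D statistic at least as
# large as observed.
perm_ks_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ks_stat <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                   numeric(1))))
  }
  d_obs <- ks_stat(x, y)
  splits <- utils::combn(length(pooled), n)
  ds <- apply(splits, 2, function(idx) ks_stat(pooled[idx], pooled[-idx]))
  mean(ds >= d_obs - 1e-12)
}

# Exhaustive-permutation two-sided Wilcoxon rank-sum p-value, measured by
# the distance of the first-sample rank sum from its null expectation.
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  expected <- n * (length(pooled) + 1) / 2
  rank_stat <- function(idx) sum(rank(pooled)[idx])
  d_obs <- abs(rank_stat(seq_len(n)) - expected)
  splits <- utils::combn(length(pooled), n)
  ds <- apply(splits, 2, function(idx) abs(rank_stat(idx) - expected))
  mean(ds >= d_obs - 1e-12)
}

# Clustering coefficients by exhaustive triangle counting on the adjacency
# matrix; 0 for degree < 2.
brute_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (A[nb[i], nb[j]] > 0) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Small random simple graph for metric cross-checks.
random_test_graph <- function(n, p = 0.4) {
  igraph::sample_gnp(n, p)
}

# A tiny labelled universe used by several tests.
toy_universe <- function() {
  tibble::tibble(
    gene_id = c("P1", "P2", "O1", "O2", "T1", "T2", "N1", "N2"),
    set_label = factor(c("POTSF", "POTSF", "ONC", "ONC", "TSG", "TSG",
                         "NCRG", "NCRG"),
                       levels = c("POTSF", "ONC", "TSG", "NCRG",
                                  "UNRESOLVED")),
    length_bp = rep(1000L, 8)
  )
}
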