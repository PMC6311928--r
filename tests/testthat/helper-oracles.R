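# Independent oracles and small fixture builders shared across the suite.

# Brute-force pair-counting ARI: classify every unordered cell pair by
# whether it is co-clustered in each partition, then apply the
# pair-count identity ARI = 2(ad - bc) / [(a+b)(b+d) + (a+c)(c+d)].
# O(N^2), no contingency table -- independent of the implementation path.
pair_count_ari <- function(l1, l2) {
  n <- length(l1)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- l1[i] == l1[j]
      s2 <- l2[i] == l2[j]
      if (s1 && s2) a <- a + 1
      else if (s1) b <- b + 1
      else if (s2) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

# Explicit-loop Calinski-Harabasz: accumulates the within- and
# between-cluster scatter traces element by element.
ch_loop_oracle <- function(X, labels) {
  n <- nrow(X)
  ks <- unique(labels)
  K <- length(ks)
  grand <- colMeans(X)
  W <- 0
  B <- 0
  for (k in ks) {
    rows <- which(labels == k)
    ck <- colMeans(X[rows, , drop = FALSE])
    for (i in rows) {
      for (dmn in seq_len(ncol(X))) W <- W + (X[i, dmn] - ck[dmn])^2
    }
    for (dmn in seq_len(ncol(X))) B <- B + length(rows) * (ck[dmn] - grand[dmn])^2
  }
  unname((B / (K - 1)) / (W / (n - K)))
}

# Random partition with every cluster occupied.
random_partition <- function(n, k_max = 8) {
  k <- sample(2:min(k_max, n - 1), 1)
  labels <- c(seq_len(k), sample(k, n - k, replace = TRUE))[sample(n)]
  names(labels) <- sprintf("c%03d", seq_len(n))
  labels
}

# Tiny counts ExpressionMatrix with default identifiers.
toy_counts <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("gene", seq_len(ncol(values)))
  }
  ExpressionMatrix(values, is_log = FALSE)
}

# Two well-separated 2-D blobs as an Embedding-like coordinate matrix.
two_blob_coords <- function(n_per = 10, gap = 100, seed = 1) {
  set.seed(seed)
  coords <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
                  matrix(rnorm(2 * n_per) + gap, ncol = 2))
  rownames(coords) <- sprintf("c%03d", seq_len(2 * n_per))
  coords
}

# Named truth vector from a SyntheticDataset.
truth_of <- function(d) stats::setNames(d$true_labels$label, d$true_labels$cell_id)

ari_of <- function(labels, truth) {
  adjusted_rand_index(contingency(labels, truth))
}

# Partition constructor for fixtures (wraps the internal validator).
new_partition_for_test <- function(labels, ids) {
  conCluster:::new_partition(labels, ids)
}
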