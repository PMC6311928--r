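fake_embedding <- function(coords, seed = 0L) {
  structure(list(coords = coords, perplexity = NA_real_, seed = seed),
            class = "Embedding")
}

test_that("k-means on two distant blobs recovers them exactly and deterministically", {
  coords <- two_blob_coords(n_per = 10, gap = 100)
  truth <- setNames(rep(1:2, each = 10), rownames(coords))
  # oracle: with a 100-sd gap the optimal 2-means split is the blob split;
  # verify by comparing the blob split objective to every 1-point swap
  blob_inertia <- function(lbl) {
    sum(vapply(unique(lbl), function(k) {
      sum(sweep(coords[lbl == k, , drop = FALSE], 2,
                colMeans(coords[lbl == k, , drop = FALSE]))^2)
    }, numeric(1)))
  }
  base <- blob_inertia(truth)
  for (i in 1:20) {
    alt <- truth
    alt[i] <- 3 - alt[i]
    expect_gt(blob_inertia(alt), base)
  }

  p <- kmeans_partition(fake_embedding(coords), 2, seed = 13)
  expect_identical(p$K, 2L)
  expect_equal(ari_of(p$labels, truth), 1)
  p2 <- kmeans_partition(fake_embedding(coords), 2, seed = 13)
  expect_identical(p$labels, p2$labels)
})

test_that("labels are canonicalized by decreasing cluster size", {
  coords <- rbind(two_blob_coords(n_per = 4, gap = 50, seed = 2),
                  matrix(rnorm(24) + 200, ncol = 2))
  rownames(coords) <- sprintf("x%02d", seq_len(nrow(coords)))
  p <- kmeans_partition(fake_embedding(coords), 3, seed = 14)
  sizes <- tabulate(p$labels, p$K)
  expect_true(all(diff(sizes) <= 0))
  expect_identical(sort(unique(unname(p$labels))), 1:3)
})

test_that("k = N yields the singleton partition and k > N errors", {
  coords <- two_blob_coords(n_per = 3, gap = 10)
  p <- kmeans_partition(fake_embedding(coords), 6, seed = 15)
  expect_identical(unname(p$labels), 1:6)
  expect_error(kmeans_partition(fake_embedding(coords), 7, seed = 15),
               "exceeds")
})

test_that("one-hot encoding has unit rows and cluster-size columns", {
  p <- new_partition_for_test(c(1, 2, 1), c("a", "b", "c"))
  B <- partition_to_binary(p)$B
  expect_identical(B, matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 3, 2,
                             dimnames = list(c("a", "b", "c"), NULL)))

  set.seed(16)
  lbl <- random_partition(80)
  p <- new_partition_for_test(unname(lbl), names(lbl))
  B <- partition_to_binary(p)$B
  expect_true(all(rowSums(B) == 1))
  # column sums equal cluster sizes counted directly
  expect_identical(unname(colSums(B)), as.numeric(tabulate(p$labels, p$K)))
})

test_that("the ensemble concatenates T one-hot blocks with row sums T", {
  coords <- two_blob_coords(n_per = 15, gap = 50, seed = 3)
  ens <- build_ensemble(fake_embedding(coords), T = 3, k_values = 2,
                        master_seed = 17)
  expect_identical(ncol(ens$B_concat), 6L)
  expect_true(all(rowSums(ens$B_concat) == 3))
  expect_identical(ens$K_list, rep(2L, 3))
  # identical (embedding, k) with per-run seeds on clean blobs: all T blocks
  # encode the same partition, so the matrix is 3 copies of one block
  expect_identical(ens$B_concat[, 1:2], ens$B_concat[, 3:4])
  expect_identical(ens$B_concat[, 1:2], ens$B_concat[, 5:6])
})

test_that("run order only permutes column blocks; the consensus is unchanged", {
  set.seed(18)
  coords <- rbind(two_blob_coords(20, 60, 4),
                  matrix(rnorm(40, 150), ncol = 2))
  rownames(coords) <- sprintf("y%02d", seq_len(nrow(coords)))
  e <- fake_embedding(coords)
  parts <- lapply(1:8, function(t) kmeans_partition(e, 2 + (t %% 4), seed = 100 + t))
  ens_a <- ensemble_from_partitions(parts)
  ens_b <- ensemble_from_partitions(rev(parts))
  pa <- consensus_kmeans(ens_a, 3, seed = 19)
  pb <- consensus_kmeans(ens_b, 3, seed = 19)
  expect_equal(adjusted_rand_index(contingency(pa, pb)), 1)
})

test_that("derived seeds are stable when runs are added", {
  s10 <- vapply(1:10, function(t) derive_seed(42, t), integer(1))
  s20 <- vapply(1:20, function(t) derive_seed(42, t), integer(1))
  expect_identical(s20[1:10], s10)
  expect_true(all(s20 >= 0 & s20 < 2^31))
})

test_that("label perturbation flips the requested fraction of cells", {
  p <- new_partition_for_test(rep(1:4, each = 25), sprintf("c%03d", 1:100))
  same <- perturb_partition(p, 0, seed = 20)
  expect_identical(same$labels, p$labels)
  noisy <- perturb_partition(p, 0.1, seed = 20)
  expect_equal(ari_of(noisy$labels, p$labels), pair_count_ari(noisy$labels, p$labels))
  expect_lt(ari_of(noisy$labels, p$labels), 1)
  expect_gt(ari_of(noisy$labels, p$labels), 0.5)
})

test_that("ensembles reject mismatched inputs", {
  coords <- two_blob_coords(5, 20, 5)
  e <- fake_embedding(coords)
  expect_error(build_ensemble(e, T = 1, k_values = 2, master_seed = 1), "T >= 2")
  expect_error(build_ensemble(e, T = 3, k_values = 99, master_seed = 1),
               "2 <= k <= N")
  p1 <- kmeans_partition(e, 2, seed = 1)
  expect_error(ensemble_from_partitions(list(p1)), "at least 2")
})
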