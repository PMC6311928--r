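test_that("Calinski-Harabasz handles degenerate dispersions explicitly", {
  # two clusters each collapsed to a distinct point: zero within-dispersion
  X <- rbind(matrix(1, 3, 2), matrix(5, 3, 2))
  lbl <- rep(1:2, each = 3)
  expect_identical(calinski_harabasz(X, lbl), Inf)
  expect_error(calinski_harabasz(X, rep(1, 6)), "K = 1")
  expect_error(calinski_harabasz(X[1:2, ], 1:2), "N > K")
})

test_that("CH at the true blob count dominates finer splits", {
  coords <- two_blob_coords(n_per = 25, gap = 40, seed = 21)
  e <- structure(list(coords = coords, perplexity = NA, seed = 0L),
                 class = "Embedding")
  ch <- vapply(2:4, function(k) {
    p <- kmeans_partition(e, k, seed = 22)
    # cross-check every evaluation against the explicit-loop oracle
    expect_equal(calinski_harabasz(coords, p),
                 ch_loop_oracle(coords, unname(p$labels)),
                 tolerance = 1e-12)
    calinski_harabasz(coords, p)
  }, numeric(1))
  expect_gt(ch[1], ch[2])
  expect_gt(ch[1], ch[3])
})

test_that("consensus of unanimous basic partitions reproduces them", {
  lbl <- rep(1:3, times = c(20, 15, 10))
  ids <- sprintf("c%03d", seq_along(lbl))
  p <- new_partition_for_test(lbl, ids)
  ens <- ensemble_from_partitions(rep(list(p), 5))
  cons <- consensus_kmeans(ens, 3, seed = 23)
  expect_equal(ari_of(cons$labels, p$labels), 1)
  # cells with identical ensemble rows can never be split
  expect_identical(unname(cons$labels), lbl)
})

test_that("select_k recovers the cluster count of a unanimous ensemble and breaks ties low", {
  lbl <- rep(1:3, times = c(12, 10, 8))
  p <- new_partition_for_test(lbl, sprintf("c%03d", seq_along(lbl)))
  ens <- ensemble_from_partitions(rep(list(p), 4))
  res <- select_k(ens, 2, 6, seed = 24)
  expect_identical(res$K_selected, 3L)
  expect_identical(names(res$ch_scores), as.character(2:6))
  expect_identical(res$ch_scores[["3"]], Inf)
  # a unanimous 3-cluster ensemble has 3 distinct rows: K > 3 is unreachable
  expect_identical(unname(res$ch_scores[c("4", "5", "6")]), rep(-Inf, 3))
  expect_error(consensus_kmeans(ens, 4, seed = 24), "distinct rows")

  noisy <- ensemble_from_partitions(lapply(1:6, function(t) {
    perturb_partition(p, 0.2, seed = derive_seed(600, t))
  }))
  single <- select_k(noisy, 4, 4, seed = 24)
  expect_identical(single$K_selected, 4L)
  expect_error(select_k(ens, 1, 4, seed = 24), "2 <= k_min")
  expect_error(select_k(ens, 5, 2, seed = 24), "2 <= k_min")
})

test_that("the full pipeline is reproducible and honors a fixed K", {
  d <- simulate_cells(n_cells = 120, n_genes = 500, k = 3,
                      n_marker_genes = 25, seed = 25)
  r1 <- run_pipeline(d$expression, min_library_size = 0, T = 12,
                     k_values = 2:6, k_min = 2, k_max = 6, seed = 26)
  r2 <- run_pipeline(d$expression, min_library_size = 0, T = 12,
                     k_values = 2:6, k_min = 2, k_max = 6, seed = 26)
  expect_identical(r1$partition$labels, r2$partition$labels)
  expect_identical(r1$ch_scores, r2$ch_scores)

  fixed <- run_pipeline(d$expression, min_library_size = 0, T = 12,
                        k_values = 2:6, fixed_k = 4, seed = 26)
  expect_identical(fixed$partition$K, 4L)
  expect_identical(fixed$K_selected, 4L)
})

test_that("pipeline results serialize to labels, scores and config", {
  d <- simulate_cells(n_cells = 100, n_genes = 400, k = 2,
                      n_marker_genes = 30, seed = 27)
  res <- run_pipeline(d$expression, min_library_size = 0, T = 8,
                      k_values = 2:4, fixed_k = 2, seed = 28)
  out <- withr::local_tempdir()
  write_consensus_result(res, out)
  lab <- read_labels(file.path(out, "labels.csv"))
  expect_identical(lab$cell_id, res$partition$cell_ids)
  cfg <- jsonlite::read_json(file.path(out, "config.json"))
  expect_identical(cfg$master_seed, 28L)
  expect_true(file.exists(file.path(out, "ch_scores.json")))
})

test_that("cell order equivariance: permuting cells permutes consensus labels", {
  lbl <- rep(1:4, times = c(15, 12, 9, 6))
  ids <- sprintf("c%03d", seq_along(lbl))
  parts <- lapply(1:6, function(t) {
    perturb_partition(new_partition_for_test(lbl, ids), 0.05,
                      seed = derive_seed(29, t))
  })
  ens <- ensemble_from_partitions(parts)
  set.seed(30)
  perm <- sample(length(lbl))
  ens_p <- ens
  ens_p$B_concat <- ens$B_concat[perm, ]
  ens_p$cell_ids <- ens$cell_ids[perm]
  pa <- consensus_kmeans(ens, 4, seed = 31)
  pb <- consensus_kmeans(ens_p, 4, seed = 31)
  expect_equal(adjusted_rand_index(contingency(pa, pb)), 1)
})
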