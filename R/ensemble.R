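#' Derive a per-run seed from a master seed
#'
#' Counter-based: `seed_t = (master + t * 7919) mod (2^31 - 1)`, so adding
#' runs never perturbs the seeds of earlier runs and every derived seed
#' fits in a 32-bit integer.
#'
#' @param master_seed Integer master seed.
#' @param t Run counter (any non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, t) {
  as.integer((as.numeric(master_seed) + as.numeric(t) * 7919) %% 2147483647)
}

# K-means labels on an arbitrary numeric matrix with canonicalized labels
# and bounded re-seeding when a run degenerates to an empty cluster.
.kmeans_labels <- function(x, k, seed, iter.max = 300, max_retries = 10) {
  n <- nrow(x)
  if (k > n) stop(sprintf("k = %d exceeds the number of points (%d)", k, n))
  if (k == n) {
    if (anyDuplicated(x)) stop("k = N requires all points distinct")
    return(list(labels = seq_len(n), inertia = 0))
  }
  for (attempt in 0:max_retries) {
    s <- if (attempt == 0) seed else derive_seed(seed, 104729 + attempt)
    set.seed(s)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, iter.max = iter.max,
                                     nstart = 1)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$cluster)) == k) {
      return(list(labels = canonicalize_labels(fit$cluster)$labels,
                  inertia = fit$tot.withinss))
    }
  }
  stop(sprintf("K-means failed to produce %d non-empty clusters after %d re-seeds (seed %d)",
               k, max_retries, seed))
}

# Relabel clusters 1..K by decreasing size, ties broken by the smallest
# member index, so identical clusterings serialize identically.
canonicalize_labels <- function(labels) {
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  first <- vapply(seq_along(sizes), function(k) match(k, labels), integer(1))
  ord <- order(-sizes, first)
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(sizes)
  list(labels = remap[labels], K = length(sizes))
}

#' Partition an embedding with K-means
#'
#' One basic partition: K-means with random-point initialization on the 2-D
#' embedding coordinates. Labels are canonicalized by decreasing cluster
#' size (ties by smallest member index) and run in 1..k, so the partition
#' is a pure function of `(embedding, k, seed)`. A run that converges with
#' an empty cluster is re-seeded internally a bounded number of times.
#'
#' @param e An `Embedding` (or any numeric matrix with rownames).
#' @param k Number of clusters, `2 <= k <= N` (`k = N` yields singletons).
#' @param seed Integer seed for the initialization.
#' @return A `Partition`: list with integer `labels` (1..K, named by cell
#'   id), `K`, `cell_ids`, and a `provenance` record.
#' @export
kmeans_partition <- function(e, k, seed) {
  x <- if (inherits(e, "Embedding")) e$coords else e
  if (any(!is.finite(x))) stop("non-finite coordinates")
  if (k < 1) stop("k must be >= 1")
  fit <- .kmeans_labels(x, k, seed)
  new_partition(fit$labels, rownames(x),
                provenance = list(seed = seed, k = k,
                                  embedding_seed = if (inherits(e, "Embedding")) e$seed else NA))
}

new_partition <- function(labels, cell_ids, provenance = list()) {
  labels <- as.integer(labels)
  K <- max(labels)
  stopifnot(length(labels) == length(cell_ids),
            all(tabulate(labels, K) > 0), all(labels >= 1))
  names(labels) <- cell_ids
  structure(list(labels = labels, K = K, cell_ids = as.character(cell_ids),
                 provenance = provenance),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %d cells in %d clusters (sizes %s)\n",
              length(x$labels), x$K,
              paste(tabulate(x$labels, x$K), collapse = ", ")))
  invisible(x)
}

#' One-hot encode a partition
#'
#' Builds the N x K binary membership matrix B with `B[i, j] = 1` iff cell
#' i belongs to cluster j; every row has exactly one 1.
#'
#' @param p A `Partition`.
#' @param run_index Optional ensemble run counter attached to the result.
#' @return A `BinaryMembership`: list with the 0/1 matrix `B`, `K_t`, and
#'   `run_index`.
#' @export
partition_to_binary <- function(p, run_index = NA_integer_) {
  stopifnot(inherits(p, "Partition"))
  n <- length(p$labels)
  B <- matrix(0L, n, p$K, dimnames = list(p$cell_ids, NULL))
  B[cbind(seq_len(n), p$labels)] <- 1L
  structure(list(B = B, K_t = p$K, run_index = run_index),
            class = "BinaryMembership")
}

#' Build the ensemble of basic partitions
#'
#' Runs `kmeans_partition` T times with per-run seeds derived
#' deterministically from `master_seed`, varying the cluster count K_t over
#' `k_values` (cycled to length T), one-hot encodes each basic partition,
#' and concatenates the membership matrices column-wise into the N x sum(K_t)
#' ensemble matrix whose rows each sum to exactly T.
#'
#' By default one shared embedding feeds every run ("different initial
#' parameters" = the K-means seed and K_t vary); passing a list of T
#' embeddings instead re-reads the step with one t-SNE per run.
#'
#' @param e An `Embedding`, or a list of T Embeddings (one per run).
#' @param T Number of basic partitions; default 50.
#' @param k_values Candidate cluster counts cycled across the runs;
#'   default `2:10`.
#' @param master_seed Integer master seed.
#' @return An `EnsembleMatrix`: list with the 0/1 matrix `B_concat`, `T`,
#'   `K_list`, `seeds`, `cell_ids`.
#' @export
build_ensemble <- function(e, T = 50, k_values = 2:10, master_seed) {
  if (T < 2) stop("an ensemble needs T >= 2 basic partitions")
  if (missing(master_seed)) stop("master_seed is required")
  embeddings <- if (inherits(e, "Embedding")) rep(list(e), T) else e
  if (length(embeddings) != T) {
    stop("when a list of embeddings is given it must have length T")
  }
  n <- nrow(embeddings[[1]]$coords)
  ks <- rep_len(as.integer(k_values), T)
  if (any(ks < 2 | ks > n)) {
    stop("every k in k_values must satisfy 2 <= k <= N")
  }
  seeds <- vapply(seq_len(T), function(t) derive_seed(master_seed, t),
                  integer(1))
  blocks <- vector("list", T)
  for (t in seq_len(T)) {
    p <- tryCatch(kmeans_partition(embeddings[[t]], ks[t], seeds[t]),
                  error = function(err) {
                    stop(sprintf("basic run %d (K_t = %d, seed = %d) failed: %s",
                                 t, ks[t], seeds[t], conditionMessage(err)))
                  })
    blocks[[t]] <- partition_to_binary(p, run_index = t)$B
  }
  B <- do.call(cbind, blocks)
  structure(list(B_concat = B, T = T, K_list = ks, seeds = seeds,
                 cell_ids = rownames(B)),
            class = "EnsembleMatrix")
}

#' Assemble an ensemble matrix from explicit basic partitions
#'
#' Lower-level companion to [build_ensemble()]: one-hot encodes an
#' arbitrary list of partitions over the same cells and concatenates them.
#' Useful for fusing partitions from other base clusterers or for
#' controlled experiments on corrupted ensembles.
#'
#' @param partitions List of `Partition` objects over identical cell ids.
#' @return An `EnsembleMatrix`.
#' @export
ensemble_from_partitions <- function(partitions) {
  if (length(partitions) < 2) stop("an ensemble needs at least 2 partitions")
  ids <- partitions[[1]]$cell_ids
  for (p in partitions) {
    stopifnot(inherits(p, "Partition"))
    if (!identical(p$cell_ids, ids)) {
      stop("all partitions must cover the same cells in the same order")
    }
  }
  blocks <- lapply(seq_along(partitions), function(t) {
    partition_to_binary(partitions[[t]], run_index = t)$B
  })
  B <- do.call(cbind, blocks)
  structure(list(B_concat = B, T = length(partitions),
                 K_list = vapply(partitions, function(p) p$K, integer(1)),
                 seeds = NA, cell_ids = ids),
            class = "EnsembleMatrix")
}

#' Randomly corrupt a partition's labels
#'
#' Reassigns a fraction of cells to a cluster drawn uniformly from the
#' other clusters. Used to emulate unstable basic partitions in
#' robustness experiments.
#'
#' @param p A `Partition` with `K >= 2`.
#' @param rate Fraction of cells to reassign, in [0, 1].
#' @param seed Integer seed.
#' @return A `Partition` (labels are canonicalized, so cluster numbering
#'   may differ from `p`).
#' @export
perturb_partition <- function(p, rate, seed) {
  stopifnot(inherits(p, "Partition"), rate >= 0, rate <= 1, p$K >= 2)
  set.seed(seed)
  labels <- unname(p$labels)
  n_flip <- round(rate * length(labels))
  if (n_flip > 0) {
    idx <- sample(length(labels), n_flip)
    shift <- sample(p$K - 1, n_flip, replace = TRUE)
    labels[idx] <- 1 + (labels[idx] - 1 + shift) %% p$K
  }
  # a flip can empty a cluster; canonicalization then renumbers compactly
  new_partition(canonicalize_labels(labels)$labels, p$cell_ids,
                provenance = c(p$provenance, list(noise_rate = rate,
                                                  noise_seed = seed)))
}

#' @export
print.EnsembleMatrix <- function(x, ...) {
  cat(sprintf("EnsembleMatrix: %d cells x %d columns (T = %d runs, K_t in %d..%d)\n",
              nrow(x$B_concat), ncol(x$B_concat), x$T,
              min(x$K_list), max(x$K_list)))
  invisible(x)
}

#' Write an ensemble matrix as Matrix Market plus a JSON sidecar
#' @param ens An `EnsembleMatrix`.
#' @param path Output `.mtx` path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  Matrix::writeMM(Matrix::Matrix(ens$B_concat, sparse = TRUE), path)
  jsonlite::write_json(list(T = ens$T, K_list = ens$K_list,
                            seeds = ens$seeds, cell_ids = ens$cell_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
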