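#' Calinski-Harabasz index of a partition
#'
#' The ratio of between-cluster to within-cluster dispersion, each
#' normalized by its degrees of freedom:
#' `[trace(B_disp)/(K-1)] / [trace(W_disp)/(N-K)]`. Larger is better. When
#' every cluster collapses to a single point but the centroids differ, the
#' within-dispersion is zero and `+Inf` is returned as a documented
#' sentinel.
#'
#' @param X Numeric matrix, N points x D features.
#' @param p A `Partition` of the N rows (or an integer label vector).
#' @return The CH score (positive real, possibly `Inf`).
#' @export
calinski_harabasz <- function(X, p) {
  labels <- if (inherits(p, "Partition")) p$labels else as.integer(p)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  K <- length(unique(labels))
  if (K < 2) stop("Calinski-Harabasz is undefined for K = 1 (K - 1 = 0)")
  if (n <= K) stop("need N > K for a positive within-cluster denominator")
  grand <- colMeans(X)
  between <- 0
  within <- 0
  for (k in unique(labels)) {
    idx <- labels == k
    nk <- sum(idx)
    ck <- colMeans(X[idx, , drop = FALSE])
    between <- between + nk * sum((ck - grand)^2)
    within <- within + sum(sweep(X[idx, , drop = FALSE], 2, ck)^2)
  }
  if (within == 0) {
    if (between == 0) return(0)
    return(Inf)
  }
  (between / (K - 1)) / (within / (n - K))
}

#' Consensus K-means on the ensemble matrix
#'
#' Clusters the rows of the concatenated binary membership matrix -- each
#' cell as a point in \{0,1\}^\{sum(K_t)\} -- with Euclidean K-means.
#' Squared Euclidean distance between one-hot blocks is proportional to the
#' number of basic partitions on which two cells disagree, so this fuses
#' the ensemble by label-disagreement. The fit is restarted `nstart` times
#' with seeds derived from `seed`, keeping the best inertia; cells with
#' identical ensemble rows are always co-clustered.
#'
#' @param B An `EnsembleMatrix`.
#' @param K Number of consensus clusters, `2 <= K <= N`.
#' @param seed Integer seed.
#' @param nstart Number of restarts (default 10).
#' @return A `Partition` with canonicalized labels.
#' @export
consensus_kmeans <- function(B, K, seed, nstart = 10) {
  stopifnot(inherits(B, "EnsembleMatrix"))
  X <- B$B_concat
  if (K < 2 || K > nrow(X)) stop("need 2 <= K <= N")
  n_distinct <- nrow(unique(X))
  if (K > n_distinct) {
    stop(sprintf(paste0("infeasible K: the ensemble has only %d distinct rows ",
                        "and identical rows are never split, so at most %d ",
                        "consensus clusters exist"), n_distinct, n_distinct),
         call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- tryCatch(.kmeans_labels(X, K, derive_seed(seed, 7907 * r)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$inertia < best$inertia)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop(sprintf("consensus K-means failed for K = %d across %d restarts", K, nstart))
  }
  new_partition(best$labels, B$cell_ids,
                provenance = list(seed = seed, k = K, stage = "consensus"))
}

#' Select the consensus cluster number with the Calinski-Harabasz index
#'
#' Fits a consensus partition for every K in `[k_min, k_max]`, scores each
#' on the ensemble matrix rows (the space actually clustered), and returns
#' the partition with the maximal score; ties go to the smaller K
#' (parsimony).
#'
#' @param B An `EnsembleMatrix`.
#' @param k_min,k_max Scan range; default 2..10.
#' @param seed Integer seed.
#' @param score_space `"embedding"` scores CH on the 2-D coordinates the
#'   basic partitions were drawn from (requires `embedding`);
#'   `"ensemble"` scores on the binary ensemble rows. Default: embedding
#'   when one is supplied, ensemble rows otherwise. The embedding space
#'   gives a far sharper CH peak at the true cluster number because the
#'   index compares real geometric dispersions, whereas on one-hot rows
#'   finer consensus partitions keep gaining between-cluster dispersion.
#' @param embedding Optional `Embedding` used when
#'   `score_space = "embedding"`.
#' @return A `ConsensusResult`: list with `partition`, `K_selected`,
#'   `ch_scores` (named by K; a candidate K exceeding the number of
#'   distinct ensemble rows is unreachable and scored `-Inf`),
#'   `config_echo`.
#' @export
select_k <- function(B, k_min = 2, k_max = 10, seed,
                     score_space = NULL, embedding = NULL) {
  stopifnot(inherits(B, "EnsembleMatrix"))
  if (is.null(score_space)) {
    score_space <- if (is.null(embedding)) "ensemble" else "embedding"
  }
  score_space <- match.arg(score_space, c("embedding", "ensemble"))
  n <- length(B$cell_ids)
  if (!(2 <= k_min && k_min <= k_max && k_max <= n - 1)) {
    stop("need 2 <= k_min <= k_max <= N - 1")
  }
  X_score <- if (score_space == "ensemble") B$B_concat else {
    if (is.null(embedding)) stop("score_space = 'embedding' needs `embedding`")
    embedding$coords
  }
  ks <- k_min:k_max
  n_distinct <- nrow(unique(B$B_concat))
  parts <- vector("list", length(ks))
  scores <- numeric(length(ks))
  for (i in seq_along(ks)) {
    if (ks[i] > n_distinct) {
      # identical ensemble rows are never split, so this K is unreachable
      scores[i] <- -Inf
      next
    }
    parts[[i]] <- consensus_kmeans(B, ks[i], seed)
    scores[i] <- calinski_harabasz(X_score, parts[[i]])
  }
  names(scores) <- ks
  if (all(scores == -Inf)) stop("no candidate K is feasible for this ensemble")
  best <- which(scores == max(scores))[1]  # ties toward smaller K
  new_consensus_result(parts[[best]], ks[best], scores,
                       config_echo = list(k_min = k_min, k_max = k_max,
                                          seed = seed,
                                          score_space = score_space))
}

new_consensus_result <- function(partition, K_selected, ch_scores,
                                 config_echo = list()) {
  K_selected <- as.integer(K_selected)
  stopifnot(partition$K == K_selected)
  structure(list(partition = partition, K_selected = K_selected,
                 ch_scores = ch_scores, config_echo = config_echo),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: K = %d selected", x$K_selected))
  if (length(x$ch_scores) > 1) {
    cat(sprintf(" from K in %s..%s by Calinski-Harabasz",
                names(x$ch_scores)[1],
                names(x$ch_scores)[length(x$ch_scores)]))
  }
  cat("\n")
  print(x$partition)
  invisible(x)
}

#' Run the full consensus clustering pipeline
#'
#' Executes, in order: library-size QC (counts input only), logTPM
#' transform, rare/ubiquitous gene removal, variable-gene selection, t-SNE
#' embedding, ensemble of T K-means basic partitions, and consensus with
#' Calinski-Harabasz model selection (or a fixed K). Fully reproducible
#' from `(input, config)`: every stage seed derives from `seed`.
#'
#' @param m An `ExpressionMatrix` (counts or logTPM). For logTPM input the
#'   QC and transform stages are skipped (QC with a warning, since library
#'   size is undefined).
#' @param r_percent,expression_threshold Rare/ubiquitous band, see
#'   [filter_rare_ubiquitous()].
#' @param v_percent Variable-gene percentage, see [select_variable_genes()].
#' @param min_library_size QC threshold on counts, see [qc_filter_cells()].
#' @param perplexity t-SNE perplexity.
#' @param T Ensemble size.
#' @param k_values K_t values cycled over the basic runs.
#' @param k_min,k_max Consensus K scan range.
#' @param fixed_k If non-NULL, skip model selection and fit this K.
#' @param seed Master seed for the whole run.
#' @return A `ConsensusResult` with an additional `reports` element (per
#'   stage) in `config_echo`.
#' @export
run_pipeline <- function(m, r_percent = 6, expression_threshold = 0,
                         v_percent = 20, min_library_size = 10000,
                         perplexity = 30, T = 50, k_values = 2:10,
                         k_min = 2, k_max = 10, fixed_k = NULL, seed) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (missing(seed)) stop("a master seed is required")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  reports <- list()
  if (!m$is_log) {
    m <- stage("qc", qc_filter_cells(m, min_library_size))
    reports$n_cells_after_qc <- nrow(m$values)
    m <- stage("logtpm", logtpm_transform(m))
  } else {
    warning("input is already logTPM: library-size QC skipped")
  }
  f1 <- stage("filter_genes", filter_rare_ubiquitous(m, r_percent,
                                                     expression_threshold))
  f2 <- stage("variable_genes", select_variable_genes(f1$matrix, v_percent))
  reports$rare_ubiquitous <- f1$report
  reports$variable_genes <- f2$report

  emb <- stage("embedding",
               tsne_embed(f2$matrix, perplexity = perplexity,
                          seed = derive_seed(seed, 1000003)))
  ens <- stage("ensemble",
               build_ensemble(emb, T = T, k_values = k_values,
                              master_seed = seed))
  consensus_seed <- derive_seed(seed, 2000003)
  res <- if (is.null(fixed_k)) {
    stage("consensus", select_k(ens, k_min, k_max, seed = consensus_seed,
                                embedding = emb))
  } else {
    p <- stage("consensus", consensus_kmeans(ens, fixed_k, consensus_seed))
    new_consensus_result(p, fixed_k,
                         stats::setNames(calinski_harabasz(ens$B_concat, p),
                                         fixed_k))
  }
  res$config_echo <- c(res$config_echo,
                       list(r_percent = r_percent, v_percent = v_percent,
                            expression_threshold = expression_threshold,
                            min_library_size = min_library_size,
                            perplexity = perplexity, T = T,
                            k_values = k_values, fixed_k = fixed_k,
                            master_seed = seed))
  res$reports <- reports
  res$embedding <- emb
  res
}

#' Write consensus results to a directory
#'
#' Writes the labels CSV (`cell_id,cluster`), the CH score map as JSON, and
#' the full configuration echo as JSON.
#'
#' @param res A `ConsensusResult`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_consensus_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labels(data.frame(cell_id = res$partition$cell_ids,
                          label = res$partition$labels),
               file.path(dir, "labels.csv"))
  jsonlite::write_json(as.list(res$ch_scores), file.path(dir, "ch_scores.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- res$config_echo
  cfg$k_values <- as.integer(cfg$k_values)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
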