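#' Generate a clustered scRNA-seq-like count matrix with known labels
#'
#' Minimal generative model with the two scRNA-seq features the pipeline's
#' assumptions rest on: negative-binomial overdispersion and
#' mean-dependent dropout. Counts are drawn per gene and cell from
#' `NB(mu, size = 1/dispersion)` with `mu = base_mean` for background
#' genes and `mu = base_mean * 2^log_fold_change` for a cluster's marker
#' genes (marker sets are disjoint across clusters). Each entry is then
#' independently zeroed with probability
#' `dropout_rate * exp(-mu / dropout_decay)`, so lowly expressed genes
#' drop out more often. Cluster structure is marker-based rather than a
#' global shift so the rare/ubiquitous and variable-gene filters have
#' genuinely informative genes to find.
#'
#' Defaults describe a moderately hard 5-population problem: 300 cells,
#' 2000 genes, 40 markers per cluster at 16-fold enrichment, 10% maximal
#' dropout, library sizes around 20,000 counts (comfortably above the
#' 10,000-count QC threshold).
#'
#' @param n_cells,n_genes,k Matrix size and number of cell populations.
#' @param cluster_proportions Population proportions (length k, summing
#'   to 1); default equal.
#' @param n_marker_genes Markers per cluster; `k * n_marker_genes` must
#'   not exceed `n_genes`.
#' @param log_fold_change log2 enrichment of a cluster's markers.
#' @param dropout_rate Maximal per-entry dropout probability, in [0, 1).
#' @param base_mean Background NB mean per gene per cell.
#' @param dispersion NB dispersion (the `size` parameter is
#'   `1/dispersion`); larger means more overdispersed.
#' @param dropout_decay Mean scale of the dropout decay (same units as
#'   `base_mean`).
#' @param seed Integer seed; regeneration with identical parameters is
#'   bit-identical.
#' @return A `SyntheticDataset`: list with `expression` (an
#'   `ExpressionMatrix` of counts), `true_labels` (data.frame `cell_id`,
#'   `label`), `marker_genes` (list per cluster), and `params`.
#' @export
simulate_cells <- function(n_cells = 300, n_genes = 2000, k = 5,
                           cluster_proportions = rep(1 / k, k),
                           n_marker_genes = 40, log_fold_change = 4,
                           dropout_rate = 0.1, base_mean = 10,
                           dispersion = 1, dropout_decay = 20, seed) {
  if (missing(seed)) stop("a seed is required for a reproducible dataset")
  if (k < 2 || n_cells < k) stop("need n_cells >= k >= 2")
  if (n_genes < k * n_marker_genes) {
    stop("need n_genes >= k * n_marker_genes (disjoint marker sets)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("need 0 <= dropout_rate < 1")
  if (length(cluster_proportions) != k || any(cluster_proportions <= 0)) {
    stop("cluster_proportions must be k positive values")
  }
  cluster_proportions <- cluster_proportions / sum(cluster_proportions)

  set.seed(seed)
  # deterministic sizes via largest remainder, so every cluster is non-empty
  sizes <- floor(n_cells * cluster_proportions)
  sizes[seq_len(n_cells - sum(sizes))] <-
    sizes[seq_len(n_cells - sum(sizes))] + 1
  if (any(sizes == 0)) stop("a cluster received zero cells; increase n_cells")
  labels <- rep(seq_len(k), times = sizes)

  markers <- split(seq_len(k * n_marker_genes),
                   rep(seq_len(k), each = n_marker_genes))
  mu <- matrix(base_mean, n_cells, n_genes)
  for (cl in seq_len(k)) {
    mu[labels == cl, markers[[cl]]] <- base_mean * 2^log_fold_change
  }
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu,
                                  size = 1 / dispersion),
                   n_cells, n_genes)
  if (dropout_rate > 0) {
    p_drop <- dropout_rate * exp(-mu / dropout_decay)
    drop <- matrix(stats::runif(n_cells * n_genes) < p_drop,
                   n_cells, n_genes)
    counts[drop] <- 0L
  }
  cell_names <- sprintf("cell_%03d", seq_len(n_cells))
  gene_names <- sprintf("gene_%04d", seq_len(n_genes))
  dimnames(counts) <- list(cell_names, gene_names)

  params <- list(n_cells = n_cells, n_genes = n_genes, k = k,
                 cluster_proportions = cluster_proportions,
                 n_marker_genes = n_marker_genes,
                 log_fold_change = log_fold_change,
                 dropout_rate = dropout_rate, base_mean = base_mean,
                 dispersion = dispersion, dropout_decay = dropout_decay,
                 seed = seed)
  structure(list(expression = ExpressionMatrix(counts, is_log = FALSE),
                 true_labels = data.frame(cell_id = cell_names,
                                          label = as.character(labels),
                                          stringsAsFactors = FALSE),
                 marker_genes = lapply(markers, function(i) gene_names[i]),
                 params = params),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("SyntheticDataset: %d cells x %d genes, %d populations ",
                     "(log2FC %g, dropout %g, seed %d)\n"),
              p$n_cells, p$n_genes, p$k, p$log_fold_change, p$dropout_rate,
              p$seed))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the count matrix as TSV, the true labels as CSV, and the
#' generating parameters as JSON. Backs the `concluster simulate` command.
#'
#' @param x A `SyntheticDataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(x$expression, file.path(dir, "matrix.tsv"))
  write_labels(x$true_labels, file.path(dir, "truth.csv"))
  jsonlite::write_json(x$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
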