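#' Embed cells in two dimensions with t-SNE
#'
#' Reduces the filtered logTPM matrix to two dimensions. Perplexity is the
#' smooth effective-neighbor count; 30 by default, with 5-50 the commonly
#' robust range (values outside it are accepted, not clamped). The
#' embedding is run directly on the filtered matrix with no PCA
#' pre-reduction, and is deterministic for a fixed `(input, seed)` pair.
#'
#' @param m An `ExpressionMatrix` with `is_log = TRUE`.
#' @param perplexity t-SNE perplexity; requires `3*perplexity < N - 1`.
#' @param seed Integer seed for the embedding's randomness.
#' @param max_iter Gradient-descent iterations (default 1000).
#' @return An `Embedding`: list with `coords` (N x 2 matrix, rownames =
#'   cell ids), `perplexity`, `seed`.
#' @export
tsne_embed <- function(m, perplexity = 30, seed, max_iter = 1000) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!m$is_log) stop("tsne_embed() expects logTPM input")
  n <- nrow(m$values)
  if (n < 5) stop("t-SNE needs at least 5 cells, got ", n)
  if (3 * perplexity >= n - 1) {
    stop(sprintf("perplexity %g too large for %d cells: need 3*perplexity < N - 1",
                 perplexity, n))
  }
  if (missing(seed)) stop("an explicit seed is required for reproducibility")
  set.seed(seed)
  fit <- Rtsne::Rtsne(m$values, dims = 2, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE,
                      max_iter = max_iter, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- cell_ids(m)
  colnames(coords) <- c("dim1", "dim2")
  if (any(!is.finite(coords))) stop("t-SNE produced non-finite coordinates")
  structure(list(coords = coords, perplexity = perplexity, seed = seed),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x 2 (perplexity %g, seed %d)\n",
              nrow(x$coords), x$perplexity, x$seed))
  invisible(x)
}

#' Write an embedding as CSV
#' @param e An `Embedding`.
#' @param path Output path (columns cell_id, dim1, dim2).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(e, path) {
  df <- data.frame(cell_id = rownames(e$coords),
                   dim1 = e$coords[, 1], dim2 = e$coords[, 2])
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}
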