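#' Remove rare and ubiquitous genes
#'
#' A gene is "expressed" in a cell when its value exceeds
#' `expression_threshold` (default 0, which on logTPM = log2(TPM+1) means
#' TPM > 0). Genes expressed in strictly fewer than `r_percent`% of cells
#' are removed as rare; genes expressed in at least `(100 - r_percent)`% of
#' cells are removed as ubiquitous. Neither band carries clustering signal.
#'
#' @param m An `ExpressionMatrix` (counts or logTPM).
#' @param r_percent Band width in percent, strictly between 0 and 50;
#'   default 6.
#' @param expression_threshold Value above which a gene counts as expressed.
#' @return A list with elements `matrix` (the filtered `ExpressionMatrix`)
#'   and `report` (a `GeneFilterReport`).
#' @export
filter_rare_ubiquitous <- function(m, r_percent = 6, expression_threshold = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (r_percent <= 0 || r_percent >= 50) {
    stop("r_percent must be in (0, 50): the rare and ubiquitous bands ",
         "would otherwise overlap or vanish")
  }
  n <- nrow(m$values)
  if (n < 1) stop("matrix has no cells")
  frac <- colMeans(m$values > expression_threshold)
  rare <- frac < r_percent / 100
  ubiq <- frac >= (100 - r_percent) / 100
  keep <- !rare & !ubiq
  report <- gene_filter_report(
    n_input_genes = ncol(m$values),
    n_removed_rare = sum(rare),
    n_removed_ubiquitous = sum(ubiq),
    n_removed_low_variability = 0L,
    kept_gene_ids = gene_ids(m)[keep],
    r_percent = r_percent, v_percent = NA_real_)
  list(matrix = ExpressionMatrix(m$values[, keep, drop = FALSE],
                                 is_log = m$is_log),
       report = report)
}

#' Select the most variable genes
#'
#' Ranks genes by a variability score that controls for mean expression and
#' keeps the top `ceil(v_percent/100 * G)`. Two scores are available:
#'
#' * `"dispersion-rank"` (default): the variance/mean ratio. Dividing by
#'   the mean removes the first-order mean-variance coupling while never
#'   discounting a gene relative to its own neighborhood, so it stays
#'   informative when differentially expressed genes are numerous and
#'   concentrated in one mean range.
#' * `"trend-residual"`: the residual of each gene's log variance from a
#'   rolling-median trend of log variance over log mean, computed in 20
#'   mean-rank bins. A stricter, non-parametric control; note that when
#'   signal genes dominate entire mean bins the trend is fit to the signal
#'   itself and the residual suppresses it.
#'
#' Ties are broken by gene identifier order so the selection is
#' deterministic and invariant to the column order of the input.
#'
#' @param m An `ExpressionMatrix` with `is_log = TRUE`.
#' @param v_percent Percentage of genes to keep, in (0, 100].
#' @param trend_method `"trend-residual"` or `"dispersion-rank"`.
#' @param n_bins Number of mean-rank bins for the rolling-median trend.
#' @return A list with elements `matrix` and `report`, as
#'   [filter_rare_ubiquitous()].
#' @export
select_variable_genes <- function(m, v_percent = 20,
                                  trend_method = c("dispersion-rank",
                                                   "trend-residual"),
                                  n_bins = 20) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  trend_method <- match.arg(trend_method)
  if (!m$is_log) stop("select_variable_genes() expects logTPM input")
  if (v_percent <= 0 || v_percent > 100) stop("v_percent must be in (0, 100]")
  G <- ncol(m$values)
  if (trend_method == "trend-residual" && G < 10) {
    stop("trend fitting needs at least 10 genes")
  }
  n_keep <- ceiling(v_percent / 100 * G)
  if (n_keep < 1) stop("v_percent selects zero genes")

  mu <- colMeans(m$values)
  v <- apply(m$values, 2, stats::var)
  if (all(v == 0)) stop("constant matrix: all gene variances are zero")

  score <- switch(trend_method,
    "dispersion-rank" = ifelse(mu > 0, v / mu, 0),
    "trend-residual" = {
      logv <- log(v + 1e-12)
      logm <- log(mu + 1e-12)
      bins <- ceiling(rank(logm, ties.method = "first") / (G / n_bins))
      bins <- pmin(pmax(bins, 1L), n_bins)
      trend <- stats::ave(logv, bins, FUN = stats::median)
      logv - trend
    })

  # deterministic ranking: score desc, then gene identifier
  ord <- order(-score, gene_ids(m))
  keep_idx <- sort(ord[seq_len(n_keep)])
  report <- gene_filter_report(
    n_input_genes = G,
    n_removed_rare = 0L,
    n_removed_ubiquitous = 0L,
    n_removed_low_variability = G - n_keep,
    kept_gene_ids = gene_ids(m)[keep_idx],
    r_percent = NA_real_, v_percent = v_percent)
  list(matrix = ExpressionMatrix(m$values[, keep_idx, drop = FALSE],
                                 is_log = TRUE),
       report = report)
}

gene_filter_report <- function(n_input_genes, n_removed_rare,
                               n_removed_ubiquitous,
                               n_removed_low_variability,
                               kept_gene_ids, r_percent, v_percent) {
  rep <- list(n_input_genes = as.integer(n_input_genes),
              n_removed_rare = as.integer(n_removed_rare),
              n_removed_ubiquitous = as.integer(n_removed_ubiquitous),
              n_removed_low_variability = as.integer(n_removed_low_variability),
              kept_gene_ids = as.character(kept_gene_ids),
              r_percent = r_percent, v_percent = v_percent)
  stopifnot(rep$n_input_genes == rep$n_removed_rare +
              rep$n_removed_ubiquitous + rep$n_removed_low_variability +
              length(rep$kept_gene_ids))
  structure(rep, class = "GeneFilterReport")
}

#' @export
print.GeneFilterReport <- function(x, ...) {
  cat(sprintf(paste0("GeneFilterReport: %d genes in; removed %d rare, ",
                     "%d ubiquitous, %d low-variability; %d kept\n"),
              x$n_input_genes, x$n_removed_rare, x$n_removed_ubiquitous,
              x$n_removed_low_variability, length(x$kept_gene_ids)))
  invisible(x)
}

#' Serialize a gene filter report
#' @param x A `GeneFilterReport`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
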