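#' Construct an expression matrix container
#'
#' An `ExpressionMatrix` holds a cells x genes numeric matrix together with
#' cell and gene identifiers and a flag recording whether the values are raw
#' counts or logTPM. All pipeline stages operate on this container.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to the colnames of `values`.
#' @param is_log Logical; `TRUE` once the matrix holds logTPM values.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, dimnames set to the identifiers) and `is_log`.
#' @export
ExpressionMatrix <- function(values, cell_ids = rownames(values),
                             gene_ids = colnames(values), is_log = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x genes)")
  }
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("cell and gene identifiers are required (rownames/colnames or explicit)")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) must equal nrow(values)")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal ncol(values)")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at cell '%s', gene '%s'; the pipeline requires a complete matrix",
                 cell_ids[bad[1]], gene_ids[bad[2]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at cell '%s', gene '%s'; expression must be non-negative",
                 cell_ids[bad[1]], gene_ids[bad[2]]))
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, is_log = isTRUE(is_log)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log) "logTPM" else "counts"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Cell and gene identifiers of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
cell_ids <- function(m) rownames(m$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$values)

#' Read an expression matrix from disk
#'
#' Reads a dense delimited file (TSV/CSV, header row, first column holds the
#' identifiers) or a Matrix Market triplet file with one-identifier-per-line
#' sidecar files for rows and columns. The on-disk orientation is an explicit
#' caller choice -- there is no auto-detection -- and the result is always
#' returned in cells x genes orientation.
#'
#' @param path Path to the matrix file.
#' @param orientation Either `"cells-by-genes"` (rows on disk are cells) or
#'   `"genes-by-cells"` (the file is transposed on load).
#' @param format `"dense"` or `"mtx"`.
#' @param row_names,col_names For `format = "mtx"`, paths to the sidecar
#'   identifier files for the MTX rows and columns. Default to
#'   `<path>.rownames` / `<path>.colnames`.
#' @param is_log Logical flag to attach to the result; `FALSE` for counts.
#'
#' @return An `ExpressionMatrix` in cells x genes orientation.
#' @export
read_expression <- function(path,
                            orientation = c("cells-by-genes", "genes-by-cells"),
                            format = c("dense", "mtx"),
                            row_names = paste0(path, ".rownames"),
                            col_names = paste0(path, ".colnames"),
                            is_log = FALSE) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "dense") {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                            colClasses = list(character = 1))
    ids <- as.character(dt[[1]])
    body <- dt[, -1, drop = FALSE]
    for (j in seq_along(body)) {
      if (!is.numeric(body[[j]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                       !is.na(body[[j]]))[1]
        stop(sprintf("non-numeric entry in column '%s', row '%s' of %s",
                     names(body)[j], ids[if (is.na(bad)) 1 else bad], path))
      }
    }
    vals <- as.matrix(body)
    rownames(vals) <- ids
  } else {
    for (f in c(row_names, col_names)) {
      if (!file.exists(f)) stop("mtx sidecar identifier file not found: ", f)
    }
    vals <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(vals) || length(cn) != ncol(vals)) {
      stop("sidecar identifier counts do not match the MTX dimensions")
    }
    dimnames(vals) <- list(rn, cn)
  }

  if (orientation == "genes-by-cells") vals <- t(vals)
  ExpressionMatrix(vals, is_log = is_log)
}

#' Write an expression matrix as a dense delimited file
#'
#' Inverse of [read_expression()] for the dense format: header row of gene
#' identifiers, first column of cell identifiers.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path; `.csv` extension writes comma-separated,
#'   anything else tab-separated.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  dt <- data.table::data.table(cell_id = cell_ids(m))
  dt <- cbind(dt, data.table::as.data.table(m$values))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Remove cells with small library size
#'
#' Quality-control step on raw counts: cells whose total count (library
#' size) is strictly below `min_library_size` are dropped. Mirrors the
#' exclusion of samples with library size under 10,000 used for the
#' published datasets; a cell at exactly the threshold is retained.
#'
#' @param m An `ExpressionMatrix` of counts (`is_log = FALSE`).
#' @param min_library_size Minimum total count per cell; default 10000.
#' @return An `ExpressionMatrix` with the passing cells, genes unchanged,
#'   cell order preserved.
#' @export
qc_filter_cells <- function(m, min_library_size = 10000) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$is_log) {
    stop("qc_filter_cells() requires raw counts: library size is undefined ",
         "on logTPM values; run QC before logtpm_transform()")
  }
  if (min_library_size < 0) stop("min_library_size must be >= 0")
  keep <- rowSums(m$values) >= min_library_size
  ExpressionMatrix(m$values[keep, , drop = FALSE], is_log = FALSE)
}

#' Transform counts to logTPM
#'
#' Each cell's counts are scaled to sum to `scale` (transcripts-per-million
#' for the default 1e6; gene lengths are not used, so this is the
#' counts-per-million reading of TPM), then `log2(x + pseudocount)` is
#' applied elementwise.
#'
#' @param m An `ExpressionMatrix` of counts.
#' @param scale Per-cell total after normalization; default 1e6.
#' @param pseudocount Added before the log; default 1, so zeros map to zero.
#' @return An `ExpressionMatrix` with `is_log = TRUE`.
#' @export
logtpm_transform <- function(m, scale = 1e6, pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$is_log) stop("matrix is already logTPM-transformed")
  lib <- rowSums(m$values)
  if (any(lib == 0)) {
    stop("cell(s) with zero total count cannot be normalized: ",
         paste(utils::head(cell_ids(m)[lib == 0], 5), collapse = ", "))
  }
  tpm <- m$values / lib * scale
  ExpressionMatrix(log2(tpm + pseudocount), is_log = TRUE)
}

#' Read or write a cell label table
#'
#' Labels are a two-column CSV (`cell_id,label`) with a header row.
#'
#' @param path Path to the CSV file.
#' @return `read_labels()`: a data.frame with character columns `cell_id`
#'   and `label`.
#' @export
read_labels <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("label file must have two columns: cell_id,label")
  df <- df[, 1:2]
  names(df) <- c("cell_id", "label")
  if (any(!nzchar(df$label))) stop("empty label(s) in ", path)
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in ", path)
  df
}

#' @rdname read_labels
#' @param labels A data.frame with columns `cell_id` and `label`, or a named
#'   vector of labels.
#' @export
write_labels <- function(labels, path) {
  if (!is.data.frame(labels)) {
    labels <- data.frame(cell_id = names(labels),
                         label = as.vector(labels),
                         stringsAsFactors = FALSE)
  }
  data.table::fwrite(labels[, c("cell_id", "label")], path, sep = ",")
  invisible(path)
}
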