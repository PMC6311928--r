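#' Contingency table between two partitions
#'
#' Cross-tabulates two partitions of the same cells, matched by cell
#' identifier (never by position): entry `n_ij` is the number of cells in
#' cluster i of the first partition and cluster j of the second. Row sums
#' `a_i`, column sums `b_j` and the total `n` are attached.
#'
#' @param p1,p2 `Partition` objects (or named label vectors) over the same
#'   cell identifiers.
#' @return A `ContingencyTable`: list with integer matrix `n_ij`, margins
#'   `a_i`, `b_j`, and total `n`.
#' @export
contingency <- function(p1, p2) {
  l1 <- if (inherits(p1, "Partition")) p1$labels else p1
  l2 <- if (inherits(p2, "Partition")) p2$labels else p2
  if (is.null(names(l1)) || is.null(names(l2))) {
    stop("partitions must carry cell identifiers (named labels)")
  }
  only1 <- setdiff(names(l1), names(l2))
  only2 <- setdiff(names(l2), names(l1))
  if (length(only1) || length(only2)) {
    stop("partitions cover different cell sets; only in first: ",
         paste(utils::head(only1, 5), collapse = ", "),
         "; only in second: ", paste(utils::head(only2, 5), collapse = ", "))
  }
  l2 <- l2[names(l1)]
  tab <- table(l1, l2)
  n_ij <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                 dimnames = dimnames(tab))
  structure(list(n_ij = n_ij, a_i = rowSums(n_ij), b_j = colSums(n_ij),
                 n = sum(n_ij)),
            class = "ContingencyTable")
}

# exact C(x, 2) on integer-valued doubles; values stay well inside 2^53
choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\frac12\left[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E}, \quad
#'   E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' All binomial sums are accumulated exactly (integer-valued doubles)
#' before the single final division, so weak-agreement values do not
#' suffer cancellation. ARI is 1 iff the partitions are identical up to
#' relabeling and is near 0 for independent partitions.
#'
#' When both partitions are the same trivial partition (all singletons, or
#' one cluster) the denominator is 0; the conventional value 1 is returned
#' (set `degenerate = "error"` to raise instead).
#'
#' @param t A `ContingencyTable`, or a `Partition` (then `p2` is required
#'   and the table is built first).
#' @param p2 Second partition when `t` is a partition.
#' @param degenerate `"one"` (default) or `"error"`: behavior when both
#'   partitions are identical trivial partitions.
#' @return The ARI, a real number `<= 1`.
#' @export
adjusted_rand_index <- function(t, p2 = NULL, degenerate = c("one", "error")) {
  degenerate <- match.arg(degenerate)
  if (!inherits(t, "ContingencyTable")) t <- contingency(t, p2)
  if (t$n < 2) stop("ARI needs at least 2 cells")
  sum_nij <- sum(choose2(t$n_ij))
  sum_a <- sum(choose2(t$a_i))
  sum_b <- sum(choose2(t$b_j))
  expected <- sum_a * sum_b / choose2(t$n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    if (degenerate == "error") {
      stop("degenerate ARI: both partitions are the same trivial partition")
    }
    return(1)
  }
  (sum_nij - expected) / denom
}

#' Evaluate a label file pair
#'
#' Reads two label CSVs (`cell_id,label`), matches by cell identifier and
#' returns the ARI. Backs the `concluster eval` command.
#'
#' @param path1,path2 Paths to the two label CSVs.
#' @return The ARI.
#' @export
evaluate_labels <- function(path1, path2) {
  as_named <- function(df) stats::setNames(df$label, df$cell_id)
  adjusted_rand_index(contingency(as_named(read_labels(path1)),
                                  as_named(read_labels(path2))))
}
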