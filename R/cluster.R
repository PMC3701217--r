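#' Hierarchical clustering (Euclidean distance, UPGMA)
#'
#' Agglomerative clustering with average linkage (UPGMA) on Euclidean
#' distances, the scheme used for both expression heat maps and the
#' PeakScore matrix. Items are either the columns (samples, the default)
#' or the rows (features) of a numeric matrix held in a tibble whose
#' first character column labels rows.
#'
#' @param mat A tibble with one label column plus numeric columns, or a
#'   plain numeric matrix.
#' @param axis `"columns"` to cluster samples, `"rows"` for features.
#' @return An object of class `hclust` (leaf labels preserved).
#' @examples
#' m <- tibble::tibble(name = c("a", "b", "c"),
#'                     s1 = c(0, 0, 5), s2 = c(0, 1, 5))
#' hc <- hcluster(m, axis = "rows")
#' hc$merge
#' @export
hcluster <- function(mat, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  x <- as_numeric_matrix(mat)
  if (axis == "columns") x <- t(x)
  if (nrow(x) < 2L) abort("need at least 2 items to cluster")
  if (!all(is.finite(x))) abort("non-finite values in matrix")
  hclust(dist(x, method = "euclidean"), method = "average")
}

as_numeric_matrix <- function(mat) {
  if (is.matrix(mat)) return(mat)
  is_num <- vapply(mat, is.numeric, logical(1))
  x <- as.matrix(mat[is_num])
  lab <- mat[!is_num]
  rownames(x) <- if (ncol(lab) >= 1L) as.character(lab[[1L]]) else
    as.character(seq_len(nrow(x)))
  x
}

#' Two-group purity of a dendrogram against known labels
#'
#' Cuts the tree into two clusters and returns the best-matching
#' accuracy against a binary labelling: the maximum, over the two ways
#' of matching clusters to labels, of the fraction of items assigned to
#' their own group. 1 means the two groups separate perfectly; values
#' near 0.5 mean chance-level grouping.
#'
#' @param dendro An `hclust` object (see [hcluster()]).
#' @param labels Binary label vector, in the leaf-label order of the
#'   items clustered (named vectors are matched by name).
#' @return A proportion in \[0.5, 1\].
#' @export
cluster_purity <- function(dendro, labels) {
  stopifnot(inherits(dendro, "hclust"))
  k <- cutree(dendro, k = 2)
  if (!is.null(names(labels))) labels <- labels[names(k)]
  if (length(labels) != length(k)) abort("labels must match clustered items")
  lv <- unique(labels)
  if (length(lv) != 2L) abort("labels must have exactly 2 levels")
  acc <- mean((k == 1) == (labels == lv[1]))
  max(acc, 1 - acc)
}

#' Export a dendrogram as a Newick string
#'
#' @param dendro An `hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(dendro, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the 'ape' package")
  }
  phy <- ape::as.phylo(dendro)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Order a matrix by a clustering for heat-map export
#'
#' Reorders rows (and optionally columns) of a label + numeric tibble by
#' the leaf order of UPGMA dendrograms, the thin export used instead of
#' a styled heat map.
#'
#' @param mat A tibble with one label column plus numeric columns.
#' @param rows,columns Reorder that axis?
#' @return The reordered tibble.
#' @export
ordered_matrix <- function(mat, rows = TRUE, columns = TRUE) {
  x <- as_numeric_matrix(mat)
  lab_col <- names(mat)[!vapply(mat, is.numeric, logical(1))][1]
  if (rows && nrow(x) >= 2L) {
    mat <- mat[hcluster(mat, axis = "rows")$order, , drop = FALSE]
  }
  if (columns && ncol(x) >= 2L) {
    ord <- hcluster(mat, axis = "columns")$order
    num <- names(mat)[vapply(mat, is.numeric, logical(1))]
    mat <- mat[c(setdiff(names(mat), num), num[ord])]
  }
  mat
}
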