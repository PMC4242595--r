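#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of seeing at least the observed overlap when
#' `|set_a|` and `|set_b|` elements are drawn without replacement from a
#' common universe.
#'
#' @param set_a,set_b character vectors, both subsets of `universe`.
#' @param universe character vector of mutually assayable elements.
#' @return list of class `overlap_result`: universe_size, set_a_size,
#'   set_b_size, overlap_size, p_value.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stopf("elements outside the universe: %s",
          paste(head(c(out_a, out_b), 10), collapse = ", "))
  k <- length(intersect(set_a, set_b))
  n <- length(universe)
  p <- phyper(k - 1, length(set_a), n - length(set_a), length(set_b),
              lower.tail = FALSE)
  structure(list(universe_size = n, set_a_size = length(set_a),
                 set_b_size = length(set_b), overlap_size = k,
                 p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap %d of sets %d and %d in a universe of %d: hypergeometric P = %.3g\n",
              x$overlap_size, x$set_a_size, x$set_b_size, x$universe_size,
              x$p_value))
  invisible(x)
}

#' Direction-stratified overlap of two deregulated-gene lists
#'
#' Runs [overlap_test()] separately on the up-regulated and down-regulated
#' partitions and on the combined lists, mirroring the Venn comparison of
#' two cohorts' recurrently deregulated genes.
#'
#' @param rec_a,rec_b [recurrent_genes()] results (or data frames with
#'   `gene_id`, `direction`, `is_recurrent`).
#' @param universe gene universe; defaults to the intersection of the two
#'   results' gene universes.
#' @return named list of `overlap_result`: `up`, `down`, `combined`.
#' @export
overlap_deg_lists <- function(rec_a, rec_b, universe = NULL) {
  universe <- universe %||% intersect(rec_a$gene_id, rec_b$gene_id)
  pick <- function(r, dir) {
    g <- r$gene_id[r$is_recurrent &
                     (if (is.null(dir)) TRUE else r$direction == dir)]
    intersect(g, universe)
  }
  list(
    up = overlap_test(pick(rec_a, "up"), pick(rec_b, "up"), universe),
    down = overlap_test(pick(rec_a, "down"), pick(rec_b, "down"), universe),
    combined = overlap_test(pick(rec_a, NULL), pick(rec_b, NULL), universe)
  )
}

#' Uncentered Pearson correlation
#'
#' Cosine-like similarity used by Cluster 3.0:
#' `s = (1/n) * sum((x_i / sx) * (y_i / sy))` with `sx`, `sy` the
#' root-mean-square about zero (no mean-centering); `s` lies in \[-1, 1\].
#'
#' @param x,y numeric vectors of equal length >= 2, not all zero.
#' @return similarity in \[-1, 1\].
#' @export
uncentered_pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stopf("vectors must have equal length >= 2")
  if (all(x == 0) || all(y == 0))
    stopf("uncentered correlation undefined for an all-zero vector")
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Hierarchical clustering under the uncentered Pearson metric
#'
#' Agglomerative clustering of rows (or columns) on the dissimilarity
#' `d = 1 - s`, `s` the uncentered Pearson similarity, with average
#' linkage. Two-way clustering is obtained by calling once per axis.
#'
#' @param mat numeric matrix, no missing values.
#' @param axis `"rows"` or `"cols"`.
#' @param linkage agglomeration method (passed to [stats::hclust()];
#'   average linkage by default).
#' @param metric dissimilarity; `"uncentered"` only.
#' @return object of class `tag_dendro` wrapping the `hclust` fit: `merge`,
#'   `height`, `order`, `labels`, plus `linkage` and `metric` names.
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "cols"),
                                 linkage = "average",
                                 metric = "uncentered") {
  axis <- match.arg(axis)
  metric <- match.arg(metric, "uncentered")
  x <- if (axis == "cols") t(mat) else mat
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  if (nrow(x) < 2) stopf("need at least 2 items on the clustered axis")
  if (anyNA(x)) stopf("missing values are not supported")
  zero <- rowSums(x^2) == 0
  if (any(zero))
    stopf("constant-zero %s: %s", if (axis == "rows") "row(s)" else "column(s)",
          paste(rownames(x)[zero], collapse = ", "))
  xn <- x / sqrt(rowSums(x^2))
  d <- 1 - tcrossprod(xn)
  d[d < 0] <- 0                      # numerical guard
  hc <- hclust(as.dist(d), method = linkage)
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels,
                 linkage = linkage, metric = metric, axis = axis),
            class = "tag_dendro")
}

#' @export
print.tag_dendro <- function(x, ...) {
  cat(sprintf("%s dendrogram (%s linkage, %s metric): %d leaves, %d merges\n",
              x$axis, x$linkage, x$metric, length(x$order),
              nrow(x$merge)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' @param dendro a [hierarchical_cluster()] result.
#' @param k number of clusters.
#' @return named integer cluster assignment.
#' @export
cut_dendro <- function(dendro, k) {
  stopifnot(inherits(dendro, "tag_dendro"))
  cutree(dendro$hclust, k = k)
}

#' Export a clustered matrix with its trees
#'
#' Writes the matrix reordered by the dendrogram leaf orders
#' (`<prefix>_matrix.tsv`, first column `id`) and one tree file per axis
#' (`<prefix>_row_tree.tsv`, `<prefix>_col_tree.tsv`; columns `node`,
#' `left`, `right`, `height`, children named by leaf label or `nodeK`),
#' for external heat-map viewers.
#'
#' @param mat the matrix the dendrograms were built from.
#' @param row_dendro,col_dendro [hierarchical_cluster()] results for the
#'   two axes.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
cluster_heat_export <- function(mat, row_dendro, col_dendro, prefix) {
  stopifnot(inherits(row_dendro, "tag_dendro"),
            inherits(col_dendro, "tag_dendro"))
  if (length(row_dendro$order) != nrow(mat) ||
      length(col_dendro$order) != ncol(mat))
    stopf("dendrogram sizes do not match the matrix dimensions")
  ord <- mat[row_dendro$order, col_dendro$order, drop = FALSE]
  paths <- c(matrix = paste0(prefix, "_matrix.tsv"),
             rows = paste0(prefix, "_row_tree.tsv"),
             cols = paste0(prefix, "_col_tree.tsv"))
  df <- data.frame(id = rownames(ord), ord, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, paths["matrix"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_tree_tsv(row_dendro, paths["rows"])
  write_tree_tsv(col_dendro, paths["cols"])
  invisible(paths)
}

#' @noRd
write_tree_tsv <- function(dendro, path) {
  m <- dendro$merge
  lab <- dendro$labels
  child <- function(v) {
    out <- character(length(v))
    leaf <- v < 0
    out[leaf] <- lab[-v[leaf]]
    out[!leaf] <- paste0("node", v[!leaf])
    out
  }
  df <- data.frame(node = paste0("node", seq_len(nrow(m))),
                   left = child(m[, 1]), right = child(m[, 2]),
                   height = dendro$height, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Re-import an exported clustered matrix
#'
#' @param prefix the prefix given to [cluster_heat_export()].
#' @return list with `matrix` (leaf-ordered), `row_order` and `col_order`
#'   (leaf label vectors).
#' @export
cluster_heat_import <- function(prefix) {
  df <- read.delim(paste0(prefix, "_matrix.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  list(matrix = m, row_order = df$id, col_order = colnames(m))
}
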