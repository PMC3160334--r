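#' Manhattan distance with pairwise-complete handling
#'
#' Sum of absolute coordinate differences over positions where both vectors
#' are observed (no rescaling for missingness; the number of complete pairs
#' is recorded). Zero complete pairs yields a missing distance.
#'
#' @param u,v numeric vectors of equal length.
#' @return distance, with attribute `n_used`.
#' @export
manhattan_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  ok <- !is.na(u) & !is.na(v)
  if (!any(ok)) return(structure(NA_real_, n_used = 0L))
  structure(sum(abs(u[ok] - v[ok])), n_used = sum(ok))
}

manhattan_dist_matrix <- function(cols) {
  n <- ncol(cols)
  d <- matrix(0, n, n, dimnames = list(colnames(cols), colnames(cols)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- as.numeric(manhattan_distance(cols[, i], cols[, j]))
  stats::as.dist(d)
}

#' Hierarchical clustering of samples on normalized expression
#'
#' Agglomerative clustering of sample columns under the Manhattan distance,
#' restricted to a gene subset (e.g. the histone-demethylase genes), with
#' flat clusters extracted by cutting the tree into `k` groups. Sample
#' columns are put in sorted-id order before clustering, so the result is
#' exactly invariant to the input column order; remaining merge ties are
#' resolved by `stats::hclust`'s deterministic order-of-appearance rule,
#' which the sorting fixes.
#'
#' @param em a gene-normalized [expr_matrix()].
#' @param gene_subset genes to cluster on (default: all rows).
#' @param linkage_method one of `"average"` (default), `"complete"`,
#'   `"single"`.
#' @param k number of flat clusters (1 <= k <= n samples).
#' @return A `clustering_result`: the `hclust` tree, `leaf_order` (sample
#'   ids), `flat_labels` (named integer vector), and the metric/linkage
#'   metadata.
#' @export
cluster_samples <- function(em, gene_subset = NULL,
                            linkage_method = c("average", "complete", "single"),
                            k = 3L) {
  stopifnot(inherits(em, "expr_matrix"))
  linkage_method <- match.arg(linkage_method)
  if (em$scale != "gene_normalized")
    stop("cluster_samples expects a gene-normalized matrix")
  vals <- em$values
  if (!is.null(gene_subset)) {
    miss <- setdiff(gene_subset, rownames(vals))
    if (length(miss)) stop("gene_subset absent from matrix: ",
                           paste(miss, collapse = ", "))
    vals <- vals[gene_subset, , drop = FALSE]
  }
  if (k < 1L || k > ncol(vals))
    stop("k = ", k, " outside [1, ", ncol(vals), "]")
  vals <- vals[, order(colnames(vals)), drop = FALSE]
  d <- manhattan_dist_matrix(vals)
  if (anyNA(d)) stop("missing distances (no complete pairs for some sample pair)")
  tree <- hclust(d, method = linkage_method)
  labels <- cutree(tree, k = k)
  structure(list(tree = tree, leaf_order = tree$labels[tree$order],
                 flat_labels = labels, distance_metric = "manhattan",
                 linkage_method = linkage_method, k = k),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d samples, %s linkage, manhattan distance, k = %d\n",
              length(x$flat_labels), x$linkage_method, x$k))
  print(table(x$flat_labels))
  invisible(x)
}

#' Export a sample dendrogram as Newick and flat labels as TSV
#'
#' The merge tree is converted to a phylogeny (branch lengths derived from
#' merge heights) and written in Newick format readable by standard tree
#' viewers; flat cluster labels go to a two-column TSV.
#'
#' @param cl a `clustering_result`.
#' @param newick_path,labels_path output paths (either may be `NULL`).
#' @export
write_clustering <- function(cl, newick_path = NULL, labels_path = NULL) {
  if (!is.null(newick_path)) {
    phy <- ape::as.phylo(cl$tree)
    ape::write.tree(phy, file = newick_path)
  }
  if (!is.null(labels_path)) {
    df <- data.frame(sample_id = names(cl$flat_labels),
                     cluster = unname(cl$flat_labels))
    write.table(df, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(cl)
}
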