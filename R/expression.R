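#' Transcriptome-based terminal-cell classification
#'
#' Hierarchically clusters cells on pairwise Euclidean distances between
#' their expression profiles and cuts the dendrogram into exactly `k`
#' groups, which are then treated as transcriptome-based cell types. Rows
#' are ordered lexicographically by cell id before clustering so ties are
#' resolved deterministically.
#'
#' @param expr numeric matrix or data frame, cells in rows (rownames = cell
#'   ids), genes in columns; no missing values.
#' @param k number of clusters, `2 <= k <=` number of cells.
#' @param linkage agglomeration method: `"complete"` (default),
#'   `"average"` or `"single"`.
#' @return A `partition`: named integer vector of cluster labels with
#'   attributes `k` and `linkage`.
#' @export
cluster_cells <- function(expr, k, linkage = c("complete", "average",
                                               "single")) {
  linkage <- match.arg(linkage)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs cell ids as rownames")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (nrow(expr) < 2L || ncol(expr) < 1L) {
    stop("need at least 2 cells and 1 gene")
  }
  if (k < 2L || k > nrow(expr)) stop("k out of range")
  expr <- expr[order(rownames(expr)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(expr, method = "euclidean"),
                      method = linkage)
  part <- stats::cutree(hc, k = k)
  attr(part, "k") <- as.integer(k)
  attr(part, "linkage") <- linkage
  class(part) <- "partition"
  part
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(x), " cells in ", attr(x, "k"),
      " clusters\n", sep = "")
  invisible(x)
}

# Shannon entropy of a partition, in bits
partition_entropy <- function(p) {
  pr <- table(unclass(p)) / length(p)
  -sum(pr * log2(pr))
}

#' Mutual information between two partitions (bits)
#'
#' Computed from the joint contingency table of cluster labels over the
#' same cell set; `MI(p, p)` equals the entropy of `p`.
#'
#' @param p1,p2 partitions (named cluster-label vectors over identical
#'   cells).
#' @return Mutual information in bits.
#' @export
partition_mutual_information <- function(p1, p2) {
  if (is.null(names(p1)) || is.null(names(p2)) ||
        !setequal(names(p1), names(p2))) {
    stop("partitions must label identical, named cell sets")
  }
  p2 <- p2[names(p1)]
  joint <- table(unclass(p1), unclass(p2)) / length(p1)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Census from a partition
#'
#' Treats cluster labels as cell types and cluster sizes as type counts,
#' with no excluded types; feeds the rare-early analysis under a
#' transcriptome-based reclassification.
#'
#' @param partition a partition from [cluster_cells()].
#' @return A [cell_type_census()].
#' @export
partition_census <- function(partition) {
  if (!length(partition)) stop("empty partition")
  counts <- table(unclass(partition))
  cell_type_census(stats::setNames(as.integer(counts),
                                   paste0("cluster_", names(counts))))
}

#' Relabel a lineage's terminal types from a partition
#'
#' Replaces the type of every cell present in the partition by its cluster
#' label, enabling rare-early and robustness analyses under a
#' transcriptome-based classification. Cells absent from the partition
#' keep their original type unless `drop_unassigned` marks them excluded.
#'
#' @param lineage a [cell_lineage()].
#' @param partition a partition whose names are terminal-cell labels.
#' @return A new [cell_lineage()] with cluster-label types.
#' @export
apply_partition_types <- function(lineage, partition) {
  idx <- match(names(partition), lineage$tip_label)
  if (anyNA(idx)) {
    stop("partition names a cell absent from the lineage: ",
         names(partition)[which(is.na(idx))[1L]])
  }
  lin <- lineage
  lin$tip_type[idx] <- paste0("cluster_", unclass(partition))
  validate_cell_lineage(lin)
}

#' Read an expression matrix
#'
#' CSV or TSV with a header row of gene names and the first column holding
#' cell ids.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return Numeric matrix, cells in rows.
#' @export
read_expression <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}
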