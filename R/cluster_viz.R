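# Hierarchical clustering of the score matrix along either axis, Newick
# dendrogram export, and static annotated heatmap rendering.

#' Pairwise distance matrix over score-matrix rows or columns
#'
#' Euclidean distance is the L2 norm of the difference; Pearson distance is
#' \code{1 - r} with r the sample correlation, so perfectly correlated
#' vectors are at distance 0 and anti-correlated vectors at distance 2.
#'
#' @param scores A \code{\link{ScoreMatrix}} or numeric matrix.
#' @param metric \code{"euclidean"} or \code{"pearson"}.
#' @param axis Cluster \code{"rows"} (signatures) or \code{"columns"}
#'   (samples)?
#' @return A symmetric numeric matrix with zero diagonal and an attribute
#'   \code{metric}.
#' @export
distance_matrix <- function(scores, metric = c("euclidean", "pearson"),
                            axis = c("rows", "columns")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  m <- if (inherits(scores, "ScoreMatrix")) scores$scores else scores
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2L)
    stop("need at least 2 ", axis, " to cluster")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(m, method = "euclidean"))
  } else {
    v <- apply(m, 1L, stats::var)
    if (any(v == 0))
      stop("zero-variance vector(s) under pearson distance: ",
           paste(rownames(m)[v == 0], collapse = ", "))
    d <- 1 - stats::cor(t(m))
  }
  diag(d) <- 0
  attr(d, "metric") <- metric
  attr(d, "axis") <- axis
  d
}

#' Agglomerative clustering of a distance matrix
#'
#' Standard agglomerative hierarchical clustering (single, complete, average
#' or Ward linkage). Ward linkage is permitted only with Euclidean distances,
#' since its objective is defined for squared Euclidean geometry.
#'
#' @param dist A symmetric distance matrix (e.g. from
#'   \code{\link{distance_matrix}}).
#' @param linkage One of \code{"single"}, \code{"complete"} (default),
#'   \code{"average"}, \code{"ward"}.
#' @return A list of class \code{ClusterOrdering}: \code{leaf_order}
#'   (permutation of indices), \code{labels}, \code{merge_tree} (the merge
#'   matrix with heights), \code{metric}, \code{linkage}, \code{axis}, and
#'   the underlying \code{hclust} object.
#' @export
hierarchical_order <- function(dist, linkage = c("complete", "single",
                                                 "average", "ward")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(d < 0))
    stop("distances must be non-negative")
  metric <- attr(dist, "metric")
  if (linkage == "ward") {
    if (!is.null(metric) && metric != "euclidean")
      stop("ward linkage requires euclidean distances")
    method <- "ward.D2"
  } else method <- linkage
  hc <- stats::hclust(stats::as.dist(d), method = method)
  structure(list(leaf_order = hc$order, labels = hc$labels,
                 merge_tree = cbind(hc$merge, height = hc$height),
                 metric = metric, linkage = linkage,
                 axis = attr(dist, "axis"), hclust = hc),
            class = "ClusterOrdering")
}

#' @export
print.ClusterOrdering <- function(x, ...) {
  cat(sprintf("ClusterOrdering: %d leaves (%s linkage, %s distance)\n",
              length(x$leaf_order), x$linkage,
              if (is.null(x$metric)) "unspecified" else x$metric))
  invisible(x)
}

#' Serialize a dendrogram to Newick
#'
#' Writes the clustering as a Newick tree with merge heights as branch
#' lengths.
#'
#' @param ordering A \code{ClusterOrdering}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(ordering, path) {
  stopifnot(inherits(ordering, "ClusterOrdering"))
  ape::write.tree(ape::as.phylo(ordering$hclust), file = path)
  invisible(path)
}

#' Render an annotated heatmap of the score matrix
#'
#' Writes a static heatmap image plus a machine-readable companion table of
#' the reordered matrix (same path with a \code{.tsv} suffix). A symmetric
#' diverging palette centered at 0 is used when the matrix contains negative
#' values (e.g. after z-scoring), else a sequential palette. Star
#' annotations, when supplied, are drawn per cell.
#'
#' @param scores A \code{\link{ScoreMatrix}}.
#' @param row_order,col_order Optional \code{ClusterOrdering}s matching the
#'   matrix dimensions.
#' @param annotations Optional character matrix (e.g. stars), aligned with
#'   the score matrix, drawn inside the cells.
#' @param path Image output path; the extension selects the device
#'   (\code{.png} or \code{.pdf}).
#' @return Invisibly, \code{path}.
#' @export
render_heatmap <- function(scores, row_order = NULL, col_order = NULL,
                           annotations = NULL, path) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  m <- scores$scores
  if (!is.null(row_order)) {
    if (length(row_order$leaf_order) != nrow(m))
      stop("row ordering does not match the matrix dimensions")
    m <- m[row_order$leaf_order, , drop = FALSE]
  }
  if (!is.null(col_order)) {
    if (length(col_order$leaf_order) != ncol(m))
      stop("column ordering does not match the matrix dimensions")
    m <- m[, col_order$leaf_order, drop = FALSE]
  }
  ann <- FALSE
  if (!is.null(annotations)) {
    ann <- annotations[rownames(m), , drop = FALSE][, colnames(m), drop = FALSE]
  }
  if (any(m < 0)) {
    lim <- max(abs(m))
    breaks <- seq(-lim, lim, length.out = 101)
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
  } else {
    lo <- min(m); hi <- max(m)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
    breaks <- seq(lo, hi, length.out = 101)
    pal <- grDevices::colorRampPalette(c("#FFF5EB", "#FD8D3C", "#7F2704"))(100)
  }
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     color = pal, breaks = breaks,
                     display_numbers = ann, silent = TRUE,
                     filename = path)
  .write_matrix_tsv(m, paste0(path, ".tsv"))
  invisible(path)
}
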