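# Ranked-signature generation from a multi-sample expression compendium via
# proportional-median (PM) values: replicate averaging, probe->gene collapse,
# PM computation, top-k extraction.

#' Average biological replicates into condition columns
#'
#' Collapses the sample columns of an expression matrix into one column per
#' condition (tissue/cell/disease), each cell the arithmetic mean of the gene
#' over the condition's replicates.
#'
#' @param matrix An \code{\link{ExpressionMatrix}}.
#' @param replicate_map Named character vector mapping every sample name to a
#'   condition label.
#' @return An \code{\link{ExpressionMatrix}} with one column per condition,
#'   in order of first appearance in \code{replicate_map}.
#' @export
average_replicates <- function(matrix, replicate_map) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  samples <- colnames(matrix$values)
  missing <- setdiff(samples, names(replicate_map))
  if (length(missing))
    stop("samples without a condition assignment: ",
         paste(missing, collapse = ", "))
  cond <- as.character(replicate_map[samples])
  conditions <- unique(as.character(replicate_map))
  empty <- setdiff(conditions, cond)
  if (length(empty))
    stop("condition with zero samples: ", paste(empty, collapse = ", "))
  out <- vapply(unique(cond), function(cc)
    rowMeans(matrix$values[, cond == cc, drop = FALSE]),
    numeric(nrow(matrix$values)))
  out <- base::matrix(out, nrow = nrow(matrix$values),
                      dimnames = list(rownames(matrix$values), unique(cond)))
  ExpressionMatrix(out, transform_log = c(matrix$transform_log, "replicates_averaged"))
}

#' Collapse probe rows to gene rows
#'
#' For each gene, keeps the full row of the probe with the highest mean
#' intensity across all samples; other probes for the gene are discarded.
#' Probes absent from the map are dropped (their count is reported via a
#' message).
#'
#' @param matrix An \code{\link{ExpressionMatrix}} whose rows are probe ids.
#' @param probe_map Named character vector: probe id -> gene symbol
#'   (many-to-one allowed).
#' @return An \code{\link{ExpressionMatrix}} keyed by gene symbols.
#' @export
collapse_probes <- function(matrix, probe_map) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  probes <- rownames(matrix$values)
  mapped <- probes[probes %in% names(probe_map)]
  n_dropped <- length(probes) - length(mapped)
  if (!length(mapped))
    stop("no probes in the matrix are present in the probe map")
  if (n_dropped > 0L)
    message(n_dropped, " unmapped probe(s) dropped")
  vals <- matrix$values[mapped, , drop = FALSE]
  gene <- as.character(probe_map[mapped])
  means <- rowMeans(vals)
  # per gene keep the probe with maximal mean; which.max keeps input order at ties
  keep <- vapply(split(seq_along(gene), gene)[unique(gene)],
                 function(idx) idx[which.max(means[idx])], integer(1))
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- unique(gene)
  ExpressionMatrix(out, transform_log = c(matrix$transform_log, "probes_collapsed"))
}

#' Compute proportional-median (PM) values
#'
#' The PM value of a gene in a condition is its intensity divided by the
#' median intensity of the same gene across all conditions of the series.
#' High PM marks condition-specific over-expression. Rows whose median is 0
#' are dropped (reported via a message); callers with multi-series compendia
#' must split the series and call this per series.
#'
#' @param matrix An \code{\link{ExpressionMatrix}} with non-negative values
#'   and at least 2 condition columns, all from one data series.
#' @return A list of class \code{PMMatrix} with \code{pm_values} (genes x
#'   conditions matrix), \code{gene_ids} and \code{condition_ids}.
#' @export
compute_pm <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  if (ncol(v) < 2L)
    stop("PM values need at least 2 conditions (a median over one sample is degenerate)")
  if (any(v < 0))
    stop("PM values require non-negative expression values")
  med <- apply(v, 1L, stats::median)
  zero <- med == 0
  if (any(zero)) {
    message(sum(zero), " gene row(s) with zero median dropped")
    v <- v[!zero, , drop = FALSE]
    med <- med[!zero]
  }
  if (!nrow(v))
    stop("all gene rows have zero median")
  pm <- v / med
  structure(list(pm_values = pm, gene_ids = rownames(pm),
                 condition_ids = colnames(pm)),
            class = "PMMatrix")
}

#' @export
print.PMMatrix <- function(x, ...) {
  cat(sprintf("PMMatrix: %d genes x %d conditions\n",
              nrow(x$pm_values), ncol(x$pm_values)))
  invisible(x)
}

#' Extract ranked signatures from a PM matrix
#'
#' One ranked signature per condition: genes sorted by descending PM in that
#' condition, truncated to the top \code{k}. Ties at the boundary are broken
#' by gene-id lexicographic order so regeneration is deterministic.
#'
#' @param pm A \code{PMMatrix} from \code{\link{compute_pm}}.
#' @param k Signature size (default 50). If \code{k} exceeds the gene count,
#'   every gene is retained, fully ranked.
#' @return A \code{\link{SignatureCollection}} of ranked signatures, named by
#'   condition.
#' @export
extract_signatures <- function(pm, k = savant_defaults()$top_k) {
  stopifnot(inherits(pm, "PMMatrix"), k >= 1L)
  genes <- pm$gene_ids
  sigs <- list()
  for (cc in pm$condition_ids) {
    v <- pm$pm_values[, cc]
    ord <- order(-v, genes, method = "radix")
    top <- ord[seq_len(min(k, length(ord)))]
    sigs[[cc]] <- list(genes = genes[top], pm = unname(v[top]), ranked = TRUE)
  }
  SignatureCollection(sigs, source = "proportional-median signature generation")
}

#' Generate ranked signatures from a compendium in one call
#'
#' Convenience wrapper chaining \code{\link{average_replicates}},
#' \code{\link{collapse_probes}} and \code{\link{compute_pm}} into
#' \code{\link{extract_signatures}}. The probe collapse, when a probe map is
#' supplied, runs before PM computation by default.
#'
#' @param matrix An \code{\link{ExpressionMatrix}} (probes or genes as rows).
#' @param k Signature size.
#' @param replicate_map Optional sample -> condition map.
#' @param probe_map Optional probe -> gene map.
#' @param collapse_first If \code{TRUE} (default) probes are collapsed to
#'   genes before PM computation; if \code{FALSE}, PM is computed at the
#'   probe level and probes collapsed afterwards by maximal mean intensity.
#' @return A \code{\link{SignatureCollection}} of ranked signatures.
#' @export
generate_signatures <- function(matrix, k = savant_defaults()$top_k,
                                replicate_map = NULL, probe_map = NULL,
                                collapse_first = TRUE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!is.null(replicate_map))
    matrix <- average_replicates(matrix, replicate_map)
  if (!is.null(probe_map) && collapse_first)
    matrix <- collapse_probes(matrix, probe_map)
  pm <- compute_pm(matrix)
  if (!is.null(probe_map) && !collapse_first) {
    pm_as_em <- ExpressionMatrix(pm$pm_values)
    # reuse the max-mean-intensity probe choice, measured on the raw matrix
    means <- rowMeans(matrix$values)[rownames(pm$pm_values)]
    gene <- as.character(probe_map[rownames(pm$pm_values)])
    keep <- vapply(split(seq_along(gene), gene)[unique(gene[!is.na(gene)])],
                   function(idx) idx[which.max(means[idx])], integer(1))
    v <- pm$pm_values[keep, , drop = FALSE]
    rownames(v) <- unique(gene[!is.na(gene)])
    pm <- structure(list(pm_values = v, gene_ids = rownames(v),
                         condition_ids = colnames(v)), class = "PMMatrix")
  }
  extract_signatures(pm, k = k)
}
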