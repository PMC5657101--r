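#' Construct an ExpressionMatrix
#'
#' An \code{ExpressionMatrix} bundles a genes-by-samples numeric matrix with
#' optional integer sample-group labels and a log of the transforms that have
#' been applied to it (e.g. \code{"log2"}, \code{"rank"}).
#'
#' @param values Numeric matrix with gene symbols as row names and sample
#'   names as column names.
#' @param groups Optional named integer vector mapping every sample name to a
#'   group code, or \code{NULL}.
#' @param transform_log Character vector of transform tags already applied, in
#'   order.
#' @return An object of class \code{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, groups = NULL, transform_log = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("gene symbols must be unique; collapse duplicates first")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!is.null(groups)) {
    groups <- as.integer(groups[colnames(values)])
    if (anyNA(groups))
      stop("'groups' must assign an integer code to every sample")
    names(groups) <- colnames(values)
  }
  structure(
    list(values = values, groups = groups, transform_log = as.character(transform_log)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%d (n=%d)", as.integer(names(table(x$groups))),
                                   as.integer(table(x$groups))), collapse = ", "), "\n")
  if (length(x$transform_log))
    cat("  transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a SignatureCollection
#'
#' A collection of molecular signatures. Each signature is either ranked (an
#' ordered gene list with non-increasing proportional-median values) or
#' unranked (an MSigDB-style gene set).
#'
#' @param signatures Named list; each element is a list with components
#'   \code{genes} (character), \code{pm} (numeric, same length, or
#'   \code{NULL} for unranked sets) and \code{ranked} (logical flag).
#' @param source Free-text provenance string.
#' @return An object of class \code{SignatureCollection}.
#' @export
SignatureCollection <- function(signatures, source = "") {
  if (is.null(names(signatures)) || anyDuplicated(names(signatures)))
    stop("signatures must be a uniquely named list")
  for (nm in names(signatures)) {
    sig <- signatures[[nm]]
    if (anyDuplicated(sig$genes))
      stop("duplicate gene symbols within signature '", nm, "'")
    if (isTRUE(sig$ranked)) {
      if (is.null(sig$pm) || length(sig$pm) != length(sig$genes))
        stop("ranked signature '", nm, "' must carry one PM value per gene")
      if (is.unsorted(rev(sig$pm)))
        stop("ranked signature '", nm, "' must have non-increasing PM values")
    }
  }
  structure(list(signatures = signatures, source = source),
            class = "SignatureCollection")
}

#' @export
print.SignatureCollection <- function(x, ...) {
  n_ranked <- sum(vapply(x$signatures, function(s) isTRUE(s$ranked), logical(1)))
  cat(sprintf("SignatureCollection: %d signatures (%d ranked, %d unranked)\n",
              length(x$signatures), n_ranked, length(x$signatures) - n_ranked))
  invisible(x)
}

#' @export
length.SignatureCollection <- function(x) length(x$signatures)

#' @export
names.SignatureCollection <- function(x) names(x$signatures)

#' Construct a ScoreMatrix
#'
#' The signature-sample matrix: rows are signatures, columns are samples, and
#' each cell holds the mean (or sum) of the signature's gene values in that
#' sample, possibly further transformed.
#'
#' @param scores Numeric matrix, signatures x samples, with dimnames.
#' @param genes_used Named integer vector: per signature, the number of
#'   signature genes found in the expression matrix.
#' @param params List recording scoring parameters (mode, k, transforms).
#' @param pvalues Optional matrix of per-cell empirical p-values, aligned with
#'   \code{scores}.
#' @param anova Optional data frame of per-signature ANOVA results.
#' @return An object of class \code{ScoreMatrix}.
#' @export
ScoreMatrix <- function(scores, genes_used, params = list(),
                        pvalues = NULL, anova = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("'scores' must be a numeric matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("'scores' must have signature row names and sample column names")
  genes_used <- genes_used[rownames(scores)]
  if (anyNA(genes_used))
    stop("'genes_used' must cover every signature row")
  if (!is.null(pvalues) && !identical(dimnames(pvalues), dimnames(scores)))
    stop("'pvalues' must be aligned cell-for-cell with 'scores'")
  structure(list(scores = scores, genes_used = genes_used, params = params,
                 pvalues = pvalues, anova = anova),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d signatures x %d samples (mode=%s)\n",
              nrow(x$scores), ncol(x$scores),
              if (is.null(x$params$mode)) "?" else x$params$mode))
  if (!is.null(x$pvalues)) cat("  with per-cell empirical p-values\n")
  if (!is.null(x$anova)) cat("  with per-signature ANOVA\n")
  invisible(x)
}

#' @export
dim.ScoreMatrix <- function(x) dim(x$scores)

#' Shipped defaults
#'
#' Returns the tool's shipped defaults: signature truncation size, the menu of
#' selectable sizes, the number of permutations for empirical p-values, and
#' whether a group-label row in the input auto-triggers ANOVA.
#'
#' @return A list with components \code{top_k}, \code{size_menu},
#'   \code{permutations}, \code{anova_auto}, \code{mode}, \code{group_tag}.
#' @export
savant_defaults <- function() {
  list(
    top_k = 50L,
    size_menu = c(10L, 25L, 50L, 100L, 250L, 500L, 1000L),
    permutations = 10000L,
    anova_auto = TRUE,
    mode = "mean",
    group_tag = "SAVANT_GROUP"
  )
}
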