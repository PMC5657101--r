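# Signature-sample scoring: expression transforms (log, rank), per-cell
# mean/sum scores over signature genes, and score-matrix post-processing
# (sqrt-size scaling, difference from row mean, grand z-score, min-value
# filter).

#' Transform an expression matrix (log and/or rank)
#'
#' Applies the optional transforms in their fixed order: log first, then
#' conversion to ranks. The log transform is base-2 with a pseudocount of 1,
#' i.e. \code{log2(x + 1)}. Ranks are computed within each sample column,
#' ascending (highest expression receives the highest rank), with ties
#' assigned the mean of the tied ranks.
#'
#' @param matrix An \code{\link{ExpressionMatrix}}.
#' @param log_flag Apply \code{log2(x + 1)}? Requires non-negative values.
#' @param rank_flag Convert each sample column to ranks?
#' @return A transformed \code{\link{ExpressionMatrix}} with the applied
#'   transforms appended to its \code{transform_log}.
#' @export
transform_expression <- function(matrix, log_flag = FALSE, rank_flag = FALSE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  log_tags <- matrix$transform_log
  if (log_flag) {
    if (any(v < 0))
      stop("log transform requires non-negative expression values")
    v <- log2(v + 1)
    log_tags <- c(log_tags, "log2")
  }
  if (rank_flag) {
    v <- apply(v, 2L, rank, ties.method = "average")
    rownames(v) <- rownames(matrix$values)
    log_tags <- c(log_tags, "rank")
  }
  ExpressionMatrix(v, groups = matrix$groups, transform_log = log_tags)
}

#' Score signatures across individual samples
#'
#' Builds the signature-sample matrix: each cell is the mean (default) or sum
#' of the expression values, in one sample, of the signature genes found in
#' the matrix. Ranked signatures are truncated to their top \code{k} genes;
#' unranked (MSigDB-style) sets are used whole regardless of \code{k}. Genes
#' absent from the matrix are skipped; the number of genes actually used is
#' recorded per signature.
#'
#' @param matrix An \code{\link{ExpressionMatrix}} (transformed or not).
#' @param sigs A \code{\link{SignatureCollection}}.
#' @param mode \code{"mean"} or \code{"sum"}.
#' @param k Truncation size for ranked signatures (default 50).
#' @param min_genes Signatures with fewer than this many genes present in the
#'   matrix are removed from the output.
#' @return A \code{\link{ScoreMatrix}}. Signatures with zero present genes
#'   are always removed (with a warning) to avoid 0/0 cells; dropped counts
#'   are recorded in \code{params$dropped_by_min_genes}.
#' @export
score_signatures <- function(matrix, sigs, mode = c("mean", "sum"),
                             k = savant_defaults()$top_k, min_genes = 0L) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(sigs, "SignatureCollection"))
  mode <- match.arg(mode)
  stopifnot(k >= 1L, min_genes >= 0L)
  v <- matrix$values
  universe <- rownames(v)
  sig_names <- names(sigs$signatures)
  scores <- base::matrix(NA_real_, nrow = length(sig_names), ncol = ncol(v),
                         dimnames = list(sig_names, colnames(v)))
  genes_used <- stats::setNames(integer(length(sig_names)), sig_names)
  for (nm in sig_names) {
    s <- sigs$signatures[[nm]]
    g <- s$genes
    if (isTRUE(s$ranked))
      g <- g[seq_len(min(k, length(g)))]
    present <- g[g %in% universe]
    genes_used[nm] <- length(present)
    if (!length(present)) next
    cs <- colSums(v[present, , drop = FALSE])
    scores[nm, ] <- if (mode == "mean") cs / length(present) else cs
  }
  empty <- genes_used == 0L
  if (any(empty))
    warning(sum(empty), " signature(s) with no genes in the matrix removed: ",
            paste(utils::head(sig_names[empty], 5L), collapse = ", "))
  keep <- !empty & genes_used >= min_genes
  if (!any(keep))
    stop("every signature was filtered out (min_genes = ", min_genes, ")")
  ScoreMatrix(scores[keep, , drop = FALSE], genes_used[keep],
              params = list(mode = mode, k = k, min_genes = min_genes,
                            transform_log = matrix$transform_log,
                            dropped_by_min_genes = sum(!keep),
                            postprocess = character()))
}

#' Post-process a score matrix
#'
#' Applies, in this fixed order: (1) \code{scale_sqrt}: multiply each
#' signature row by the square root of its present-gene count, making mean
#' scores comparable across signature sizes; (2) \code{diff_from_mean}:
#' subtract each signature row's mean across samples; (3) \code{zscore}:
#' subtract the grand mean of the entire matrix and divide by its grand
#' standard deviation (population convention, denominator = cell count);
#' (4) \code{min_value}: drop signature rows whose maximum falls below the
#' threshold.
#'
#' @param scores A \code{\link{ScoreMatrix}}.
#' @param diff_from_mean Subtract per-signature row means? Mutually exclusive
#'   with \code{zscore}.
#' @param zscore Convert to grand-matrix z-scores?
#' @param scale_sqrt Scale rows by \code{sqrt(genes_used)}?
#' @param min_value Optional numeric display threshold.
#' @return The transformed \code{\link{ScoreMatrix}}; applied steps are
#'   appended to \code{params$postprocess}, and rows dropped by
#'   \code{min_value} counted in \code{params$dropped_by_min_value}.
#' @export
postprocess_scores <- function(scores, diff_from_mean = FALSE, zscore = FALSE,
                               scale_sqrt = FALSE, min_value = NULL) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  if (diff_from_mean && zscore)
    stop("diff_from_mean and zscore are mutually exclusive rescalings")
  m <- scores$scores
  gu <- scores$genes_used
  steps <- scores$params$postprocess
  if (scale_sqrt) {
    m <- m * sqrt(gu[rownames(m)])
    steps <- c(steps, "scale_sqrt")
  }
  if (diff_from_mean) {
    m <- m - rowMeans(m)
    steps <- c(steps, "diff_from_mean")
  }
  if (zscore) {
    mu <- mean(m)
    sd_pop <- sqrt(mean((m - mu)^2))
    if (sd_pop == 0)
      stop("cannot z-score a constant score matrix (grand standard deviation is 0)")
    m <- (m - mu) / sd_pop
    steps <- c(steps, "zscore")
  }
  dropped <- 0L
  if (!is.null(min_value)) {
    keep <- apply(m, 1L, max) >= min_value
    if (!any(keep))
      stop("min_value = ", min_value, " removed every signature")
    dropped <- sum(!keep)
    m <- m[keep, , drop = FALSE]
    gu <- gu[rownames(m)]
    steps <- c(steps, sprintf("min_value=%g", min_value))
  }
  params <- scores$params
  params$postprocess <- steps
  params$dropped_by_min_value <- dropped
  pv <- scores$pvalues
  if (!is.null(pv)) pv <- pv[rownames(m), , drop = FALSE]
  ScoreMatrix(m, gu, params = params, pvalues = pv, anova = scores$anova)
}
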