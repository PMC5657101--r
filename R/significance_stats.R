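# Statistical evidence for signature scores: permutation-based empirical
# p-values per signature-sample cell, one-way ANOVA per signature across
# declared sample groups, star annotations, and p-value filtering.

#' Empirical p-values for signature scores by random gene-set draws
#'
#' For each signature with m present genes and each sample, draws
#' \code{n_perm} random gene sets of size m uniformly without replacement
#' from the matrix's gene universe, scores them with the same mode as the
#' observed scores, and reports the one-sided upper-tail empirical p-value
#' with an add-one guard:
#' \code{p = (1 + #\{null >= observed\}) / (n_perm + 1)}.
#'
#' Gene-label resampling preserves each sample's expression distribution
#' exactly. Null draws are stratified by present-gene count m and cached per
#' m, so signatures of equal size share null sets and each null set's member
#' genes are scored in every sample. A single seeded random stream is
#' consumed with signatures processed in output order, so results are
#' bit-reproducible.
#'
#' @param matrix The \code{\link{ExpressionMatrix}} the scores were computed
#'   from (after any transforms).
#' @param sigs The \code{\link{SignatureCollection}} that was scored (used
#'   only for validation; sizes come from \code{scores$genes_used}).
#' @param scores The observed \code{\link{ScoreMatrix}} (mean or sum mode).
#' @param n_perm Number of random gene sets per signature size
#'   (default 10,000).
#' @param seed Integer seed for the random stream.
#' @return The \code{\link{ScoreMatrix}} with a \code{pvalues} matrix
#'   attached; its attributes record \code{n_permutations} and \code{seed}.
#'   Every p-value lies in \code{[1/(n_perm+1), 1]}.
#' @export
permutation_pvalues <- function(matrix, sigs, scores,
                                n_perm = savant_defaults()$permutations,
                                seed) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(scores, "ScoreMatrix"))
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  v <- matrix$values
  n_genes <- nrow(v)
  sizes <- scores$genes_used
  if (any(sizes > n_genes))
    stop("signature size exceeds the gene universe (",
         max(sizes), " > ", n_genes, ")")
  if (any(sizes < 1L))
    stop("signatures with zero present genes cannot be tested")
  mode <- scores$params$mode
  if (is.null(mode)) mode <- "mean"

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  pvals <- scores$scores
  pvals[] <- NA_real_
  null_cache <- new.env(parent = emptyenv())
  # signatures in output order; null scores cached per present-gene count
  for (nm in rownames(scores$scores)) {
    m <- sizes[[nm]]
    key <- as.character(m)
    if (is.null(null_cache[[key]])) {
      null_scores <- base::matrix(NA_real_, nrow = n_perm, ncol = ncol(v))
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n_genes, m)
        cs <- colSums(v[idx, , drop = FALSE])
        null_scores[i, ] <- if (mode == "mean") cs / m else cs
      }
      null_cache[[key]] <- null_scores
    }
    null_scores <- null_cache[[key]]
    obs <- scores$scores[nm, ]
    exceed <- colSums(null_scores >= rep(obs, each = n_perm))
    pvals[nm, ] <- (1 + exceed) / (n_perm + 1)
  }
  attr(pvals, "n_permutations") <- as.integer(n_perm)
  attr(pvals, "seed") <- as.integer(seed)
  ScoreMatrix(scores$scores, scores$genes_used, params = scores$params,
              pvalues = pvals, anova = scores$anova)
}

#' One-way ANOVA per signature across sample groups
#'
#' For each signature row of the score matrix, runs a classical one-way
#' fixed-effects ANOVA of scores across the declared sample groups:
#' F = (between-group SS / (g-1)) / (within-group SS / (n-g)), with the
#' p-value from the F distribution on (g-1, n-g) degrees of freedom.
#' A constant row (zero between- and within-group SS) is reported as F = 0,
#' p = 1; perfect separation (zero within-group SS, distinct means) is
#' reported at the smallest representable p.
#'
#' @param scores A \code{\link{ScoreMatrix}}.
#' @param groups Named integer vector mapping every sample name to a group
#'   code; at least 2 groups, each with at least 2 samples.
#' @return A data frame with columns \code{signature}, \code{F},
#'   \code{p.value}, \code{stars}, one row per signature.
#' @export
anova_by_group <- function(scores, groups) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  samples <- colnames(scores$scores)
  g <- groups[samples]
  if (anyNA(g))
    stop("every sample needs a group code")
  tab <- table(g)
  if (length(tab) < 2L)
    stop("ANOVA needs at least 2 groups")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  fg <- factor(g)
  res <- lapply(rownames(scores$scores), function(nm) {
    y <- scores$scores[nm, ]
    within_ss <- sum(tapply(y, fg, function(x) sum((x - mean(x))^2)))
    between_ss <- sum(tapply(y, fg, function(x) length(x) * (mean(x) - mean(y))^2))
    if (between_ss == 0 && within_ss == 0)
      return(c(F = 0, p = 1))
    if (within_ss == 0)
      return(c(F = Inf, p = .Machine$double.xmin))
    ow <- stats::oneway.test(y ~ fg, var.equal = TRUE)
    c(F = unname(ow$statistic), p = max(unname(ow$p.value), .Machine$double.xmin))
  })
  res <- do.call(rbind, res)
  data.frame(signature = rownames(scores$scores),
             F = res[, "F"], p.value = res[, "p"],
             stars = significance_stars(res[, "p"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Star annotation for a p-value
#'
#' Maps p-values to the significance labels used in the ANOVA output:
#' \code{"***"} for p <= 0.0001, \code{"**"} for p <= 0.001, \code{"*"} for
#' p <= 0.01, otherwise \code{""}.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- character(length(p))
  out[p <= 0.01] <- "*"
  out[p <= 0.001] <- "**"
  out[p <= 0.0001] <- "***"
  out
}

#' Filter a score matrix by ANOVA p-value
#'
#' Keeps exactly the signatures whose ANOVA p-value is strictly below
#' \code{alpha}, preserving row order.
#'
#' @param scores A \code{\link{ScoreMatrix}}.
#' @param anova The ANOVA table from \code{\link{anova_by_group}}, covering
#'   every signature row.
#' @param alpha Significance threshold (the group-discrimination examples use
#'   0.0001).
#' @return The filtered \code{\link{ScoreMatrix}}; the number of rows removed
#'   is recorded in \code{params$dropped_by_alpha}.
#' @export
filter_by_pvalue <- function(scores, anova, alpha) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  p <- stats::setNames(anova$p.value, anova$signature)[rownames(scores$scores)]
  if (anyNA(p))
    stop("every retained signature needs an ANOVA p-value")
  keep <- p < alpha
  if (!any(keep))
    stop("no signature passes the p < ", alpha, " filter")
  params <- scores$params
  params$dropped_by_alpha <- sum(!keep)
  pv <- scores$pvalues
  if (!is.null(pv)) pv <- pv[keep, , drop = FALSE]
  ScoreMatrix(scores$scores[keep, , drop = FALSE],
              scores$genes_used[keep], params = params, pvalues = pv,
              anova = anova[anova$signature %in% rownames(scores$scores)[keep], ])
}
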