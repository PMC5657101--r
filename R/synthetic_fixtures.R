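# Synthetic expression data with recorded ground truth: spiked gene sets in
# grouped sample matrices (for scoring/statistics validation) and marker-gene
# compendia with replicates (for signature-generation validation).
#
# Background expression is i.i.d. log-normal — 2^N(6, 1), i.e. location 6 and
# scale 1 on the log2 scale — mimicking normalized array intensities. Spikes
# are multiplicative, matching the ratio semantics of proportional medians.

.with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

.gene_names <- function(n) sprintf("GENE%05d", seq_len(n))

#' Generate a grouped expression matrix with spiked gene sets
#'
#' Draws an i.i.d. log-normal background (2^N(6,1)) over \code{n_genes} genes
#' and \code{n_samples} samples, then multiplies each spiked gene set by its
#' fold change in the samples of its target group. Spiked sets are disjoint
#' by construction. The matching true signatures and a ground-truth record
#' are returned alongside the matrix.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples.
#' @param groups Named integer vector mapping each sample name to a group
#'   code, or an unnamed integer vector of length \code{n_samples}.
#' @param spikes List of spikes, each a list with \code{size} (gene-set
#'   size), \code{group} (target group code) and \code{fold} (multiplicative
#'   fold change > 0).
#' @param seed Integer seed; regeneration from the same parameters and seed
#'   is bit-identical.
#' @return A list with \code{matrix} (an \code{\link{ExpressionMatrix}} with
#'   group labels), \code{signatures} (unranked
#'   \code{\link{SignatureCollection}} of the true spiked sets) and
#'   \code{truth} (a \code{SyntheticTruth} record).
#' @export
generate_dataset <- function(n_genes, n_samples, groups, spikes = list(), seed) {
  total_spiked <- sum(vapply(spikes, function(s) as.integer(s$size), integer(1)))
  if (total_spiked > n_genes)
    stop("spiked gene demands (", total_spiked, ") exceed the gene pool (",
         n_genes, ")")
  if (any(vapply(spikes, function(s) s$fold <= 0, logical(1))))
    stop("fold changes must be positive")
  if (is.null(names(groups)))
    names(groups) <- sprintf("sample%02d", seq_len(n_samples))
  stopifnot(length(groups) == n_samples)
  .with_seed(seed, {
    vals <- base::matrix(2^stats::rnorm(n_genes * n_samples, mean = 6, sd = 1),
                         nrow = n_genes,
                         dimnames = list(.gene_names(n_genes), names(groups)))
    pool <- sample.int(n_genes)  # disjoint blocks of a random permutation
    offset <- 0L
    sig_list <- list()
    spiked <- list()
    for (i in seq_along(spikes)) {
      sp <- spikes[[i]]
      idx <- pool[offset + seq_len(sp$size)]
      offset <- offset + as.integer(sp$size)
      target <- names(groups)[groups == sp$group]
      vals[idx, target] <- vals[idx, target] * sp$fold
      nm <- sprintf("SPIKE%02d", i)
      sig_list[[nm]] <- list(genes = rownames(vals)[sort(idx)], pm = NULL,
                             ranked = FALSE)
      spiked[[nm]] <- list(signature = nm, genes = rownames(vals)[sort(idx)],
                           group = sp$group, fold = sp$fold)
    }
    truth <- structure(list(spiked = spiked,
                            background_law = "2^Normal(mean=6, sd=1) on log2 scale",
                            seed = as.integer(seed)),
                       class = "SyntheticTruth")
    sigs <- if (length(sig_list))
      SignatureCollection(sig_list, source = "synthetic spike-in truth")
    else SignatureCollection(stats::setNames(list(), character()),
                             source = "synthetic (no spikes)")
    list(matrix = ExpressionMatrix(vals, groups = groups),
         signatures = sigs, truth = truth)
  })
}

#' Generate a replicated compendium with condition-specific markers
#'
#' Builds an expression compendium of \code{n_conditions} conditions with
#' \code{replicates_per_condition} replicates each. Every condition receives
#' a disjoint marker set of \code{markers_per_condition} genes, upregulated
#' \code{fold}-fold in its replicates over the log-normal background. Used to
#' exercise the replicate-averaging / PM / signature-extraction path against
#' recorded truth.
#'
#' @param n_conditions Number of conditions.
#' @param replicates_per_condition Replicates per condition.
#' @param markers_per_condition Marker genes per condition.
#' @param fold Multiplicative upregulation of markers (> 0).
#' @param seed Integer seed.
#' @param n_genes Size of the gene pool (default 2000).
#' @return A list with \code{matrix} (an \code{\link{ExpressionMatrix}} of
#'   samples named \code{<condition>_r<j>}), \code{replicate_map} (sample ->
#'   condition) and \code{truth} (marker sets per condition).
#' @export
generate_compendium <- function(n_conditions, replicates_per_condition,
                                markers_per_condition, fold, seed,
                                n_genes = 2000L) {
  if (n_conditions * markers_per_condition > n_genes)
    stop("marker demands exceed the gene pool")
  if (fold <= 0) stop("fold must be positive")
  .with_seed(seed, {
    conds <- sprintf("COND%02d", seq_len(n_conditions))
    samples <- as.vector(t(outer(conds, seq_len(replicates_per_condition),
                                 function(c, r) sprintf("%s_r%d", c, r))))
    replicate_map <- stats::setNames(rep(conds, each = replicates_per_condition),
                                     samples)
    vals <- base::matrix(2^stats::rnorm(n_genes * length(samples), 6, 1),
                         nrow = n_genes,
                         dimnames = list(.gene_names(n_genes), samples))
    pool <- sample.int(n_genes)
    spiked <- list()
    for (i in seq_along(conds)) {
      idx <- pool[(i - 1L) * markers_per_condition + seq_len(markers_per_condition)]
      reps <- samples[replicate_map == conds[i]]
      vals[idx, reps] <- vals[idx, reps] * fold
      spiked[[conds[i]]] <- list(signature = conds[i],
                                 genes = rownames(vals)[sort(idx)],
                                 group = i, fold = fold)
    }
    truth <- structure(list(spiked = spiked,
                            background_law = "2^Normal(mean=6, sd=1) on log2 scale",
                            seed = as.integer(seed)),
                       class = "SyntheticTruth")
    list(matrix = ExpressionMatrix(vals), replicate_map = replicate_map,
         truth = truth)
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d spiked set(s), background %s, seed %d\n",
              length(x$spiked), x$background_law, x$seed))
  invisible(x)
}
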