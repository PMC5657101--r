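# End-to-end pipeline: read -> transform -> score -> postprocess ->
# statistics -> cluster -> render, with a JSON run manifest. The only
# order constraint the transforms impose is log before rank; everything
# else follows the fixed stage order declared in the manifest.

#' Build a validated pipeline configuration
#'
#' @param expression Path to the expression matrix, or an
#'   \code{\link{ExpressionMatrix}}.
#' @param signatures Path to a GMT file or ranked-signature table, or a
#'   \code{\link{SignatureCollection}}.
#' @param outdir Output directory (created if absent).
#' @param mode Scoring mode, \code{"mean"} or \code{"sum"}.
#' @param top_k Ranked-signature truncation size (default 50).
#' @param log_transform,rank_transform Expression transforms (log before
#'   rank).
#' @param diff_from_mean,zscore,scale_sqrt,min_value Score post-processing;
#'   \code{diff_from_mean} and \code{zscore} are mutually exclusive.
#' @param min_genes Minimum present-gene count per signature.
#' @param permutations Number of null draws for empirical p-values, or
#'   \code{NULL} to skip them.
#' @param alpha Optional ANOVA p-value filter threshold.
#' @param cluster \code{"none"}, \code{"rows"}, \code{"cols"} or
#'   \code{"both"}.
#' @param metric,linkage Clustering distance and linkage.
#' @param heatmap Optional heatmap file name (png/pdf) relative to
#'   \code{outdir}.
#' @param seed Integer seed for every random draw in the run.
#' @return A validated list of class \code{RunConfig}.
#' @export
run_config <- function(expression, signatures, outdir,
                       mode = c("mean", "sum"),
                       top_k = savant_defaults()$top_k,
                       log_transform = FALSE, rank_transform = FALSE,
                       diff_from_mean = FALSE, zscore = FALSE,
                       scale_sqrt = FALSE, min_value = NULL,
                       min_genes = 0L, permutations = NULL, alpha = NULL,
                       cluster = c("none", "rows", "cols", "both"),
                       metric = c("euclidean", "pearson"),
                       linkage = c("complete", "single", "average", "ward"),
                       heatmap = NULL, seed = 1L) {
  mode <- match.arg(mode)
  cluster <- match.arg(cluster)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (diff_from_mean && zscore)
    stop("diff_from_mean and zscore are mutually exclusive")
  structure(list(expression = expression, signatures = signatures,
                 outdir = outdir, mode = mode, top_k = top_k,
                 log_transform = log_transform, rank_transform = rank_transform,
                 diff_from_mean = diff_from_mean, zscore = zscore,
                 scale_sqrt = scale_sqrt, min_value = min_value,
                 min_genes = min_genes, permutations = permutations,
                 alpha = alpha, cluster = cluster, metric = metric,
                 linkage = linkage, heatmap = heatmap,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full scoring pipeline
#'
#' Executes read, expression transforms, signature scoring, score
#' post-processing, statistics (permutation p-values if requested; ANOVA
#' automatically when group labels are present), clustering and rendering in
#' that fixed order, writing all outputs and a JSON manifest to the
#' configured directory. Identical configuration and seed reproduce
#' byte-identical score and p-value files.
#'
#' @param config A \code{RunConfig} from \code{\link{run_config}}.
#' @return Invisibly, a list with the final \code{\link{ScoreMatrix}}, the
#'   ANOVA table (or \code{NULL}) and the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "read"
  out <- tryCatch({
    em <- config$expression
    if (is.character(em)) em <- read_expression_matrix(em)
    sigs <- config$signatures
    if (is.character(sigs)) {
      first <- strsplit(readLines(sigs, n = 1L), "\t", fixed = TRUE)[[1L]]
      sigs <- if (length(first) == 3L &&
                  !is.na(suppressWarnings(as.numeric(first[3L]))))
        read_ranked_signatures(sigs) else read_gmt(sigs)
    }
    n_genes_read <- nrow(em$values)

    stage <- "transform"
    em <- transform_expression(em, log_flag = config$log_transform,
                               rank_flag = config$rank_transform)

    stage <- "score"
    scores <- score_signatures(em, sigs, mode = config$mode,
                               k = config$top_k, min_genes = config$min_genes)

    stage <- "postprocess"
    scores <- postprocess_scores(scores,
                                 diff_from_mean = config$diff_from_mean,
                                 zscore = config$zscore,
                                 scale_sqrt = config$scale_sqrt,
                                 min_value = config$min_value)

    stage <- "statistics"
    if (!is.null(config$permutations)) {
      raw <- score_signatures(em, sigs, mode = config$mode,
                              k = config$top_k, min_genes = config$min_genes)
      raw <- permutation_pvalues(em, sigs, raw,
                                 n_perm = config$permutations,
                                 seed = config$seed)
      pv <- raw$pvalues[rownames(scores$scores), , drop = FALSE]
      scores <- ScoreMatrix(scores$scores, scores$genes_used,
                            params = scores$params, pvalues = pv)
    }
    anova_tab <- NULL
    if (!is.null(em$groups)) {
      anova_tab <- anova_by_group(scores, em$groups)
      if (!is.null(config$alpha))
        scores <- filter_by_pvalue(scores, anova_tab, config$alpha)
      else {
        sc <- scores
        sc$anova <- anova_tab
        scores <- sc
      }
    }

    stage <- "cluster"
    row_ord <- col_ord <- NULL
    if (config$cluster %in% c("rows", "both") && nrow(scores$scores) >= 2L) {
      row_ord <- hierarchical_order(
        distance_matrix(scores, metric = config$metric, axis = "rows"),
        linkage = config$linkage)
      write_newick(row_ord, file.path(config$outdir, "dendrogram_rows.nwk"))
    }
    if (config$cluster %in% c("cols", "both") && ncol(scores$scores) >= 2L) {
      col_ord <- hierarchical_order(
        distance_matrix(scores, metric = config$metric, axis = "columns"),
        linkage = config$linkage)
      write_newick(col_ord, file.path(config$outdir, "dendrogram_cols.nwk"))
    }

    stage <- "render"
    write_score_matrix(scores, file.path(config$outdir, "scores.tsv"),
                       pvalue_path = file.path(config$outdir, "pvalues.tsv"))
    if (!is.null(anova_tab))
      utils::write.table(anova_tab, file.path(config$outdir, "anova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(config$heatmap)) {
      stars <- NULL
      if (!is.null(scores$pvalues)) {
        stars <- scores$pvalues
        stars[] <- significance_stars(as.vector(scores$pvalues))
      }
      render_heatmap(scores, row_order = row_ord, col_order = col_ord,
                     annotations = stars,
                     path = file.path(config$outdir, config$heatmap))
    }

    stage <- "manifest"
    dropped_mg <- scores$params$dropped_by_min_genes
    dropped_mv <- scores$params$dropped_by_min_value
    dropped_al <- scores$params$dropped_by_alpha
    manifest <- list(
      package_version = as.character(utils::packageVersion("savant")),
      seed = config$seed,
      parameters = config[setdiff(names(config),
                                  c("expression", "signatures"))],
      transforms = scores$params$transform_log,
      postprocess = scores$params$postprocess,
      counts = list(
        genes_read = n_genes_read,
        signatures_in = length(sigs),
        signatures_out = nrow(scores$scores),
        dropped_by_min_genes = if (is.null(dropped_mg)) 0L else dropped_mg,
        dropped_by_min_value = if (is.null(dropped_mv)) 0L else dropped_mv,
        dropped_by_alpha = if (is.null(dropped_al)) 0L else dropped_al
      ),
      anova_run = !is.null(anova_tab)
    )
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(scores = scores, anova = anova_tab, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out)
}
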