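# On-disk formats: tab-delimited expression matrices (with the SAVANT_GROUP
# convention), GMT gene sets, ranked signature tables, score-matrix outputs.
# All parsing is strictly tab-delimited; comma/space files are rejected rather
# than guessed.

GROUP_TAG <- "SAVANT_GROUP"

.split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a tab-delimited gene expression matrix
#'
#' Reads a matrix with gene symbols in the first column and sample names in
#' the first row (the top-left corner cell may be empty or carry a label).
#' A row labelled \code{SAVANT_GROUP} holding integer group codes is removed
#' from the gene rows and stored as sample group labels. Gene symbols that
#' appear multiple times are collapsed to their per-sample mean.
#'
#' @param path Path to a tab-delimited text file.
#' @param aggregate_duplicates If \code{TRUE} (default), duplicated gene
#'   symbols are averaged per sample; if \code{FALSE}, duplicates raise an
#'   error.
#' @return An \code{\link{ExpressionMatrix}}.
#' @export
read_expression_matrix <- function(path, aggregate_duplicates = TRUE) {
  if (!file.exists(path))
    stop("cannot open expression matrix: no such file '", path, "'")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression matrix needs a header line and at least one gene row: ", path)
  fields <- .split_tsv(lines)
  header <- trimws(fields[[1L]])
  body <- fields[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L)
    stop("inconsistent column count across rows (expected tab-delimited input)")
  n_cols <- widths[1L]
  if (n_cols < 2L)
    stop("no tab-delimited columns found; the field separator must be a tab")
  # header may or may not include a corner label over the gene-symbol column
  if (length(header) == n_cols) {
    samples <- header[-1L]
  } else if (length(header) == n_cols - 1L) {
    samples <- header
  } else {
    stop("header has ", length(header), " fields but data rows have ", n_cols)
  }
  if (anyDuplicated(samples))
    stop("duplicate sample names: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))

  labels <- trimws(vapply(body, `[`, character(1), 1L))
  is_group <- labels == GROUP_TAG
  if (sum(is_group) > 1L)
    stop("more than one ", GROUP_TAG, " row")

  groups <- NULL
  if (any(is_group)) {
    graw <- body[[which(is_group)]][-1L]
    gnum <- suppressWarnings(as.numeric(graw))
    if (anyNA(gnum) || any(gnum != round(gnum)))
      stop(GROUP_TAG, " row must contain only integer group codes")
    groups <- as.integer(gnum)
    names(groups) <- samples
    body <- body[!is_group]
    labels <- labels[!is_group]
  }
  if (!length(body))
    stop("no gene rows found in ", path)

  vals <- matrix(NA_real_, nrow = length(body), ncol = n_cols - 1L)
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | raw == "" | toupper(raw) == "NA")
    if (length(bad))
      stop("non-numeric or missing value at gene row '", labels[i],
           "', sample column '", samples[bad[1L]], "'")
    vals[i, ] <- v
  }
  rownames(vals) <- labels
  colnames(vals) <- samples

  if (anyDuplicated(labels)) {
    if (!aggregate_duplicates)
      stop("duplicated gene symbols present and aggregate_duplicates = FALSE")
    counts <- table(labels)
    vals <- rowsum(vals, group = labels, reorder = FALSE) /
      as.vector(counts[unique(labels)])
  }
  ExpressionMatrix(vals, groups = groups)
}

#' Write an expression matrix to tab-delimited text
#'
#' Inverse of \code{\link{read_expression_matrix}}: writes the gene rows and,
#' if group labels are present, a \code{SAVANT_GROUP} row.
#'
#' @param x An \code{\link{ExpressionMatrix}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(x$values)), collapse = "\t"), con)
  if (!is.null(x$groups))
    writeLines(paste(c(GROUP_TAG, x$groups[colnames(x$values)]), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard Broad/MSigDB dialect: one set per line; tab-separated fields are
#' the set name, a description, then the gene symbols. Sets read this way are
#' unranked. Duplicate symbols within a set are dropped, keeping the first
#' occurrence.
#'
#' @param path Path to a GMT file.
#' @return A \code{\link{SignatureCollection}} of unranked signatures.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- .split_tsv(lines)
  sigs <- list()
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (!length(genes))
      stop("GMT line ", i, " (set '", f[1L], "') has an empty gene list")
    sigs[[f[1L]]] <- list(genes = genes, pm = NULL, ranked = FALSE,
                          description = f[2L])
  }
  SignatureCollection(sigs, source = path)
}

#' Write a SignatureCollection to GMT
#'
#' @param sigs A \code{\link{SignatureCollection}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sigs, path) {
  stopifnot(inherits(sigs, "SignatureCollection"))
  lines <- vapply(names(sigs$signatures), function(nm) {
    s <- sigs$signatures[[nm]]
    desc <- if (is.null(s$description)) "na" else s$description
    paste(c(nm, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read ranked signatures from a three-column table
#'
#' Tab-delimited rows of (signature name, gene symbol, PM value), rows of one
#' signature contiguous. Genes within a signature are ordered by descending
#' PM value; ties keep file order.
#'
#' @param path Path to the table (no header).
#' @return A \code{\link{SignatureCollection}} of ranked signatures.
#' @export
read_ranked_signatures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- .split_tsv(lines)
  if (any(lengths(fields) != 3L))
    stop("ranked signature table must have exactly 3 tab-separated columns")
  tab <- do.call(rbind, fields)
  sig_name <- trimws(tab[, 1L])
  gene <- trimws(tab[, 2L])
  pm <- suppressWarnings(as.numeric(tab[, 3L]))
  if (anyNA(pm))
    stop("non-numeric PM value at line ", which(is.na(pm))[1L])
  sigs <- list()
  for (nm in unique(sig_name)) {
    sel <- sig_name == nm
    g <- gene[sel]
    if (anyDuplicated(g))
      stop("gene '", g[duplicated(g)][1L], "' appears twice in signature '", nm, "'")
    v <- pm[sel]
    ord <- order(-v)  # radix sort: stable, ties keep file order
    sigs[[nm]] <- list(genes = g[ord], pm = v[ord], ranked = TRUE)
  }
  SignatureCollection(sigs, source = path)
}

#' Write ranked signatures to a three-column table
#'
#' @param sigs A \code{\link{SignatureCollection}}; every signature must be
#'   ranked.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_ranked_signatures <- function(sigs, path) {
  stopifnot(inherits(sigs, "SignatureCollection"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sigs$signatures)) {
    s <- sigs$signatures[[nm]]
    if (!isTRUE(s$ranked))
      stop("signature '", nm, "' is unranked; use write_gmt()")
    writeLines(paste(nm, s$genes,
                     format(s$pm, digits = 17, trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a score matrix (and optional p-value companion) to disk
#'
#' Tab-delimited with signatures as rows and samples as columns. If the
#' \code{ScoreMatrix} carries per-cell p-values, a companion file with
#' identical row/column labels is written next to it (suffix
#' \code{.pvalues.tsv}).
#'
#' @param scores A \code{\link{ScoreMatrix}}.
#' @param path Output file path.
#' @param pvalue_path Path for the p-value companion; default derives from
#'   \code{path}.
#' @return Invisibly, \code{path}.
#' @export
write_score_matrix <- function(scores, path,
                               pvalue_path = paste0(tools::file_path_sans_ext(path),
                                                    ".pvalues.tsv")) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  if (!nrow(scores$scores) || !ncol(scores$scores))
    stop("score matrix is empty")
  .write_matrix_tsv(scores$scores, path)
  if (!is.null(scores$pvalues))
    .write_matrix_tsv(scores$pvalues, pvalue_path)
  invisible(path)
}

.write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a score matrix written by \code{write_score_matrix}
#'
#' @param path Path to the score table.
#' @param pvalue_path Optional path to the aligned p-value companion.
#' @return A \code{\link{ScoreMatrix}}. Per-signature gene counts are not
#'   serialized, so \code{genes_used} is restored as zeros.
#' @export
read_score_matrix <- function(path, pvalue_path = NULL) {
  m <- .read_matrix_tsv(path)
  p <- if (!is.null(pvalue_path)) .read_matrix_tsv(pvalue_path) else NULL
  gu <- rep(0L, nrow(m))
  names(gu) <- rownames(m)
  ScoreMatrix(m, genes_used = gu, params = list(source = path), pvalues = p)
}

.read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- .split_tsv(lines)
  header <- fields[[1L]]
  body <- fields[-1L]
  n_cols <- lengths(body)[1L]
  samples <- if (length(header) == n_cols) header[-1L] else header
  vals <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(n_cols - 1L)))
  rownames(vals) <- vapply(body, `[`, character(1), 1L)
  colnames(vals) <- samples
  vals
}
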