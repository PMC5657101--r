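# Shared fixtures and independent oracles for the test suite.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Expression matrix built directly in code
make_em <- function(values, genes, samples, groups = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  ExpressionMatrix(m, groups = groups)
}

make_sigs <- function(..., ranked = FALSE) {
  lst <- list(...)
  sigs <- lapply(lst, function(g) {
    if (is.list(g)) list(genes = g$genes, pm = g$pm, ranked = TRUE)
    else list(genes = g, pm = NULL, ranked = ranked)
  })
  SignatureCollection(sigs)
}

# Independent scoring oracle: naive double loop over signatures and samples
oracle_score <- function(values, gene_sets, mode = "mean") {
  out <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(values),
                dimnames = list(names(gene_sets), colnames(values)))
  for (s in names(gene_sets)) {
    present <- intersect(gene_sets[[s]], rownames(values))
    for (j in seq_len(ncol(values))) {
      acc <- sum(values[present, j])
      out[s, j] <- if (mode == "mean") acc / length(present) else acc
    }
  }
  out
}

# Exhaustive permutation-p oracle: enumerate all size-m gene sets
oracle_exhaustive_p <- function(values, sig_genes, sample, mode = "mean") {
  universe <- rownames(values)
  m <- length(sig_genes)
  obs <- mean(values[sig_genes, sample])
  if (mode == "sum") obs <- obs * m
  sets <- utils::combn(universe, m)
  null_scores <- apply(sets, 2L, function(g) {
    v <- sum(values[g, sample])
    if (mode == "mean") v / m else v
  })
  mean(null_scores >= obs)
}

# Naive O(n^3) agglomerative clustering oracle returning the cophenetic
# distance matrix (complete / single / average linkage)
oracle_agglomerative_cophenetic <- function(d, linkage = "complete") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      pairs <- expand.grid(clusters[[i]], clusters[[j]])
      dd <- mapply(function(a, b) d[a, b], pairs[[1]], pairs[[2]])
      link_d <- switch(linkage, complete = max(dd), single = min(dd),
                       average = mean(dd))
      if (link_d < best_d) { best_d <- link_d; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    for (x in a) for (y in b) { coph[x, y] <- best_d; coph[y, x] <- best_d }
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  dimnames(coph) <- dimnames(d)
  coph
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
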