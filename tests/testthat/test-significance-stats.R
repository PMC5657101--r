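test_that("sampled permutation p-values converge to the exhaustive-enumeration oracle", {
  em <- make_em(c(4, 3, 2, 1), c("A", "B", "C", "D"), "s1")
  sigs <- make_sigs(TOP2 = c("A", "B"))
  sc <- score_signatures(em, sigs)
  expect_equal(unname(sc$scores["TOP2", "s1"]), 3.5)
  n_perm <- 10000
  got <- permutation_pvalues(em, sigs, sc, n_perm = n_perm, seed = 123)
  p_exact <- oracle_exhaustive_p(em$values, c("A", "B"), "s1")  # 1/6
  expect_equal(p_exact, 1 / 6)
  expected <- (1 + n_perm * p_exact) / (n_perm + 1)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(got$pvalues["TOP2", "s1"] - expected), 3 * se)
})

test_that("the maximal gene set attains the minimum attainable p-value", {
  em <- make_em(c(9, 9, 8, 8, rep(1, 16)),
                sprintf("G%d", 1:10), c("s1", "s2"))
  sigs <- make_sigs(MAX = c("G1", "G2"))
  sc <- score_signatures(em, sigs)
  got <- permutation_pvalues(em, sigs, sc, n_perm = 500, seed = 1)
  # no null set can strictly beat the maximal set, but draws of the set
  # itself tie; p stays near the enumeration floor 1/choose(10,2)
  expect_lte(max(got$pvalues), 0.05)
  expect_gte(min(got$pvalues), 1 / 501)
})

test_that("permutation p-values are reproducible under a fixed seed and bounded", {
  set.seed(99)
  vals <- matrix(rexp(300, 1 / 50), 30, 10,
                 dimnames = list(sprintf("G%02d", 1:30), sprintf("s%02d", 1:10)))
  em <- ExpressionMatrix(vals)
  sigs <- make_sigs(S1 = sprintf("G%02d", 1:5), S2 = sprintf("G%02d", 6:10),
                    S3 = sprintf("G%02d", c(2, 4, 6, 8, 10)))
  sc <- score_signatures(em, sigs)
  a <- permutation_pvalues(em, sigs, sc, n_perm = 200, seed = 42)
  b <- permutation_pvalues(em, sigs, sc, n_perm = 200, seed = 42)
  expect_identical(a$pvalues, b$pvalues)
  expect_true(all(a$pvalues >= 1 / 201 & a$pvalues <= 1))
  expect_equal(attr(a$pvalues, "n_permutations"), 200L)
  # equal-size signatures share null draws: identical observed scores
  # imply identical p-values
  expect_error(permutation_pvalues(em, sigs, sc, n_perm = 0, seed = 1),
               "at least 1")
})

test_that("null-data empirical p-values are approximately uniform", {
  ds <- generate_dataset(500, 10, rep(1:2, each = 5), spikes = list(), seed = 31)
  em <- ds$matrix
  set.seed(32)  # signatures drawn independently of the data
  sig_list <- lapply(1:20, function(i)
    list(genes = sample(rownames(em$values), 15), pm = NULL, ranked = FALSE))
  names(sig_list) <- sprintf("RAND%02d", 1:20)
  sigs <- SignatureCollection(sig_list)
  sc <- score_signatures(em, sigs)
  got <- permutation_pvalues(em, sigs, sc, n_perm = 1000, seed = 33)
  cells <- as.vector(got$pvalues)
  expect_gte(length(cells), 200)
  ks <- suppressWarnings(stats::ks.test(cells, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("one-way ANOVA reproduces the closed-form F and the t-squared identity", {
  # worked instance: g1=(1,2,3), g2=(2,3,4) -> F = 1.5
  sm <- ScoreMatrix(matrix(c(1, 2, 3, 2, 3, 4), 1,
                           dimnames = list("SIG", sprintf("s%d", 1:6))),
                    genes_used = c(SIG = 1L))
  groups <- stats::setNames(rep(1:2, each = 3), sprintf("s%d", 1:6))
  res <- anova_by_group(sm, groups)
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$p.value,
               stats::pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # two-group F equals t^2 on random inputs
  set.seed(17)
  for (rep in 1:10) {
    y <- rnorm(12)
    g <- stats::setNames(rep(1:2, each = 6), sprintf("s%02d", 1:12))
    sm2 <- ScoreMatrix(matrix(y, 1, dimnames = list("S", names(g))),
                       genes_used = c(S = 1L))
    f <- anova_by_group(sm2, g)$F
    t2 <- stats::t.test(y[1:6], y[7:12], var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-9)
  }
})

test_that("ANOVA handles degenerate rows and rejects invalid group structure", {
  g <- stats::setNames(rep(1:2, each = 2), sprintf("s%d", 1:4))
  const <- ScoreMatrix(matrix(5, 1, 4, dimnames = list("C", names(g))),
                       genes_used = c(C = 1L))
  res <- anova_by_group(const, g)
  expect_equal(res$F, 0)
  expect_equal(res$p.value, 1)
  sep <- ScoreMatrix(matrix(c(0, 0, 1, 1), 1, dimnames = list("S", names(g))),
                     genes_used = c(S = 1L))
  res2 <- anova_by_group(sep, g)
  expect_gt(res2$p.value, 0)  # smallest representable p, never exactly 0
  expect_lte(res2$p.value, 1e-300)
  same_means <- ScoreMatrix(matrix(c(0, 2, 1, 1), 1,
                                   dimnames = list("S", names(g))),
                            genes_used = c(S = 1L))
  expect_equal(anova_by_group(same_means, g)$F, 0)
  expect_equal(anova_by_group(same_means, g)$p.value, 1)
  expect_error(anova_by_group(const, stats::setNames(rep(1, 4), names(g))),
               "2 groups")
  expect_error(anova_by_group(const,
                              stats::setNames(c(1, 1, 1, 2), names(g))),
               "fewer than 2")
})

test_that("star labels follow the shipped thresholds and are monotone in p", {
  expect_identical(significance_stars(c(0.01, 0.001, 0.0001, 0.5, 0.02)),
                   c("*", "**", "***", "", ""))
  expect_error(significance_stars(-0.1), "0, 1")
  ps <- sort(runif(50))
  stars <- significance_stars(ps)
  expect_true(all(diff(nchar(stars)) <= 0))
})

test_that("p-value filtering keeps strictly significant signatures in order", {
  sm <- ScoreMatrix(matrix(1:6, 3, 2,
                           dimnames = list(c("A", "B", "C"), c("s1", "s2"))),
                    genes_used = c(A = 1L, B = 1L, C = 1L))
  an <- data.frame(signature = c("A", "B", "C"),
                   p.value = c(0.00005, 0.5, 0.00001),
                   F = c(50, 1, 80), stars = c("***", "", "***"))
  kept <- filter_by_pvalue(sm, an, alpha = 0.0001)
  expect_equal(rownames(kept$scores), c("A", "C"))
  expect_equal(kept$params$dropped_by_alpha, 1L)
  all_kept <- filter_by_pvalue(sm, an, alpha = 1.0)
  expect_equal(nrow(all_kept$scores), 3L)
  expect_error(filter_by_pvalue(sm, an, alpha = 0), "no signature")
})
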