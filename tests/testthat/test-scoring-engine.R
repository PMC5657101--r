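test_that("expression transforms apply log2(x+1) then per-column mean-tie ranks", {
  em <- make_em(c(7, 5, 2,
                  0, 1, 2,
                  3, 3, 2), c("G1", "G2", "G3"), c("s1", "s2", "s3"))
  lg <- transform_expression(em, log_flag = TRUE)
  expect_equal(lg$values["G1", "s1"], 3)  # log2(7 + 1)
  expect_equal(lg$values["G2", "s1"], 0)
  expect_equal(lg$transform_log, "log2")

  rk <- transform_expression(em, rank_flag = TRUE)
  expect_equal(unname(rk$values[, "s1"]), c(3, 1, 2))
  expect_equal(unname(rk$values[, "s3"]), c(2, 2, 2))  # three-way tie -> mean rank

  both <- transform_expression(em, log_flag = TRUE, rank_flag = TRUE)
  expect_equal(both$transform_log, c("log2", "rank"))
  # ranks are monotone-invariant, so log-then-rank equals rank alone
  expect_equal(both$values, rk$values)

  two <- make_em(c(2, 5, 2, 1), c("G1", "G2"), c("s1", "s2"))
  expect_equal(unname(transform_expression(two, rank_flag = TRUE)$values[, "s1"]),
               c(1.5, 1.5))
  neg <- make_em(c(-1, 1), "G1", c("s1", "s2"))
  expect_error(transform_expression(neg, log_flag = TRUE), "non-negative")
})

test_that("signature scores are the mean or sum of present genes", {
  em <- make_em(c(2, 6,
                  4, 10,
                  100, 100), c("A", "B", "C"), c("s1", "s2"))
  sigs <- make_sigs(SIG = c("A", "B"), SOLO = "A", GHOSTLY = c("A", "ZZZ"))
  sc <- score_signatures(em, sigs, mode = "mean")
  expect_equal(unname(sc$scores["SIG", ]), c(3, 8))
  expect_equal(unname(sc$scores["SOLO", ]), unname(em$values["A", ]))
  # absent genes never contribute
  expect_equal(unname(sc$scores["GHOSTLY", ]), unname(em$values["A", ]))
  expect_equal(sc$genes_used, c(SIG = 2L, SOLO = 1L, GHOSTLY = 1L))
  su <- score_signatures(em, sigs, mode = "sum")
  expect_equal(unname(su$scores["SIG", ]), c(6, 16))
  # mean-mode score x genes_used == sum-mode score, cell for cell
  expect_equal(sc$scores * sc$genes_used, su$scores)
})

test_that("scoring matches the naive double-loop oracle on random inputs", {
  set.seed(42)
  for (rep in 1:20) {
    ng <- sample(20:200, 1); ns <- sample(2:20, 1)
    vals <- matrix(rexp(ng * ns, 1 / 100), ng, ns,
                   dimnames = list(sprintf("G%04d", seq_len(ng)),
                                   sprintf("s%02d", seq_len(ns))))
    em <- ExpressionMatrix(vals)
    sets <- lapply(1:5, function(i)
      sample(c(rownames(vals), "ABSENT1", "ABSENT2"), sample(2:min(30, ng), 1)))
    names(sets) <- sprintf("SET%d", 1:5)
    sets <- sets[vapply(sets, function(g) any(g %in% rownames(vals)), logical(1))]
    sigs <- SignatureCollection(lapply(sets, function(g)
      list(genes = g, pm = NULL, ranked = FALSE)))
    for (mode in c("mean", "sum")) {
      got <- score_signatures(em, sigs, mode = mode)
      expect_identical(got$scores, oracle_score(vals, sets, mode)[rownames(got$scores), , drop = FALSE])
    }
  }
})

test_that("ranked signatures truncate to top k; unranked are used whole", {
  em <- make_em(rep(1:6, 2), sprintf("G%d", 1:6), c("s1", "s2"))
  ranked <- make_sigs(R = list(genes = c("G6", "G5", "G4", "G3"),
                               pm = c(4, 3, 2, 1)))
  expect_equal(score_signatures(em, ranked, k = 2)$genes_used[["R"]], 2L)
  unranked <- make_sigs(U = c("G6", "G5", "G4", "G3"))
  expect_equal(score_signatures(em, unranked, k = 2)$genes_used[["U"]], 4L)
})

test_that("min_genes filtering removes sparse signatures and errors when all drop", {
  em <- make_em(c(1, 2, 3, 4), c("A", "B"), c("s1", "s2"))
  sigs <- make_sigs(BIG = c("A", "B"), SMALL = c("A", "NOPE"))
  sc <- score_signatures(em, sigs, min_genes = 2)
  expect_equal(rownames(sc$scores), "BIG")
  expect_equal(sc$params$dropped_by_min_genes, 1L)
  expect_error(score_signatures(em, sigs, min_genes = 5), "min_genes")
  ghost <- make_sigs(NONE = c("X", "Y"), OK = "A")
  expect_warning(sc2 <- score_signatures(em, ghost), "no genes")
  expect_equal(rownames(sc2$scores), "OK")
})

test_that("score order is equivariant under signature and sample permutation", {
  set.seed(7)
  vals <- matrix(runif(40), 10, 4,
                 dimnames = list(sprintf("G%02d", 1:10), sprintf("s%d", 1:4)))
  sets <- list(S1 = sprintf("G%02d", 1:3), S2 = sprintf("G%02d", 4:8),
               S3 = sprintf("G%02d", c(1, 9, 10)))
  sigs <- SignatureCollection(lapply(sets, function(g)
    list(genes = g, pm = NULL, ranked = FALSE)))
  sc <- score_signatures(ExpressionMatrix(vals), sigs)
  perm <- c(3, 1, 4, 2)
  sc_p <- score_signatures(ExpressionMatrix(vals[, perm]), sigs)
  expect_equal(sc_p$scores, sc$scores[, perm])
  sigs_r <- SignatureCollection(lapply(rev(sets), function(g)
    list(genes = g, pm = NULL, ranked = FALSE)))
  sc_r <- score_signatures(ExpressionMatrix(vals), sigs_r)
  expect_equal(sc_r$scores, sc$scores[rev(names(sets)), ])
})

test_that("post-processing applies sqrt scaling, row centering and grand z-score", {
  sm <- ScoreMatrix(matrix(c(1, 3, 2, 6), 2, byrow = TRUE,
                           dimnames = list(c("S1", "S2"), c("a", "b"))),
                    genes_used = c(S1 = 4L, S2 = 9L))
  sq <- postprocess_scores(sm, scale_sqrt = TRUE)
  expect_equal(unname(sq$scores["S1", ]), c(2, 6))   # x sqrt(4)
  expect_equal(unname(sq$scores["S2", ]), c(6, 18))  # x sqrt(9)

  dm <- postprocess_scores(sm, diff_from_mean = TRUE)
  expect_equal(unname(dm$scores["S1", ]), c(-1, 1))
  expect_equal(unname(rowSums(dm$scores)), c(0, 0))

  # worked z-score instance: grand mean 2.5, population sd sqrt(1.25)
  zm <- ScoreMatrix(matrix(c(1, 2, 3, 4), 2, byrow = TRUE,
                           dimnames = list(c("S1", "S2"), c("a", "b"))),
                    genes_used = c(S1 = 1L, S2 = 1L))
  z <- postprocess_scores(zm, zscore = TRUE)
  expect_equal(z$scores["S1", "a"], (1 - 2.5) / sqrt(1.25))
  expect_equal(mean(z$scores), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z$scores - mean(z$scores))^2)), 1, tolerance = 1e-12)

  const <- ScoreMatrix(matrix(0, 2, 2, dimnames = list(c("S1", "S2"), c("a", "b"))),
                       genes_used = c(S1 = 1L, S2 = 1L))
  expect_error(postprocess_scores(const, zscore = TRUE), "standard deviation")
  expect_error(postprocess_scores(sm, diff_from_mean = TRUE, zscore = TRUE),
               "exclusive")
})

test_that("min_value keeps rows whose maximum clears the threshold", {
  sm <- ScoreMatrix(matrix(c(1, 3, 0.1, 0.2), 2, byrow = TRUE,
                           dimnames = list(c("HI", "LO"), c("a", "b"))),
                    genes_used = c(HI = 1L, LO = 1L))
  kept <- postprocess_scores(sm, min_value = 1)
  expect_equal(rownames(kept$scores), "HI")
  expect_equal(kept$params$dropped_by_min_value, 1L)
  expect_error(postprocess_scores(sm, min_value = 100), "every signature")
})
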