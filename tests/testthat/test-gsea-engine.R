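test_that("enrichment_score matches hand-derived and boundary cases", {
  rl4 <- ranked_list(paste0("g", 1:4), c(3, 2, 1, 0.5))
  top <- enrichment_score(rl4, "g1", weight_p = 0)
  expect_equal(top$es, 1)
  expect_identical(top$peak_position, 1L)
  bottom <- enrichment_score(rl4, "g4", weight_p = 0)
  expect_equal(bottom$es, -1)
  expect_identical(bottom$peak_position, 3L)  # the -1 dip precedes the hit

  rl5 <- ranked_list(paste0("g", 1:5), c(5, 4, 3, 2, 1))
  es <- enrichment_score(rl5, c("g1", "g3"), weight_p = 1)
  expect_equal(es$running_sum,
               c(0.625, 0.625 - 1/3, 0.625 - 1/3 + 0.375,
                 0.625 - 1/3 + 0.375 - 1/3, 0),
               tolerance = 1e-12)
  expect_equal(es$es, 2/3, tolerance = 1e-12)
  expect_identical(es$peak_position, 3L)

  expect_error(enrichment_score(rl5, "absent"), "does not intersect")
  expect_error(enrichment_score(rl5, paste0("g", 1:5)), "whole ranked list")
  rl0 <- ranked_list(c("a", "b", "c"), c(1, 0, -1))
  expect_error(enrichment_score(rl0, "b", weight_p = 1), "N_R = 0")
  expect_message(enrichment_score(rl5, c("g1", "zz")), "1 set gene")
})

test_that("enrichment_score agrees with the brute-force enumerator and
          with fgsea on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    rl <- random_ranked(n, seed = i + 100)
    k <- sample(2:min(8, n - 1), 1)
    members <- sample(rl$gene, k)
    hit <- rl$gene %in% members
    for (wp in c(0, 1)) {
      mine <- enrichment_score(rl, members, weight_p = wp)
      ora <- oracle_es(rl$metric, hit, wp)
      expect_equal(mine$es, ora$es, tolerance = 1e-12)
      expect_identical(mine$peak_position, ora$peak)
    }
    ref <- fgsea::calcGseaStat(rl$metric, which(hit), gseaParam = 1)
    expect_equal(enrichment_score(rl, members, weight_p = 1)$es, ref,
                 tolerance = 1e-8)
  }
})

test_that("ES negates when the ranked list is reversed", {
  for (i in 1:10) {
    rl <- random_ranked(20, seed = i)
    members <- sample(rl$gene, 4)
    rev_rl <- ranked_list(rev(rl$gene), rev(-rl$metric))
    for (wp in c(0, 1)) {
      f <- enrichment_score(rl, members, weight_p = wp)
      r <- enrichment_score(rev_rl, members, weight_p = wp)
      # magnitudes always mirror; the sign flips except at an exact
      # top/bottom tie, where the earliest-extremum rule picks the same
      # side in both orientations
      expect_equal(abs(f$es), abs(r$es), tolerance = 1e-12)
      untied <- abs(max(f$running_sum) + min(f$running_sum)) > 1e-9
      if (untied) expect_equal(f$es, -r$es, tolerance = 1e-12)
    }
  }
})

test_that("gene-permutation GSEA is deterministic and exhaustively
          calibrated for single-gene sets", {
  rl <- ranked_list(paste0("g", 1:4), c(2, 1, -1, -2))
  r1 <- suppressMessages(gsea(rl, gene_set("s", "g1"), n_perm = 200,
                              weight_p = 0, seed = 9))
  r2 <- suppressMessages(gsea(rl, gene_set("s", "g1"), n_perm = 200,
                              weight_p = 0, seed = 9))
  expect_identical(r1, r2)

  # N = 4, k = 1, unweighted: null = {1, 2/3, -2/3, -1}; for the set at
  # position 1 (ES = 1), exhaustive same-sign p = 1/2, NES = 1/(5/6) = 1.2
  null4 <- oracle_null_k1(rl$metric, 0)
  expect_equal(sort(null4), c(-1, -2/3, 2/3, 1), tolerance = 1e-12)
  big <- suppressMessages(gsea(rl, gene_set("s", "g1"), n_perm = 4000,
                               weight_p = 0, seed = 2))
  expect_equal(big$es, 1)
  p_ex <- oracle_exhaustive_p(1, null4)
  expect_equal(p_ex, 0.5)
  se <- sqrt(p_ex * (1 - p_ex) / 4000)
  expect_lt(abs(big$p - p_ex), 3 * se + 2e-3)  # small add-one offset
  expect_lt(abs(big$nes - 1.2), 0.02)
})

test_that("q equals p for a single set and q is within [0, 1] for many", {
  rl <- random_ranked(100, seed = 5)
  single <- suppressMessages(gsea(rl, gene_set("a", rl$gene[1:5]),
                                  n_perm = 100, seed = 1))
  expect_identical(single$q, single$p)
  sets <- list(gene_set("top", rl$gene[1:6]),
               gene_set("bottom", rl$gene[95:100]),
               gene_set("mid", rl$gene[48:53]))
  multi <- suppressMessages(gsea(rl, sets, n_perm = 300, seed = 1))
  expect_true(all(multi$q >= 0 & multi$q <= 1, na.rm = TRUE))
  expect_true(multi$es[1] > 0 && multi$es[2] < 0)
  # strong top/bottom sets get small q, the random mid set does not
  expect_lt(max(multi$q[1:2]), 0.2)
})

test_that("leading_edge follows the peak on both sides", {
  rl5 <- ranked_list(paste0("g", 1:5), c(5, 4, 3, 2, 1))
  es <- enrichment_score(rl5, c("g1", "g3"), weight_p = 1)
  expect_identical(leading_edge(rl5, c("g1", "g3"), es), c("g1", "g3"))

  es_top <- enrichment_score(rl5, "g1", weight_p = 0)
  expect_identical(leading_edge(rl5, "g1", es_top), "g1")

  es_bot <- enrichment_score(rl5, c("g4", "g5"), weight_p = 0)
  expect_lt(es_bot$es, 0)
  expect_identical(leading_edge(rl5, c("g4", "g5"), es_bot), c("g5", "g4"))

  expect_identical(leading_edge(rl5, c("g1", "g3"), es, top = 1), "g1")

  flat <- list(es = 0, peak_position = 1L)
  expect_warning(le0 <- leading_edge(rl5, "g1", flat), "ES is 0")
  expect_length(le0, 0)
})

test_that("ES stays in [-1, 1] and hits 1 only at the unweighted extremes", {
  for (i in 1:20) {
    rl <- random_ranked(15, seed = 300 + i)
    members <- sample(rl$gene, sample(1:5, 1))
    for (wp in c(0, 1)) {
      es <- enrichment_score(rl, members, weight_p = wp)$es
      expect_gte(es, -1)
      expect_lte(es, 1)
    }
  }
})
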