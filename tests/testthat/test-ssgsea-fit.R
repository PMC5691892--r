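test_that("ssgsea_score matches hand-enumerated step sums", {
  v <- matrix(c(5, 1), 2, 1, dimnames = list(c("A", "B"), "S1"))
  em <- expression_matrix(v)
  expect_equal(unname(ssgsea_score(em, "A", alpha = 0)), 1)
  expect_equal(unname(ssgsea_score(em, "B", alpha = 0)), -1)

  v4 <- matrix(c(9, 8, 7, 6), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), "S1"))
  em4 <- expression_matrix(v4)
  # set at that sample's positions {1, 3}: 0.5 + 0 + 0.5 + 0
  expect_equal(unname(ssgsea_score(em4, c("A", "C"), alpha = 0)), 1)

  expect_error(ssgsea_score(em4, "absent"), "does not intersect")
  expect_error(ssgsea_score(em4, c("A", "B", "C", "D")), "every gene")
})

test_that("ssgsea_score agrees with the scalar oracle on random data", {
  for (i in 1:10) {
    em <- random_expr(30, c(A = 2, B = 2), seed = 400 + i)
    members <- sample(gene_ids(em), 6)
    for (alpha in c(0, 0.25, 1)) {
      mine <- ssgsea_score(em, members, alpha = alpha)
      ref <- vapply(seq_len(4), function(j) {
        oracle_ssgsea(em$values[, j], gene_ids(em), members, alpha)
      }, numeric(1))
      expect_equal(unname(mine), ref, tolerance = 1e-10)
    }
  }
})

test_that("ssgsea_score depends only on within-sample ranks", {
  em <- random_expr(40, c(A = 3, B = 3), seed = 77)
  members <- sample(gene_ids(em), 8)
  base <- ssgsea_score(em, members, alpha = 0.25)
  transforms <- list(function(x) 2 * x + 1,
                     function(x) exp(x / 4),
                     function(x) x^3,
                     function(x) rank(x, ties.method = "first") * 1.0)
  for (f in transforms) {
    v2 <- apply(em$values, 2, f)
    dimnames(v2) <- dimnames(em$values)
    em2 <- expression_matrix(v2)
    expect_equal(unname(ssgsea_score(em2, members, alpha = 0.25)),
                 unname(base), tolerance = 1e-12)
  }
})

test_that("normalize_scores divides by the pooled span and is
          scale-invariant", {
  out <- normalize_scores(c(2, -2, 1))
  expect_equal(as.numeric(out), c(0.5, -0.5, 0.25))
  expect_equal(attr(out, "span"), 4)
  expect_error(normalize_scores(rep(3, 5)), "zero span")
  expect_error(normalize_scores(1), "at least 2")
  raw <- c(-1.5, 0.5, 3)
  expect_equal(as.numeric(normalize_scores(7 * raw)),
               as.numeric(normalize_scores(raw)), tolerance = 1e-12)
})

test_that("fit_score is the normalized difference, negates under direction
          swap, and classifies with strict thresholds", {
  set.seed(12)
  em <- random_expr(60, c(g1 = 3, g2 = 3), seed = 31)
  sig <- bidirectional_signature("s", up = gene_ids(em)[1:8],
                                 down = gene_ids(em)[9:16])
  ft <- fit_score(sig, em)
  expect_s3_class(ft, "fit_tbl")
  expect_equal(ft$fit, ft$up_norm - ft$down_norm, tolerance = 1e-12)
  span <- attr(ft, "span")
  expect_equal(ft$up_norm * span, ft$up_es, tolerance = 1e-10)

  swapped <- bidirectional_signature("s_rev", up = sig$down$genes,
                                     down = sig$up$genes)
  ft2 <- fit_score(swapped, em)
  expect_equal(ft2$fit, -ft$fit, tolerance = 1e-12)

  expect_identical(as.character(classify_fit(c(0.25, 0.40, 0.400001, -1))),
                   c("none", "moderate", "high", "none"))
  expect_identical(as.character(classify_fit(0.2500001)), "moderate")
})

test_that("compare_groups reproduces the stats battery and flags strong
          shifts", {
  # two identical groups: F ~ 0, Tukey differences 0
  vals <- rep(c(1, 2, 3), 2)
  cmp0 <- compare_groups(vals, groups = rep(c("a", "b"), each = 3))
  expect_equal(cmp0$anova$f, 0, tolerance = 1e-12)
  expect_equal(cmp0$tukey$diff, 0, tolerance = 1e-12)

  set.seed(8)
  vals <- c(rnorm(8), rnorm(8), rnorm(8, mean = 6))
  grp <- rep(c("a", "b", "c"), each = 8)
  cmp <- compare_groups(vals, groups = grp)
  # oracle: the standard-library battery applied directly
  ref_aov <- aov(vals ~ factor(grp))
  ref_tk <- TukeyHSD(ref_aov)[[1]]
  expect_equal(cmp$anova$p, summary(ref_aov)[[1]][["Pr(>F)"]][1],
               tolerance = 1e-10)
  expect_equal(cmp$bartlett$p, bartlett.test(vals, factor(grp))$p.value,
               tolerance = 1e-10)
  expect_equal(cmp$tukey$p_adj, unname(ref_tk[, "p adj"]), tolerance = 1e-10)
  # only the two pairs involving the shifted group are significant
  sig_pairs <- cmp$tukey$p_adj < 0.05
  has_c <- cmp$tukey$group_1 == "c" | cmp$tukey$group_2 == "c"
  expect_identical(sig_pairs, has_c)
  # Tukey adjusted p for the null pair is at least the plain two-sample p
  null_pair <- which(!has_c)
  plain_p <- t.test(vals[grp == "a"], vals[grp == "b"],
                    var.equal = TRUE)$p.value
  expect_gte(cmp$tukey$p_adj[null_pair], plain_p)

  expect_error(compare_groups(1:5, groups = c("a", "a", "a", "a", "b")),
               "at least 2 samples")
  expect_error(compare_groups(1:4, groups = rep("a", 4)), "at least 2 groups")
})

test_that("tidy and glance summarize comparisons and fits", {
  set.seed(2)
  vals <- c(rnorm(6), rnorm(6, 3))
  cmp <- compare_groups(vals, groups = rep(c("x", "y"), each = 6))
  expect_s3_class(tidy(cmp), "tbl_df")
  g <- glance(cmp)
  expect_identical(g$n_groups, 2L)
  expect_identical(g$n, 12L)
})
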