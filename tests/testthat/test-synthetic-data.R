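test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(overlap_fraction = 1.2), "overlap_fraction")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(vav1_hes1_r = 1), "vav1_hes1_r")
  expect_error(sim_config(mouse_a_sizes = c(no_tumor = 1, dn_tumor = 3,
                                            cd8_tumor = 3)),
               "size >= 2")
  expect_error(sim_config(n_genes = 120), "exceed")
  expect_error(sim_config(overlap_fraction = 0), "n_dev_confounders")
})

test_that("simulate_study is deterministic and leaves the global RNG alone", {
  cfg <- sim_config(seed = 5, n_genes = 400, n_signature_up = 20,
                    n_signature_down = 20, n_dev_confounders = 4)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1, b2)
  expect_false(identical(b1$mouse_a$values,
                         simulate_study(sim_config(seed = 6, n_genes = 400,
                                                   n_signature_up = 20,
                                                   n_signature_down = 20,
                                                   n_dev_confounders = 4)
                         )$mouse_a$values))
  set.seed(123)
  state <- .Random.seed
  invisible(simulate_study(cfg))
  expect_identical(.Random.seed, state)
})

test_that("the truth record round-trips to realized effects", {
  cfg <- sim_config(seed = 9)
  b <- simulate_study(cfg)
  tr <- b$truth
  g <- sample_groups(b$mouse_a)
  tumor <- g != "no_tumor"
  n_eff <- 1 / sum(tumor) + 1 / sum(!tumor)
  tol <- 4 * cfg$noise_sd * sqrt(n_eff)
  diff_up <- rowMeans(b$mouse_a$values[tr$up_a, tumor]) -
    rowMeans(b$mouse_a$values[tr$up_a, !tumor])
  expect_true(all(abs(diff_up - cfg$effect_log2fc) < tol))
  diff_dn <- rowMeans(b$mouse_a$values[tr$down_a, tumor]) -
    rowMeans(b$mouse_a$values[tr$down_a, !tumor])
  expect_true(all(abs(diff_dn + cfg$effect_log2fc) < tol))
  # embedded human genes are ortholog images of embedded mouse genes
  expect_identical(tr$human_up,
                   unlist(b$ortholog_map[tr$shared_up], use.names = FALSE))
  expect_true(all(tr$human_up %in% gene_ids(b$human$dataset1)))
  # confounders live inside the shared blocks
  expect_true(all(tr$conf_up %in% tr$shared_up))
  expect_identical(tr$tumor_specific_up, setdiff(tr$shared_up, tr$conf_up))
})

test_that("the embedded VAV1-HES1 correlation lands near its target", {
  cfg <- sim_config(seed = 14)
  b <- simulate_study(cfg)
  h <- b$human$dataset3  # largest cohort: tightest sampling distribution
  pos <- sample_groups(h) == "TLX"
  r <- cor(h$values["VAV1", pos], h$values["HES1", pos])
  expect_lt(abs(r - cfg$vav1_hes1_r), 0.15)
  # other subtypes stay uncorrelated
  neg <- sample_groups(h) == "TAL1"
  r0 <- cor(h$values["VAV1", neg], h$values["HES1", neg])
  expect_lt(abs(r0), 0.4)
})

test_that("marker-based TLX calling recovers the embedded subtype", {
  b <- simulate_study(sim_config(seed = 3))
  h <- b$human$dataset2
  called <- call_tlx_by_markers(h)
  truth <- ifelse(sample_groups(h) == "TLX", "TLX", "other")
  expect_gt(mean(called == truth), 0.95)
  expect_error(call_tlx_by_markers(b$mouse_a), "absent")
})

test_that("simulate_null_dataset is structureless and seed-faithful", {
  nd <- simulate_null_dataset(300, 12, seed = 2)
  expect_identical(dim(nd), c(300L, 12L))
  expect_identical(nd$values, simulate_null_dataset(300, 12, seed = 2)$values)
  expect_false(identical(nd$values,
                         simulate_null_dataset(300, 12, seed = 3)$values))
  # per-gene sample mean within 4 standard errors of the baseline range
  se4 <- 4 * 0.5 / sqrt(12)
  expect_true(all(rowMeans(nd$values) > 4 - se4 &
                    rowMeans(nd$values) < 12 + se4))
  # ANOVA on arbitrary labels of a null fit table is non-significant
  # at the aggregate level: p roughly uniform
  sig <- bidirectional_signature("s", gene_ids(nd)[1:15],
                                 gene_ids(nd)[16:30])
  ft <- fit_score(sig, nd)
  ps <- vapply(1:20, function(i) {
    set.seed(i)
    compare_groups(ft, groups = sample(rep(c("a", "b", "c"), c(4, 4, 4))))$anova$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
  expect_error(simulate_null_dataset(10, 3, seed = 1), "n_samples")
})

test_that("bundles round-trip through the standard formats", {
  skip_if_not_installed("jsonlite")
  cfg <- sim_config(seed = 4, n_genes = 300, n_signature_up = 15,
                    n_signature_down = 15, n_dev_confounders = 4,
                    human_sizes = list(dataset1 = c(immature = 4, TLX = 4,
                                                    TAL1 = 4)))
  b <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study_bundle(b, dir)
  ma <- read_gct(file.path(dir, "mouse_a.gct"))
  expect_equal(ma$values, b$mouse_a$values, tolerance = 1e-12)
  expect_identical(read_cls(file.path(dir, "mouse_a.cls")),
                   unname(sample_groups(b$mouse_a)))
  om <- read_ortholog_map(file.path(dir, "orthologs.tsv"))
  expect_identical(om[["Vav1"]], "VAV1")
})
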