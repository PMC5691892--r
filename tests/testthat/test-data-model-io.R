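test_that("expression_matrix enforces its invariants", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
  storage.mode(v) <- "double"
  em <- expression_matrix(v, groups = c("A", "A", "B"))
  expect_s3_class(em, "expr_mat")
  expect_identical(dim(em), c(2L, 3L))
  expect_named(sample_groups(em), c("S1", "S2", "S3"))

  dup <- v; rownames(dup) <- c("G1", "G1")
  expect_error(expression_matrix(dup), "duplicate gene")
  nav <- v; nav[1, 1] <- NA
  expect_error(expression_matrix(nav), "finite")
  expect_error(expression_matrix(v, groups = c(S1 = "A", S2 = "A")),
               "cover every sample")
})

test_that("GCT round-trips and rejects dialect violations by line", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "1\t1", "NAME\tDescription\tS1", "G1\tna\t2.0"), path)
  em <- read_gct(path)
  expect_identical(dim(em), c(1L, 1L))
  expect_equal(unname(em$values["G1", "S1"]), 2.0)

  set.seed(1)
  v <- matrix(rnorm(12, 8), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  em0 <- expression_matrix(v)
  p2 <- withr::local_tempfile(fileext = ".gct")
  write_gct(em0, p2)
  em1 <- read_gct(p2)
  expect_identical(gene_ids(em1), gene_ids(em0))
  expect_identical(sample_ids(em1), sample_ids(em0))
  expect_equal(em1$values, em0$values, tolerance = 1e-12)
  # write . read is idempotent
  p3 <- withr::local_tempfile(fileext = ".gct")
  write_gct(em1, p3)
  expect_identical(readLines(p2), readLines(p3))

  bad <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "1\t1", "NAME\tDescription\tS1", "G1\tna\t2.0"), bad)
  expect_error(read_gct(bad), "line 1")
  writeLines(c("#1.2", "2\t1", "NAME\tDescription\tS1", "G1\tna\t2.0"), bad)
  expect_error(read_gct(bad), "declared 2 rows")
  writeLines(c("#1.2", "2\t1", "NAME\tDescription\tS1",
               "G1\tna\t2.0", "G1\tna\t3.0"), bad)
  expect_error(read_gct(bad), "duplicate gene id")
})

test_that("GMT parses, dedups with a message, and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SIG_UP\tna\tA\tB", "SIG_DN\tdesc\tC\tD\tE"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("SIG_UP", "SIG_DN"))
  expect_identical(sets$SIG_UP$genes, c("A", "B"))
  expect_identical(sets$SIG_DN$genes, c("C", "D", "E"))

  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, p2)
  expect_identical(read_gmt(p2), sets)

  writeLines("S\tna\tA\tA", path)
  expect_message(sets2 <- read_gmt(path), "duplicate")
  expect_identical(sets2$S$genes, "A")

  writeLines("S\tna", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("CLS accepts index and name dialects and checks counts", {
  path <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# WT KO", "0 0 1 1"), path)
  expect_identical(read_cls(path), c("WT", "WT", "KO", "KO"))
  writeLines(c("4 2 1", "# WT KO", "WT WT KO KO"), path)
  expect_identical(read_cls(path), c("WT", "WT", "KO", "KO"))
  writeLines(c("4 2 1", "# WT KO", "0 0 1"), path)
  expect_error(read_cls(path), "line 3")

  p2 <- withr::local_tempfile(fileext = ".cls")
  write_cls(c("WT", "WT", "KO", "KO"), p2)
  expect_identical(read_cls(p2), c("WT", "WT", "KO", "KO"))
})

test_that("collapse_probes keeps the max-mean probe and counts drops", {
  v <- rbind(P1 = c(5, 5), P2 = c(3, 3), P3 = c(1, 1))
  colnames(v) <- c("S1", "S2")
  em <- expression_matrix(v)
  out <- suppressMessages(
    collapse_probes(em, c(P1 = "G", P2 = "G", P3 = "H")))
  expect_identical(sort(gene_ids(out)), c("G", "H"))
  expect_equal(unname(out$values["G", ]), c(5, 5))

  out2 <- collapse_probes(em, c(P1 = "A", P2 = "B", P3 = "C"))
  expect_identical(dim(out2), dim(em))
  expect_message(out3 <- collapse_probes(em, c(P1 = "G1", P2 = "G2")),
                 "1 unmapped")
  expect_identical(nrow(out3$values), 2L)
  expect_error(suppressMessages(collapse_probes(em, c(PX = "G"))),
               "no probe maps")
})

test_that("map_orthologs expands, drops conflicts, and errors when empty", {
  sig <- bidirectional_signature("s", up = "Hes1", down = "Vav1")
  m <- list(Hes1 = "HES1", Vav1 = "VAV1")
  out <- map_orthologs(sig, m)
  expect_identical(out$up$genes, "HES1")
  expect_identical(out$down$genes, "VAV1")

  # identity map leaves the gene content unchanged
  idm <- list(Hes1 = "Hes1", Vav1 = "Vav1")
  out2 <- map_orthologs(sig, idm)
  expect_identical(out2$up$genes, sig$up$genes)

  # a target reached from both directions is dropped from both -> empty
  conflict <- list(Hes1 = "X", Vav1 = "X")
  expect_error(suppressMessages(map_orthologs(sig, conflict)),
               "empty after mapping")

  # one-to-many expansion
  sig2 <- bidirectional_signature("s2", up = c("A", "B"), down = "C")
  m2 <- list(A = c("A1", "A2"), B = "B1", C = "C1")
  out3 <- map_orthologs(sig2, m2)
  expect_setequal(out3$up$genes, c("A1", "A2", "B1"))
})

test_that("ortholog tables read back as source -> target lists", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_id\ttarget_id", "Hes1\tHES1", "A\tA1", "A\tA2"), path)
  m <- read_ortholog_map(path)
  expect_identical(m$Hes1, "HES1")
  expect_setequal(m$A, c("A1", "A2"))
})
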