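# Readers, writers, domain-type validation and cohort alignment.

test_that("read_matrix parses TSV and enforces the beta range", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tS1\tS2", "cg1\t0.1\t0.9", "cg2\t\t0.5"), f)
  b <- read_matrix(f, "beta")
  expect_s3_class(b, "beta_matrix")
  expect_equal(unclass(b)["cg1", ], c(S1 = 0.1, S2 = 0.9))
  expect_true(is.na(unclass(b)["cg2", "S1"]))  # blank -> missing

  writeLines(c("probe_id\tS1", "cg1\t1.2"), f)
  expect_error(read_matrix(f, "beta"), "cg1.*S1|out of \\[0,1\\]")
  b2 <- read_matrix(f, "expression")  # expression has no range rule
  expect_s3_class(b2, "expression_matrix")

  writeLines(c("probe_id\tS1", "cg1\t0.1", "cg1\t0.2"), f)
  expect_error(read_matrix(f, "beta"), "duplicated")

  writeLines(c("probe_id\tS1", "cg1\tabc"), f)
  expect_error(read_matrix(f, "beta"), "non-numeric cell.*cg1.*S1")
})

test_that("matrix write/read round-trips values and id order exactly", {
  set.seed(1)
  m <- matrix(runif(30), 5, 6,
              dimnames = list(paste0("cg", 5:1), paste0("S", 1:6)))
  m[2, 3] <- NA
  b <- beta_matrix(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(b, f, feature_col = "probe_id")
  b2 <- read_matrix(f, "beta")
  expect_equal(rownames(b2), rownames(b))
  expect_equal(colnames(b2), colnames(b))
  expect_equal(unclass(b2), unclass(b), tolerance = 1e-12)
})

test_that("beta_matrix validates range and ids", {
  expect_error(beta_matrix(matrix(c(0.5, 1.3), 1, 2,
                                  dimnames = list("cg1", c("A", "B")))),
               "out of \\[0,1\\]")
  expect_error(beta_matrix(matrix(0.5, 2, 1,
                                  dimnames = list(c("cg1", "cg1"), "A"))),
               "duplicated")
})

test_that("align_cohort averages probes per gene and reports retention", {
  tc <- tiny_cohort()
  al <- align_cohort(tc$beta, tc$expr, tc$probes)
  # geneA probes at 0.2 and 0.6 in S1 -> promoter beta 0.4
  expect_equal(al$beta["geneA", "S1"], mean(c(0.2, 0.6)))
  expect_equal(al$beta["geneB", ], c(S1 = 0.3, S2 = 0.5, S3 = 0.7))
  expect_equal(al$n_genes_retained, 2)
  expect_equal(al$retained_fraction, 1)

  # gene with no expression row lowers the retained fraction
  p3 <- probe_annotation(c("cg1", "cg2", "cg3"),
                         c("geneA", "geneA", "geneC"))
  al3 <- align_cohort(tc$beta, tc$expr, p3)
  expect_equal(al3$n_promoters_annotated, 2)
  expect_equal(al3$n_genes_retained, 1)
  expect_equal(al3$retained_fraction, 0.5)

  # missing probe values: sample contributes if >= 1 probe non-missing
  bna <- unclass(tc$beta); bna["cg1", "S1"] <- NA
  alna <- align_cohort(beta_matrix(bna), tc$expr, tc$probes)
  expect_equal(alna$beta["geneA", "S1"], 0.6)

  e2 <- expression_matrix(matrix(1, 1, 1, dimnames = list("geneA", "SX")))
  expect_error(align_cohort(tc$beta, e2, tc$probes), "no samples shared")
})

test_that("align_cohort is idempotent on an aligned pair", {
  tc <- tiny_cohort()
  al <- align_cohort(tc$beta, tc$expr, tc$probes)
  # feed the aligned per-gene matrices back with an identity annotation
  b2 <- beta_matrix(al$beta)
  e2 <- expression_matrix(al$expr)
  id_probes <- probe_annotation(rownames(al$beta), rownames(al$beta))
  al2 <- align_cohort(b2, e2, id_probes)
  expect_equal(al2$beta, al$beta)
  expect_equal(al2$expr, al$expr)
})

test_that("per-probe alignment keeps probes and maps them to genes", {
  tc <- tiny_cohort()
  al <- align_cohort(tc$beta, tc$expr, tc$probes, aggregate = "per_probe")
  expect_equal(rownames(al$beta), c("cg1", "cg2", "cg3"))
  expect_equal(unname(al$gene_map["cg2"]), "geneA")
  expect_equal(al$expr["cg1", ], al$expr["cg2", ])  # both carry geneA expression
})

test_that("promoter FASTA reading parses headers and validates sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">G1 tss=100", strrep("acgt", 75), ">G2",
               paste0(strrep("ACGT", 10), "N")), f)
  ps <- read_promoter_fasta(f)
  expect_equal(ps$gene_symbol, c("G1", "G2"))
  expect_equal(ps$tss_offset, c(100L, 0L))
  expect_equal(substr(ps$sequence[1], 1, 4), "ACGT")  # upper-cased

  writeLines(c(">G1", "ACGX"), f)
  expect_error(read_promoter_fasta(f), "illegal character 'X'")

  ps0 <- promoter_set("G1", "ACGTACGT", tss_offset = 3)
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_promoter_fasta(ps0, f2)
  back <- read_promoter_fasta(f2)
  expect_equal(back, ps0)

  expect_error(promoter_set("G1", ""), "empty")
  expect_error(promoter_set("G1", "ACGT", tss_offset = 4), "tss_offset")
})

test_that("annotation tables round-trip through TSV", {
  sa <- sample_annotation(c("S1", "S2"), msi_status = c("MSI", "MSS"),
                          doubling_time = c(20, NA),
                          survival_time = c(100, 50), event = c(1L, 0L),
                          mut_APC = c("mut", "wt"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(sa), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sa2 <- read_sample_annotation(f)
  expect_equal(sa2$msi_status, sa$msi_status)
  expect_equal(sa2$mut_APC, sa$mut_APC)
  expect_equal(sa2$doubling_time, sa$doubling_time)

  expect_error(sample_annotation("S1", survival_time = -1), ">= 0")
  expect_error(sample_annotation(c("S1", "S1")), "duplicated")
})
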