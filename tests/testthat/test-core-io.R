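test_that("parent of origin and design coding follow the reciprocal direction", {
  x <- tiny_ase()
  # s1 comes from AxB: the line-A mother contributed allele A
  po <- x$obs$parent_of_origin[x$obs$obs_id == "s1.A"]
  expect_equal(po, "maternal")
  expect_equal(x$obs$parent_of_origin[x$obs$obs_id == "s1.B"], "paternal")

  d <- balanced_design()
  row <- function(id) d[d$obs_id == id, ]
  # AxB, allele B: B allele, paternal copy, AxB mother
  expect_equal(unlist(row("s1.B")[, c("CR", "PO", "MG")]),
               c(CR = 1, PO = 1, MG = 0))
  # BxA, allele A: paternal copy, BxA mother
  expect_equal(unlist(row("s3.A")[, c("CR", "PO", "MG")]),
               c(CR = 0, PO = 1, MG = 1))
  expect_equal(unlist(row("s3.B")[, c("CR", "PO", "MG")]),
               c(CR = 1, PO = 0, MG = 1))
})

test_that("flipping the reciprocal direction flips PO and MG but not CR", {
  x <- tiny_ase()
  d1 <- build_design(x, "F", "head", "c1")
  meta2 <- x$meta
  meta2$direction <- ifelse(meta2$direction == "AxB", "BxA", "AxB")
  x2 <- ase_table(x$counts, meta2)
  d2 <- build_design(x2, "F", "head", "c1")
  expect_equal(d2$CR, d1$CR)
  expect_equal(d2$PO, 1 - d1$PO)
  expect_equal(d2$MG, 1 - d1$MG)
})

test_that("library size is the per-sample sum over autosomal genes and feeds a shared offset", {
  x <- tiny_ase()  # 2 genes, all counts 5: each sample has 2 genes x 2 alleles
  expect_equal(x$meta$library_size, rep(20, 4))
  d <- build_design(x, "F", "head", "c1")
  off <- tapply(d$offset, d$sample_id, function(o) length(unique(o)))
  expect_true(all(off == 1))

  # non-autosomal genes are excluded from the totals
  flags <- data.frame(gene_id = c("g1", "g2"),
                      is_autosomal = c(TRUE, FALSE), has_min_snvs = TRUE)
  counts <- matrix(5, 2, 8, dimnames = dimnames(x$counts))
  x2 <- ase_table(counts, x$meta, flags)
  expect_equal(x2$meta$library_size, rep(10, 4))
})

test_that("count columns without metadata raise an error naming the sample", {
  x <- tiny_ase()
  counts <- cbind(x$counts, `s9.A` = c(1, 1))
  expect_error(ase_table(counts, x$meta), "s9")
  neg <- x$counts; neg[1, 1] <- -1
  expect_error(ase_table(neg, x$meta), "egative")
})

test_that("write then read round-trips counts and metadata exactly", {
  set.seed(11)
  counts <- matrix(round(rgamma(16, 5, 0.1), 3), nrow = 2,
                   dimnames = dimnames(tiny_ase()$counts))
  x <- tiny_ase(counts)
  dir <- withr::local_tempdir()
  write_ase_counts(x, file.path(dir, "c.tsv"), file.path(dir, "m.tsv"),
                   file.path(dir, "f.tsv"))
  y <- read_ase_counts(file.path(dir, "c.tsv"), file.path(dir, "m.tsv"),
                       file.path(dir, "f.tsv"))
  expect_equal(y$counts, x$counts)
  expect_equal(y$meta, x$meta)
  expect_equal(y$gene_flags, x$gene_flags)
  expect_equal(y$obs$parent_of_origin, x$obs$parent_of_origin)
})

test_that("a scope with one direction and one replicate is an insufficient design", {
  x <- tiny_ase()
  keep <- x$meta$sample_id == "s1"
  x1 <- ase_table(x$counts[, c("s1.A", "s1.B"), drop = FALSE], x$meta[keep, ])
  expect_error(build_design(x1, "F", "head", "c1"), "insufficient design")
})

test_that("expression filter applies a strict threshold over enough observations", {
  tpm <- rbind(g1 = c(2, 2, 2, 2, 0, 0, 0, 0),
               g2 = c(2, 2, 2, 0.5, 0, 0, 0, 0),
               g3 = rep(1, 8))
  kept <- filter_expressed(tpm, analysis_config())
  expect_equal(kept, "g1")   # g2 has only 3 > 1; g3 never exceeds 1 strictly
  # idempotent
  expect_equal(filter_expressed(tpm[kept, , drop = FALSE]), kept)
})

test_that("parental read-sum filter keeps genes with at least 20 summed reads", {
  s1 <- c(a = 10, b = 19, c = 0)
  s2 <- c(a = 10, b = 0, c = 25)
  kept <- filter_parental_reads(s1, s2, analysis_config())
  expect_equal(kept, c("a", "c"))
  expect_equal(filter_parental_reads(s1[kept], s2[kept]), kept)
})

test_that("configuration validates thresholds and reads YAML overrides", {
  expect_error(analysis_config(alpha_fdr = 1.2), "alpha_fdr")
  expect_error(analysis_config(sb_bounds = c(1, 0.3)), "increasing")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha_fdr: 0.1", "parental_min_reads: 30"), path)
  cfg <- read_config(path)
  expect_equal(cfg$alpha_fdr, 0.1)
  expect_equal(cfg$parental_min_reads, 30)
  expect_equal(cfg$hybrid_fold_cutoff, 1.25)
  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), "unknown configuration key")
})
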