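test_that("effect classes are apportioned exactly, not sampled", {
  cfg <- sim_config(n_genes = 1000, class_props = c(cis_only = 0.1,
                                                    trans_only = 0.033),
                    seed = 3)
  truth <- simulate_truth(cfg)
  tab <- table(truth$class)
  expect_equal(unname(tab["cis_only"]), 100, ignore_attr = TRUE)
  # largest remainder: 33.0 -> 33, remainder goes to the larger fraction
  expect_equal(unname(tab["trans_only"]), 33, ignore_attr = TRUE)
  expect_equal(unname(tab["null"]), 867, ignore_attr = TRUE)
})

test_that("truth and counts are deterministic given the seed", {
  cfg <- sim_config(n_genes = 50, seed = 42)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_counts(t1, cfg)
  s2 <- simulate_counts(t2, cfg)
  expect_identical(s1$hybrid$counts, s2$hybrid$counts)
  expect_identical(s1$parental$counts, s2$parental$counts)
  expect_identical(s1$hybrid_tpm$values, s2$hybrid_tpm$values)
})

test_that("an all-null configuration has zero effects everywhere", {
  cfg <- sim_config(n_genes = 40, class_props = c(cis_only = 0), seed = 5)
  truth <- simulate_truth(cfg)
  for (col in c("cis_F_head", "cis_F_gonad", "cis_M_head", "cis_M_gonad",
                "trans", "po", "mg")) {
    expect_true(all(truth[[col]] == 0), info = col)
  }
  expect_error(sim_config(class_props = c(cis_only = 0.8, trans_only = 0.4)),
               "sum to at most 1")
})

test_that("expected means encode cis as allelic imbalance and trans as parental divergence", {
  base <- gene_truth("g1", base_mean = 100, dispersion = 0.01)
  # no effects: hybrid alleles balanced
  em <- expected_means(base, "F", "head", "hybrid", "AxB")
  expect_equal(unname(em[, "B"] / em[, "A"]), 1)

  cis1 <- gene_truth("g1", 100, 0.01, cis_F_head = 1, cis_F_gonad = 1,
                     cis_M_head = 1, cis_M_gonad = 1)
  pm <- expected_means(cis1, "F", "head", "parent")
  expect_equal(unname(pm[, "B"] / pm[, "A"]), 2)
  hm <- expected_means(cis1, "F", "head", "hybrid", "AxB")
  expect_equal(unname(hm[, "B"] / hm[, "A"]), 2)

  trans1 <- gene_truth("g1", 100, 0.01, trans = 1)
  pm <- expected_means(trans1, "F", "head", "parent")
  expect_equal(unname(pm[, "B"] / pm[, "A"]), 2)
  hm <- expected_means(trans1, "F", "head", "hybrid", "AxB")
  expect_equal(unname(hm[, "B"] / hm[, "A"]), 1)

  expect_error(expected_means(base, "X", "head", "parent"), "unknown sex")
  expect_error(expected_means(base, "F", "head", "hybrid"), "direction")
})

test_that("parent-of-origin and maternal-genotype effects act on the right cells", {
  tr <- gene_truth("g1", 100, 0.01, po = 1)
  axb <- expected_means(tr, "F", "head", "hybrid", "AxB")
  bxa <- expected_means(tr, "F", "head", "hybrid", "BxA")
  # paternal copy doubled: allele B in AxB, allele A in BxA
  expect_equal(unname(axb[, "B"] / axb[, "A"]), 2)
  expect_equal(unname(bxa[, "B"] / bxa[, "A"]), 0.5)

  tr <- gene_truth("g1", 100, 0.01, mg = 1)
  axb <- expected_means(tr, "F", "head", "hybrid", "AxB")
  bxa <- expected_means(tr, "F", "head", "hybrid", "BxA")
  expect_equal(unname(bxa[, "A"] / axb[, "A"]), 2)
  expect_equal(unname(bxa[, "B"] / axb[, "B"]), 2)
})

test_that("near-Poisson counts at high depth give tightly balanced allele fractions", {
  n <- 400
  truth <- gene_truth(sprintf("g%03d", 1:n), base_mean = 1e4,
                      dispersion = 1e-6)
  cfg <- sim_config(n_genes = n, seed = 9)
  sim <- simulate_counts(truth, cfg)
  a <- sim$hybrid$counts[, sim$hybrid$obs$allele == "A"]
  b <- sim$hybrid$counts[, sim$hybrid$obs$allele == "B"]
  frac <- rowSums(a) / (rowSums(a) + rowSums(b))
  expect_true(all(abs(frac - 0.5) < 0.02))
})

test_that("simulated hybrid log allelic ratios recover the cis effect within 3 SE", {
  n <- 1500
  truth <- gene_truth(sprintf("g%04d", 1:n), base_mean = 500,
                      dispersion = 0.005,
                      cis_F_head = 1, cis_F_gonad = 1,
                      cis_M_head = 1, cis_M_gonad = 1)
  cfg <- sim_config(n_genes = n, seed = 21)
  sim <- simulate_counts(truth, cfg)
  keep <- sim$hybrid$obs$sample_id %in%
    sim$hybrid$meta$sample_id[sim$hybrid$meta$sex == "F" &
                                sim$hybrid$meta$tissue == "head"]
  a <- rowSums(sim$hybrid$counts[, keep & sim$hybrid$obs$allele == "A"])
  b <- rowSums(sim$hybrid$counts[, keep & sim$hybrid$obs$allele == "B"])
  lr <- log2(b + 0.5) - log2(a + 0.5)
  se <- sd(lr) / sqrt(n)
  expect_lt(abs(mean(lr) - 1), 3 * se)
})

test_that("generated tables satisfy the core validators and round-trip through TSV", {
  sim <- simulate_ase(sim_config(n_genes = 30, seed = 13))
  expect_s3_class(sim$hybrid, "ase_table")
  expect_s3_class(sim$parental, "parental_table")
  expect_true(all(sim$hybrid$counts >= 0))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  y <- read_ase_counts(file.path(dir, "hybrid_counts.tsv"),
                       file.path(dir, "hybrid_meta.tsv"),
                       file.path(dir, "gene_flags.tsv"))
  expect_equal(y$counts, sim$hybrid$counts)
  p <- read_parental_counts(file.path(dir, "parental_counts.tsv"),
                            file.path(dir, "parental_meta.tsv"))
  expect_equal(p$counts, sim$parental$counts)
})

test_that("compensatory and sex-reversed classes carry the promised structure", {
  cfg <- sim_config(n_genes = 400, seed = 17)
  truth <- simulate_truth(cfg)
  comp <- truth[truth$class == "compensatory", ]
  expect_true(all(comp$trans == -comp$cis_F_head & comp$cis_F_head != 0))
  rev <- truth[truth$class == "sex_reversed", ]
  expect_true(all(rev$cis_F_head == -rev$cis_M_head & rev$cis_F_head != 0))
  cis <- truth[truth$class == "cis_only", ]
  expect_true(all(cis$trans == 0 & cis$cis_F_head != 0))
})
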