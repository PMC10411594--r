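# independent hand-coded decision table, enumerating the category for
# every significance combination and ratio regime
.oracle_category <- function(P, H, T, ratio) {
  nsig <- sum(P, H, T)
  if (nsig == 0) return("conserved")
  if (nsig == 1) return("ambiguous")
  if (P && H && !T) return("cis_only")
  if (P && !H && T) return("trans_only")
  if (!P && H && T) return("compensatory")
  if (ratio >= 1 || is.nan(ratio)) return("cis_plus_trans")
  "cis_by_trans"
}

test_that("the seven-way classification agrees with the oracle on all flag and ratio combinations", {
  flags <- expand.grid(P = c(FALSE, TRUE), H = c(FALSE, TRUE),
                       T = c(FALSE, TRUE))
  # ratio regimes <1, =1, >1 realized through (log2_P, log2_H) pairs,
  # including sign flips and a zero denominator
  pairs <- rbind(c(0.5, 1), c(-2, 1), c(1, 1), c(3, 1), c(-3, -1),
                 c(1, 0), c(0, 0))
  for (i in seq_len(nrow(flags))) {
    for (j in seq_len(nrow(pairs))) {
      got <- as.character(classify_regulatory(flags$P[i], flags$H[i],
                                              flags$T[i], pairs[j, 1],
                                              pairs[j, 2]))
      want <- .oracle_category(flags$P[i], flags$H[i], flags$T[i],
                               pairs[j, 1] / pairs[j, 2])
      expect_equal(got, want,
                   info = sprintf("flags %d pair %d", i, j))
    }
  }
})

test_that("Fisher trans test matches exact hypergeometric enumeration", {
  expect_equal(test_trans_fisher(100, 100, 100, 100), 1)
  expect_equal(test_trans_fisher(5, 5, 5, 5), 1)
  # [[10,0],[0,10]]: only the two extreme tables are as or more extreme
  p_exact <- 2 / choose(20, 10)
  expect_equal(test_trans_fisher(10, 0, 0, 10), p_exact, tolerance = 1e-10)
  # estimated counts are rounded half-up before the exact test
  expect_equal(test_trans_fisher(10.5, 0.2, 0.4, 10.5),
               test_trans_fisher(11, 0, 0, 11))
  expect_equal(test_trans_fisher(0, 0, 0, 0), 1)
  expect_error(test_trans_fisher(-1, 0, 0, 0), "nonnegative")
})

test_that("identical parental lines and degenerate zero counts give null P-test p-values", {
  Y <- rbind(g1 = c(50, 50, 50, 50), g2 = c(0, 0, 0, 0))
  line <- c("A", "A", "B", "B")
  res <- test_parental_de(Y, line, lib_size = rep(100, 4))
  expect_gt(res$p[1], 0.9)
  expect_equal(res$p[2], 1)
})

test_that("parental divergence is detected with high power at a 4x fold", {
  n <- 80
  set.seed(51)
  mu1 <- 500; mu2 <- 2000
  Y <- cbind(matrix(rnbinom(2 * n, mu = mu1, size = 1 / 0.05), ncol = 2),
             matrix(rnbinom(2 * n, mu = mu2, size = 1 / 0.05), ncol = 2))
  rownames(Y) <- paste0("g", 1:n)
  res <- test_parental_de(Y, c("A", "A", "B", "B"), rep(1e6, 4))
  expect_gte(mean(res$p < 0.05), 0.9)
})

test_that("hybrid allelic imbalance is detected when one allele is doubled", {
  n <- 80
  truth <- gene_truth(sprintf("h%03d", 1:n), base_mean = 500,
                      dispersion = 0.005,
                      cis_F_head = 1, cis_F_gonad = 1, cis_M_head = 1,
                      cis_M_gonad = 1)
  sim <- simulate_counts(truth, sim_config(n_genes = n, seed = 52))
  d <- build_design(sim$hybrid, "F", "head", "cross1")
  Y <- sim$hybrid$counts[, match(d$obs_id, colnames(sim$hybrid$counts))]
  res <- test_hybrid_imbalance(Y, d)
  expect_gte(mean(res$p < 0.05), 0.8)

  # balanced alleles: noise-free expected counts give p ~ 1
  bal <- matrix(rep(c(200, 200), 4), nrow = 1,
                dimnames = list("b1", d$obs_id[1:8]))
  d0 <- d; d0$offset <- 0
  expect_gt(test_hybrid_imbalance(bal, d0)$p, 0.9)

  # a missing observation still fits, with n_obs recorded
  res7 <- test_hybrid_imbalance(Y[1:3, 1:7], d[1:7, ])
  expect_equal(unique(res7$n_obs), 7)
  expect_true(all(is.finite(res7$p)))
})

test_that("the full pipeline reproduces a single gene's category from its flags", {
  sim <- simulate_ase(sim_config(n_genes = 150, seed = 53))
  out <- run_cistrans(sim$parental, sim$hybrid, analysis_config())
  calls <- out$calls[out$calls$sex == "F" & out$calls$tissue == "head", ]
  cfg <- analysis_config()
  redo <- classify_regulatory(calls$fdr_parental < cfg$alpha_fdr,
                              calls$fdr_hybrid < cfg$alpha_fdr,
                              calls$fdr_trans < cfg$alpha_fdr,
                              calls$log2_P, calls$log2_H)
  expect_equal(as.character(redo), as.character(calls$category))
})

test_that("per-scope category proportions sum to one", {
  sim <- simulate_ase(sim_config(n_genes = 120, seed = 54))
  out <- run_cistrans(sim$parental, sim$hybrid, analysis_config())
  key <- paste(out$proportions$cross_id, out$proportions$sex,
               out$proportions$tissue)
  sums <- tapply(out$proportions$proportion, key, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("pooled and per-reciprocal analyses agree on strong cis genes", {
  n <- 150
  truth <- gene_truth(sprintf("c%03d", 1:n), base_mean = 800,
                      dispersion = 0.005,
                      cis_F_head = 1.5, cis_F_gonad = 1.5,
                      cis_M_head = 1.5, cis_M_gonad = 1.5)
  sim <- simulate_counts(truth, sim_config(n_genes = n, seed = 55))
  cfg <- analysis_config()
  pooled <- run_cistrans(sim$parental, sim$hybrid, cfg,
                         pool_reciprocals = TRUE)$calls
  split <- run_cistrans(sim$parental, sim$hybrid, cfg,
                        pool_reciprocals = FALSE)$calls
  pooled <- pooled[pooled$sex == "F" & pooled$tissue == "head", ]
  split <- split[split$sex == "F" & split$tissue == "head" &
                   split$reciprocals == "AxB", ]
  m <- match(pooled$gene_id, split$gene_id)
  cis_call_pooled <- pooled$category %in% c("cis_only", "cis_plus_trans",
                                            "cis_by_trans")
  cis_call_split <- split$category[m] %in% c("cis_only", "cis_plus_trans",
                                             "cis_by_trans")
  expect_gte(mean(cis_call_pooled == cis_call_split, na.rm = TRUE), 0.9)
})
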