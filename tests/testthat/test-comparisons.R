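test_that("sex bias scores follow the pseudocounted log ratio", {
  expect_equal(sex_bias(5, 5), 0)
  expect_equal(sex_bias(7, 1), 2)        # log2(8/2)
  expect_equal(sex_bias(0, 0), 0)
  expect_error(sex_bias(-1, 2), "nonnegative")
})

test_that("sex-bias binning matches an interval-membership oracle including boundaries", {
  oracle <- function(sb) {
    if (sb < -1) "MS"
    else if (sb < -0.3) "MB"     # boundary -1 goes to the less biased bin
    else if (sb < 0.3) "UB"
    else if (sb <= 1) "FB"       # boundary 0.3 and 1 both fall in FB
    else "FS"
  }
  grid <- c(-2, -1.0001, -1, -0.9999, -0.3, -0.2999, 0, 0.2999, 0.3,
            0.9999, 1, 1.0001, 2)
  got <- as.character(sb_category(grid))
  expect_equal(got, vapply(grid, oracle, character(1)))
  expect_error(sb_category(0, bounds = c(1, 0)), "increasing")
})

test_that("Mann-Whitney comparisons reproduce exact enumeration on small groups", {
  # {1,2,3} vs {4,5,6}: U = 0; 2 of the C(6,3) = 20 assignments are as extreme
  expect_equal(mann_whitney_p(1:3, 4:6), 2 / choose(6, 3))
  expect_equal(mann_whitney_p(c(1, 2, 3), c(1, 2, 3)), 1)

  dev <- c(1, 2, 3, 4, 5, 6, 10)
  cat <- factor(c("MS", "MS", "MS", "FB", "FB", "FB", "UB"),
                levels = c("MS", "MB", "UB", "FB", "FS"))
  P <- compare_deviance_by_sb(dev, cat)
  expect_equal(P["MS", "FB"], 0.1)
  expect_equal(P["FB", "MS"], 0.1)
  expect_true(is.na(P["MS", "UB"]))   # UB has a single gene
  expect_true(all(is.na(P[, "MB"]))) # empty category
})

test_that("the pooled two-proportion z statistic matches the hand formula", {
  res <- proportion_test_z(50, 100, 30, 100)
  z_hand <- 0.2 / sqrt(0.4 * 0.6 * (1 / 100 + 1 / 100))
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-z_hand), tolerance = 1e-12)
  expect_equal(proportion_test_z(30, 100, 30, 100), list(z = 0, p = 1))
  expect_equal(proportion_test_z(0, 10, 0, 10), list(z = 0, p = 1))
  expect_error(proportion_test_z(5, 0, 1, 10), "positive")
})

test_that("Fisher proportion comparisons match hypergeometric enumeration", {
  expect_equal(proportion_test_fisher(10, 10, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_equal(proportion_test_fisher(1, 10, 1, 10), 1)
  expect_equal(proportion_test_fisher(5, 10, 5, 10), 1)
})

test_that("the shared-CR chi-square test matches the hand-computed statistic", {
  calls1 <- setNames(rep(c(TRUE, FALSE), c(50, 50)), paste0("g", 1:100))
  calls2 <- setNames(rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 20, 20, 30)),
                     paste0("g", 1:100))
  ov <- overlap_chi2(calls1, calls2)
  # table [[30,20],[20,30]], all expected cells 25: chi2 = 4 * 25/25 = 4
  expect_equal(ov$chi2, 4, tolerance = 1e-12)
  expect_equal(ov$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(ov$direction, "over")
  # symmetry in the two scopes
  ov2 <- overlap_chi2(calls2, calls1)
  expect_equal(ov2$chi2, ov$chi2)
  expect_equal(ov2$p, ov$p)

  # identical calls: strong overrepresentation
  set.seed(71)
  calls <- setNames(runif(500) < 0.2, paste0("h", 1:500))
  self <- overlap_chi2(calls, calls)
  expect_equal(self$direction, "over")
  expect_lt(self$p, 1e-6)

  # degenerate margin
  none <- setNames(rep(FALSE, 100), paste0("g", 1:100))
  z <- overlap_chi2(calls1, none)
  expect_true(is.na(z$p))
  expect_equal(z$reason, "zero margin")
  expect_error(overlap_chi2(calls1[1:5], calls2[1:5]), "at least 20")
})

test_that("independent calls reject at close to the nominal rate", {
  set.seed(72)
  rej <- replicate(300, {
    a <- setNames(runif(200) < 0.25, paste0("g", 1:200))
    b <- setNames(runif(200) < 0.25, paste0("g", 1:200))
    ov <- overlap_chi2(a, b)
    !is.na(ov$p) && ov$p < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("tissue specificity is the focal share of total expression", {
  expr <- rbind(g1 = c(10, 0, 0, 0), g2 = c(1, 1, 1, 1),
                g3 = c(3, 1, 0, 0), g4 = c(0, 0, 0, 0))
  ts <- tissue_specificity(expr, 1)
  expect_equal(unname(ts), c(1, 0.25, 0.75, NA))
})

test_that("Spearman association uses average ranks and handles degenerate input", {
  expect_equal(spearman_assoc(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_assoc(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_true(is.na(spearman_assoc(rep(1, 5), 1:5)$rho))
  expect_true(is.na(spearman_assoc(1:2, 2:1)$rho))
})

test_that("scope-level sex bias joins expression across sexes", {
  sim <- simulate_ase(sim_config(n_genes = 60, seed = 73, sb_sd = 2))
  tab <- sex_bias_table(sim$hybrid_tpm, tissue = "head", cross = "cross1")
  expect_equal(nrow(tab), 60)
  expect_setequal(levels(tab$category), c("MS", "MB", "UB", "FB", "FS"))
  # strongly female-biased truth should land on the female side
  tr <- sim$truth
  strong_f <- tr$gene_id[tr$sb_true > 2]
  if (length(strong_f) >= 3) {
    expect_gt(mean(tab$sb[tab$gene_id %in% strong_f] > 0), 0.8)
  }
})
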