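#' Sex-bias score
#'
#' `SB = log2((exp_F + 1) / (exp_M + 1))`: positive for female-biased,
#' negative for male-biased expression. The +1 pseudocount keeps the score
#' finite and pulls lowly expressed genes toward 0.
#'
#' @param exp_F,exp_M nonnegative female and male expression (TPM-like).
#' @return numeric vector of SB scores.
#' @export
sex_bias <- function(exp_F, exp_M) {
  if (any(exp_F < 0) || any(exp_M < 0)) stop("expression must be nonnegative")
  log2((exp_F + 1) / (exp_M + 1))
}

.SB_LEVELS <- c("MS", "MB", "UB", "FB", "FS")

#' Sex-bias category
#'
#' Bins SB scores into strongly male-biased (MS, SB < -1), male-biased
#' (MB), unbiased (UB), female-biased (FB) and strongly female-biased
#' (FS, SB > 1), with bin boundaries from the configuration. Boundary
#' values are assigned to the less-biased side, so e.g. SB = -1 is MB and
#' SB = 1 is FB.
#'
#' @param sb numeric SB scores.
#' @param bounds strictly increasing boundaries, default `(-1, -0.3, 0.3, 1)`.
#' @return factor with levels MS, MB, UB, FB, FS.
#' @export
sb_category <- function(sb, bounds = c(-1, -0.3, 0.3, 1)) {
  if (is.unsorted(bounds, strictly = TRUE)) stop("bounds must be strictly increasing")
  out <- rep(NA_character_, length(sb))
  out[sb < bounds[1]] <- "MS"
  out[sb >= bounds[1] & sb < bounds[2]] <- "MB"
  out[sb >= bounds[2] & sb < bounds[3]] <- "UB"
  out[sb >= bounds[3] & sb <= bounds[4]] <- "FB"
  out[sb > bounds[4]] <- "FS"
  factor(out, levels = .SB_LEVELS)
}

#' Per-gene sex-bias table for a scope
#'
#' Computes exp_F and exp_M as the mean TPM across the female and male
#' samples of one tissue x cross, then the SB score and category.
#'
#' @param tpm an [expression_table()] whose `meta` carries `sex`,
#'   `tissue`, `cross_id`.
#' @param tissue,cross scope selectors.
#' @param cfg an [analysis_config()].
#' @return data.frame `gene_id`, `exp_F`, `exp_M`, `sb`, `category`.
#' @export
sex_bias_table <- function(tpm, tissue, cross, cfg = analysis_config()) {
  stopifnot(inherits(tpm, "expression_table"))
  m <- tpm$meta
  if (is.null(m)) stop("expression table needs sample metadata")
  sel <- m$tissue == tissue & m$cross_id == cross
  fe <- rowMeans(tpm$values[, m$sample_id[sel & m$sex == "F"], drop = FALSE])
  ma <- rowMeans(tpm$values[, m$sample_id[sel & m$sex == "M"], drop = FALSE])
  sb <- sex_bias(fe, ma)
  data.frame(gene_id = rownames(tpm$values), exp_F = fe, exp_M = ma,
             sb = sb, category = sb_category(sb, cfg$sb_bounds),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test wrapper
#'
#' Two-sided test; exact enumeration when both groups have at most 20
#' observations and there are no ties, normal approximation with tie
#' correction (and no continuity correction) otherwise.
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
mann_whitney_p <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      correct = FALSE))$p.value
}

#' Pairwise deviance-by-sex-bias comparisons
#'
#' Compares the distribution of per-gene deviance explained by CR between
#' every pair of sex-bias categories with two-sided Mann-Whitney U tests.
#' Pairs where either category has fewer than 2 genes are `NA`.
#'
#' @param deviance per-gene deviance explained by CR.
#' @param category per-gene sex-bias category (factor MS/MB/UB/FB/FS).
#' @return 5x5 symmetric matrix of p-values (`NA` diagonal).
#' @export
compare_deviance_by_sb <- function(deviance, category) {
  stopifnot(length(deviance) == length(category))
  category <- factor(category, levels = .SB_LEVELS)
  groups <- split(deviance, category)
  P <- matrix(NA_real_, 5, 5, dimnames = list(.SB_LEVELS, .SB_LEVELS))
  for (i in 1:4) for (j in (i + 1):5) {
    a <- groups[[i]]; b <- groups[[j]]
    if (length(a) >= 2 && length(b) >= 2) {
      P[i, j] <- P[j, i] <- mann_whitney_p(a, b)
    }
  }
  P
}

#' Two-proportion z-test
#'
#' Pooled-variance two-proportion z statistic without continuity
#' correction; a degenerate pooled proportion (0 or 1) gives z = 0, p = 1.
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @return list `z`, `p` (two-sided).
#' @export
proportion_test_z <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("need 0 <= k <= n")
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) return(list(z = 0, p = 1))
  z <- (k1 / n1 - k2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fisher's exact two-proportion test
#'
#' Two-sided Fisher's exact test on `[[k1, n1 - k1], [k2, n2 - k2]]`.
#'
#' @inheritParams proportion_test_z
#' @return two-sided p-value.
#' @export
proportion_test_fisher <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("need 0 <= k <= n")
  stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                            byrow = TRUE))$p.value
}

#' Overlap of CR calls between two scopes
#'
#' Builds the 2x2 contingency table of shared cis-regulatory calls over
#' the genes tested in both scopes (CR in both / one / neither) and
#' applies a chi-square test without continuity correction. `direction`
#' says whether shared CR genes are over- or underrepresented relative to
#' independence.
#'
#' @param calls1,calls2 named logical vectors (gene id -> CR significant).
#' @param min_common minimum number of genes in common (default 20).
#' @return list of class `overlap_table`: `n11`, `n10`, `n01`, `n00`,
#'   `chi2`, `p`, `direction`, `n_common`, `reason` (`NA` unless the test
#'   was not computable).
#' @export
overlap_chi2 <- function(calls1, calls2, min_common = 20) {
  genes <- intersect(names(calls1), names(calls2))
  if (length(genes) < min_common) {
    stop("need at least ", min_common, " genes tested in both scopes")
  }
  a <- calls1[genes]; b <- calls2[genes]
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b); n00 <- sum(!a & !b)
  tab <- matrix(c(n11, n10, n01, n00), nrow = 2, byrow = TRUE)
  exp11 <- sum(a) * sum(b) / length(genes)
  out <- list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
              chi2 = NA_real_, p = NA_real_,
              direction = if (n11 >= exp11) "over" else "under",
              n_common = length(genes), reason = NA_character_)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out$reason <- "zero margin"
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out$chi2 <- unname(ct$statistic)
    out$p <- unname(ct$p.value)
  }
  class(out) <- "overlap_table"
  out
}

#' Pairwise CR-overlap tests across scopes
#'
#' Applies [overlap_chi2()] to every pair of scopes of a [run_cr_glm()]
#' result, using `fdr_CR < alpha_fdr` as the CR call.
#'
#' @param cr_results data.frame from [run_cr_glm()].
#' @param cfg an [analysis_config()].
#' @param min_common minimum shared gene count per pair.
#' @return data.frame with one row per scope pair: the contingency
#'   counts, chi-square statistic, p-value and direction.
#' @export
run_overlap <- function(cr_results, cfg = analysis_config(), min_common = 20) {
  cr_results <- cr_results[!is.na(cr_results$fdr_CR), , drop = FALSE]
  key <- paste(cr_results$cross_id, cr_results$sex, cr_results$tissue, sep = ":")
  scopes <- unique(key)
  res <- list()
  for (i in seq_along(scopes)) for (j in seq_along(scopes)) {
    if (j <= i) next
    d1 <- cr_results[key == scopes[i], ]
    d2 <- cr_results[key == scopes[j], ]
    c1 <- stats::setNames(d1$fdr_CR < cfg$alpha_fdr, d1$gene_id)
    c2 <- stats::setNames(d2$fdr_CR < cfg$alpha_fdr, d2$gene_id)
    ov <- tryCatch(overlap_chi2(c1, c2, min_common), error = function(e) NULL)
    if (is.null(ov)) next
    res[[length(res) + 1]] <- data.frame(
      scope1 = scopes[i], scope2 = scopes[j],
      n11 = ov$n11, n10 = ov$n10, n01 = ov$n01, n00 = ov$n00,
      chi2 = ov$chi2, p = ov$p, direction = ov$direction,
      n_common = ov$n_common, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tissue specificity of expression
#'
#' Fraction of a gene's summed expression across an atlas of tissues that
#' comes from the focal tissue (e.g. testis specificity from a
#' user-supplied atlas table). All-zero genes give `NA`.
#'
#' @param expr matrix genes x tissues of nonnegative expression.
#' @param focal focal tissue column (name or index).
#' @return numeric vector in \[0, 1\] (or `NA`).
#' @export
tissue_specificity <- function(expr, focal) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression must be nonnegative")
  tot <- rowSums(expr)
  out <- expr[, focal] / tot
  out[tot == 0] <- NA_real_
  out
}

#' Spearman rank association
#'
#' Rank correlation with average ranks for ties and a large-sample
#' p-value; used e.g. to relate tissue specificity to CR significance.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return list `rho`, `p` (both `NA` when fewer than 3 complete pairs or
#'   either vector is constant).
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
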