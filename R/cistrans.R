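#' Parental differential expression test (P test)
#'
#' Negative-binomial likelihood-ratio test of the line effect on overall
#' parental expression, with log library-size offsets; the same engine as
#' the allelic models. Genes with all-zero counts get p = 1.
#'
#' @param Y counts matrix genes x parental samples (a scope's columns).
#' @param line character/factor of `A`/`B` per sample.
#' @param lib_size library sizes per sample (offsets are `log(lib_size)`).
#' @param cfg an [analysis_config()].
#' @return data.frame `gene_id`, `p`, `n_obs`.
#' @export
test_parental_de <- function(Y, line, lib_size, cfg = analysis_config()) {
  Y <- as.matrix(Y)
  X_full <- cbind(1, line = as.integer(line == "B"))
  X_red <- X_full[, 1, drop = FALSE]
  .genewise_lrt(Y, X_full, X_red, log(lib_size), cfg, balance_col = X_full[, 2])
}

#' Hybrid allelic imbalance test (H test)
#'
#' Negative-binomial likelihood-ratio test of the allele effect on hybrid
#' allele-specific counts, paired within sample through a sample covariate
#' (each hybrid library contributes both alleles). Reciprocal directions
#' are pooled as replicates by default upstream.
#'
#' @param Y counts matrix genes x observations for the scope.
#' @param design data.frame from [build_design()] for those observations.
#' @param cfg an [analysis_config()].
#' @return data.frame `gene_id`, `p`, `n_obs`.
#' @export
test_hybrid_imbalance <- function(Y, design, cfg = analysis_config()) {
  Y <- as.matrix(Y)
  sample_f <- factor(design$sample_id)
  S <- stats::model.matrix(~sample_f)[, -1, drop = FALSE]
  X_full <- cbind(1, S, CR = design$CR)
  X_red <- cbind(1, S)
  .genewise_lrt(Y, X_full, X_red, design$offset, cfg, balance_col = design$CR)
}

# shared gene-by-gene LRT with common-dispersion shrinkage; balance_col is
# the tested binary covariate, used for the half-count adjustment
.genewise_lrt <- function(Y, X_full, X_red, offset, cfg, balance_col) {
  genes <- rownames(Y)
  cd <- common_dispersion(Y, X_full, offset)
  resid_df <- ncol(Y) - ncol(X_full)
  p <- rep(NA_real_, nrow(Y))
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    if (all(y == 0)) {
      p[i] <- 1
      next
    }
    if (.needs_half_count(y, balance_col)) y <- y + 0.5
    if (cfg$common_dispersion_only) {
      disp <- cd
    } else {
      disp <- estimate_dispersion(y, X_full, offset, init = cd)
      disp <- .shrink_dispersion(disp, cd, resid_df, cfg$prior_df)
    }
    p[i] <- .nb_lrt(y, X_full, X_red, offset, 1 / disp)$p
  }
  data.frame(gene_id = genes, p = p, n_obs = ncol(Y),
             stringsAsFactors = FALSE)
}

#' Fisher's exact trans test (T test)
#'
#' Two-sided Fisher's exact test on the 2x2 table `[[P1, P2], [A1, A2]]`
#' comparing the parental expression ratio with the hybrid allelic ratio:
#' a difference between the two ratios indicates a trans component.
#' Estimated counts are rounded half-up to integers; an all-zero table
#' gives p = 1.
#'
#' @param P1,P2 per-gene summed parental counts (lines A and B).
#' @param A1,A2 per-gene summed hybrid allele counts (alleles A and B).
#' @return numeric vector of two-sided p-values.
#' @export
test_trans_fisher <- function(P1, P2, A1, A2) {
  n <- length(P1)
  stopifnot(length(P2) == n, length(A1) == n, length(A2) == n)
  if (any(c(P1, P2, A1, A2) < 0)) stop("counts must be nonnegative")
  rhu <- function(x) floor(x + 0.5)  # round half-up, not banker's rounding
  vapply(seq_len(n), function(i) {
    tab <- matrix(rhu(c(P1[i], P2[i], A1[i], A2[i])), nrow = 2, byrow = TRUE)
    if (sum(tab) == 0) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
}

.REG_CATEGORIES <- c("conserved", "cis_only", "trans_only", "cis_plus_trans",
                     "cis_by_trans", "compensatory", "ambiguous")

#' Seven-category cis/trans regulatory classification
#'
#' Combines the significance flags of the parental (P), hybrid-allelic (H)
#' and trans (T) tests into the regulatory category of each gene:
#' \describe{
#'   \item{conserved}{no test significant.}
#'   \item{cis_only}{P and H significant, T not.}
#'   \item{trans_only}{P and T significant, H not.}
#'   \item{cis_plus_trans}{P, H and T significant and
#'     `log2(P1/P2) / log2(A1/A2) >= 1`: cis and trans favor the same
#'     allele (the boundary ratio of exactly 1 is assigned here).}
#'   \item{cis_by_trans}{P, H and T significant, ratio < 1: cis and trans
#'     favor different alleles.}
#'   \item{compensatory}{H and T significant, P not: opposite cis and
#'     trans effects cancel in the parentals.}
#'   \item{ambiguous}{exactly one test significant.}
#' }
#' The rule is total over the eight flag combinations.
#'
#' @param sig_P,sig_H,sig_T logical vectors of per-gene significance at
#'   the configured FDR.
#' @param log2_P,log2_H pseudocounted log2 parental and hybrid allelic
#'   ratios (same orientation: line/allele A over B).
#' @return factor with the seven category levels.
#' @export
classify_regulatory <- function(sig_P, sig_H, sig_T, log2_P, log2_H) {
  n <- length(sig_P)
  stopifnot(length(sig_H) == n, length(sig_T) == n,
            length(log2_P) == n, length(log2_H) == n)
  ratio <- log2_P / log2_H
  n_sig <- sig_P + sig_H + sig_T
  out <- rep("ambiguous", n)
  out[n_sig == 0] <- "conserved"
  out[sig_P & sig_H & !sig_T] <- "cis_only"
  out[sig_P & !sig_H & sig_T] <- "trans_only"
  out[!sig_P & sig_H & sig_T] <- "compensatory"
  full <- sig_P & sig_H & sig_T
  # ratio >= 1 (including an undefined 0/0 boundary case) -> same-direction
  out[full & (is.nan(ratio) | ratio >= 1)] <- "cis_plus_trans"
  out[full & !is.nan(ratio) & ratio < 1] <- "cis_by_trans"
  factor(out, levels = .REG_CATEGORIES)
}

#' Full cis/trans divergence pipeline
#'
#' For each sex x tissue x cross scope: filters genes on the summed
#' parental read count, runs the P, H and T tests, applies
#' Benjamini-Hochberg FDR per test within the scope, computes the
#' pseudocounted log ratios and assigns the seven-way category. Reciprocal
#' hybrid directions are pooled as replicates by default; with
#' `pool_reciprocals = FALSE` each direction is classified separately.
#'
#' @param parental a [parental_table()] of overall parental counts.
#' @param hybrid an [ase_table()] of hybrid allele-specific counts.
#' @param cfg an [analysis_config()].
#' @param pool_reciprocals pool the two reciprocal directions (default) or
#'   analyse them separately.
#' @return list with `calls` (per gene x scope: p/fdr for the three tests,
#'   log ratios, category) and `proportions` (per scope category
#'   fractions, summing to 1).
#' @export
run_cistrans <- function(parental, hybrid, cfg = analysis_config(),
                         pool_reciprocals = TRUE) {
  stopifnot(inherits(parental, "parental_table"), inherits(hybrid, "ase_table"))
  auto <- hybrid$gene_flags$gene_id[hybrid$gene_flags$is_autosomal]
  scopes <- .scopes(hybrid$meta)
  calls <- list()
  for (s in seq_len(nrow(scopes))) {
    sc <- scopes[s, ]
    pmeta <- parental$meta
    psel <- pmeta$sex == sc$sex & pmeta$tissue == sc$tissue &
      pmeta$cross_id == sc$cross_id
    if (!any(psel)) next
    pmeta <- pmeta[psel, , drop = FALSE]
    design_all <- build_design(hybrid, sex = sc$sex, tissue = sc$tissue,
                               cross = sc$cross_id)
    directions <- if (pool_reciprocals) list(c("AxB", "BxA")) else
      as.list(unique(hybrid$meta$direction[match(design_all$sample_id,
                                                 hybrid$meta$sample_id)]))
    for (dirs in directions) {
      dsel <- hybrid$meta$direction[match(design_all$sample_id,
                                          hybrid$meta$sample_id)] %in% dirs
      design <- design_all[dsel, , drop = FALSE]
      if (!nrow(design)) next
      idx <- match(design$obs_id, colnames(hybrid$counts))

      Pc <- parental$counts[, pmeta$sample_id, drop = FALSE]
      P1 <- rowSums(Pc[, pmeta$line == "A", drop = FALSE])
      P2 <- rowSums(Pc[, pmeta$line == "B", drop = FALSE])
      genes <- intersect(auto, filter_parental_reads(P1, P2, cfg))
      if (!length(genes)) next

      Hc <- hybrid$counts[genes, idx, drop = FALSE]
      A1 <- rowSums(Hc[, design$allele == "A", drop = FALSE])
      A2 <- rowSums(Hc[, design$allele == "B", drop = FALSE])

      pP <- test_parental_de(Pc[genes, , drop = FALSE], pmeta$line,
                             pmeta$library_size, cfg)$p
      pH <- test_hybrid_imbalance(Hc, design, cfg)$p
      pT <- test_trans_fisher(P1[genes], P2[genes], A1, A2)

      fP <- bh_adjust(pP); fH <- bh_adjust(pH); fT <- bh_adjust(pT)
      pc <- cfg$pseudocount
      l2P <- log2((P1[genes] + pc) / (P2[genes] + pc))
      l2H <- log2((A1 + pc) / (A2 + pc))
      cat_f <- classify_regulatory(fP < cfg$alpha_fdr, fH < cfg$alpha_fdr,
                                   fT < cfg$alpha_fdr, l2P, l2H)
      calls[[length(calls) + 1]] <- data.frame(
        gene_id = genes, cross_id = sc$cross_id, sex = sc$sex,
        tissue = sc$tissue,
        reciprocals = paste(dirs, collapse = "+"),
        p_parental = pP, p_hybrid = pH, p_trans = pT,
        fdr_parental = fP, fdr_hybrid = fH, fdr_trans = fT,
        log2_P = l2P, log2_H = l2H, ratio = l2P / l2H,
        category = cat_f, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  key <- interaction(calls$cross_id, calls$sex, calls$tissue,
                     calls$reciprocals, drop = TRUE)
  props <- do.call(rbind, lapply(split(calls, key), function(d) {
    tab <- table(d$category) / nrow(d)
    data.frame(cross_id = d$cross_id[1], sex = d$sex[1], tissue = d$tissue[1],
               reciprocals = d$reciprocals[1],
               category = names(tab), proportion = as.numeric(tab),
               n_genes = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(props) <- NULL
  list(calls = calls, proportions = props)
}
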