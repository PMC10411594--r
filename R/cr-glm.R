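#' Test cis-regulatory, parent-of-origin and maternal-genotype effects
#'
#' Fits the per-gene allelic model `E ~ mu + CR + PO + MG` as a
#' negative-binomial GLM with log library-size offsets and tests each
#' effect by a likelihood-ratio test against the model dropping that
#' column, with the dispersion estimated once on the full model and held
#' fixed across the nested fits (so every deviance difference is
#' nonnegative). The deviance explained by CR is the deviance of the
#' PO + MG model minus the deviance of the full model.
#'
#' @param y nonnegative counts for one gene, aligned with `design`.
#' @param design data.frame from [build_design()] for a single
#'   sex x tissue x cross scope.
#' @param cfg an [analysis_config()].
#' @param common_disp optional common dispersion of the scope, the
#'   shrinkage target for the per-gene estimate (see
#'   [common_dispersion()]). When `cfg$common_dispersion_only` is set it is
#'   used directly.
#' @param gene_id identifier carried into the result.
#' @return A one-row data.frame: `gene_id`, `p_CR`, `p_PO`, `p_MG`,
#'   `deviance_explained_CR`, `coef_CR`, `dispersion`, `n_obs`,
#'   `half_count_adjusted`, `skipped_reason` (`NA` when analysed).
#'   Effects whose covariate is constant in the scope (e.g. a missing
#'   reciprocal direction) get `NA` p-values.
#' @export
test_cr_po_mg <- function(y, design, cfg = analysis_config(),
                          common_disp = NULL, gene_id = NA_character_) {
  out <- data.frame(gene_id = gene_id, p_CR = NA_real_, p_PO = NA_real_,
                    p_MG = NA_real_, deviance_explained_CR = NA_real_,
                    coef_CR = NA_real_, dispersion = NA_real_,
                    n_obs = length(y), half_count_adjusted = FALSE,
                    skipped_reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(y) < cfg$min_obs) {
    out$skipped_reason <- "insufficient design"
    return(out)
  }
  if (length(unique(design$CR)) < 2) {
    out$skipped_reason <- "single CR level"
    return(out)
  }
  if (all(y == 0)) {
    out$skipped_reason <- "all-zero counts"
    return(out)
  }
  if (.needs_half_count(y, design$CR)) {
    y <- y + 0.5
    out$half_count_adjusted <- TRUE
  }
  # covariates constant within the scope (e.g. one reciprocal missing)
  # cannot be estimated and are left out of the model
  cols <- c("CR", "PO", "MG")
  varying <- cols[vapply(cols, function(cl) length(unique(design[[cl]])) > 1,
                         logical(1))]
  X <- cbind(`(Intercept)` = 1, as.matrix(design[, varying, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    out$skipped_reason <- "rank-deficient design"
    return(out)
  }
  offset <- design$offset
  disp <- NULL
  if (!is.null(common_disp) && cfg$common_dispersion_only) {
    disp <- common_disp
  } else {
    disp <- estimate_dispersion(y, X, offset,
                                init = if (is.null(common_disp)) 0.1 else common_disp)
    if (is.na(disp)) {
      out$skipped_reason <- "dispersion estimation failed"
      return(out)
    }
    if (!is.null(common_disp)) {
      disp <- .shrink_dispersion(disp, common_disp,
                                 resid_df = length(y) - ncol(X),
                                 prior_df = cfg$prior_df)
    }
  }
  out$dispersion <- disp
  theta <- 1 / disp
  for (cl in varying) {
    X_red <- X[, setdiff(colnames(X), cl), drop = FALSE]
    lrt <- .nb_lrt(y, X, X_red, offset, theta)
    out[[paste0("p_", cl)]] <- lrt$p
    if (cl == "CR") {
      out$deviance_explained_CR <- lrt$stat
      out$coef_CR <- unname(lrt$coef_full["CR"])
    }
  }
  out
}

#' Per-scope CR/PO/MG analysis across all genes
#'
#' Runs [test_cr_po_mg()] for every autosomal gene passing the expression
#' filter, separately for each cross x sex x tissue scope present in the
#' table (the "12 models" framing when 3 crosses, 2 sexes and 2 tissues
#' are present), and applies Benjamini-Hochberg FDR per effect within each
#' scope.
#'
#' @param x an [ase_table()] of hybrid allele-specific counts.
#' @param obs_tpm matrix of TPM-like abundances with the same gene x
#'   observation layout as `x$counts`, used by the expression filter.
#' @param cfg an [analysis_config()].
#' @return A data.frame with one row per gene x scope: identifiers, raw
#'   p-values, FDRs (`fdr_CR`, `fdr_PO`, `fdr_MG`), deviance explained by
#'   CR, CR coefficient, dispersion, and skip annotations.
#' @export
run_cr_glm <- function(x, obs_tpm, cfg = analysis_config()) {
  stopifnot(inherits(x, "ase_table"))
  obs_tpm <- as.matrix(obs_tpm)
  scopes <- .scopes(x$meta)
  auto <- x$gene_flags$gene_id[x$gene_flags$is_autosomal]
  res <- vector("list", nrow(scopes))
  for (s in seq_len(nrow(scopes))) {
    sc <- scopes[s, ]
    design <- build_design(x, sex = sc$sex, tissue = sc$tissue,
                           cross = sc$cross_id)
    idx <- match(design$obs_id, colnames(x$counts))
    genes <- intersect(auto,
                       filter_expressed(obs_tpm[, idx, drop = FALSE], cfg))
    if (!length(genes)) next
    Y <- x$counts[genes, idx, drop = FALSE]
    X <- cbind(1, as.matrix(design[, c("CR", "PO", "MG")]))
    cd <- common_dispersion(Y, X, design$offset)
    rows <- lapply(genes, function(g) {
      test_cr_po_mg(Y[g, ], design, cfg, common_disp = cd, gene_id = g)
    })
    df <- do.call(rbind, rows)
    df$cross_id <- sc$cross_id
    df$sex <- sc$sex
    df$tissue <- sc$tissue
    df$common_dispersion <- cd
    for (eff in c("CR", "PO", "MG")) {
      df[[paste0("fdr_", eff)]] <- bh_adjust(df[[paste0("p_", eff)]])
    }
    res[[s]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
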