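#' Sex- or tissue-dependent cis effects: interaction model
#'
#' Fits `E ~ mu + CR + factor + CR*factor` on observations spanning both
#' levels of the factor (both sexes within one tissue, or both tissues
#' within one sex) and tests the interaction term by a likelihood-ratio
#' test against the additive `CR + factor` model. A significant
#' interaction captures sex (tissue) differences in cis effects of either
#' magnitude or direction.
#'
#' @param y nonnegative counts for one gene, aligned with `design`.
#' @param design data.frame from [build_design()] spanning both levels of
#'   the factor (up to 16 observations).
#' @param factor `"sex"` or `"tissue"`.
#' @param cfg an [analysis_config()].
#' @param common_disp optional common dispersion used as shrinkage target.
#' @param gene_id identifier carried into the result.
#' @return One-row data.frame: `gene_id`, `model`, `p`, `coef`,
#'   `dispersion`, `n_obs`, `skipped_reason`.
#' @export
test_interaction <- function(y, design, factor = c("sex", "tissue"),
                             cfg = analysis_config(), common_disp = NULL,
                             gene_id = NA_character_) {
  factor <- match.arg(factor)
  fac <- design[[paste0(factor, "_code")]]
  .fit_two_level_model(y, design, fac, cfg, common_disp, gene_id,
                       model = paste0(factor, "_interaction"),
                       build = function(CR, fac) {
                         list(full = cbind(1, CR = CR, fac = fac,
                                           CRxfac = CR * fac),
                              red = cbind(1, CR = CR, fac = fac),
                              term = "CRxfac")
                       })
}

#' Sex- or tissue-dependent cis effects: reversal model
#'
#' Fits `E ~ mu + CRsex` where `CRsex` recodes the allele indicator to be
#' contrary in the two factor levels (allele B is 1 in females and 0 in
#' males; analogously for tissues), and tests it against the
#' intercept-only model. Significance indicates opposite-direction allelic
#' usage in the two levels, i.e. reversal, rather than a mere difference
#' in magnitude.
#'
#' @inheritParams test_interaction
#' @return One-row data.frame as for [test_interaction()], with `model`
#'   `"sex_reversal"` or `"tissue_reversal"`.
#' @export
test_reversal <- function(y, design, factor = c("sex", "tissue"),
                          cfg = analysis_config(), common_disp = NULL,
                          gene_id = NA_character_) {
  factor <- match.arg(factor)
  fac <- design[[paste0(factor, "_code")]]
  .fit_two_level_model(y, design, fac, cfg, common_disp, gene_id,
                       model = paste0(factor, "_reversal"),
                       build = function(CR, fac) {
                         CRrev <- ifelse(fac == 0, CR, 1 - CR)
                         list(full = cbind(1, CRrev = CRrev),
                              red = matrix(1, length(CR), 1),
                              term = "CRrev")
                       })
}

.fit_two_level_model <- function(y, design, fac, cfg, common_disp, gene_id,
                                 model, build) {
  out <- data.frame(gene_id = gene_id, model = model, p = NA_real_,
                    coef = NA_real_, dispersion = NA_real_,
                    n_obs = length(y), half_count_adjusted = FALSE,
                    skipped_reason = NA_character_, stringsAsFactors = FALSE)
  both_levels <- length(unique(fac)) == 2 &&
    all(vapply(split(design$CR, fac),
               function(cr) length(unique(cr)) == 2, logical(1)))
  if (!both_levels) {
    out$skipped_reason <- "factor level missing"
    return(out)
  }
  if (length(y) < cfg$min_obs) {
    out$skipped_reason <- "insufficient design"
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
  M <- build(design$CR, fac)
  if (qr(M$full)$rank < ncol(M$full)) {
    out$skipped_reason <- "rank-deficient design"
    return(out)
  }
  offset <- design$offset
  if (!is.null(common_disp) && cfg$common_dispersion_only) {
    disp <- common_disp
  } else {
    disp <- estimate_dispersion(y, M$full, offset,
                                init = if (is.null(common_disp)) 0.1 else common_disp)
    if (is.na(disp)) {
      out$skipped_reason <- "dispersion estimation failed"
      return(out)
    }
    if (!is.null(common_disp)) {
      disp <- .shrink_dispersion(disp, common_disp,
                                 resid_df = length(y) - ncol(M$full),
                                 prior_df = cfg$prior_df)
    }
  }
  out$dispersion <- disp
  lrt <- .nb_lrt(y, M$full, M$red, offset, 1 / disp)
  out$p <- lrt$p
  out$coef <- unname(lrt$coef_full[M$term])
  out
}

#' Interaction and reversal models across all genes and scopes
#'
#' For `factor = "sex"` each scope is one cross x tissue spanning both
#' sexes; for `factor = "tissue"` one cross x sex spanning both tissues.
#' Genes must pass the expression filter in each half-scope separately.
#' Both the interaction and the reversal model are fitted; FDR is applied
#' per model type within each scope.
#'
#' @param x an [ase_table()] of hybrid allele-specific counts.
#' @param obs_tpm TPM-like matrix matching `x$counts` (see [run_cr_glm()]).
#' @param factor `"sex"` or `"tissue"`.
#' @param cfg an [analysis_config()].
#' @return A data.frame with one row per gene x scope x model: `gene_id`,
#'   `cross_id`, the fixed factor level, `model`, `p`, `fdr`, `coef`, skip
#'   annotations.
#' @export
run_interactions <- function(x, obs_tpm, factor = c("sex", "tissue"),
                             cfg = analysis_config()) {
  stopifnot(inherits(x, "ase_table"))
  factor <- match.arg(factor)
  obs_tpm <- as.matrix(obs_tpm)
  auto <- x$gene_flags$gene_id[x$gene_flags$is_autosomal]
  within <- if (factor == "sex") "tissue" else "sex"
  halves <- if (factor == "sex") c("F", "M") else c("head", "gonad")
  combos <- unique(x$meta[, c("cross_id", within)])
  res <- list()
  for (k in seq_len(nrow(combos))) {
    cross <- combos$cross_id[k]
    fixed <- combos[[within]][k]
    sex <- if (factor == "sex") c("F", "M") else fixed
    tissue <- if (factor == "sex") fixed else c("head", "gonad")
    design <- tryCatch(build_design(x, sex = sex, tissue = tissue, cross = cross),
                       error = function(e) NULL)
    if (is.null(design)) next
    fac <- design[[paste0(factor, "_code")]]
    if (length(unique(fac)) < 2) next
    idx <- match(design$obs_id, colnames(x$counts))
    # expression filter applied in each factor level separately
    keep <- auto
    for (lv in unique(fac)) {
      cols <- idx[fac == lv]
      keep <- intersect(keep,
                        filter_expressed(obs_tpm[, cols, drop = FALSE], cfg))
    }
    if (!length(keep)) next
    Y <- x$counts[keep, idx, drop = FALSE]
    Xd <- cbind(1, CR = design$CR, fac = fac, CRxfac = design$CR * fac)
    cd <- common_dispersion(Y, Xd, design$offset)
    for (fun in list(test_interaction, test_reversal)) {
      rows <- lapply(keep, function(g) {
        fun(Y[g, ], design, factor = factor, cfg = cfg,
            common_disp = cd, gene_id = g)
      })
      df <- do.call(rbind, rows)
      df$cross_id <- cross
      df[[within]] <- fixed
      df$fdr <- bh_adjust(df$p)
      res[[length(res) + 1]] <- df
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
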