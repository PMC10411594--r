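#' Build the binary design for a model scope
#'
#' Translates the experimental design of a set of allele-level observations
#' into the binary covariates of the allelic negative-binomial models:
#' `CR` is 0 for allele A and 1 for allele B; `PO` is 0 for a maternally
#' and 1 for a paternally inherited copy; `MG` is 0 for samples from the
#' AxB cross direction and 1 for BxA. `sex_code` (F = 0, M = 1) and
#' `tissue_code` (head = 0, gonad = 1) support the interaction models. The
#' offset is the natural log of the sample library size and is shared by
#' the two allele rows of a sample.
#'
#' The base model scope is one sex x one tissue x one cross, both
#' reciprocal directions and all replicates: 8 observations when no sample
#' is missing. Vectors may be passed (e.g. both sexes) for the
#' interaction/reversal scopes.
#'
#' @param x an [ase_table()].
#' @param sex,tissue,cross values selecting samples; `cross = NULL` keeps
#'   all crosses (use with single-cross tables).
#' @return A data.frame with one row per (sample, allele) observation:
#'   `obs_id`, `sample_id`, `allele`, `CR`, `PO`, `MG`, `sex_code`,
#'   `tissue_code`, `offset`.
#' @export
build_design <- function(x, sex, tissue, cross = NULL) {
  stopifnot(inherits(x, "ase_table"))
  meta <- x$meta
  keep <- meta$sex %in% sex & meta$tissue %in% tissue
  if (!is.null(cross)) keep <- keep & meta$cross_id %in% cross
  meta <- meta[keep, , drop = FALSE]
  obs <- x$obs[x$obs$sample_id %in% meta$sample_id, , drop = FALSE]
  if (nrow(obs) < 4 ||
      (length(unique(meta$direction)) < 2 && length(unique(meta$replicate)) < 2)) {
    stop("insufficient design: scope needs at least two samples spanning ",
         "replicates or reciprocal directions (4+ observations)")
  }
  i <- match(obs$sample_id, meta$sample_id)
  data.frame(obs_id = obs$obs_id,
             sample_id = obs$sample_id,
             allele = obs$allele,
             CR = as.integer(obs$allele == "B"),
             PO = as.integer(obs$parent_of_origin == "paternal"),
             MG = as.integer(meta$direction[i] == "BxA"),
             sex_code = as.integer(meta$sex[i] == "M"),
             tissue_code = as.integer(meta$tissue[i] == "gonad"),
             offset = log(meta$library_size[i]),
             stringsAsFactors = FALSE)
}

#' Expression filter for a model scope
#'
#' Keeps genes whose abundance exceeds a threshold (strictly) in at least a
#' minimum number of the scope's observations; with the defaults, TPM > 1
#' in at least 4 of the 8 allele-level observations.
#'
#' @param tpm numeric matrix of TPM-like abundances, genes x observations,
#'   restricted to the scope's observation columns.
#' @param cfg an [analysis_config()].
#' @return Character vector of retained gene ids (possibly empty). The
#'   operation is idempotent: filtering an already-filtered matrix changes
#'   nothing.
#' @export
filter_expressed <- function(tpm, cfg = analysis_config()) {
  tpm <- as.matrix(tpm)
  n_over <- rowSums(tpm > cfg$tpm_filter_threshold)
  rownames(tpm)[n_over >= cfg$tpm_filter_min_samples]
}

#' Parental read-sum filter
#'
#' Keeps genes whose estimated reads summed over the replicates of the two
#' parental lines reach `parental_min_reads` (default: at least 20).
#'
#' @param sum_line1,sum_line2 named numeric vectors of per-gene counts
#'   summed over each line's replicates.
#' @param cfg an [analysis_config()].
#' @return Character vector of retained gene ids.
#' @export
filter_parental_reads <- function(sum_line1, sum_line2, cfg = analysis_config()) {
  stopifnot(length(sum_line1) == length(sum_line2))
  genes <- names(sum_line1)
  if (is.null(genes)) stop("parental sums must be named by gene")
  genes[(sum_line1 + sum_line2) >= cfg$parental_min_reads]
}

# scope iteration helper: unique cross x sex x tissue combinations present
.scopes <- function(meta, sexes = NULL, tissues = NULL) {
  sc <- unique(meta[, c("cross_id", "sex", "tissue")])
  if (!is.null(sexes)) sc <- sc[sc$sex %in% sexes, ]
  if (!is.null(tissues)) sc <- sc[sc$tissue %in% tissues, ]
  sc <- sc[order(sc$cross_id, sc$sex, sc$tissue), , drop = FALSE]
  rownames(sc) <- NULL
  sc
}
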