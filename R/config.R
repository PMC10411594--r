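#' Analysis configuration
#'
#' Thresholds and conventions shared across the pipeline stages. Defaults
#' follow the study design this package models: a Benjamini-Hochberg FDR of
#' 0.05 for every significance call, the `TPM > 1 in at least 4 of 8
#' observations` expression filter, a minimum of 20 summed parental reads
#' for the cis/trans and inheritance stages, a 1.5-fold parental difference
#' for inheritance eligibility, the 1.25-fold hybrid-vs-parent cutoff, and
#' sex-bias bin boundaries at -1, -0.3, 0.3 and 1 on the log2 scale.
#'
#' @param alpha_fdr FDR threshold for significance calls, in (0, 1).
#' @param tpm_filter_threshold,tpm_filter_min_samples a gene is analysed in
#'   a scope when its TPM exceeds `tpm_filter_threshold` (strictly) in at
#'   least `tpm_filter_min_samples` of the scope's observations.
#' @param parental_min_reads minimum summed estimated reads across the two
#'   parental lines.
#' @param parental_fold_min minimum parental fold difference for a gene to
#'   be eligible for inheritance classification.
#' @param hybrid_fold_cutoff fold cutoff separating "similar to" from
#'   "different from" a parent in the inheritance rules (inclusive).
#' @param sb_bounds strictly increasing log2 sex-bias bin boundaries
#'   separating MS / MB / UB / FB / FS.
#' @param tpm_floor TPM values are floored at this value before fold
#'   computations, avoiding division by zero.
#' @param pseudocount added to each summed count before log-ratio
#'   computation in the cis/trans stage (never fed to Fisher's test).
#' @param prior_df prior degrees of freedom for shrinking per-gene
#'   dispersions toward the common dispersion (empirical-Bayes weight).
#' @param common_dispersion_only if `TRUE`, skip per-gene dispersion
#'   estimation and use the common value for every gene.
#' @param min_obs minimum number of observations for a per-gene model fit.
#' @param seed integer seed recorded in run manifests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_fdr = 0.05,
                            tpm_filter_threshold = 1,
                            tpm_filter_min_samples = 4,
                            parental_min_reads = 20,
                            parental_fold_min = 1.5,
                            hybrid_fold_cutoff = 1.25,
                            sb_bounds = c(-1, -0.3, 0.3, 1),
                            tpm_floor = 0.01,
                            pseudocount = 0.5,
                            prior_df = 20,
                            common_dispersion_only = FALSE,
                            min_obs = 6,
                            seed = 1L) {
  cfg <- list(alpha_fdr = alpha_fdr,
              tpm_filter_threshold = tpm_filter_threshold,
              tpm_filter_min_samples = as.integer(tpm_filter_min_samples),
              parental_min_reads = parental_min_reads,
              parental_fold_min = parental_fold_min,
              hybrid_fold_cutoff = hybrid_fold_cutoff,
              sb_bounds = sb_bounds,
              tpm_floor = tpm_floor,
              pseudocount = pseudocount,
              prior_df = prior_df,
              common_dispersion_only = isTRUE(common_dispersion_only),
              min_obs = as.integer(min_obs),
              seed = as.integer(seed))
  if (!(cfg$alpha_fdr > 0 && cfg$alpha_fdr < 1)) stop("alpha_fdr must be in (0, 1)")
  pos <- c("tpm_filter_threshold", "parental_min_reads", "parental_fold_min",
           "hybrid_fold_cutoff", "tpm_floor", "prior_df")
  for (nm in pos) if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (cfg$hybrid_fold_cutoff <= 1) stop("hybrid_fold_cutoff must exceed 1")
  if (is.unsorted(cfg$sb_bounds, strictly = TRUE))
    stop("sb_bounds must be strictly increasing")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Keys present in the file override [analysis_config()] defaults; unknown
#' keys are an error.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed, package version and per-stage filter
#' summary of a pipeline run so that outputs are reproducible.
#'
#' @param path output JSON path.
#' @param cfg an [analysis_config()].
#' @param stage name of the pipeline stage.
#' @param filters named list of filter summaries (e.g. genes retained).
#' @param extra further named entries to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, cfg, stage, filters = list(), extra = list()) {
  manifest <- c(list(stage = stage,
                     package = "asereg",
                     version = as.character(utils::packageVersion("asereg")),
                     r_version = as.character(getRversion()),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     seed = cfg$seed,
                     config = unclass(cfg),
                     filters = filters),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
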