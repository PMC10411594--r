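#' Classify the mode of inheritance of hybrid expression
#'
#' Compares hybrid overall expression with the two parents using a fold
#' cutoff (default 1.25): a gene is eligible when its parents differ by at
#' least `parental_fold_min` (default 1.5-fold); among eligible genes the
#' hybrid is
#' \describe{
#'   \item{overdominant}{at least 1.25-fold above the higher parent;}
#'   \item{underdominant}{at least 1.25-fold below the lower parent;}
#'   \item{additive}{at least 1.25-fold above the lower parent and at
#'     least 1.25-fold below the higher parent (between the parents);}
#'   \item{dominant}{within 1.25-fold of exactly one parent;}
#'   \item{conserved}{within 1.25-fold of both parents.}
#' }
#' All fold comparisons are inclusive; boundary cases are resolved in the
#' order above (over/under, then additive, then dominant), so the rule is
#' total and mutually exclusive. TPM values are floored at `tpm_floor`
#' before fold computation.
#'
#' @param p1,p2 per-gene parental TPM (lines A and B), averaged across
#'   replicates; nonnegative.
#' @param h per-gene hybrid TPM averaged across reciprocals/replicates.
#' @param cfg an [analysis_config()].
#' @param eligible_reads optional logical vector from the parental
#'   read-sum filter; genes failing it are `ineligible`.
#' @return data.frame `mode` (factor: additive, dominant, overdominant,
#'   underdominant, conserved, ineligible), `eligible`,
#'   `which_parent_matched` (`P1`/`P2` for dominant genes, else `NA`).
#' @export
classify_inheritance <- function(p1, p2, h, cfg = analysis_config(),
                                 eligible_reads = TRUE) {
  n <- length(h)
  stopifnot(length(p1) == n, length(p2) == n)
  if (any(c(p1, p2, h) < 0)) stop("expression values must be nonnegative")
  fl <- cfg$tpm_floor
  p1f <- pmax(p1, fl); p2f <- pmax(p2, fl); hf <- pmax(h, fl)
  lo <- pmin(p1f, p2f); hi <- pmax(p1f, p2f)
  fc <- cfg$hybrid_fold_cutoff
  eligible <- (hi / lo >= cfg$parental_fold_min) & rep(eligible_reads, length.out = n)

  near1 <- hf >= p1f / fc & hf <= p1f * fc
  near2 <- hf >= p2f / fc & hf <= p2f * fc
  mode <- rep("conserved", n)
  mode[xor(near1, near2)] <- "dominant"
  mode[hf >= lo * fc & hf <= hi / fc] <- "additive"
  mode[hf <= lo / fc] <- "underdominant"
  mode[hf >= hi * fc] <- "overdominant"
  mode[!eligible] <- "ineligible"

  which_parent <- rep(NA_character_, n)
  dom <- mode == "dominant"
  which_parent[dom & near1] <- "P1"
  which_parent[dom & near2] <- "P2"
  data.frame(mode = factor(mode, levels = c("additive", "dominant",
                                            "overdominant", "underdominant",
                                            "conserved", "ineligible")),
             eligible = eligible,
             which_parent_matched = which_parent,
             stringsAsFactors = FALSE)
}

#' Inheritance classification across scopes
#'
#' For each sex x tissue x cross scope: averages parental TPM across each
#' line's replicates and hybrid TPM across reciprocals and replicates,
#' applies the parental read-sum and 1.5-fold eligibility filters, and
#' classifies every gene with [classify_inheritance()]. Proportions are
#' reported over eligible genes.
#'
#' @param parental_tpm an [expression_table()] with role
#'   `parental_overall`; its `meta` must carry `line`, `cross_id`, `sex`,
#'   `tissue`.
#' @param hybrid_tpm an [expression_table()] with role `hybrid_overall`;
#'   its `meta` must carry `cross_id`, `sex`, `tissue`, `direction`.
#' @param parental_counts a [parental_table()] supplying the read-sum
#'   filter.
#' @param cfg an [analysis_config()].
#' @return list with `calls` (per gene x scope) and `proportions` (per
#'   scope mode fractions over eligible genes, summing to 1).
#' @export
run_inheritance <- function(parental_tpm, hybrid_tpm, parental_counts,
                            cfg = analysis_config()) {
  stopifnot(inherits(parental_tpm, "expression_table"),
            inherits(hybrid_tpm, "expression_table"),
            inherits(parental_counts, "parental_table"))
  pm <- parental_tpm$meta
  hm <- hybrid_tpm$meta
  if (is.null(pm) || is.null(hm)) stop("expression tables need sample metadata")
  genes <- rownames(hybrid_tpm$values)
  scopes <- .scopes(hm)
  calls <- list()
  for (s in seq_len(nrow(scopes))) {
    sc <- scopes[s, ]
    ps <- pm$sex == sc$sex & pm$tissue == sc$tissue & pm$cross_id == sc$cross_id
    hs <- hm$sex == sc$sex & hm$tissue == sc$tissue & hm$cross_id == sc$cross_id
    if (!any(ps) || !any(hs)) next
    p1 <- rowMeans(parental_tpm$values[genes, pm$sample_id[ps & pm$line == "A"],
                                       drop = FALSE])
    p2 <- rowMeans(parental_tpm$values[genes, pm$sample_id[ps & pm$line == "B"],
                                       drop = FALSE])
    h <- rowMeans(hybrid_tpm$values[genes, hm$sample_id[hs], drop = FALSE])

    cm <- parental_counts$meta
    cs <- cm$sex == sc$sex & cm$tissue == sc$tissue & cm$cross_id == sc$cross_id
    s1 <- rowSums(parental_counts$counts[genes, cm$sample_id[cs & cm$line == "A"],
                                         drop = FALSE])
    s2 <- rowSums(parental_counts$counts[genes, cm$sample_id[cs & cm$line == "B"],
                                         drop = FALSE])
    ok_reads <- genes %in% filter_parental_reads(s1, s2, cfg)

    cl <- classify_inheritance(p1, p2, h, cfg, eligible_reads = ok_reads)
    cl <- cbind(data.frame(gene_id = genes, cross_id = sc$cross_id,
                           sex = sc$sex, tissue = sc$tissue,
                           p1 = p1, p2 = p2, h = h,
                           stringsAsFactors = FALSE), cl)
    calls[[length(calls) + 1]] <- cl
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  key <- interaction(calls$cross_id, calls$sex, calls$tissue, drop = TRUE)
  props <- do.call(rbind, lapply(split(calls, key), function(d) {
    d <- d[d$eligible, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    tab <- table(droplevels(d$mode, exclude = "ineligible")) / nrow(d)
    data.frame(cross_id = d$cross_id[1], sex = d$sex[1], tissue = d$tissue[1],
               mode = names(tab), proportion = as.numeric(tab),
               n_eligible = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(props) <- NULL
  list(calls = calls, proportions = props)
}
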