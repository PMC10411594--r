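#' Simulation configuration
#'
#' Defines the generative conditions for synthetic allele-specific data:
#' one cross between lines A and B, both reciprocal hybrid directions, two
#' sexes, two tissues and `n_replicates` replicate libraries — the
#' reciprocal-cross design the analysis models expect. Genes are
#' apportioned exactly (largest remainder, not sampled) among regulatory
#' effect classes; the remainder after the listed classes is null.
#'
#' Default effect-class proportions put 10% of genes under pure cis
#' regulation and smaller fractions under trans, joint, compensatory,
#' parent-of-origin, maternal-genotype and sex-reversed regulation.
#' Dispersions are drawn log-normal with median 0.005 (biological
#' coefficient of variation ~7%), reflecting replicate libraries prepared
#' from pools of many individuals of an isogenic line; `depth = NULL`
#' leaves expected totals at the sum of per-gene means.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicate libraries per direction/sex/tissue.
#' @param depth expected library size; `NULL` (default) keeps the
#'   per-gene base means unscaled.
#' @param class_props named proportions for classes `cis_only`,
#'   `trans_only`, `cis_plus_trans`, `cis_by_trans`, `compensatory`,
#'   `po`, `mg`, `sex_reversed`, `tissue_reversed`; must sum to <= 1.
#' @param effect_mean,effect_sd mean and SD of |log2 fold change| draws.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   per-gene base mean (expected count at reference conditions).
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   per-gene NB dispersion (variance = mu + dispersion * mu^2).
#' @param sb_sd SD of the true sex-bias log2 ratio.
#' @param inheritance_props named proportions over inheritance modes
#'   (`additive`, `dominant_p1`, `dominant_p2`, `overdominant`,
#'   `underdominant`; remainder `conserved`), apportioned exactly and
#'   assigned independently of the regulatory class.
#' @param cross_id cross identifier written into sample metadata.
#' @param seed integer seed; `simulate_truth()` uses `seed` and
#'   [simulate_counts()] uses `seed + 1`, so truth and counts are each
#'   reproducible on their own.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_replicates = 2L,
                       depth = NULL,
                       class_props = c(cis_only = 0.10, trans_only = 0.05,
                                       cis_plus_trans = 0.03,
                                       cis_by_trans = 0.02,
                                       compensatory = 0.03,
                                       po = 0.01, mg = 0.01,
                                       sex_reversed = 0.05,
                                       tissue_reversed = 0),
                       effect_mean = 1, effect_sd = 0.25,
                       base_mean_meanlog = log(200), base_mean_sdlog = 1,
                       dispersion_meanlog = log(0.005),
                       dispersion_sdlog = 0.5,
                       sb_sd = 1,
                       inheritance_props = c(additive = 0.25,
                                             dominant_p1 = 0.22,
                                             dominant_p2 = 0.22,
                                             overdominant = 0.05,
                                             underdominant = 0.05),
                       cross_id = "cross1",
                       seed = 1L) {
  known <- c("cis_only", "trans_only", "cis_plus_trans", "cis_by_trans",
             "compensatory", "po", "mg", "sex_reversed", "tissue_reversed")
  full <- stats::setNames(rep(0, length(known)), known)
  bad <- setdiff(names(class_props), known)
  if (length(bad)) stop("unknown effect class(es): ", paste(bad, collapse = ", "))
  full[names(class_props)] <- class_props
  if (any(full < 0) || sum(full) > 1 + 1e-12)
    stop("class proportions must be nonnegative and sum to at most 1")
  imodes <- c("additive", "dominant_p1", "dominant_p2", "overdominant",
              "underdominant")
  ifull <- stats::setNames(rep(0, length(imodes)), imodes)
  bad <- setdiff(names(inheritance_props), imodes)
  if (length(bad)) stop("unknown inheritance mode(s): ", paste(bad, collapse = ", "))
  ifull[names(inheritance_props)] <- inheritance_props
  if (any(ifull < 0) || sum(ifull) > 1 + 1e-12)
    stop("inheritance proportions must be nonnegative and sum to at most 1")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 depth = depth,
                 class_props = full,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 dispersion_meanlog = dispersion_meanlog,
                 dispersion_sdlog = dispersion_sdlog,
                 sb_sd = sb_sd,
                 inheritance_props = ifull,
                 cross_id = cross_id,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder apportionment: exact class counts, no sampling
.allocate <- function(n, props) {
  target <- props * n
  counts <- floor(target)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- target - counts
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Per-gene simulation ground truth
#'
#' Light constructor/validator for the truth table the generator produces;
#' useful for building bespoke truths (e.g. a block of genes with an
#' exactly specified cis effect) that [simulate_counts()] can consume.
#'
#' @param gene_id gene identifiers.
#' @param base_mean positive expected counts at reference conditions.
#' @param dispersion positive NB dispersions.
#' @param cis_F_head,cis_F_gonad,cis_M_head,cis_M_gonad cis log2 fold
#'   changes (allele B vs A) per sex x tissue.
#' @param trans,po,mg trans (line 2 vs line 1 background),
#'   parent-of-origin (paternal vs maternal) and maternal-genotype (BxA vs
#'   AxB) log2 fold changes.
#' @param sb_true true sex-bias log2 ratio (female vs male).
#' @param class effect-class label.
#' @param inheritance_mode inheritance mode label.
#' @return data.frame of class `gene_truth`.
#' @export
gene_truth <- function(gene_id, base_mean, dispersion,
                       cis_F_head = 0, cis_F_gonad = 0,
                       cis_M_head = 0, cis_M_gonad = 0,
                       trans = 0, po = 0, mg = 0, sb_true = 0,
                       class = "custom", inheritance_mode = "conserved") {
  df <- data.frame(gene_id = as.character(gene_id),
                   class = class, base_mean = base_mean,
                   dispersion = dispersion,
                   cis_F_head = cis_F_head, cis_F_gonad = cis_F_gonad,
                   cis_M_head = cis_M_head, cis_M_gonad = cis_M_gonad,
                   trans = trans, po = po, mg = mg, sb_true = sb_true,
                   inheritance_mode = inheritance_mode,
                   stringsAsFactors = FALSE)
  if (any(df$base_mean <= 0)) stop("base_mean must be positive")
  if (any(df$dispersion <= 0)) stop("dispersion must be positive")
  if (anyDuplicated(df$gene_id)) stop("gene_id must be unique")
  class(df) <- c("gene_truth", "data.frame")
  df
}

#' Draw the simulation ground truth
#'
#' Deterministic given the seed. Effect classes are apportioned exactly
#' and assigned to genes in order; inheritance modes are apportioned
#' exactly and assigned via a seeded permutation so the two labelings are
#' unlinked. Class semantics: `cis_only` genes have a nonzero cis effect
#' and zero trans; `compensatory` genes have `trans = -cis`;
#' `cis_plus_trans` same-sign cis and trans; `cis_by_trans` opposite-sign;
#' `sex_reversed` genes have `cis_F = -cis_M`; `tissue_reversed` genes
#' have opposite cis effects in head and gonad.
#'
#' @param cfg a [sim_config()].
#' @return A [gene_truth()] data.frame with `cfg$n_genes` rows.
#' @export
simulate_truth <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  props <- c(cfg$class_props, null = 1 - sum(cfg$class_props))
  counts <- .allocate(n, props)
  class <- rep(names(props), counts)

  base_mean <- stats::rlnorm(n, cfg$base_mean_meanlog, cfg$base_mean_sdlog)
  dispersion <- stats::rlnorm(n, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  sb_true <- stats::rnorm(n, 0, cfg$sb_sd)
  m1 <- abs(stats::rnorm(n, cfg$effect_mean, cfg$effect_sd))
  m2 <- abs(stats::rnorm(n, cfg$effect_mean, cfg$effect_sd))
  sign1 <- sample(c(-1, 1), n, replace = TRUE)

  cis <- numeric(n); trans <- numeric(n); po <- numeric(n); mg <- numeric(n)
  cis[class == "cis_only"] <- (sign1 * m1)[class == "cis_only"]
  trans[class == "trans_only"] <- (sign1 * m1)[class == "trans_only"]
  i <- class == "cis_plus_trans"
  cis[i] <- (sign1 * m1)[i]; trans[i] <- (sign1 * m2)[i]
  i <- class == "cis_by_trans"
  cis[i] <- (sign1 * m1)[i]; trans[i] <- (-sign1 * m2)[i]
  i <- class == "compensatory"
  cis[i] <- (sign1 * m1)[i]; trans[i] <- -cis[i]
  po[class == "po"] <- (sign1 * m1)[class == "po"]
  mg[class == "mg"] <- (sign1 * m1)[class == "mg"]

  cis_F <- cis; cis_M <- cis
  i <- class == "sex_reversed"
  cis_F[i] <- (sign1 * m1)[i]; cis_M[i] <- -cis_F[i]
  cis_F_head <- cis_F; cis_F_gonad <- cis_F
  cis_M_head <- cis_M; cis_M_gonad <- cis_M
  i <- class == "tissue_reversed"
  cis_F_head[i] <- (sign1 * m1)[i]; cis_F_gonad[i] <- -cis_F_head[i]
  cis_M_head[i] <- cis_F_head[i]; cis_M_gonad[i] <- -cis_F_head[i]

  # conserved inheritance is only meaningful for genes whose parents are
  # similar (a hybrid at the midpoint of divergent parents is additive by
  # definition), so conserved slots go preferentially to genes with a
  # parental fold below 1.2; all other modes are permuted over the rest
  imodes <- c(cfg$inheritance_props,
              conserved = 1 - sum(cfg$inheritance_props))
  icounts <- .allocate(n, imodes)
  max_div <- pmax(abs(cis_F_head + trans), abs(cis_F_gonad + trans),
                  abs(cis_M_head + trans), abs(cis_M_gonad + trans))
  shuffle <- function(x) x[sample.int(length(x))]
  similar <- shuffle(which(max_div < log2(1.2)))
  divergent <- shuffle(setdiff(seq_len(n), similar))
  n_cons <- icounts[length(icounts)]
  cons_idx <- c(similar, divergent)[seq_len(n_cons)]
  rest_idx <- shuffle(setdiff(seq_len(n), cons_idx))
  inheritance <- character(n)
  inheritance[cons_idx] <- "conserved"
  inheritance[rest_idx] <- rep(names(imodes)[-length(imodes)],
                               icounts[-length(icounts)])

  gene_truth(gene_id = sprintf("g%05d", seq_len(n)),
             base_mean = base_mean, dispersion = dispersion,
             cis_F_head = cis_F_head, cis_F_gonad = cis_F_gonad,
             cis_M_head = cis_M_head, cis_M_gonad = cis_M_gonad,
             trans = trans, po = po, mg = mg, sb_true = sb_true,
             class = class, inheritance_mode = inheritance)
}

#' Closed-form expected allele means
#'
#' The generative model evaluated without noise. With `b` the base mean,
#' `s` the sex multiplier `2^(+/- sb/2)` (plus for females), `c` the cis
#' and `t` the trans log2 effect for the sample's sex and tissue:
#' parental line A samples have mean `b*s`, line B samples
#' `b*s*2^(c + t)`; hybrid alleles share `b*s*2^(t/2)*2^(mg*[BxA])` and
#' allele B is further multiplied by `2^c`, with the paternal copy (B in
#' AxB, A in BxA) multiplied by `2^po`. The hybrid trans environment is
#' the geometric midpoint of the two parental backgrounds, so trans-only
#' genes diverge between parents but stay allelically balanced in hybrids.
#'
#' @param truth a [gene_truth()] data.frame.
#' @param sex `"F"` or `"M"`.
#' @param tissue `"head"` or `"gonad"`.
#' @param role `"parent"` or `"hybrid"`.
#' @param direction `"AxB"` or `"BxA"` (hybrids only).
#' @return matrix with columns `A` and `B`: for parents, the expected
#'   overall means of line A and line B samples; for hybrids, the expected
#'   allele A and allele B means within one sample.
#' @export
expected_means <- function(truth, sex, tissue, role = c("hybrid", "parent"),
                           direction = NULL) {
  role <- match.arg(role)
  if (!sex %in% c("F", "M")) stop("unknown sex: ", sex)
  if (!tissue %in% c("head", "gonad")) stop("unknown tissue: ", tissue)
  cis <- truth[[paste0("cis_", sex, "_", tissue)]]
  sexmult <- 2^(ifelse(sex == "F", 0.5, -0.5) * truth$sb_true)
  b <- truth$base_mean * sexmult
  if (role == "parent") {
    out <- cbind(A = b, B = b * 2^(cis + truth$trans))
  } else {
    if (is.null(direction) || !direction %in% c("AxB", "BxA"))
      stop("hybrid means need direction AxB or BxA")
    common <- b * 2^(truth$trans / 2) * 2^(truth$mg * (direction == "BxA"))
    poA <- 2^(truth$po * (direction == "BxA"))  # allele A paternal in BxA
    poB <- 2^(truth$po * (direction == "AxB"))
    out <- cbind(A = common * poA, B = common * 2^cis * poB)
  }
  rownames(out) <- truth$gene_id
  out
}

# expected hybrid overall mean under the gene's inheritance mode, given
# the parental means of the same sex/tissue
.inheritance_mean <- function(mode, pA, pB) {
  lo <- pmin(pA, pB); hi <- pmax(pA, pB)
  out <- (pA + pB) / 2                      # additive and conserved
  out[mode == "dominant_p1"] <- pA[mode == "dominant_p1"]
  out[mode == "dominant_p2"] <- pB[mode == "dominant_p2"]
  out[mode == "overdominant"] <- 1.5 * hi[mode == "overdominant"]
  out[mode == "underdominant"] <- (lo / 1.5)[mode == "underdominant"]
  out
}

#' Simulate count and expression tables from a ground truth
#'
#' Draws negative-binomial counts around [expected_means()] for every
#' hybrid observation and parental sample, and builds the TPM-like tables
#' the downstream stages consume. Hybrid overall expression is generated
#' from the gene's inheritance mode (midpoint of the parents for additive
#' and conserved genes, one parent for dominant genes, 1.5x beyond the
#' more extreme parent for over-/underdominant genes) rather than as the
#' sum of the allelic counts, so the inheritance classifier has its own
#' clean ground truth. TPM columns are scaled to one million per sample;
#' gene lengths are treated as equal.
#'
#' @param truth a [gene_truth()] data.frame.
#' @param cfg the [sim_config()] that describes the design (replicates,
#'   depth, cross id, seed).
#' @return list of class `ase_sim`: `truth`, `hybrid` (an [ase_table()]),
#'   `hybrid_obs_tpm` (matrix matching `hybrid$counts`), `parental` (a
#'   [parental_table()]), `parental_tpm` and `hybrid_tpm`
#'   ([expression_table()]s), and `cfg`.
#' @export
simulate_counts <- function(truth, cfg = sim_config()) {
  stopifnot(inherits(truth, "gene_truth"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(truth)
  size <- 1 / truth$dispersion
  reps <- seq_len(cfg$n_replicates)
  grid_h <- expand.grid(replicate = reps, tissue = c("head", "gonad"),
                        sex = c("F", "M"), direction = c("AxB", "BxA"),
                        stringsAsFactors = FALSE)

  hyb_counts <- matrix(0, n, 2 * nrow(grid_h))
  hyb_tpm <- hyb_counts
  obs_names <- character(2 * nrow(grid_h))
  hmeta <- data.frame(sample_id = character(nrow(grid_h)),
                      cross_id = cfg$cross_id,
                      direction = grid_h$direction, sex = grid_h$sex,
                      tissue = grid_h$tissue, replicate = grid_h$replicate,
                      stringsAsFactors = FALSE)
  overall_counts <- matrix(0, n, nrow(grid_h))
  for (k in seq_len(nrow(grid_h))) {
    g <- grid_h[k, ]
    sid <- paste(g$direction, g$sex, g$tissue, paste0("R", g$replicate),
                 sep = "_")
    hmeta$sample_id[k] <- sid
    mu <- expected_means(truth, g$sex, g$tissue, role = "hybrid",
                         direction = g$direction)
    scale <- if (is.null(cfg$depth)) 1 else cfg$depth / sum(mu)
    cA <- stats::rnbinom(n, mu = mu[, "A"] * scale, size = size)
    cB <- stats::rnbinom(n, mu = mu[, "B"] * scale, size = size)
    j <- 2 * k - 1
    hyb_counts[, j] <- cA
    hyb_counts[, j + 1] <- cB
    obs_names[j] <- paste0(sid, ".A")
    obs_names[j + 1] <- paste0(sid, ".B")
    tot <- sum(cA) + sum(cB)
    if (tot > 0) hyb_tpm[, c(j, j + 1)] <- cbind(cA, cB) / tot * 1e6

    pm <- expected_means(truth, g$sex, g$tissue, role = "parent")
    mu_h <- .inheritance_mean(truth$inheritance_mode, pm[, "A"], pm[, "B"])
    overall_counts[, k] <- stats::rnbinom(n, mu = mu_h * scale, size = size)
  }
  dimnames(hyb_counts) <- list(truth$gene_id, obs_names)
  dimnames(hyb_tpm) <- dimnames(hyb_counts)
  hybrid <- ase_table(hyb_counts, hmeta)

  grid_p <- expand.grid(replicate = reps, tissue = c("head", "gonad"),
                        sex = c("F", "M"), line = c("A", "B"),
                        stringsAsFactors = FALSE)
  par_counts <- matrix(0, n, nrow(grid_p))
  psamples <- character(nrow(grid_p))
  for (k in seq_len(nrow(grid_p))) {
    g <- grid_p[k, ]
    psamples[k] <- paste("P", g$line, g$sex, g$tissue,
                         paste0("R", g$replicate), sep = "_")
    pm <- expected_means(truth, g$sex, g$tissue, role = "parent")
    mu <- pm[, g$line]
    scale <- if (is.null(cfg$depth)) 1 else cfg$depth / sum(mu)
    par_counts[, k] <- stats::rnbinom(n, mu = mu * scale, size = size)
  }
  dimnames(par_counts) <- list(truth$gene_id, psamples)
  pmeta <- data.frame(sample_id = psamples, line = grid_p$line,
                      cross_id = cfg$cross_id, sex = grid_p$sex,
                      tissue = grid_p$tissue, replicate = grid_p$replicate,
                      stringsAsFactors = FALSE)
  parental <- parental_table(par_counts, pmeta)

  to_tpm <- function(m) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    sweep(m, 2, cs, "/") * 1e6
  }
  parental_tpm <- expression_table(to_tpm(par_counts), "parental_overall",
                                   meta = pmeta)
  dimnames(overall_counts) <- list(truth$gene_id, hmeta$sample_id)
  hybrid_tpm <- expression_table(to_tpm(overall_counts), "hybrid_overall",
                                 meta = hmeta)

  structure(list(truth = truth, hybrid = hybrid, hybrid_obs_tpm = hyb_tpm,
                 parental = parental, parental_tpm = parental_tpm,
                 hybrid_tpm = hybrid_tpm, cfg = cfg),
            class = "ase_sim")
}

#' One-call simulation
#'
#' [simulate_truth()] followed by [simulate_counts()].
#'
#' @param cfg a [sim_config()].
#' @return An `ase_sim` list; see [simulate_counts()].
#' @export
simulate_ase <- function(cfg = sim_config()) {
  simulate_counts(simulate_truth(cfg), cfg)
}

#' Write a simulation to TSV files
#'
#' Writes the hybrid counts/metadata, allele-level TPM, parental
#' counts/metadata, parental and hybrid overall TPM and the truth table
#' into a directory.
#'
#' @param sim an `ase_sim` from [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ase_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_ase_counts(sim$hybrid, fp("hybrid_counts.tsv"), fp("hybrid_meta.tsv"),
                   fp("gene_flags.tsv"))
  .write_tsv(data.frame(gene_id = rownames(sim$hybrid_obs_tpm),
                        sim$hybrid_obs_tpm, check.names = FALSE),
             fp("hybrid_obs_tpm.tsv"))
  write_parental_counts(sim$parental, fp("parental_counts.tsv"),
                        fp("parental_meta.tsv"))
  write_expression(sim$parental_tpm, fp("parental_tpm.tsv"))
  write_expression(sim$hybrid_tpm, fp("hybrid_tpm.tsv"))
  .write_tsv(as.data.frame(sim$truth), fp("truth.tsv"))
  invisible(dir)
}
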