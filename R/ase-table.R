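#' Allele-specific count table for reciprocal hybrid crosses
#'
#' The central container of the package: a genes x observations matrix of
#' allele-resolved (estimated) read counts, where each hybrid sample
#' contributes two observations per gene, one per parental allele. Sample
#' metadata records the experimental design factors (cross, reciprocal
#' direction, sex, tissue, replicate); the parent of origin of each allele
#' is derived from the reciprocal direction (allele A is maternal iff the
#' direction is `AxB`, i.e. the line-A mother is listed first).
#'
#' @param counts numeric matrix (genes x observations). Column names must be
#'   `<sample_id>.<allele>` with allele `A` or `B`; row names are gene ids.
#'   Fractional (estimated) counts are accepted; all values must be >= 0.
#' @param meta data.frame with one row per sample and columns `sample_id`,
#'   `cross_id`, `direction` (`AxB` or `BxA`, mother listed first), `sex`
#'   (`F`/`M`), `tissue` (`head`/`gonad`), `replicate` (positive integer).
#'   A `library_size` column, if present, is ignored and recomputed.
#' @param gene_flags optional data.frame with columns `gene_id`,
#'   `is_autosomal`, `has_min_snvs`. Defaults to all `TRUE`. Analyses use
#'   only genes flagged autosomal; the minimum-SNV eligibility of the
#'   upstream allele-assignment step is carried as a flag only.
#'
#' @return An object of class `ase_table`: a list with elements `counts`,
#'   `obs` (per-observation metadata including `parent_of_origin`), `meta`
#'   (per-sample metadata with `library_size` recomputed as the sum of
#'   counts over autosomal genes) and `gene_flags`.
#' @export
ase_table <- function(counts, meta, gene_flags = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) stop("counts must have gene ids as row names")
  if (is.null(colnames(counts))) stop("counts must have <sample>.<allele> column names")
  if (any(counts < 0)) stop("negative counts are not allowed")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "cross_id", "direction", "sex", "tissue", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("sample_id must be unique in metadata")
  .check_levels(meta$direction, c("AxB", "BxA"), "direction")
  .check_levels(meta$sex, c("F", "M"), "sex")
  .check_levels(meta$tissue, c("head", "gonad"), "tissue")
  if (any(meta$replicate < 1)) stop("replicate must be a positive integer")

  obs <- .parse_obs_ids(colnames(counts))
  unknown <- setdiff(unique(obs$sample_id), meta$sample_id)
  if (length(unknown)) {
    stop("count columns reference sample(s) with no metadata row: ",
         paste(unknown, collapse = ", "))
  }
  direction <- meta$direction[match(obs$sample_id, meta$sample_id)]
  # allele A is the maternal copy exactly when the line-A mother founded the cross
  obs$parent_of_origin <- ifelse((obs$allele == "A") == (direction == "AxB"),
                                 "maternal", "paternal")

  if (is.null(gene_flags)) {
    gene_flags <- data.frame(gene_id = rownames(counts),
                             is_autosomal = TRUE, has_min_snvs = TRUE,
                             stringsAsFactors = FALSE)
  } else {
    gene_flags <- as.data.frame(gene_flags, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "is_autosomal", "has_min_snvs") %in% names(gene_flags)))
      stop("gene_flags needs columns gene_id, is_autosomal, has_min_snvs")
    gene_flags <- gene_flags[match(rownames(counts), gene_flags$gene_id), ]
    if (anyNA(gene_flags$gene_id)) stop("gene_flags must cover every gene in counts")
  }

  keep <- gene_flags$is_autosomal
  meta$library_size <- vapply(meta$sample_id, function(s) {
    sum(counts[keep, obs$sample_id == s, drop = FALSE])
  }, numeric(1))

  structure(list(counts = counts, obs = obs, meta = meta,
                 gene_flags = gene_flags),
            class = "ase_table")
}

.check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad)) {
    stop(what, " must be one of ", paste(levels, collapse = "/"),
         " (found: ", paste(bad, collapse = ", "), ")")
  }
  invisible(TRUE)
}

.parse_obs_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)\\.([AB])$", ids))
  bad <- ids[vapply(m, length, integer(1)) != 3]
  if (length(bad)) {
    stop("count columns must be named <sample>.<allele> with allele A or B: ",
         paste(bad, collapse = ", "))
  }
  data.frame(obs_id = ids,
             sample_id = vapply(m, `[`, character(1), 2),
             allele = vapply(m, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' @export
print.ase_table <- function(x, ...) {
  cat("ase_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "observations (", nrow(x$meta), "samples )\n")
  cat("  crosses:", paste(unique(x$meta$cross_id), collapse = ", "), "\n")
  cat("  autosomal genes:", sum(x$gene_flags$is_autosomal), "\n")
  invisible(x)
}

#' Read an allele-specific count table from TSV files
#'
#' Canonical dialect: UTF-8, tab-separated, header row, `.` decimal mark,
#' no quoting. The counts file has a `gene_id` column followed by one
#' column per `<sample>.<allele>` observation; the metadata file has one
#' row per sample.
#'
#' @param counts_path path to the counts TSV.
#' @param meta_path path to the sample metadata TSV.
#' @param gene_flags_path optional path to a gene-flags TSV
#'   (`gene_id`, `is_autosomal`, `has_min_snvs`).
#' @return An [ase_table()]. Library sizes are recomputed from the counts.
#' @export
read_ase_counts <- function(counts_path, meta_path, gene_flags_path = NULL) {
  counts <- .read_tsv(counts_path)
  if (names(counts)[1] != "gene_id") stop("first column of counts must be gene_id")
  mat <- as.matrix(counts[, -1, drop = FALSE])
  rownames(mat) <- counts$gene_id
  # read.delim turns "s1.A" into "s1.A" untouched (check.names = FALSE below)
  meta <- .read_meta_tsv(meta_path)
  flags <- if (!is.null(gene_flags_path)) .read_tsv(gene_flags_path) else NULL
  ase_table(mat, meta, flags)
}

#' Write an allele-specific count table to TSV files
#'
#' @param x an [ase_table()].
#' @param counts_path,meta_path,gene_flags_path output paths; gene flags are
#'   written only when a path is supplied.
#' @return `x`, invisibly.
#' @export
write_ase_counts <- function(x, counts_path, meta_path, gene_flags_path = NULL) {
  stopifnot(inherits(x, "ase_table"))
  .write_tsv(data.frame(gene_id = rownames(x$counts), x$counts,
                        check.names = FALSE), counts_path)
  .write_tsv(x$meta, meta_path)
  if (!is.null(gene_flags_path)) .write_tsv(x$gene_flags, gene_flags_path)
  invisible(x)
}

.read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = colClasses)
}

# sample metadata columns that must never be type-guessed ("F" is a sex,
# not FALSE)
.meta_classes <- c(sample_id = "character", sex = "character",
                   tissue = "character", direction = "character",
                   line = "character", cross_id = "character")

.read_meta_tsv <- function(path) {
  header <- names(.read_tsv_header(path))
  .read_tsv(path, colClasses = .meta_classes[intersect(names(.meta_classes),
                                                       header)])
}

.read_tsv_header <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    quote = "", nrows = 1)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Overall-expression table for parental lines or hybrids
#'
#' Holds TPM-like nonnegative abundances, genes x samples, together with a
#' role tag saying which stage consumes it (parental overall expression,
#' hybrid overall expression, or sex-wise expression summaries).
#'
#' @param values numeric matrix genes x samples, nonnegative, with row and
#'   column names.
#' @param role one of `parental_overall`, `hybrid_overall`,
#'   `sexwise_expression`.
#' @param meta optional per-sample data.frame (must contain `sample_id`
#'   matching the column names).
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values,
                             role = c("parental_overall", "hybrid_overall",
                                      "sexwise_expression"),
                             meta = NULL) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene and sample names")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!all(colnames(values) %in% meta$sample_id))
      stop("meta must describe every sample column")
    meta <- meta[match(colnames(values), meta$sample_id), ]
  }
  structure(list(values = values, role = role, meta = meta),
            class = "expression_table")
}

#' Read / write expression tables
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @param role see [expression_table()].
#' @param meta_path optional sample metadata TSV.
#' @return An `expression_table` (reader) or the input, invisibly (writer).
#' @export
read_expression <- function(path, role = "hybrid_overall", meta_path = NULL) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  meta <- if (!is.null(meta_path)) .read_meta_tsv(meta_path) else NULL
  expression_table(mat, role, meta)
}

#' @rdname read_expression
#' @param x an `expression_table`.
#' @export
write_expression <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "expression_table"))
  .write_tsv(data.frame(gene_id = rownames(x$values), x$values,
                        check.names = FALSE), path)
  if (!is.null(meta_path) && !is.null(x$meta)) .write_tsv(x$meta, meta_path)
  invisible(x)
}

#' Overall count table for the two parental lines
#'
#' Parental samples are homozygous, so each sample contributes a single
#' overall count per gene; the `line` column says which parental line
#' (A or B) the sample comes from.
#'
#' @param counts numeric matrix genes x samples (nonnegative).
#' @param meta data.frame with columns `sample_id`, `line` (`A`/`B`),
#'   `cross_id`, `sex`, `tissue`, `replicate`.
#' @return An object of class `parental_table`.
#' @export
parental_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("negative counts are not allowed")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "line", "cross_id", "sex", "tissue", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("parental metadata is missing: ", paste(miss, collapse = ", "))
  .check_levels(meta$line, c("A", "B"), "line")
  unknown <- setdiff(colnames(counts), meta$sample_id)
  if (length(unknown)) {
    stop("count columns reference sample(s) with no metadata row: ",
         paste(unknown, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  meta$library_size <- colSums(counts)
  structure(list(counts = counts, meta = meta), class = "parental_table")
}

#' Read a parental overall count table from TSV files
#'
#' @param counts_path,meta_path TSV paths, same dialect as
#'   [read_ase_counts()].
#' @return A [parental_table()].
#' @export
read_parental_counts <- function(counts_path, meta_path) {
  df <- .read_tsv(counts_path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  parental_table(mat, .read_meta_tsv(meta_path))
}

#' @rdname read_parental_counts
#' @param x a `parental_table`.
#' @export
write_parental_counts <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "parental_table"))
  .write_tsv(data.frame(gene_id = rownames(x$counts), x$counts,
                        check.names = FALSE), counts_path)
  .write_tsv(x$meta, meta_path)
  invisible(x)
}

#' Subset an ASE table by design factors
#'
#' Keeps the samples matching the given factor levels (and their
#' observation columns); library sizes are preserved, since they describe
#' the original sequencing libraries.
#'
#' @param x an [ase_table()].
#' @param sex,tissue,cross,direction optional vectors of levels to keep;
#'   `NULL` keeps all.
#' @return An `ase_table` with the selected samples.
#' @export
subset_samples <- function(x, sex = NULL, tissue = NULL, cross = NULL,
                           direction = NULL) {
  stopifnot(inherits(x, "ase_table"))
  keep <- rep(TRUE, nrow(x$meta))
  if (!is.null(sex)) keep <- keep & x$meta$sex %in% sex
  if (!is.null(tissue)) keep <- keep & x$meta$tissue %in% tissue
  if (!is.null(cross)) keep <- keep & x$meta$cross_id %in% cross
  if (!is.null(direction)) keep <- keep & x$meta$direction %in% direction
  if (!any(keep)) stop("no samples match the requested subset")
  meta <- x$meta[keep, , drop = FALSE]
  cols <- x$obs$sample_id %in% meta$sample_id
  out <- list(counts = x$counts[, cols, drop = FALSE],
              obs = x$obs[cols, , drop = FALSE],
              meta = meta, gene_flags = x$gene_flags)
  class(out) <- "ase_table"
  out
}
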