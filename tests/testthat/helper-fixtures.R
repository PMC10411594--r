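# Fixtures built in code: a tiny hand-specified ASE table and a balanced
# 8-observation design shared across tests.

# 2 genes x 4 hybrid samples (2 directions x 2 replicates), one sex/tissue
tiny_ase <- function(counts = NULL) {
  samples <- c("s1", "s2", "s3", "s4")
  meta <- data.frame(sample_id = samples, cross_id = "c1",
                     direction = c("AxB", "AxB", "BxA", "BxA"),
                     sex = "F", tissue = "head", replicate = c(1, 2, 1, 2),
                     stringsAsFactors = FALSE)
  if (is.null(counts)) {
    counts <- matrix(5, nrow = 2, ncol = 8,
                     dimnames = list(c("g1", "g2"),
                                     paste0(rep(samples, each = 2),
                                            c(".A", ".B"))))
  }
  ase_table(counts, meta)
}

# balanced design of the base allelic model: 4 samples x 2 alleles,
# equal offsets
balanced_design <- function() {
  build_design(tiny_ase(), sex = "F", tissue = "head", cross = "c1")
}

# independent NB log-likelihood used by oracle fits in tests; written
# against the test's own formula, not the package internals
oracle_nb_ll <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * (log(theta) - log(theta + mu)) +
        y * (log(mu) - log(theta + mu)))
}
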