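#' @importFrom MASS negative.binomial
NULL

# NB log-likelihood in the mean/dispersion parameterization
# (variance = mu + dispersion * mu^2, theta = 1/dispersion).
# Written with lgamma so fractional estimated counts are accepted.
nb_loglik <- function(y, mu, theta) {
  mu <- pmax(mu, 1e-12)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) +
        y * log(mu / (theta + mu)))
}

# one weighted-least-squares NB fit at fixed theta; never throws on
# numerical trouble, reports converged = FALSE instead
.nb_glm <- function(y, X, offset, theta, start = NULL) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, offset = offset,
                                    family = MASS::negative.binomial(theta),
                                    start = start,
                                    control = list(epsilon = 1e-10,
                                                   maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(ok = FALSE, converged = FALSE))
  }
  list(ok = TRUE,
       coefficients = fit$coefficients,
       fitted = fit$fitted.values,
       deviance = fit$deviance,
       converged = fit$converged,
       rank = fit$rank)
}

# Cox-Reid adjusted profile log-likelihood of the dispersion, given fitted
# means; the 0.5*logdet(X'WX) penalty removes most of the downward bias of
# the ML estimate at few residual degrees of freedom
.cr_apl <- function(dispersion, y, X, offset, mu) {
  theta <- 1 / dispersion
  W <- mu / (1 + mu / theta)
  ld <- determinant(crossprod(X * sqrt(W)), logarithm = TRUE)$modulus
  nb_loglik(y, mu, theta) - 0.5 * as.numeric(ld)
}

#' Per-gene dispersion by Cox-Reid adjusted profile likelihood
#'
#' Alternates a mean fit at the current dispersion with a one-dimensional
#' maximization of the Cox-Reid adjusted profile likelihood in
#' log-dispersion.
#'
#' @param y nonnegative counts (fractional allowed).
#' @param X design matrix including the intercept.
#' @param offset log library-size offsets.
#' @param init initial dispersion.
#' @param iter number of alternation cycles.
#' @return Dispersion estimate (scalar, > 0), or `NA` when no fit succeeds.
#' @export
estimate_dispersion <- function(y, X, offset, init = 0.1, iter = 3L) {
  disp <- init
  for (k in seq_len(iter)) {
    f <- .nb_glm(y, X, offset, 1 / disp)
    if (!f$ok) return(NA_real_)
    o <- stats::optimize(function(ld) .cr_apl(exp(ld), y, X, offset, f$fitted),
                         interval = c(log(1e-4), log(20)), maximum = TRUE)
    disp <- exp(o$maximum)
  }
  disp
}

#' Common dispersion across genes
#'
#' Maximizes the Cox-Reid adjusted profile likelihood summed over genes,
#' yielding a single dispersion shared by all genes of a scope. Used as
#' the shrinkage target for per-gene estimates (and, with
#' `common_dispersion_only`, as the dispersion itself). A deterministic
#' evenly spaced subsample of genes caps the cost on large matrices.
#'
#' @param Y counts matrix, genes x observations (a scope's columns).
#' @param X design matrix including the intercept.
#' @param offset log library-size offsets.
#' @param max_genes maximum number of genes entering the summed likelihood.
#' @return Common dispersion (scalar, > 0).
#' @export
common_dispersion <- function(Y, X, offset, max_genes = 400L) {
  Y <- as.matrix(Y)
  use <- which(rowSums(Y) > 0)
  if (!length(use)) return(0.1)
  if (length(use) > max_genes) {
    use <- use[unique(round(seq(1, length(use), length.out = max_genes)))]
  }
  obj <- function(ld) {
    theta <- 1 / exp(ld)
    s <- 0
    for (g in use) {
      f <- .nb_glm(Y[g, ], X, offset, theta)
      if (f$ok) s <- s + .cr_apl(exp(ld), Y[g, ], X, offset, f$fitted)
    }
    s
  }
  exp(stats::optimize(obj, interval = c(log(1e-4), log(5)),
                      maximum = TRUE, tol = 1e-3)$maximum)
}

# empirical-Bayes shrinkage of a per-gene dispersion toward the common
# value, weighted by residual degrees of freedom against the prior df
.shrink_dispersion <- function(disp_gene, disp_common, resid_df, prior_df) {
  if (is.na(disp_gene)) return(disp_common)
  (resid_df * disp_gene + prior_df * disp_common) / (resid_df + prior_df)
}

#' Fit a per-gene negative-binomial GLM
#'
#' Maximum-likelihood NB fit with log link and log library-size offsets on
#' the selected design columns. When no dispersion is supplied it is
#' profiled by Cox-Reid adjusted likelihood. Never crashes on a bad gene:
#' non-convergence or a rank-deficient design is reported through
#' `converged`/`skipped_reason`.
#'
#' @param y nonnegative per-observation counts for one gene.
#' @param design design data.frame from [build_design()].
#' @param columns covariate columns to include (after the intercept).
#' @param dispersion optional fixed dispersion; profiled when `NULL`.
#' @return A list of class `nb_fit`: `coefficients` (log scale),
#'   `deviance`, `dispersion`, `converged`, `n_obs`, `skipped_reason`
#'   (`NULL` when the fit is usable).
#' @export
fit_nb <- function(y, design, columns = c("CR", "PO", "MG"),
                   dispersion = NULL) {
  n <- length(y)
  skip <- function(reason) {
    structure(list(coefficients = NULL, deviance = NA_real_,
                   dispersion = dispersion, converged = FALSE,
                   n_obs = n, skipped_reason = reason), class = "nb_fit")
  }
  if (n != nrow(design)) stop("y and design must have matching length")
  if (n < 6) return(skip("insufficient design"))
  X <- cbind(`(Intercept)` = 1, as.matrix(design[, columns, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) return(skip("rank-deficient design"))
  offset <- design$offset
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(y, X, offset)
    if (is.na(dispersion)) return(skip("dispersion estimation failed"))
  }
  f <- .nb_glm(y, X, offset, 1 / dispersion)
  if (!f$ok) return(skip("fit failed"))
  structure(list(coefficients = f$coefficients, deviance = f$deviance,
                 dispersion = dispersion, converged = f$converged,
                 n_obs = n, skipped_reason = if (f$converged) NULL else "non-convergence"),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  if (!is.null(x$skipped_reason)) {
    cat("nb_fit (skipped:", x$skipped_reason, ")\n")
  } else {
    cat("nb_fit on", x$n_obs, "observations, dispersion",
        signif(x$dispersion, 4), "\n")
    print(signif(x$coefficients, 5))
  }
  invisible(x)
}

# nested-model likelihood-ratio deviance at fixed theta; refits the full
# model from the reduced solution if the difference comes out negative, so
# the nesting inequality holds up to numerical tolerance
.nb_lrt <- function(y, X_full, X_red, offset, theta) {
  ffull <- .nb_glm(y, X_full, offset, theta)
  fred <- .nb_glm(y, X_red, offset, theta)
  if (!ffull$ok || !fred$ok) return(list(stat = NA_real_, p = NA_real_,
                                         dev_full = NA_real_, dev_red = NA_real_))
  if (fred$deviance < ffull$deviance) {
    start <- numeric(ncol(X_full))
    names(start) <- colnames(X_full)
    start[colnames(X_red)] <- fred$coefficients
    f2 <- .nb_glm(y, X_full, offset, theta, start = start)
    if (f2$ok && f2$deviance < ffull$deviance) ffull <- f2
  }
  df <- ncol(X_full) - ncol(X_red)
  stat <- max(fred$deviance - ffull$deviance, 0)
  list(stat = stat,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       dev_full = ffull$deviance, dev_red = fred$deviance,
       coef_full = ffull$coefficients)
}

# continuity adjustment: when one level of a binary column has all-zero
# counts the MLE diverges; add half a count everywhere and flag the gene
.needs_half_count <- function(y, col) {
  all(y[col == 0] == 0) || all(y[col == 1] == 0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: monotone, capped at 1. `NA`s are carried
#' through.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
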