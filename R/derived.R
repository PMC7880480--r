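# Headline derived statistics of a fitted Cholesky model. All work on
# standardized paths: each trait's loadings are divided by the square root of
# its total implied variance, so squared paths are variance fractions even
# when standardization of the fitted phenotypes is imperfect.

#' Standardize a Cholesky model to unit implied total variance per trait
#'
#' @param model a [CholeskyModel-class] or [GsemFit-class].
#' @return a [CholeskyModel-class] with rescaled rows.
#' @export
standardizeModel <- function(model) {
  g <- gammaPaths(model); e <- epsilonPaths(model)
  tot <- rowSums(g^2) + rowSums(e^2)
  if (any(tot <= 0)) stop("trait with zero total implied variance")
  s <- sqrt(tot)
  choleskyModel(g / s, e / s, rownames(g))
}

#' Variance explained per factor
#'
#' Entry (i, j) is the squared standardized genetic path a_ij^2: the fraction
#' of trait i's phenotypic variance explained by genetic factor j. Negative
#' path estimates square in as-is.
#'
#' @param model a [CholeskyModel-class] or [GsemFit-class].
#' @return m x m trait-by-factor matrix of fractions.
#' @export
varianceExplained <- function(model) {
  std <- standardizeModel(model)
  std@gamma^2
}

#' Per-trait SNP heritability from a Cholesky model
#'
#' \eqn{h^2_i = \sum_j a_{ij}^2 / (\sum_j a_{ij}^2 + \sum_j e_{ij}^2)}. For
#' the first trait this is exactly a_11^2 of the standardized model (single
#' loading).
#'
#' @param model a [CholeskyModel-class] or [GsemFit-class].
#' @return named numeric vector of per-trait heritabilities.
#' @export
snpH2 <- function(model) {
  g <- gammaPaths(model); e <- epsilonPaths(model)
  tot <- rowSums(g^2) + rowSums(e^2)
  if (any(tot <= 0)) stop("trait with zero total implied variance")
  setNames(rowSums(g^2) / tot, rownames(g))
}

#' Genetic correlation matrix from the genetic path triangle
#'
#' \eqn{r_g(i,k) = \sum_j a_{ij} a_{kj} / \sqrt{\sum_j a_{ij}^2 \sum_j
#' a_{kj}^2}}, i.e. the correlation matrix of the implied genetic covariance
#' gamma gamma'. Entries involving a trait with zero genetic variance are
#' NA.
#'
#' @param model a [CholeskyModel-class] or [GsemFit-class].
#' @return symmetric m x m matrix with unit diagonal.
#' @export
geneticCorrelation <- function(model) {
  g <- gammaPaths(model)
  factorCorrelation(g)
}

#' @rdname geneticCorrelation
#' @export
residualCorrelation <- function(model) {
  factorCorrelation(epsilonPaths(model))
}

factorCorrelation <- function(loadings) {
  C <- tcrossprod(loadings)
  v <- diag(C)
  R <- C / sqrt(outer(v, v))
  R[v == 0, ] <- NA; R[, v == 0] <- NA
  diag(R)[v > 0] <- 1
  R
}

#' Factorial co-heritability
#'
#' Proportion of a trait's total genetic variance attributable to each
#' genetic factor: \eqn{f_{ij} = a_{ij}^2 / \sum_{j'} a_{ij'}^2}. Rows sum to
#' 1 for traits with nonzero genetic variance; rows of traits without
#' genetic variance are NA.
#'
#' @param model a [CholeskyModel-class] or [GsemFit-class].
#' @return m x m trait-by-factor matrix of proportions.
#' @export
factorialCoheritability <- function(model) {
  g <- gammaPaths(model)
  gv <- rowSums(g^2)
  out <- g^2 / gv
  out[gv == 0, ] <- NA
  out
}

#' Bivariate heritability
#'
#' Contribution of genetics to an observed phenotypic correlation:
#' \eqn{b(i,k) = \sum_j a_{ij} a_{kj} / r_p(i,k)} on standardized traits,
#' using the model-implied genetic covariance and the observed phenotypic
#' correlation. Pairs with `r_p = 0` (or NA) are NA, not infinite.
#'
#' @param model a [CholeskyModel-class] or [GsemFit-class].
#' @param rp observed m x m phenotypic correlation matrix.
#' @return m x m matrix; diagonal is the per-trait heritability of the
#'   standardized model.
#' @export
bivariateHeritability <- function(model, rp) {
  std <- standardizeModel(model)
  G <- tcrossprod(std@gamma)
  if (!all(dim(rp) == dim(G)))
    stop("rp dimension does not match the model")
  out <- G / rp
  out[is.na(rp) | rp == 0] <- NA
  out
}

#' Delta-method standard error of a derived statistic
#'
#' First-order propagation of the free-parameter covariance through any
#' scalar function of the fitted model: the gradient is computed by central
#' differences on the free-path vector and the SE is
#' \eqn{\sqrt{g' V g}}. NA when the fit carries no parameter covariance.
#'
#' @param fit a [GsemFit-class] with a parameter covariance.
#' @param statistic function taking a [CholeskyModel-class] and returning a
#'   scalar (e.g. `function(m) snpH2(m)[2]`).
#' @param rel relative finite-difference step.
#' @return standard error (scalar).
#' @export
deltaSE <- function(fit, statistic, rel = 1e-5) {
  if (is.null(fit@vcov)) return(NA_real_)
  par <- modelToPar(fit@model)
  m <- nTraits(fit)
  k <- length(par)
  g <- numeric(k)
  h <- rel * pmax(abs(par), 1e-3)
  for (i in seq_len(k)) {
    pp <- par; pp[i] <- par[i] + h[i]
    pm <- par; pm[i] <- par[i] - h[i]
    g[i] <- (statistic(parToModel(pp, m)) - statistic(parToModel(pm, m))) /
      (2 * h[i])
  }
  sqrt(max(0, drop(t(g) %*% fit@vcov %*% g)))
}

#' Parametric-bootstrap standard error of a derived statistic
#'
#' Draws free-path vectors from N(estimate, vcov) and returns the SD of the
#' statistic over draws; a cross-check for [deltaSE()].
#'
#' @param fit a [GsemFit-class].
#' @param statistic scalar function of a [CholeskyModel-class].
#' @param B number of draws.
#' @param seed RNG seed.
#' @return standard error (scalar).
#' @export
bootstrapSE <- function(fit, statistic, B = 500, seed = 1) {
  if (is.null(fit@vcov)) return(NA_real_)
  par <- modelToPar(fit@model)
  m <- nTraits(fit)
  ch <- chol(fit@vcov + diag(1e-12, length(par)))
  withSeed(seed, {
    draws <- matrix(rnorm(B * length(par)), B) %*% ch
  })
  vals <- apply(draws, 1, function(d) statistic(parToModel(par + d, m)))
  sd(vals)
}

#' Full derived-statistic summary of a fitted model
#'
#' Computes every headline quantity (variance explained per factor, SNP-h2,
#' genetic/residual correlations, factorial co-heritability and -- when a
#' phenotypic correlation matrix is supplied -- bivariate heritability),
#' with delta-method SEs where a parameter covariance is available.
#'
#' @param fit a [GsemFit-class].
#' @param rp optional observed phenotypic correlation matrix for bivariate
#'   heritability.
#' @param withSE compute delta-method SEs for variance explained, h2 and
#'   factorial co-heritability (slower: one gradient per entry).
#' @return named list of matrices/vectors; `$seOf` holds the matching SEs.
#' @export
derivedSummary <- function(fit, rp = NULL, withSE = TRUE) {
  m <- nTraits(fit)
  out <- list(
    varExplained = varianceExplained(fit),
    snpH2 = snpH2(fit),
    rG = geneticCorrelation(fit),
    rE = residualCorrelation(fit),
    factorialCoherit = factorialCoheritability(fit))
  if (!is.null(rp)) out$bivariateH2 <- bivariateHeritability(fit, rp)
  if (withSE && !is.null(fit@vcov)) {
    seVar <- matrix(NA_real_, m, m)
    seCoh <- matrix(NA_real_, m, m)
    seH2 <- numeric(m)
    for (i in seq_len(m)) {
      seH2[i] <- deltaSE(fit, function(md) snpH2(md)[i])
      for (j in seq_len(i)) {
        seVar[i, j] <- deltaSE(fit, function(md) varianceExplained(md)[i, j])
        seCoh[i, j] <- deltaSE(fit, function(md) {
          v <- factorialCoheritability(md)[i, j]
          if (is.na(v)) 0 else v
        })
      }
    }
    out$seOf <- list(varExplained = seVar, snpH2 = seH2,
                     factorialCoherit = seCoh)
  }
  out
}

#' Write derived-statistic report tables
#'
#' TSV trait-by-factor grids (estimate and SE columns) plus correlation
#' matrices, mirroring the usual supplementary-table layout.
#'
#' @param summary result of [derivedSummary()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of files written, invisibly.
#' @export
writeDerivedReport <- function(summary, dir, prefix = "gsem") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name) {
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, name))
    df <- data.frame(trait = rownames(x) %||% seq_len(nrow(x)),
                     formatRound(x), check.names = FALSE)
    write.table(df, f, quote = FALSE, row.names = FALSE, sep = "\t")
    files <<- c(files, f)
  }
  emit(summary$varExplained, "variance_explained")
  emit(as.matrix(t(summary$snpH2)), "snp_h2")
  emit(summary$rG, "genetic_correlation")
  emit(summary$rE, "residual_correlation")
  emit(summary$factorialCoherit, "factorial_coheritability")
  if (!is.null(summary$bivariateH2)) emit(summary$bivariateH2, "bivariate_h2")
  invisible(files)
}

formatRound <- function(x, digits = 6) {
  x <- as.matrix(x)
  out <- matrix(sprintf("%.*f", digits, x), nrow(x), ncol(x))
  out[is.na(x)] <- "NA"
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- colnames(x) %||% paste0("c", seq_len(ncol(out)))
  out
}
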