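#' Rank-based inverse normal transformation (van der Waerden)
#'
#' Scores \eqn{\Phi^{-1}(r_i / (n + 1))} with average ranks for ties, applied
#' to the observed entries of a vector; NAs are preserved. The Blom offset
#' (\eqn{(r - 3/8)/(n + 1/4)}) is available as an option.
#'
#' @param x numeric vector (NA = missing); at least two distinct observed
#'   values required.
#' @param offset "vanderwaerden" (default) or "blom".
#' @return transformed vector, same length and NA pattern as `x`.
#' @export
rankInverseNormal <- function(x, offset = c("vanderwaerden", "blom")) {
  offset <- match.arg(offset)
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2) stop("rank transform needs at least 2 observed values")
  if (length(unique(x[obs])) < 2)
    stop("rank transform undefined for all-identical input")
  r <- rank(x[obs], ties.method = "average")
  u <- switch(offset,
              vanderwaerden = r / (n + 1),
              blom = (r - 3 / 8) / (n + 1 / 4))
  out <- x
  out[obs] <- qnorm(u)
  out
}

#' Covariate-adjustment recipes
#'
#' Standard recipes for developmental traits: early-life measures are
#' adjusted for sex, assessment age, age squared and the first two ancestry
#' PCs; reading for sex, age and PCs; IQ measures (already age-normed) for
#' sex and PCs only.
#'
#' @param traits character trait labels.
#' @param kind character vector (recycled) with entries "earlylife",
#'   "reading" or "iq".
#' @return named list of covariate-name vectors, one per trait.
#' @export
covariateRecipe <- function(traits,
                            kind = rep("earlylife", length(traits))) {
  kind <- rep(kind, length.out = length(traits))
  r <- lapply(kind, function(k) switch(k,
    earlylife = c("sex", "age", "age2", "PC1", "PC2"),
    reading   = c("sex", "age", "PC1", "PC2"),
    iq        = c("sex", "PC1", "PC2"),
    stop("unknown recipe kind: ", k)))
  names(r) <- traits
  r
}

#' Regress covariates out of each trait
#'
#' Per-trait ordinary-least-squares residuals on the requested covariates
#' (complete cases per trait; rows with missing trait or covariate values
#' stay NA). Residuals are exactly orthogonal to the design columns used.
#'
#' @param phenotypes a [PhenotypeTable-class].
#' @param covariates a [CovariateTable-class], row-aligned by individual ID.
#' @param recipe named list per trait of covariate names among "sex", "age",
#'   "age2", "PC1", "PC2", ... (see [covariateRecipe()]); traits absent from
#'   the recipe are centred only.
#' @return a [PhenotypeTable-class] of residuals.
#' @export
adjustCovariates <- function(phenotypes, covariates, recipe = list()) {
  stopifnot(is(phenotypes, "PhenotypeTable"), is(covariates, "CovariateTable"))
  v <- phenoValues(phenotypes)
  idx <- match(rownames(v), covariates@ids)
  if (anyNA(idx)) stop("covariate table missing individuals present in phenotypes")
  out <- v
  for (j in seq_len(ncol(v))) {
    trait <- colnames(v)[j]
    wanted <- recipe[[trait]] %||% character(0)
    X <- matrix(1, nrow(v), 1)
    for (cv in wanted) {
      col <- covariateColumn(covariates, cv, j, idx)
      if (is.null(col))
        stop(sprintf("covariate '%s' required for trait '%s' is not available",
                     cv, trait))
      X <- cbind(X, col)
    }
    cc <- !is.na(v[, j]) & !apply(X, 1, anyNA)
    if (sum(cc) <= ncol(X))
      stop(sprintf("too few complete cases to adjust trait '%s'", trait))
    fit <- lm.fit(X[cc, , drop = FALSE], v[cc, j])
    out[, j] <- NA
    out[cc, j] <- fit$residuals
  }
  res <- phenotypeTable(out, traitAges = traitAges(phenotypes))
  attr(res, "covariates") <- covariates
  res
}

covariateColumn <- function(covariates, name, traitIndex, idx) {
  if (name == "sex") return(covariates@sex[idx])
  if (name == "age") {
    if (ncol(covariates@age) == 0) return(NULL)
    a <- covariates@age[idx, min(traitIndex, ncol(covariates@age))]
    return(a - mean(a, na.rm = TRUE))
  }
  if (name == "age2") {
    a <- covariateColumn(covariates, "age", traitIndex, idx)
    return(if (is.null(a)) NULL else a^2)
  }
  if (grepl("^PC[0-9]+$", name)) {
    k <- as.integer(sub("PC", "", name))
    if (ncol(covariates@pcs) < k) return(NULL)
    return(covariates@pcs[idx, k])
  }
  NULL
}

#' Attach ancestry principal components to a covariate table
#'
#' @param covariates a [CovariateTable-class].
#' @param pcs matrix of PC scores with rownames = individual IDs (e.g. from
#'   [grmPrincipalComponents()]).
#' @return the updated [CovariateTable-class].
#' @export
setPCs <- function(covariates, pcs) {
  idx <- match(covariates@ids, rownames(pcs))
  if (anyNA(idx)) stop("PC scores missing for some individuals")
  covariates@pcs <- pcs[idx, , drop = FALSE]
  covariates
}

#' Rank-transform every trait of a table
#'
#' Applies [rankInverseNormal()] per trait (after covariate adjustment, in
#' the standard order of operations: adjust, then transform).
#'
#' @param phenotypes a [PhenotypeTable-class].
#' @param offset passed to [rankInverseNormal()].
#' @return transformed [PhenotypeTable-class].
#' @export
rankTransformTable <- function(phenotypes, offset = "vanderwaerden") {
  v <- phenoValues(phenotypes)
  for (j in seq_len(ncol(v))) v[, j] <- rankInverseNormal(v[, j], offset)
  out <- phenotypeTable(v, traitAges = traitAges(phenotypes))
  attr(out, "covariates") <- attr(phenotypes, "covariates")
  out
}

#' Phenotypic correlation matrix
#'
#' Pairwise-complete Pearson or Spearman correlations; symmetric with unit
#' diagonal. Pairs with fewer than `minOverlap` joint observations are NA
#' rather than fabricated.
#'
#' @param phenotypes a [PhenotypeTable-class].
#' @param method "pearson" or "spearman".
#' @param minOverlap minimum pairwise-complete observations (default 3).
#' @return m x m correlation matrix.
#' @export
phenotypicCorrelations <- function(phenotypes,
                                   method = c("pearson", "spearman"),
                                   minOverlap = 3) {
  method <- match.arg(method)
  v <- phenoValues(phenotypes)
  R <- cor(v, use = "pairwise.complete.obs", method = method)
  obs <- !is.na(v)
  overlap <- crossprod(obs * 1)
  R[overlap < minOverlap] <- NA
  diag(R) <- 1
  R
}

#' Write phenotypes / covariates in GCTA-style whitespace format
#'
#' `FID IID value...` with NA written as `NA`.
#'
#' @param phenotypes a [PhenotypeTable-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePhen <- function(phenotypes, path) {
  v <- phenoValues(phenotypes)
  df <- data.frame(FID = rownames(v), IID = rownames(v),
                   format(v, digits = 8, trim = TRUE),
                   check.names = FALSE)
  write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = " ")
  invisible(path)
}

#' Read a GCTA-style phenotype file
#'
#' @param path whitespace file `FID IID value...`.
#' @param traitNames optional labels for the value columns.
#' @return a [PhenotypeTable-class].
#' @export
readPhen <- function(path, traitNames = NULL) {
  df <- read.table(path, stringsAsFactors = FALSE, na.strings = c("NA", "-9"))
  v <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df[[2]])
  colnames(v) <- traitNames %||% sprintf("trait%d", seq_len(ncol(v)))
  phenotypeTable(v)
}
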