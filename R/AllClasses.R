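#' @import methods
#' @importFrom stats cor lm lm.fit qnorm pnorm pchisq rbinom rnorm runif sd
#'   var complete.cases optim setNames
#' @importFrom utils write.table read.table head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypeMatrix: SNP dosage data with marker metadata
#'
#' Holds an n x M dosage matrix with entries in \{0, 1, 2, NA\}, per-SNP
#' metadata (chromosome, position, alleles) and individual identifiers.
#' Allele frequencies are always computed from the non-missing dosages of the
#' stored sample.
#'
#' @slot dosages numeric matrix, individuals in rows (rownames = individual
#'   IDs), SNPs in columns (colnames = SNP IDs); values 0/1/2/NA count the A1
#'   allele.
#' @slot snpInfo data.frame with columns `chr`, `id`, `pos`, `a1`, `a2`,
#'   one row per SNP.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snpInfo = "data.frame"),
  validity = function(object) {
    d <- object@dosages
    if (is.null(rownames(d)) || is.null(colnames(d)))
      return("dosages must carry individual IDs (rownames) and SNP IDs (colnames)")
    if (nrow(object@snpInfo) != ncol(d))
      return(sprintf("snpInfo has %d rows but dosages has %d SNPs",
                     nrow(object@snpInfo), ncol(d)))
    if (!all(c("chr", "id", "pos", "a1", "a2") %in% names(object@snpInfo)))
      return("snpInfo must contain columns chr, id, pos, a1, a2")
    v <- d[!is.na(d)]
    if (length(v) && any(v != 0 & v != 1 & v != 2))
      return("dosages must be 0, 1, 2 or NA")
    TRUE
  }
)

#' GRM: realized genomic-relationship matrix
#'
#' Symmetric n x n matrix of realized genetic relationships among individuals,
#' with the number of markers entering each pairwise estimate (the GCTA
#' `.grm.N.bin` convention) and individual IDs.
#'
#' @slot values symmetric numeric matrix of relationships (the "A" matrix).
#' @slot nMarkers numeric matrix of per-pair marker counts.
#' @slot ids character vector of individual IDs, in row order.
#' @export
setClass("GRM",
  representation(values = "matrix", nMarkers = "matrix", ids = "character"),
  validity = function(object) {
    n <- length(object@ids)
    if (!all(dim(object@values) == c(n, n)))
      return("values dimension does not match number of ids")
    if (!all(dim(object@nMarkers) == c(n, n)))
      return("nMarkers dimension does not match number of ids")
    if (any(!is.finite(object@values)))
      return("GRM values must be finite")
    if (max(abs(object@values - t(object@values))) > 1e-8)
      return("GRM must be symmetric")
    TRUE
  }
)

#' PhenotypeTable: multi-trait phenotypes in model (chronological) order
#'
#' An n x m matrix of trait values with per-trait missingness. Column order is
#' the model order: traits are listed chronologically, with any late outcome
#' last, because the Cholesky decomposition is order-dependent.
#'
#' @slot values numeric matrix, individuals in rows (rownames = IDs), traits
#'   in columns (colnames = trait labels); NA marks missing assessments.
#' @slot traitAges numeric vector of mean assessment ages (months), one per
#'   trait; NA when unknown.
#' @export
setClass("PhenotypeTable",
  representation(values = "matrix", traitAges = "numeric"),
  validity = function(object) {
    if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
      return("values must carry individual IDs (rownames) and trait labels (colnames)")
    if (length(object@traitAges) != ncol(object@values))
      return("traitAges length must equal the number of traits")
    TRUE
  }
)

#' CovariateTable: per-individual covariates aligned to a PhenotypeTable
#'
#' @slot sex numeric vector (0/1 coding), one per individual.
#' @slot age numeric matrix n x m of per-trait assessment ages (an age can
#'   differ between waves); NA allowed.
#' @slot pcs numeric matrix n x k of ancestry principal-component scores
#'   (zero columns when not yet computed).
#' @slot ids character individual IDs.
#' @export
setClass("CovariateTable",
  representation(sex = "numeric", age = "matrix", pcs = "matrix",
                 ids = "character"),
  validity = function(object) {
    n <- length(object@ids)
    if (length(object@sex) != n) return("sex length must match ids")
    if (nrow(object@age) != n) return("age rows must match ids")
    if (nrow(object@pcs) != n && ncol(object@pcs) > 0)
      return("pcs rows must match ids")
    TRUE
  }
)

#' CholeskyModel: lower-triangular genetic and residual path matrices
#'
#' The saturated ("Cholesky") factor model over m ordered traits: as many
#' latent genetic factors (loadings `gamma`, entries a_ij) as traits,
#' identified through the GRM, and as many residual factors (loadings
#' `epsilon`, entries e_ij), identified through the identity matrix. Both
#' matrices are lower triangular with non-negative diagonals (sign
#' identification).
#'
#' @slot gamma lower-triangular m x m genetic path matrix (factor j on trait i).
#' @slot epsilon lower-triangular m x m residual path matrix.
#' @export
setClass("CholeskyModel",
  representation(gamma = "matrix", epsilon = "matrix"),
  validity = function(object) {
    m <- nrow(object@gamma)
    if (!all(dim(object@gamma) == c(m, m)) ||
        !all(dim(object@epsilon) == c(m, m)))
      return("gamma and epsilon must be square with identical dimension")
    if (any(abs(object@gamma[upper.tri(object@gamma)]) > 0) ||
        any(abs(object@epsilon[upper.tri(object@epsilon)]) > 0))
      return("gamma and epsilon must be lower triangular")
    TRUE
  }
)

#' GremlFit: univariate or bivariate GREML variance components
#'
#' @slot components named numeric vector of variance components
#'   (univariate: varG, varE; bivariate: varG1, varG2, covG12, varE1, varE2,
#'   covE12).
#' @slot se named numeric vector of standard errors (inverse AI matrix).
#' @slot h2 named numeric vector of SNP heritabilities (one per trait).
#' @slot h2SE delta-method standard errors of h2.
#' @slot rg genetic correlation (bivariate fits; NA otherwise).
#' @slot rgSE delta-method SE of rg.
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot loglik0 restricted log-likelihood of the no-genetics null
#'   (univariate fits; NA otherwise).
#' @slot lrtP boundary likelihood-ratio p-value for varG = 0 (0.5:0.5
#'   chi-square mixture).
#' @slot converged logical convergence flag.
#' @slot iterations iteration count.
#' @slot identifiable FALSE when the GRM carries no relatedness contrast
#'   (e.g. identity GRM) and the genetic/residual split is not identified.
#' @slot n number of individuals used (per trait for bivariate fits).
#' @export
setClass("GremlFit",
  representation(components = "numeric", se = "numeric", h2 = "numeric",
                 h2SE = "numeric", rg = "numeric", rgSE = "numeric",
                 loglik = "numeric", loglik0 = "numeric", lrtP = "numeric",
                 converged = "logical", iterations = "numeric",
                 identifiable = "logical", n = "numeric"))

#' GsemFit: fitted Cholesky GSEM
#'
#' @slot model CholeskyModel holding the estimated paths (non-negative
#'   diagonals after sign fixing).
#' @slot seGamma,seEpsilon per-path standard errors from the inverse numerical
#'   Hessian (NA where suppressed).
#' @slot waldGamma,waldEpsilon two-sided normal Wald p-values per free path.
#' @slot vcov free-parameter covariance matrix (order: gamma lower triangle
#'   column-major, then epsilon), or NULL when the Hessian was not positive
#'   definite.
#' @slot loglik maximized log-likelihood.
#' @slot nObs integer vector of observed counts per trait.
#' @slot converged optimizer convergence flag.
#' @slot identifiable FALSE when the GRM is (numerically) the identity and
#'   only the total covariance is identified.
#' @slot hessianCondition condition number of the Hessian (diagnostic).
#' @export
setClass("GsemFit",
  representation(model = "CholeskyModel", seGamma = "matrix",
                 seEpsilon = "matrix", waldGamma = "matrix",
                 waldEpsilon = "matrix", vcov = "matrixOrNULL",
                 loglik = "numeric", nObs = "numeric", converged = "logical",
                 identifiable = "logical", hessianCondition = "numeric"))

#' SimulationSpec: ground-truth description of a synthetic cohort
#'
#' Defines genotypes, covariates and a multivariate phenotype with known
#' lower-triangular genetic (`gamma`) and residual (`epsilon`) factor
#' structure, per-trait assessment-age distributions, missingness rates and
#' covariate effects, so downstream estimators can be validated against
#' truth.
#'
#' @slot nIndividuals,nSnps cohort and marker panel size.
#' @slot mafRange length-2 numeric in (0, 0.5]; per-SNP allele frequencies
#'   are drawn uniformly from this interval.
#' @slot gamma,epsilon lower-triangular m x m truth loadings.
#' @slot traitNames character labels, chronological order.
#' @slot traitAges m x 2 matrix (mean, sd) of assessment ages in months.
#' @slot missingFraction per-trait missingness proportion in [0, 1).
#' @slot covariateEffects m x 3 matrix of per-trait coefficients for sex,
#'   centred age, and centred age squared.
#' @slot seed integer random seed.
#' @export
setClass("SimulationSpec",
  representation(nIndividuals = "numeric", nSnps = "numeric",
                 mafRange = "numeric", gamma = "matrix", epsilon = "matrix",
                 traitNames = "character", traitAges = "matrix",
                 missingFraction = "numeric", covariateEffects = "matrix",
                 seed = "numeric"),
  validity = function(object) {
    m <- nrow(object@gamma)
    if (object@nIndividuals < 2) return("nIndividuals must be >= 2")
    if (object@nSnps < 1) return("nSnps must be >= 1")
    if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
        object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
      return("mafRange must lie in (0, 0.5] with lower <= upper")
    if (!all(dim(object@epsilon) == c(m, m)))
      return("gamma and epsilon must have matching dimension")
    if (any(abs(object@gamma[upper.tri(object@gamma)]) > 0) ||
        any(abs(object@epsilon[upper.tri(object@epsilon)]) > 0))
      return("gamma and epsilon must be lower triangular")
    if (any(diag(object@gamma) < 0) || any(diag(object@epsilon) < 0))
      return("gamma and epsilon diagonals must be non-negative")
    if (length(object@traitNames) != m) return("traitNames length must be m")
    if (any(object@missingFraction < 0) || any(object@missingFraction >= 1))
      return("missingFraction must lie in [0, 1) per trait")
    if (length(object@missingFraction) != m)
      return("missingFraction must have one entry per trait")
    if (!all(dim(object@traitAges) == c(m, 2)))
      return("traitAges must be an m x 2 (mean, sd) matrix")
    if (!all(dim(object@covariateEffects) == c(m, 3)))
      return("covariateEffects must be m x 3 (sex, age, age^2)")
    TRUE
  }
)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
})

setMethod("show", "GRM", function(object) {
  n <- length(object@ids)
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("GRM: %d individuals; mean diagonal %.4f; off-diagonal range [%.4f, %.4f]\n",
              n, mean(diag(object@values)),
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
})

setMethod("show", "PhenotypeTable", function(object) {
  v <- object@values
  cat(sprintf("PhenotypeTable: %d individuals x %d traits\n", nrow(v), ncol(v)))
  for (j in seq_len(ncol(v)))
    cat(sprintf("  %-24s n = %d\n", colnames(v)[j], sum(!is.na(v[, j]))))
})

setMethod("show", "CholeskyModel", function(object) {
  cat(sprintf("CholeskyModel: %d traits, %d free paths\n",
              nrow(object@gamma), nrow(object@gamma) * (nrow(object@gamma) + 1)))
  cat("gamma (genetic paths):\n"); print(round(object@gamma, 4))
  cat("epsilon (residual paths):\n"); print(round(object@epsilon, 4))
})

setMethod("show", "GremlFit", function(object) {
  kind <- if (length(object@h2) > 1) "bivariate" else "univariate"
  cat(sprintf("GremlFit (%s): logL = %.4f, converged = %s\n",
              kind, object@loglik, object@converged))
  for (k in seq_along(object@components))
    cat(sprintf("  %-8s %9.5f (SE %.5f)\n", names(object@components)[k],
                object@components[k], object@se[k]))
  for (k in seq_along(object@h2))
    cat(sprintf("  h2[%d] = %.4f (SE %.4f)\n", k, object@h2[k], object@h2SE[k]))
  if (!is.na(object@rg))
    cat(sprintf("  rg = %.4f (SE %.4f)\n", object@rg, object@rgSE))
  if (!is.na(object@lrtP))
    cat(sprintf("  LRT p (varG = 0) = %.3g\n", object@lrtP))
})

setMethod("show", "GsemFit", function(object) {
  m <- nrow(object@model@gamma)
  cat(sprintf("GsemFit: %d traits, logL = %.4f, converged = %s%s\n", m,
              object@loglik, object@converged,
              if (!object@identifiable) " [A/E split not identified]" else ""))
  show(object@model)
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: n = %d, M = %d, %d traits, seed = %d\n",
              object@nIndividuals, object@nSnps, nrow(object@gamma),
              object@seed))
  h2 <- rowSums(object@gamma^2) /
    (rowSums(object@gamma^2) + rowSums(object@epsilon^2))
  cat("  truth h2:", paste(sprintf("%.3f", h2), collapse = ", "), "\n")
})
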