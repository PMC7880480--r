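#' Build a simulation specification
#'
#' Describes a synthetic cohort with known lower-triangular genetic and
#' residual factor structure. The defaults emulate a longitudinal vocabulary
#' cohort: four traits measured at 15, 24, 38 and 38 months (expressive
#' vocabulary at three waves, then receptive vocabulary), modest SNP
#' heritabilities (0.11-0.16), phenotypic correlations declining with the age
#' gap (largest, 0.63, between the two same-age traits), wave-specific
#' missingness matching observed Ns of 6,524 / 6,014 / 6,092 / 6,092 at full
#' cohort size, and sex/age/age-squared covariate effects.
#'
#' The default truth loadings are fixed by construction: `gamma` rows imply
#' per-trait h2 of 0.109, 0.147, 0.160 and 0.121, and `epsilon` is the
#' Cholesky factor of P - gamma %*% t(gamma) for a target phenotypic
#' correlation matrix P, so each trait has unit total variance
#' (standardized truth).
#'
#' @param nIndividuals,nSnps cohort and marker panel size.
#' @param mafRange allele-frequency interval in (0, 0.5].
#' @param gamma,epsilon lower-triangular truth loadings (defaults above).
#' @param traitNames trait labels in chronological order.
#' @param traitAges m x 2 matrix of (mean, sd) assessment age in months.
#' @param missingFraction per-trait missingness in [0, 1).
#' @param covariateEffects m x 3 coefficients for sex, centred age, centred
#'   age squared.
#' @param seed integer seed.
#' @return a [SimulationSpec-class].
#' @examples
#' spec <- simulationSpec(nIndividuals = 200, nSnps = 500)
#' spec
#' @export
simulationSpec <- function(nIndividuals = 1000, nSnps = 2000,
                           mafRange = c(0.05, 0.5),
                           gamma = NULL, epsilon = NULL,
                           traitNames = NULL, traitAges = NULL,
                           missingFraction = NULL,
                           covariateEffects = NULL, seed = 1L) {
  if (is.null(gamma)) {
    truth <- defaultTruthModel()
    gamma <- truth$gamma
    if (is.null(epsilon)) epsilon <- truth$epsilon
  }
  gamma <- as.matrix(gamma)
  m <- nrow(gamma)
  if (is.null(epsilon)) {
    # standardized complement: unit total variance, no residual correlation
    d <- 1 - rowSums(gamma^2)
    if (any(d < 0)) stop("gamma rows imply genetic variance > 1; supply epsilon")
    epsilon <- diag(sqrt(d), m)
  }
  epsilon <- as.matrix(epsilon)
  if (is.null(traitNames))
    traitNames <- if (m == 4)
      c("expressive15m", "expressive24m", "expressive38m", "receptive38m")
    else sprintf("trait%d", seq_len(m))
  if (is.null(traitAges))
    traitAges <- if (m == 4)
      cbind(c(15.41, 24.39, 38.48, 38.48), c(0.97, 1.03, 1.17, 1.17))
    else cbind(seq(15, by = 12, length.out = m), rep(1, m))
  if (is.null(missingFraction))
    missingFraction <- if (m == 4) c(0, 0.08, 0.07, 0.07) else rep(0, m)
  if (is.null(covariateEffects))
    covariateEffects <- matrix(rep(c(0.2, 0.05, -0.005), each = m), m, 3)
  new("SimulationSpec", nIndividuals = nIndividuals, nSnps = nSnps,
      mafRange = mafRange, gamma = unname(gamma), epsilon = unname(epsilon),
      traitNames = traitNames, traitAges = unname(as.matrix(traitAges)),
      missingFraction = missingFraction,
      covariateEffects = unname(as.matrix(covariateEffects)),
      seed = as.integer(seed))
}

#' Default four-trait truth loadings
#'
#' Genetic loadings chosen so implied SNP-h2 per trait is 0.109 / 0.147 /
#' 0.160 / 0.121; residual loadings are the Cholesky factor of P - GG' for a
#' target phenotypic correlation matrix with r(1,2) = 0.53, r(3,4) = 0.63 and
#' intermediate values declining with the age gap. Total variance is 1 per
#' trait.
#'
#' @return list with lower-triangular matrices `gamma` and `epsilon`.
#' @export
defaultTruthModel <- function() {
  gamma <- rbind(c(0.33, 0.00, 0.00, 0.00),
                 c(0.21, 0.32, 0.00, 0.00),
                 c(0.05, 0.27, 0.29, 0.00),
                 c(0.05, 0.33, 0.00, 0.10))
  P <- rbind(c(1.00, 0.53, 0.35, 0.30),
             c(0.53, 1.00, 0.55, 0.45),
             c(0.35, 0.55, 1.00, 0.63),
             c(0.30, 0.45, 0.63, 1.00))
  E <- P - tcrossprod(gamma)
  epsilon <- t(chol(E))
  list(gamma = gamma, epsilon = epsilon)
}

#' Extend the four-trait truth with a mid-childhood outcome row
#'
#' Appends a fifth trait to [defaultTruthModel()] with genetic loadings on
#' the second and fourth early-life factors plus a small unique factor,
#' emulating mid-childhood reading (h2 ~ 0.40), verbal IQ (~ 0.55) or
#' performance IQ (~ 0.26). Residual covariance with the fourth trait is kept
#' near zero so most of that phenotypic correlation is genetic.
#'
#' @param outcome one of "reading", "viq", "piq", or "null" (no genetic or
#'   shared variance at all beyond noise).
#' @return list with 5 x 5 `gamma` and `epsilon`, plus `traitNames`.
#' @export
outcomeTruthModel <- function(outcome = c("viq", "reading", "piq", "null")) {
  outcome <- match.arg(outcome)
  base <- defaultTruthModel()
  arow <- switch(outcome,
    reading = c(0.00, 0.25, 0.00, 0.57, 0.10),
    viq     = c(0.00, 0.42, 0.00, 0.60, 0.10),
    piq     = c(0.00, -0.03, 0.00, 0.50, 0.10),
    null    = c(0, 0, 0, 0, 0))
  # residual covariances with early-life traits: modest with wave 2, ~0 with
  # trait 4 (phenotypic correlation with trait 4 then mostly genetic)
  ecov <- switch(outcome,
    reading = c(0.05, 0.12, 0.08, 0.03),
    viq     = c(0.05, 0.12, 0.08, 0.03),
    piq     = c(0.03, 0.08, 0.05, 0.03),
    null    = c(0, 0, 0, 0))
  gamma <- rbind(cbind(base$gamma, 0), arow)
  E4 <- tcrossprod(base$epsilon)
  evar <- 1 - sum(arow^2)
  if (evar <= 0) stop("outcome genetic loadings exceed unit variance")
  E5 <- rbind(cbind(E4, ecov), c(ecov, evar))
  epsilon <- t(chol(E5))
  name <- switch(outcome, reading = "reading7y", viq = "viq8y",
                 piq = "piq8y", null = "nullOutcome")
  list(gamma = unname(gamma), epsilon = unname(epsilon),
       traitNames = c("expressive15m", "expressive24m", "expressive38m",
                      "receptive38m", name))
}

#' Simulate genotype dosages
#'
#' Per-SNP allele frequencies are drawn uniformly from `mafRange`; dosages
#' are Binomial(2, p) per individual and SNP (Hardy-Weinberg proportions, no
#' linkage disequilibrium or structure). Reproducible under the spec seed.
#'
#' @param spec a [SimulationSpec-class].
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  n <- spec@nIndividuals; M <- spec@nSnps
  withSeed(spec@seed, {
    p <- runif(M, spec@mafRange[1], spec@mafRange[2])
    d <- matrix(rbinom(n * M, 2L, rep(p, each = n)), n, M)
  })
  rownames(d) <- sprintf("ind%05d", seq_len(n))
  colnames(d) <- sprintf("snp%06d", seq_len(M))
  genotypeMatrix(d)
}

#' Simulate multivariate phenotypes with known factor structure
#'
#' For each genetic factor j, per-SNP effects are drawn with variance 1/M and
#' applied to column-standardized genotypes, giving a factor score of unit
#' variance (asymptotically); trait i receives \eqn{\sum_j a_{ij} f_j}.
#' Residual factors are iid standard normal scaled by the epsilon loadings.
#' Sex (Bernoulli 0.5), per-wave assessment age (normal around the trait-age
#' mean) and age-squared effects are added per the spec coefficients. The
#' empirical cross-trait genetic covariance converges to gamma %*% t(gamma)
#' as n and M grow.
#'
#' @param genotypes a [GenotypeMatrix-class] (drives the genetic values so the
#'   same genotypes can feed GRM construction).
#' @param spec a [SimulationSpec-class]; trait count must match `gamma`.
#' @param returnTruth when TRUE, attach the simulated genetic values and
#'   covariates as attributes `geneticValues` and `covariates`.
#' @return a [PhenotypeTable-class]; covariates are available via
#'   `attr(x, "covariates")` (a [CovariateTable-class]).
#' @export
simulatePhenotypes <- function(genotypes, spec, returnTruth = FALSE) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(spec, "SimulationSpec"))
  d <- dosages(genotypes)
  n <- nrow(d); M <- ncol(d)
  if (n != spec@nIndividuals)
    stop("genotype individual count does not match spec")
  m <- nrow(spec@gamma)
  p <- alleleFrequencies(genotypes)
  sdv <- sqrt(2 * p * (1 - p))
  keep <- sdv > 0
  Z <- sweep(sweep(d[, keep, drop = FALSE], 2, 2 * p[keep]), 2, sdv[keep], "/")
  Mk <- sum(keep)
  withSeed(spec@seed + 1L, {
    beta <- matrix(rnorm(Mk * m, sd = sqrt(1 / Mk)), Mk, m)
    f <- Z %*% beta                       # n x m genetic factor scores
    g <- f %*% t(spec@gamma)              # genetic values per trait
    u <- matrix(rnorm(n * m), n, m)
    r <- u %*% t(spec@epsilon)            # residual values per trait
    sex <- rbinom(n, 1L, 0.5)
    age <- sapply(seq_len(m), function(j)
      rnorm(n, spec@traitAges[j, 1], spec@traitAges[j, 2]))
  })
  y <- g + r
  for (j in seq_len(m)) {
    ac <- age[, j] - mean(age[, j])
    y[, j] <- y[, j] + spec@covariateEffects[j, 1] * sex +
      spec@covariateEffects[j, 2] * ac +
      spec@covariateEffects[j, 3] * (ac^2 - mean(ac^2))
  }
  rownames(y) <- rownames(d)
  colnames(y) <- spec@traitNames
  pt <- phenotypeTable(y, traitAges = spec@traitAges[, 1])
  covar <- new("CovariateTable", sex = as.numeric(sex), age = age,
               pcs = matrix(0, n, 0), ids = rownames(d))
  attr(pt, "covariates") <- covar
  if (returnTruth) attr(pt, "geneticValues") <- g
  pt
}

#' Apply completely-at-random missingness per trait
#'
#' Masks each trait at its spec missingness rate (Bernoulli per entry), so a
#' full-size cohort reproduces wave-specific observed Ns up to binomial
#' error. The underlying attrition process of a real longitudinal cohort is
#' not modelled beyond this; `monotone = TRUE` additionally carries forward
#' dropout (an individual missing at wave j stays missing afterwards).
#'
#' @param phenotypes a [PhenotypeTable-class].
#' @param spec a [SimulationSpec-class] (supplies rates and seed).
#' @param monotone logical; propagate missingness to later waves.
#' @return the masked [PhenotypeTable-class].
#' @export
applyMissingness <- function(phenotypes, spec, monotone = FALSE) {
  stopifnot(is(phenotypes, "PhenotypeTable"), is(spec, "SimulationSpec"))
  v <- phenoValues(phenotypes)
  m <- ncol(v)
  if (length(spec@missingFraction) != m)
    stop("missingFraction length does not match trait count")
  withSeed(spec@seed + 2L, {
    for (j in seq_len(m)) {
      if (spec@missingFraction[j] > 0) {
        drop <- runif(nrow(v)) < spec@missingFraction[j]
        v[drop, j] <- NA
      }
      if (monotone && j > 1) v[is.na(v[, j - 1L]), j] <- NA
    }
  })
  out <- phenotypeTable(v, traitAges = traitAges(phenotypes))
  attr(out, "covariates") <- attr(phenotypes, "covariates")
  out
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper: genotypes, phenotypes, missingness.
#'
#' @param spec a [SimulationSpec-class].
#' @param missing apply the spec missingness (default TRUE).
#' @return list with `genotypes` ([GenotypeMatrix-class]), `phenotypes`
#'   ([PhenotypeTable-class]) and `covariates` ([CovariateTable-class]).
#' @export
simulateCohort <- function(spec, missing = TRUE) {
  gt <- simulateGenotypes(spec)
  ph <- simulatePhenotypes(gt, spec)
  if (missing && any(spec@missingFraction > 0))
    ph <- applyMissingness(ph, spec)
  list(genotypes = gt, phenotypes = ph,
       covariates = attr(ph, "covariates"))
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
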