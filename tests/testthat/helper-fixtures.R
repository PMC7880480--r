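# Shared fixtures and independent oracles. Heavier objects are built once
# per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# small 4-trait cohort with complete data and no covariate effects
smallCohort <- function() {
  if (is.null(.fixtures$small)) {
    spec <- simulationSpec(nIndividuals = 500, nSnps = 800,
                           missingFraction = rep(0, 4),
                           covariateEffects = matrix(0, 4, 3), seed = 42)
    co <- simulateCohort(spec, missing = FALSE)
    grm <- computeGRM(co$genotypes)
    .fixtures$small <- list(spec = spec, cohort = co, grm = grm,
                            eig = grmEigen(grm))
  }
  .fixtures$small
}

namedTrait <- function(pt, j) {
  Y <- phenoValues(pt)
  setNames(Y[, j], rownames(Y))
}

# independent brute-force Gaussian log-density (no chol: determinant + solve)
denseGaussianLoglik <- function(V, y) {
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + sum(y * solve(V, y)))
}

# brute-force correlation of an implied covariance
bruteCorrelation <- function(S) {
  d <- sqrt(diag(S))
  S / outer(d, d)
}

# random lower-triangular model with unit total variance per trait
randomStandardizedModel <- function(m, seed) {
  set.seed(seed)
  repeat {
    g <- matrix(0, m, m)
    g[lower.tri(g, diag = TRUE)] <- runif(m * (m + 1) / 2, -0.3, 0.5)
    diag(g) <- abs(diag(g)) + 0.05
    P <- diag(m)
    P[lower.tri(P)] <- runif(m * (m - 1) / 2, 0.2, 0.5)
    P <- P + t(P) - diag(diag(P))
    E <- P - tcrossprod(g)
    ok <- tryCatch({chol(E); TRUE}, error = function(e) FALSE)
    if (ok) return(choleskyModel(g, t(chol(E))))
  }
}
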