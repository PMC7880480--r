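test_that("univariate GSEM likelihood matches a brute-force dense Gaussian", {
  fx <- smallCohort()
  keep <- individualIds(fx$grm)[1:150]
  grm <- subsetGRM(fx$grm, keep)
  pt <- rankTransformTable(fx$cohort$phenotypes)
  y <- phenoValues(pt)[keep, 1, drop = FALSE]
  ptSub <- phenotypeTable(y)
  for (par in list(c(0.4, 0.9), c(0.1, 1.1), c(0.9, 0.4))) {
    md <- choleskyModel(matrix(par[1], 1, 1), matrix(par[2], 1, 1))
    ours <- gsemLoglik(md, grm, ptSub)
    V <- par[1]^2 * grmValues(grm) + par[2]^2 * diag(150)
    oracle <- denseGaussianLoglik(V, as.numeric(y))
    expect_lt(abs(ours - oracle), 1e-8)
  }
})

test_that("zero genetic paths reduce the likelihood to an iid factorized form", {
  fx <- smallCohort()
  keep <- individualIds(fx$grm)[1:100]
  grm <- subsetGRM(fx$grm, keep)
  pt <- rankTransformTable(fx$cohort$phenotypes)
  Y <- phenoValues(pt)[keep, 1:3]
  md <- randomStandardizedModel(3, seed = 71)
  zeroG <- choleskyModel(matrix(0, 3, 3), epsilonPaths(md))
  ours <- gsemLoglik(zeroG, grm, phenotypeTable(Y))
  E <- tcrossprod(epsilonPaths(md))
  Ei <- solve(E)
  ld <- as.numeric(determinant(E, logarithm = TRUE)$modulus)
  oracle <- sum(apply(Y, 1, function(r)
    -0.5 * (3 * log(2 * pi) + ld + drop(r %*% Ei %*% r))))
  expect_lt(abs(ours - oracle), 1e-8)
})

test_that("the likelihood is invariant to consistent relabelling of individuals", {
  fx <- smallCohort()
  keep <- individualIds(fx$grm)[1:120]
  grm <- subsetGRM(fx$grm, keep)
  pt <- rankTransformTable(fx$cohort$phenotypes)
  Y <- phenoValues(pt)[keep, ]
  md <- randomStandardizedModel(4, seed = 72)
  l1 <- gsemLoglik(md, grm, phenotypeTable(Y))
  set.seed(73)
  perm <- sample(120)
  l2 <- gsemLoglik(md, subsetGRM(grm, keep[perm]),
                   phenotypeTable(Y[perm, ]))
  expect_lt(abs(l1 - l2), 1e-8)
})

test_that("missing-data likelihood equals the Kronecker selection oracle", {
  fx <- smallCohort()
  keep <- individualIds(fx$grm)[1:60]
  grm <- subsetGRM(fx$grm, keep)
  pt <- rankTransformTable(fx$cohort$phenotypes)
  Y <- phenoValues(pt)[keep, 1:3]
  set.seed(74)
  Y[sample(60, 12), 2] <- NA
  Y[sample(60, 10), 3] <- NA
  md <- randomStandardizedModel(3, seed = 75)
  ours <- gsemLoglik(md, grm, phenotypeTable(Y))
  # oracle: build the full (trait x individual) covariance by Kronecker
  # products, select observed entries, evaluate the dense normal density
  G <- tcrossprod(gammaPaths(md)); E <- tcrossprod(epsilonPaths(md))
  V <- kronecker(G, grmValues(grm)) + kronecker(E, diag(60))
  obs <- which(!is.na(as.numeric(Y)))
  oracle <- denseGaussianLoglik(V[obs, obs], as.numeric(Y)[obs])
  expect_lt(abs(ours - oracle), 1e-8)

  # complete-data fast path agrees with the same oracle construction
  Yc <- phenoValues(pt)[keep, 1:3]
  oursC <- gsemLoglik(md, grm, phenotypeTable(Yc))
  oracleC <- denseGaussianLoglik(V, as.numeric(Yc))
  expect_lt(abs(oursC - oracleC), 1e-8)
})

test_that("non-positive-definite path matrices give -Inf, not an error", {
  fx <- smallCohort()
  pt <- rankTransformTable(fx$cohort$phenotypes)
  bad <- choleskyModel(diag(0.5, 4), matrix(0, 4, 4))  # zero residual: singular
  expect_identical(gsemLoglik(bad, fx$grm, pt), -Inf)
})

test_that("whole-column sign flips leave the likelihood unchanged and fits report non-negative diagonals", {
  fx <- smallCohort()
  pt <- rankTransformTable(fx$cohort$phenotypes)
  md <- randomStandardizedModel(4, seed = 76)
  g2 <- gammaPaths(md); g2[, 2] <- -g2[, 2]
  flipped <- choleskyModel(g2, epsilonPaths(md))
  expect_equal(gsemLoglik(md, fx$grm, pt),
               gsemLoglik(flipped, fx$grm, pt), tolerance = 1e-10)

  fit <- fitGsem(fx$grm, pt, eig = fx$eig, se = FALSE)
  expect_true(all(diag(gammaPaths(fit)) >= 0))
  expect_true(all(diag(epsilonPaths(fit)) >= 0))
})

test_that("the saturated fit reproduces the sample covariance and truth heritabilities", {
  fx <- smallCohort()
  pt <- rankTransformTable(fx$cohort$phenotypes)
  fit <- fitGsem(fx$grm, pt, eig = fx$eig)
  expect_true(fit@converged)
  implied <- impliedCovariance(fit)$phenotypic
  S <- cov(phenoValues(pt))
  expect_lt(max(abs(implied - S)), 0.1)
  truthH2 <- rowSums(fx$spec@gamma^2)
  h2 <- snpH2(fit)
  seH2 <- vapply(1:4, function(i) deltaSE(fit, function(m) snpH2(m)[i]),
                 numeric(1))
  for (i in 1:4)
    expect_lt(abs(h2[i] - truthH2[i]), 3 * seH2[i] + 0.02)
  # starting-value route without the eigen cache reaches the same optimum
  fit2 <- fitGsem(fx$grm, pt, se = FALSE)
  expect_lt(abs(fit2@loglik - fit@loglik), 1e-3)
})

test_that("an identity GRM flags the unidentified genetic/residual split", {
  n <- 100
  g <- new("GRM", values = diag(n), nMarkers = matrix(1, n, n),
           ids = sprintf("i%03d", 1:n))
  set.seed(77)
  Y <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(sprintf("i%03d", 1:n), c("a", "b")))
  expect_warning(fit <- fitGsem(g, phenotypeTable(Y), se = FALSE),
                 "identity-like")
  expect_false(fit@identifiable)
})

test_that("stage-2 extension refits the full model with the outcome last", {
  fx <- smallCohort()
  pt <- rankTransformTable(fx$cohort$phenotypes)
  base <- fitGsem(fx$grm, pt, eig = fx$eig, se = FALSE)

  # pure-noise outcome: its genetic paths jointly consistent with zero
  set.seed(78)
  noise <- setNames(rnorm(500), individualIds(fx$grm))
  ext <- stage2Extend(fx$grm, pt, rankInverseNormal(noise),
                      outcomeName = "noise")
  expect_equal(nTraits(ext), 5)
  expect_identical(traitNames(ext@model)[5], "noise")
  a5 <- gammaPaths(ext)[5, ]
  se5 <- ext@seGamma[5, ]
  z2 <- sum((a5 / se5)^2, na.rm = TRUE)   # joint Wald, 5 df
  expect_gt(pchisq(z2, df = 5, lower.tail = FALSE), 0.001)

  # stage-1 substructure is preserved within sampling noise of the refit
  g4 <- gammaPaths(base)
  g5 <- gammaPaths(ext)[1:4, 1:4]
  expect_lt(max(abs(abs(g4) - abs(g5))), 0.06)
})

test_that("an outcome loading on one factor is recovered by the extension", {
  truth <- outcomeTruthModel("viq")
  spec <- simulationSpec(nIndividuals = 600, nSnps = 800,
                         gamma = truth$gamma, epsilon = truth$epsilon,
                         traitNames = truth$traitNames,
                         traitAges = cbind(c(15, 24, 38, 38, 96), rep(1, 5)),
                         missingFraction = rep(0, 5),
                         covariateEffects = matrix(0, 5, 3), seed = 80)
  co <- simulateCohort(spec, missing = FALSE)
  grm <- computeGRM(co$genotypes)
  pt <- rankTransformTable(co$phenotypes)
  Y <- phenoValues(pt)
  base <- phenotypeTable(Y[, 1:4])
  ext <- stage2Extend(grm, base, setNames(Y[, 5], rownames(Y)),
                      outcomeName = "viq8y")
  a54 <- gammaPaths(ext)[5, 4]
  se54 <- ext@seGamma[5, 4]
  expect_lt(abs(abs(a54) - 0.60), 3 * se54 + 0.05)
})
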