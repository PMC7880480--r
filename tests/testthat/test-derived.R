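test_that("variance explained is the squared standardized path", {
  # a = 0.6 on one factor -> 36% of phenotypic variance
  md <- choleskyModel(matrix(0.6, 1, 1), matrix(0.8, 1, 1))
  expect_equal(varianceExplained(md)[1, 1], 0.36, tolerance = 1e-12)
  # zero path -> zero; full genetic trait -> 100%
  md0 <- choleskyModel(matrix(0, 1, 1), matrix(1, 1, 1))
  expect_equal(varianceExplained(md0)[1, 1], 0)
  md1 <- choleskyModel(matrix(1, 1, 1), matrix(0, 1, 1))
  expect_equal(varianceExplained(md1)[1, 1], 1)
  # negative estimates square in as-is
  g <- rbind(c(0.5, 0), c(-0.3, 0.4))
  e <- diag(sqrt(1 - rowSums(g^2)))
  md2 <- choleskyModel(g, e)
  expect_equal(varianceExplained(md2)[2, 1], 0.09, tolerance = 1e-12)
})

test_that("per-trait SNP-h2 sums squared loadings over total implied variance", {
  # loadings (0.21, 0.32) with unit total variance -> h2 = 0.0441 + 0.1024
  g <- rbind(c(0.21, 0), c(0.21, 0.32))
  e <- diag(sqrt(1 - rowSums(g^2)))
  md <- choleskyModel(g, e)
  expect_equal(unname(snpH2(md)[2]), 0.1465, tolerance = 1e-12)
  # first trait: h2 equals a11^2 exactly (single loading)
  expect_equal(unname(snpH2(md)[1]), 0.21^2, tolerance = 1e-12)
  # all-genetic trait
  mdg <- choleskyModel(diag(c(0.5, 0.5)), matrix(0, 2, 2))
  expect_equal(unname(snpH2(mdg)), c(1, 1))
})

test_that("genetic correlations equal the brute-force correlation of the implied covariance", {
  # loading rows (0.3, 0.4) and (0.5, 0): 0.15 / (0.5 * 0.5) = 0.6;
  # realized here as a valid lower-triangular model with traits reordered
  # (trait 1 on factor 1 only, trait 2 on both)
  gam <- rbind(c(0.5, 0), c(0.3, 0.4))
  e2 <- diag(sqrt(1 - rowSums(gam^2)))
  md <- choleskyModel(gam, e2)
  expect_equal(geneticCorrelation(md)[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(bruteCorrelation(tcrossprod(gam))[1, 2], 0.6,
               tolerance = 1e-12)

  # package route on a valid lower-triangular model, against brute force
  md3 <- randomStandardizedModel(4, seed = 90)
  rg <- geneticCorrelation(md3)
  expect_equal(rg, bruteCorrelation(tcrossprod(gammaPaths(md3))),
               tolerance = 1e-14)
  re <- residualCorrelation(md3)
  expect_equal(re, bruteCorrelation(tcrossprod(epsilonPaths(md3))),
               tolerance = 1e-14)
  expect_equal(diag(rg), rep(1, 4), ignore_attr = TRUE)

  # identical rows -> 1; orthogonal rows -> 0
  gi <- rbind(c(0.4, 0), c(0.4, 0))
  ei <- diag(sqrt(1 - rowSums(gi^2)))
  expect_equal(geneticCorrelation(choleskyModel(gi, ei))[1, 2], 1)
  go <- rbind(c(0.4, 0), c(0, 0.4))
  expect_equal(geneticCorrelation(choleskyModel(go, ei))[1, 2], 0)

  # zero genetic variance -> flagged NA
  gz <- rbind(c(0.4, 0), c(0, 0))
  rz <- geneticCorrelation(choleskyModel(gz, diag(0.5, 2)))
  expect_true(is.na(rz[1, 2]))
})

test_that("factorial co-heritability proportions come from squared loadings", {
  # per-factor variance contributions (4.6%, 10.1%) -> (31.3%, 68.7%)
  g <- rbind(c(sqrt(0.046), 0), c(sqrt(0.046), sqrt(0.101)))
  e <- diag(sqrt(1 - rowSums(g^2)))
  fc <- factorialCoheritability(choleskyModel(g, e))
  expect_equal(fc[2, 1], 0.046 / 0.147, tolerance = 1e-12)
  expect_equal(fc[2, 2], 0.101 / 0.147, tolerance = 1e-12)
  expect_equal(sum(fc[2, ]), 1, tolerance = 1e-12)
  # single loaded factor -> 1; equal loadings -> 1/3 each
  expect_equal(fc[1, 1], 1)
  g3 <- matrix(0, 3, 3); g3[3, ] <- 0.2; g3[1, 1] <- 0.2; g3[2, 1:2] <- 0.2
  g3[upper.tri(g3)] <- 0
  fc3 <- factorialCoheritability(choleskyModel(g3, diag(0.5, 3)))
  expect_equal(unname(fc3[3, ]), rep(1 / 3, 3), tolerance = 1e-12)
  # zero genetic variance row is NA
  gz <- rbind(c(0.3, 0), c(0, 0))
  fz <- factorialCoheritability(choleskyModel(gz, diag(0.7, 2)))
  expect_true(all(is.na(fz[2, ])))
})

test_that("bivariate heritability relates genetic covariance to observed correlation", {
  md <- randomStandardizedModel(3, seed = 91)
  G <- tcrossprod(gammaPaths(md))
  rp <- G + tcrossprod(epsilonPaths(md))
  b <- bivariateHeritability(md, rp)
  # identity: b * rp = genetic covariance at machine precision
  expect_equal(b * rp, G, tolerance = 1e-12)
  # genetic covariance 0.18 over rp 0.5 -> 0.36
  g <- rbind(c(0.6, 0), c(0.3, 0.4))
  e <- diag(sqrt(1 - rowSums(g^2)))
  rp2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  b2 <- bivariateHeritability(choleskyModel(g, e), rp2)
  expect_equal(b2[1, 2], 0.18 / 0.5, tolerance = 1e-12)
  # zero residual covariance: rp equals the genetic covariance -> b = 1
  rp3 <- matrix(c(1, 0.18, 0.18, 1), 2)
  b3 <- bivariateHeritability(choleskyModel(g, e), rp3)
  expect_equal(b3[1, 2], 1, tolerance = 1e-12)
  # rp = 0 -> NA, not infinite
  rp4 <- matrix(c(1, 0, 0, 1), 2)
  expect_true(is.na(bivariateHeritability(choleskyModel(g, e), rp4)[1, 2]))
})

test_that("delta-method SEs agree with the parametric bootstrap and with GREML", {
  gamma <- rbind(c(0.6, 0), c(0.35, 0.45))
  epsilon <- t(chol(rbind(c(1, 0.45), c(0.45, 1)) - tcrossprod(gamma)))
  spec <- simulationSpec(nIndividuals = 500, nSnps = 600, gamma = gamma,
                         epsilon = epsilon, traitNames = c("t1", "t2"),
                         traitAges = cbind(c(15, 24), c(1, 1)),
                         missingFraction = c(0, 0),
                         covariateEffects = matrix(0, 2, 3), seed = 92)
  co <- simulateCohort(spec, missing = FALSE)
  grm <- computeGRM(co$genotypes)
  pt <- rankTransformTable(co$phenotypes)
  fit <- fitGsem(grm, pt)
  stat <- function(m) snpH2(m)[2]
  dse <- deltaSE(fit, stat)
  bse <- bootstrapSE(fit, stat, B = 500, seed = 7)
  expect_lt(abs(dse - bse) / dse, 0.15)

  # m = 1: GSEM h2 SE matches the univariate GREML delta-method SE
  pt1 <- phenotypeTable(phenoValues(pt)[, 1, drop = FALSE])
  fit1 <- fitGsem(grm, pt1)
  g1 <- fitUnivariateGreml(grm, namedTrait(pt, 1))
  dse1 <- deltaSE(fit1, function(m) snpH2(m)[1])
  expect_lt(abs(dse1 - g1@h2SE), 0.25 * g1@h2SE)

  # statistic with zero gradient at the estimate -> SE 0
  expect_equal(deltaSE(fit, function(m) 1.0), 0)
})

test_that("derived summary assembles consistent tables and report files", {
  fx <- smallCohort()
  pt <- rankTransformTable(fx$cohort$phenotypes)
  fit <- fitGsem(fx$grm, pt, eig = fx$eig)
  rp <- phenotypicCorrelations(pt)
  ds <- derivedSummary(fit, rp = rp)
  m <- 4
  # row sums of factorial co-heritability are 1 for heritable traits
  expect_equal(unname(rowSums(ds$factorialCoherit)), rep(1, m),
               tolerance = 1e-9)
  # h2 equals the row sum of variance explained (standardized model)
  expect_equal(unname(rowSums(ds$varExplained)), unname(ds$snpH2),
               tolerance = 1e-9)
  dir <- file.path(tempdir(), "derivedrep")
  files <- writeDerivedReport(ds, dir)
  expect_true(all(file.exists(files)))
  expect_gte(length(files), 5)
})
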