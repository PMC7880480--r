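test_that("QC removes SNPs failing MAF, call-rate and HWE rules", {
  set.seed(1)
  n <- 200
  common <- rbinom(n, 2, 0.3)
  rare <- rbinom(n, 2, 0.005)            # MAF ~ 0.005 < 0.01
  gappy <- rbinom(n, 2, 0.3)
  gappy[1:5] <- NA                       # call rate 0.975 < 0.99
  allHet <- rep(1, n)                    # extreme HWE violation
  filler <- replicate(5, rbinom(n, 2, 0.4))
  d <- cbind(common, rare, gappy, allHet, filler)
  colnames(d) <- c("common", "rare", "gappy", "allhet", paste0("f", 1:5))
  gt <- genotypeMatrix(d)
  out <- qcFilter(gt)
  kept <- colnames(dosages(out))
  expect_true("common" %in% kept)
  expect_false("rare" %in% kept)
  expect_false("gappy" %in% kept)
  expect_false("allhet" %in% kept)
  log <- attr(out, "qcLog")
  expect_gte(log["failMaf"], 1)
  expect_gte(log["failCallRate"], 1)
  expect_gte(log["failHwe"], 1)
})

test_that("HWE chi-square matches the brute-force contingency evaluation", {
  # all-heterozygote SNP, n = 100: expected (25, 50, 25) at p = 0.5,
  # observed (0, 100, 0) -> chi-square = 25 + 50 + 25 = 100
  d <- matrix(1, 100, 1)
  p <- hweChiSq(d)
  expect_equal(unname(p), pchisq(100, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(p, 5e-7)
  # brute-force check on an arbitrary count configuration
  counts <- c(n0 = 30, n1 = 40, n2 = 30)
  d2 <- matrix(rep(c(0, 1, 2), counts), ncol = 1)
  phat <- (2 * 30 + 40) / 200
  e <- 100 * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
  chi <- sum((counts - e)^2 / e)
  expect_equal(unname(hweChiSq(d2)), pchisq(chi, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("GRM entries equal the direct estimator formula", {
  # one SNP, p = 0.5, dosages (2, 0): off-diagonal (1)(-1)/0.5 = -2,
  # self-relatedness of the dosage-2 individual 1/0.5 = 2
  d <- matrix(c(2, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  grm <- computeGRM(genotypeMatrix(d))
  A <- grmValues(grm)
  expect_equal(A[1, 2], -2, tolerance = 1e-12)
  expect_equal(A[1, 1], 2, tolerance = 1e-12)
  expect_equal(grmMarkerCounts(grm)[1, 2], 1)
})

test_that("simulated-cohort GRM has mean diagonal near 1 and permutes correctly", {
  fx <- smallCohort()
  A <- grmValues(fx$grm)
  n <- nrow(A); M <- ncol(dosages(fx$cohort$genotypes))
  expect_lt(abs(mean(diag(A)) - 1), 3 * sqrt(2 / M) / sqrt(n) * 5)
  expect_lt(max(abs(A - t(A))), 1e-12)

  # permutation equivariance
  perm <- sample(n)
  d <- dosages(fx$cohort$genotypes)
  gPerm <- computeGRM(genotypeMatrix(d[perm, ]))
  expect_equal(grmValues(gPerm), A[perm, perm], tolerance = 1e-12)
})

test_that("monomorphic SNPs are rejected by the GRM estimator", {
  d <- cbind(rep(1, 10), rep(2, 10))
  colnames(d) <- c("ok", "mono")
  expect_error(computeGRM(genotypeMatrix(d)), "monomorphic")
})

test_that("relatedness pruning enforces the cutoff with minimal greedy removals", {
  base <- diag(4) * 0.98
  ids <- letters[1:4]
  # single violating pair a-b at 0.10 -> exactly one of the two removed
  A <- base; A[1, 2] <- A[2, 1] <- 0.10
  g <- new("GRM", values = A, nMarkers = matrix(100, 4, 4), ids = ids)
  p <- pruneRelated(g, 0.05)
  expect_length(attr(p, "removed"), 1)
  expect_true(all(grmValues(p)[upper.tri(grmValues(p))] < 0.05))

  # triangle: a-b and b-c above cutoff, a-c below -> b alone removed
  A2 <- base
  A2[1, 2] <- A2[2, 1] <- 0.08
  A2[2, 3] <- A2[3, 2] <- 0.09
  g2 <- new("GRM", values = A2, nMarkers = matrix(100, 4, 4), ids = ids)
  p2 <- pruneRelated(g2, 0.05)
  expect_identical(attr(p2, "removed"), "b")

  # nothing to prune -> identity subset
  g3 <- new("GRM", values = base, nMarkers = matrix(100, 4, 4), ids = ids)
  expect_identical(individualIds(pruneRelated(g3, 0.05)), ids)
})

test_that("pruned GRMs never retain a pair at or above the cutoff", {
  fx <- smallCohort()
  p <- pruneRelated(fx$grm, 0.05)
  off <- grmValues(p)[upper.tri(grmValues(p))]
  expect_true(all(off < 0.05))
})

test_that("GRM principal components recover a planted rank-one direction", {
  set.seed(8)
  n <- 80
  v <- rnorm(n); v <- v / sqrt(sum(v^2))
  A <- diag(n) + 5 * tcrossprod(v)
  g <- new("GRM", values = A, nMarkers = matrix(100, n, n),
           ids = sprintf("i%02d", 1:n))
  pcs <- grmPrincipalComponents(g, 2)
  # PC1 recovers v up to sign (sign fixed internally)
  align <- abs(sum(pcs[, 1] * v))
  expect_gt(align, 1 - 1e-8)
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])), 1e-8)
  expect_true(attr(pcs, "informative"))

  # identity GRM: flat spectrum flagged uninformative
  gI <- new("GRM", values = diag(n), nMarkers = matrix(100, n, n),
            ids = sprintf("i%02d", 1:n))
  pcsI <- grmPrincipalComponents(gI, 2)
  expect_false(attr(pcsI, "informative"))
  expect_error(grmPrincipalComponents(g, 0), "positive")
})

test_that("GCTA binary GRM round-trip is lossless at float32 precision", {
  fx <- smallCohort()
  g <- fx$grm
  prefix <- file.path(tempdir(), "rt")
  writeGRM(g, prefix)
  back <- readGRM(prefix)
  expect_identical(individualIds(back), individualIds(g))
  expect_lt(max(abs(grmValues(back) - grmValues(g))), 1e-6)
  expect_lt(max(abs(grmMarkerCounts(back) - grmMarkerCounts(g))), 0.5)

  # n = 2 triangle holds exactly 3 float32 records
  A2 <- rbind(c(1.0, 0.02), c(0.02, 0.98))
  g2 <- new("GRM", values = A2, nMarkers = matrix(50, 2, 2),
            ids = c("x", "y"))
  p2 <- file.path(tempdir(), "tiny")
  writeGRM(g2, p2)
  expect_equal(file.info(paste0(p2, ".grm.bin"))$size, 3 * 4)

  # truncated binary file raises a size-mismatch error naming both sides
  bin <- paste0(prefix, ".grm.bin")
  raw <- readBin(bin, "raw", file.info(bin)$size)
  writeBin(raw[1:(length(raw) - 8)], bin)
  expect_error(readGRM(prefix), "size mismatch")
})

test_that("PLINK bed/bim/fam round-trip preserves dosages and missingness", {
  set.seed(3)
  d <- matrix(sample(c(0, 1, 2, NA), 37 * 11, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 37, 11)
  gt <- genotypeMatrix(d)
  prefix <- file.path(tempdir(), "plink")
  writePlink(gt, prefix)
  back <- readPlink(prefix)
  expect_identical(dosages(back), dosages(gt))
  expect_identical(snpInfo(back)$id, snpInfo(gt)$id)
})
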