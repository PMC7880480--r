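#' SNP quality control
#'
#' Removes SNPs failing minor-allele-frequency, call-rate or Hardy-Weinberg
#' filters, with per-criterion removal counts attached as attribute
#' `qcLog`. Defaults follow common practice for GRM construction: MAF >= 1%,
#' call rate >= 99%, HWE p >= 5e-7.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param mafMin minimum minor-allele frequency (exclusive threshold is
#'   `maf < mafMin`).
#' @param callRateMin minimum per-SNP call rate.
#' @param hweMin minimum HWE test p-value; the test is a 1-df chi-square on
#'   observed genotype counts against Hardy-Weinberg expectations (see
#'   [hweChiSq()]).
#' @return filtered [GenotypeMatrix-class]; errors if nothing survives.
#' @export
qcFilter <- function(genotypes, mafMin = 0.01, callRateMin = 0.99,
                     hweMin = 5e-7) {
  stopifnot(is(genotypes, "GenotypeMatrix"),
            mafMin > 0, mafMin < 1, callRateMin > 0, callRateMin <= 1,
            hweMin > 0, hweMin < 1)
  d <- dosages(genotypes)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  callRate <- colMeans(!is.na(d))
  hweP <- hweChiSq(d)
  failMaf <- maf < mafMin | is.na(maf)
  failCall <- callRate < callRateMin
  failHwe <- !is.na(hweP) & hweP < hweMin
  keep <- !(failMaf | failCall | failHwe)
  if (!any(keep)) stop("QC removed all SNPs")
  out <- genotypeMatrix(d[, keep, drop = FALSE],
                        snpInfo(genotypes)[keep, , drop = FALSE])
  attr(out, "qcLog") <- c(input = ncol(d), failMaf = sum(failMaf),
                          failCallRate = sum(failCall),
                          failHwe = sum(failHwe), retained = sum(keep))
  out
}

#' Hardy-Weinberg 1-df chi-square test per SNP
#'
#' Compares observed genotype counts (n0, n1, n2) against Hardy-Weinberg
#' expectations at the sample allele frequency; 1 degree of freedom.
#'
#' @param d dosage matrix (individuals x SNPs).
#' @return per-SNP p-values (NA for monomorphic SNPs).
#' @export
hweChiSq <- function(d) {
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  stat <- ifelse(p > 0 & p < 1,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2,
                 NA_real_)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Compute the genomic-relationship matrix
#'
#' Standard GRM estimator on centred, variance-standardized dosages:
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#' {2 p_i (1 - p_i)}}
#' Missing dosages are excluded pairwise; the per-pair marker counts
#' \eqn{M_{jk}} are retained (the `.grm.N.bin` convention).
#'
#' @param genotypes post-QC [GenotypeMatrix-class]; monomorphic SNPs raise an
#'   error (they should have been filtered).
#' @return a [GRM-class].
#' @export
computeGRM <- function(genotypes) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  d <- dosages(genotypes)
  if (ncol(d) < 1) stop("at least one SNP required")
  p <- colMeans(d, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP encountered; run qcFilter first")
  W <- sweep(d, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(W)
  W[!obs] <- 0
  counts <- tcrossprod(obs * 1)
  A <- tcrossprod(W) / counts
  A <- (A + t(A)) / 2
  new("GRM", values = A, nMarkers = counts, ids = rownames(d))
}

#' Prune related individuals from a GRM
#'
#' Greedy removal until no off-diagonal relationship is at or above the
#' cutoff: repeatedly drop the individual participating in the most violating
#' pairs (ties broken by input order). The post-condition (all remaining
#' off-diagonals < cutoff) is guaranteed; the selection heuristic is a
#' documented choice.
#'
#' @param grm a [GRM-class].
#' @param cutoff relatedness threshold (default 0.05, i.e. keep "unrelated"
#'   individuals with relatedness < 0.05).
#' @return the pruned [GRM-class]; removed IDs are in attribute `removed`.
#' @export
pruneRelated <- function(grm, cutoff = 0.05) {
  stopifnot(is(grm, "GRM"), cutoff > 0)
  A <- grmValues(grm)
  n <- nrow(A)
  viol <- A >= cutoff
  diag(viol) <- FALSE
  active <- rep(TRUE, n)
  removed <- integer(0)
  deg <- rowSums(viol)
  while (any(deg[active] > 0)) {
    cand <- which(active & deg == max(deg[active]))[1]
    active[cand] <- FALSE
    removed <- c(removed, cand)
    hit <- which(viol[cand, ] & active)
    deg[hit] <- deg[hit] - 1L
    deg[cand] <- 0L
  }
  keep <- which(active)
  out <- new("GRM", values = A[keep, keep, drop = FALSE],
             nMarkers = grmMarkerCounts(grm)[keep, keep, drop = FALSE],
             ids = grm@ids[keep])
  attr(out, "removed") <- grm@ids[removed]
  out
}

#' Principal components of a GRM
#'
#' Top-k eigenvectors of the relationship matrix, used as ancestry
#' covariates. Deterministic up to sign; the sign is fixed so each
#' component's largest-magnitude loading is positive. When the eigenvalue
#' spectrum is (numerically) flat -- e.g. an identity GRM -- the scores carry
#' no ancestry information and attribute `informative` is set FALSE.
#'
#' @param grm a [GRM-class].
#' @param k number of components (1 <= k <= n).
#' @return n x k matrix of PC scores (unit-norm eigenvectors), rownames =
#'   individual IDs; eigenvalues in attribute `eigenvalues`.
#' @export
grmPrincipalComponents <- function(grm, k = 2) {
  stopifnot(is(grm, "GRM"))
  if (k <= 0) stop("k must be positive")
  A <- grmValues(grm)
  n <- nrow(A)
  if (k > n) stop("k exceeds the number of individuals")
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- grm@ids
  colnames(V) <- paste0("PC", seq_len(k))
  attr(V, "eigenvalues") <- e$values[seq_len(k)]
  attr(V, "informative") <- sd(e$values) > 1e-8
  V
}

#' Read / write GCTA binary GRM triplets
#'
#' The GCTA interchange format: `prefix.grm.bin` (float32 lower triangle
#' including the diagonal, pair (i, j) with j <= i in row-major order),
#' `prefix.grm.N.bin` (float32 per-pair marker counts, same order) and
#' `prefix.grm.id` (two whitespace columns, FID IID).
#'
#' @param grm a [GRM-class] (for writing).
#' @param prefix path prefix for the three files.
#' @return `readGRM` returns a [GRM-class]; `writeGRM` returns the prefix
#'   invisibly. A size mismatch between the ID count and the stored triangle
#'   raises an error naming both.
#' @export
writeGRM <- function(grm, prefix) {
  stopifnot(is(grm, "GRM"))
  A <- grmValues(grm); Nm <- grmMarkerCounts(grm)
  n <- nrow(A)
  lt <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]  # row-major (i, j<=i)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(A[lt]), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(Nm[lt]), con, size = 4)
  close(con)
  write.table(data.frame(grm@ids, grm@ids), paste0(prefix, ".grm.id"),
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname writeGRM
#' @export
readGRM <- function(prefix) {
  idFile <- paste0(prefix, ".grm.id")
  ids <- read.table(idFile, stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  nt <- n * (n + 1) / 2
  binFile <- paste0(prefix, ".grm.bin")
  sz <- file.info(binFile)$size
  if (is.na(sz) || sz != 4 * nt)
    stop(sprintf(
      "GRM size mismatch: %s lists %d individuals (triangle of %d float32 = %d bytes) but %s has %s bytes",
      idFile, n, nt, 4 * nt, binFile, ifelse(is.na(sz), "no", sz)))
  con <- file(binFile, "rb")
  vals <- readBin(con, "numeric", n = nt, size = 4)
  close(con)
  nFile <- paste0(prefix, ".grm.N.bin")
  counts <- rep(NA_real_, nt)
  if (file.exists(nFile)) {
    con <- file(nFile, "rb")
    counts <- readBin(con, "numeric", n = nt, size = 4)
    close(con)
    if (length(counts) != nt)
      stop(sprintf("GRM size mismatch: expected %d marker-count records in %s, found %d",
                   nt, nFile, length(counts)))
  }
  A <- matrix(0, n, n); Nm <- matrix(0, n, n)
  lt <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  A[lt] <- vals; Nm[lt] <- counts
  A[lt[, c(2, 1)]] <- vals; Nm[lt[, c(2, 1)]] <- counts
  new("GRM", values = A, nMarkers = Nm, ids = as.character(ids))
}

#' Read / write PLINK bed/bim/fam genotype files
#'
#' SNP-major PLINK 1 binary format (magic bytes 0x6c 0x1b, mode 0x01). Two
#' bits per individual: 00 = homozygous A1 (dosage 2), 10 = heterozygous,
#' 11 = homozygous A2 (dosage 0), 01 = missing.
#'
#' @param genotypes a [GenotypeMatrix-class] (for writing).
#' @param prefix path prefix for the .bed/.bim/.fam files.
#' @return `readPlink` returns a [GenotypeMatrix-class]; `writePlink` the
#'   prefix, invisibly.
#' @export
writePlink <- function(genotypes, prefix) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  d <- dosages(genotypes)
  n <- nrow(d); M <- ncol(d)
  info <- snpInfo(genotypes)
  write.table(data.frame(info$chr, info$id, 0, info$pos, info$a1, info$a2),
              paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  write.table(data.frame(rownames(d), rownames(d), 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  # dosage (A1 count) -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(3L, n, M)
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[is.na(d)] <- 1L
  bytesPerSnp <- ceiling(n / 4)
  pad <- bytesPerSnp * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, M))
  i1 <- seq(1, nrow(code), by = 4)
  packed <- code[i1, , drop = FALSE] + 4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] + 64L * code[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(packed), con)
  close(con)
  invisible(prefix)
}

#' @rdname writePlink
#' @export
readPlink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam); M <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    close(con)
    stop("not a SNP-major PLINK v1.00 bed file")
  }
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytesPerSnp * M)
  close(con)
  b <- as.integer(raw)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4 * bytesPerSnp, M)
  codes <- codes[seq_len(n), , drop = FALSE]
  d <- matrix(NA_real_, n, M)
  d[codes == 0L] <- 2; d[codes == 2L] <- 1; d[codes == 3L] <- 0
  rownames(d) <- as.character(fam[[2]])
  colnames(d) <- as.character(bim[[2]])
  genotypeMatrix(d, data.frame(chr = bim[[1]], id = bim[[2]], pos = bim[[4]],
                               a1 = bim[[5]], a2 = bim[[6]],
                               stringsAsFactors = FALSE))
}

#' Eigendecomposition of a GRM (cached fast path)
#'
#' REML and GSEM fits on complete data reduce to O(n) per-iteration work in
#' the GRM eigenbasis; precomputing the decomposition once lets many
#' phenotype replicates share it.
#'
#' @param grm a [GRM-class].
#' @return list with `values`, `vectors`, `ids` (as `eigen`, plus IDs).
#' @export
grmEigen <- function(grm) {
  e <- eigen(grmValues(grm), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, ids = grm@ids)
}

#' Subset a GRM to a set of individual IDs
#'
#' @param grm a [GRM-class].
#' @param ids character IDs to keep (order preserved as given).
#' @return the subset [GRM-class].
#' @export
subsetGRM <- function(grm, ids) {
  idx <- match(ids, grm@ids)
  if (anyNA(idx)) stop("IDs not present in GRM: ",
                       paste(head(ids[is.na(idx)], 5), collapse = ", "))
  new("GRM", values = grmValues(grm)[idx, idx, drop = FALSE],
      nMarkers = grmMarkerCounts(grm)[idx, idx, drop = FALSE],
      ids = grm@ids[idx])
}
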