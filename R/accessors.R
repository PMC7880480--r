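#' Accessors for gsemkit data classes
#'
#' Small accessor functions used throughout the package in preference to
#' direct slot access.
#'
#' @param x object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
dosages <- function(x) x@dosages

#' @rdname accessors
#' @export
snpInfo <- function(x) x@snpInfo

#' @rdname accessors
#' @export
individualIds <- function(x) {
  if (is(x, "GRM")) return(x@ids)
  if (is(x, "CovariateTable")) return(x@ids)
  rownames(x@values %||% x@dosages)
}

#' @rdname accessors
#' @export
grmValues <- function(x) x@values

#' @rdname accessors
#' @export
grmMarkerCounts <- function(x) x@nMarkers

#' @rdname accessors
#' @export
phenoValues <- function(x) x@values

#' @rdname accessors
#' @export
traitNames <- function(x) {
  if (is(x, "PhenotypeTable")) return(colnames(x@values))
  if (is(x, "SimulationSpec")) return(x@traitNames)
  if (is(x, "CholeskyModel")) return(rownames(x@gamma))
  stop("no trait names for class ", class(x))
}

#' @rdname accessors
#' @export
traitAges <- function(x) x@traitAges

#' @rdname accessors
#' @export
gammaPaths <- function(x) {
  if (is(x, "GsemFit")) x@model@gamma else x@gamma
}

#' @rdname accessors
#' @export
epsilonPaths <- function(x) {
  if (is(x, "GsemFit")) x@model@epsilon else x@epsilon
}

#' @rdname accessors
#' @export
nTraits <- function(x) {
  if (is(x, "PhenotypeTable")) return(ncol(x@values))
  if (is(x, "CholeskyModel")) return(nrow(x@gamma))
  if (is(x, "GsemFit")) return(nrow(x@model@gamma))
  if (is(x, "SimulationSpec")) return(nrow(x@gamma))
  stop("no trait count for class ", class(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a GenotypeMatrix
#'
#' @param dosages n x M dosage matrix (0/1/2/NA). Row and column names are
#'   used as individual and SNP IDs; defaults are generated when absent.
#' @param snpInfo optional data.frame with columns chr, id, pos, a1, a2.
#' @return a [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(dosages, snpInfo = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind%04d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp%05d", seq_len(ncol(dosages)))
  if (is.null(snpInfo))
    snpInfo <- data.frame(chr = 1L, id = colnames(dosages),
                          pos = seq_len(ncol(dosages)), a1 = "A", a2 = "G",
                          stringsAsFactors = FALSE)
  new("GenotypeMatrix", dosages = dosages, snpInfo = snpInfo)
}

#' Allele frequencies from non-missing dosages
#'
#' Frequency of the counted (A1) allele per SNP, estimated from the sample
#' itself.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @return numeric vector of per-SNP allele frequencies.
#' @export
alleleFrequencies <- function(genotypes) {
  colMeans(dosages(genotypes), na.rm = TRUE) / 2
}

#' Construct a PhenotypeTable
#'
#' @param values n x m numeric matrix (NA = missing); rownames are individual
#'   IDs, colnames trait labels in chronological model order.
#' @param traitAges numeric vector of mean assessment ages (months).
#' @return a [PhenotypeTable-class].
#' @export
phenotypeTable <- function(values, traitAges = rep(NA_real_, ncol(values))) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ind%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("trait%d", seq_len(ncol(values)))
  new("PhenotypeTable", values = values, traitAges = traitAges)
}

#' Construct a CholeskyModel
#'
#' @param gamma lower-triangular genetic path matrix.
#' @param epsilon lower-triangular residual path matrix.
#' @param traitNames optional trait labels (row/col names).
#' @return a [CholeskyModel-class].
#' @export
choleskyModel <- function(gamma, epsilon, traitNames = NULL) {
  gamma <- as.matrix(gamma); epsilon <- as.matrix(epsilon)
  if (!is.null(traitNames)) {
    dimnames(gamma) <- list(traitNames, paste0("A", seq_len(ncol(gamma))))
    dimnames(epsilon) <- list(traitNames, paste0("E", seq_len(ncol(epsilon))))
  }
  new("CholeskyModel", gamma = gamma, epsilon = epsilon)
}

#' Per-trait observed counts
#'
#' @param phenotypes a [PhenotypeTable-class].
#' @return named integer vector of non-missing counts per trait.
#' @export
observedCounts <- function(phenotypes) {
  colSums(!is.na(phenoValues(phenotypes)))
}
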