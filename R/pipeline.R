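#' Pipeline configuration
#'
#' Bundles every knob of the two-stage analysis: the simulation spec (or
#' input file prefixes), QC thresholds, the relatedness cutoff, screening
#' alpha, trait order, covariate recipes, output directory and master seed.
#' The configuration is serialized (YAML) into every output directory for
#' provenance.
#'
#' @param spec a [SimulationSpec-class] for simulated cohorts, or NULL when
#'   loading from files.
#' @param plinkPrefix,phenFile optional input paths (used when `spec` is
#'   NULL): PLINK bed/bim/fam prefix and a GCTA-style phenotype file.
#' @param mafMin,callRateMin,hweMin SNP QC thresholds.
#' @param relatednessCutoff pairwise pruning threshold (default 0.05).
#' @param alpha heritability-screening significance level.
#' @param nPCs ancestry principal components to adjust for.
#' @param recipeKinds per-trait covariate recipe kinds (see
#'   [covariateRecipe()]).
#' @param outcomeTraits trait labels reserved for Stage 2 (excluded from the
#'   Stage-1 model; must be the last columns chronologically).
#' @param outDir output directory (NULL = no files written).
#' @param seed master seed.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(spec = simulationSpec(),
                           plinkPrefix = NULL, phenFile = NULL,
                           mafMin = 0.01, callRateMin = 0.99, hweMin = 5e-7,
                           relatednessCutoff = 0.05, alpha = 0.05,
                           nPCs = 2, recipeKinds = NULL,
                           outcomeTraits = character(0), outDir = NULL,
                           seed = 1L) {
  stopifnot(mafMin > 0, mafMin < 1, callRateMin > 0, callRateMin <= 1,
            hweMin > 0, hweMin < 1, relatednessCutoff > 0,
            alpha > 0, alpha < 1, nPCs >= 0)
  cfg <- list(spec = spec, plinkPrefix = plinkPrefix, phenFile = phenFile,
              mafMin = mafMin, callRateMin = callRateMin, hweMin = hweMin,
              relatednessCutoff = relatednessCutoff, alpha = alpha,
              nPCs = nPCs, recipeKinds = recipeKinds,
              outcomeTraits = outcomeTraits, outDir = outDir,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run Stage 1: screened multivariate Cholesky fit
#'
#' End-to-end: simulate or load the cohort, SNP QC, GRM construction,
#' relatedness pruning, ancestry PCs, covariate adjustment, rank-based
#' inverse normal transformation, univariate GREML screening (traits with
#' LRT p >= alpha are excluded and logged), then the saturated Cholesky GSEM
#' on the surviving traits in chronological order, with derived statistics.
#' Every run is reproducible from the config seed; when `outDir` is set the
#' config snapshot, a per-stage log and TSV report tables are written.
#'
#' @param config a [pipelineConfig()].
#' @return list with `fit` ([GsemFit-class]), `derived`
#'   ([derivedSummary()]), `greml` (per-trait univariate fits), `screen`
#'   (retained labels + exclusions), `grm`, `phenotypes` (prepared), `log`
#'   (character vector of per-stage counts).
#' @export
runStage1 <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  prep <- preparePipelineData(config)
  log <- prep$log

  allFits <- prep$gremlFits
  stage1Names <- setdiff(names(allFits), config$outcomeTraits)
  fits <- allFits[stage1Names]
  keep <- screenHeritability(fits, config$alpha)
  excl <- attr(keep, "excluded")
  if (nrow(excl))
    log <- c(log, sprintf("screening: excluded %s (LRT p = %.3g)",
                          excl$trait, excl$lrtP))
  log <- c(log, sprintf("screening: %d of %d traits retained",
                        length(keep), length(fits)))
  if (length(keep) < 2)
    stop("fewer than 2 traits survive heritability screening")

  Y <- phenoValues(prep$phenotypes)[, keep, drop = FALSE]
  pt <- phenotypeTable(Y, traitAges = traitAges(prep$phenotypes)[
    match(keep, traitNames(prep$phenotypes))])
  fit <- fitGsem(prep$grm, pt, eig = if (anyNA(Y)) NULL else prep$eig)
  rp <- phenotypicCorrelations(pt)
  derived <- derivedSummary(fit, rp = rp)
  log <- c(log, sprintf("stage1: fitted %d-variate Cholesky model, logL = %.4f",
                        ncol(Y), fit@loglik))

  if (!is.null(config$outDir))
    writeStageOutputs(config, fit, derived, log, "stage1")
  list(fit = fit, derived = derived, greml = allFits, screen = keep,
       grm = prep$grm, phenotypes = prep$phenotypes, eig = prep$eig,
       log = log)
}

#' Run Stage 2: extend with each mid-childhood outcome in turn
#'
#' For every outcome trait, refits the full (m+1)-variate Cholesky model
#' with the outcome appended last (fresh saturated fit, not a constrained
#' update), after screening the outcome for heritability evidence. Produces
#' a comparative table of the outcome's loadings on each genetic factor, a
#' full per-path table and a "significant paths" view (Wald p < 0.05).
#'
#' @param stage1 result of [runStage1()].
#' @param outcomes named list of outcome vectors (named numeric, NA =
#'   missing) already adjusted/transformed, a [PhenotypeTable-class] of
#'   outcome columns, or NULL to use the config's `outcomeTraits` columns of
#'   the prepared Stage-1 table.
#' @param config the [pipelineConfig()] used for stage 1.
#' @return list with per-outcome `fits`, `derived`, a `comparison` table of
#'   outcome loadings and the updated `log`.
#' @export
runStage2 <- function(stage1, outcomes = NULL, config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(outcomes)) {
    Yall <- phenoValues(stage1$phenotypes)
    miss <- setdiff(config$outcomeTraits, colnames(Yall))
    if (length(miss)) stop("outcome traits not in prepared data: ",
                           paste(miss, collapse = ", "))
    outcomes <- lapply(config$outcomeTraits, function(nm)
      setNames(Yall[, nm], rownames(Yall)))
    names(outcomes) <- config$outcomeTraits
  }
  if (is(outcomes, "PhenotypeTable")) {
    Y <- phenoValues(outcomes)
    outcomes <- lapply(seq_len(ncol(Y)), function(j)
      setNames(Y[, j], rownames(Y)))
    names(outcomes) <- colnames(Y)
  }
  keep <- stage1$screen
  Y1 <- phenoValues(stage1$phenotypes)[, keep, drop = FALSE]
  base <- phenotypeTable(Y1)
  log <- character(0)
  fits <- list(); derived <- list(); comparison <- NULL
  for (nm in names(outcomes)) {
    y <- outcomes[[nm]]
    uf <- fitUnivariateGreml(stage1$grm, y,
                             eig = if (anyNA(y)) NULL else stage1$eig)
    if (is.na(uf@lrtP) || uf@lrtP >= config$alpha) {
      log <- c(log, sprintf("stage2: outcome %s excluded (LRT p = %.3g)",
                            nm, uf@lrtP))
      next
    }
    f <- stage2Extend(stage1$grm, base, y, outcomeName = nm)
    m <- nTraits(f)
    rp <- phenotypicCorrelations(phenotypeTable(
      cbind(Y1, y[match(rownames(Y1), names(y))])))
    d <- derivedSummary(f, rp = rp)
    fits[[nm]] <- f; derived[[nm]] <- d
    comparison <- rbind(comparison,
                        data.frame(outcome = nm,
                                   factor = paste0("A", seq_len(m)),
                                   loading = gammaPaths(f)[m, ],
                                   se = f@seGamma[m, ],
                                   waldP = f@waldGamma[m, ]))
    log <- c(log, sprintf("stage2: %s fitted (%d traits, logL = %.4f)",
                          nm, m, f@loglik))
    if (!is.null(config$outDir))
      writeStageOutputs(config, f, d, log, paste0("stage2_", nm))
  }
  list(fits = fits, derived = derived, comparison = comparison, log = log)
}

# simulate/load, QC, GRM, prune, PCs, adjust, transform, univariate GREML
preparePipelineData <- function(config) {
  log <- character(0)
  if (!is.null(config$spec)) {
    cohort <- simulateCohort(config$spec)
    gt <- cohort$genotypes; ph <- cohort$phenotypes
    covar <- cohort$covariates
    log <- c(log, sprintf("simulated cohort: n = %d, M = %d",
                          nrow(dosages(gt)), ncol(dosages(gt))))
  } else {
    if (is.null(config$plinkPrefix) || is.null(config$phenFile))
      stop("either a simulation spec or input paths are required")
    gt <- readPlink(config$plinkPrefix)
    ph <- readPhen(config$phenFile)
    n <- nrow(dosages(gt))
    covar <- new("CovariateTable", sex = rep(NA_real_, n),
                 age = matrix(NA_real_, n, 0), pcs = matrix(0, n, 0),
                 ids = rownames(dosages(gt)))
    log <- c(log, sprintf("loaded cohort: n = %d, M = %d", n,
                          ncol(dosages(gt))))
  }
  gtQC <- qcFilter(gt, config$mafMin, config$callRateMin, config$hweMin)
  qcLog <- attr(gtQC, "qcLog")
  log <- c(log, sprintf(
    "QC: %d SNPs in, %d removed (MAF %d, call rate %d, HWE %d), %d retained",
    qcLog["input"], qcLog["input"] - qcLog["retained"], qcLog["failMaf"],
    qcLog["failCallRate"], qcLog["failHwe"], qcLog["retained"]))

  grm <- computeGRM(gtQC)
  grm <- pruneRelated(grm, config$relatednessCutoff)
  removed <- attr(grm, "removed")
  log <- c(log, sprintf("GRM: %d individuals after pruning (%d removed at cutoff %.3f)",
                        length(grm@ids), length(removed),
                        config$relatednessCutoff))

  # intersect GRM and phenotype individuals
  ids <- intersect(grm@ids, rownames(phenoValues(ph)))
  grm <- subsetGRM(grm, ids)
  Y <- phenoValues(ph)[ids, , drop = FALSE]
  ph <- phenotypeTable(Y, traitAges = traitAges(ph))
  covar@pcs <- matrix(0, length(ids), 0)
  keepIdx <- match(ids, covar@ids)
  covar <- new("CovariateTable", sex = covar@sex[keepIdx],
               age = covar@age[keepIdx, , drop = FALSE],
               pcs = matrix(0, length(ids), 0), ids = ids)
  log <- c(log, sprintf("intersection: %d individuals with genotypes and phenotypes",
                        length(ids)))

  if (config$nPCs > 0) {
    pcs <- grmPrincipalComponents(grm, config$nPCs)
    covar <- setPCs(covar, pcs)
  }
  kinds <- config$recipeKinds %||% rep("earlylife", ncol(Y))
  recipe <- if (all(is.na(covar@sex))) list()
            else covariateRecipe(colnames(Y), kinds)
  adj <- adjustCovariates(ph, covar, recipe)
  trans <- rankTransformTable(adj)
  log <- c(log, sprintf("prep: adjusted and rank-transformed %d traits (n per trait: %s)",
                        ncol(Y), paste(observedCounts(trans), collapse = "/")))

  eig <- grmEigen(grm)
  fits <- lapply(seq_len(ncol(Y)), function(j) {
    y <- phenoValues(trans)[, j]
    names(y) <- rownames(phenoValues(trans))
    fitUnivariateGreml(grm, y, eig = if (anyNA(y)) NULL else eig)
  })
  names(fits) <- colnames(Y)
  for (j in seq_along(fits))
    log <- c(log, sprintf("GREML %s: h2 = %.3f (SE %.3f), LRT p = %.3g",
                          names(fits)[j], fits[[j]]@h2[1], fits[[j]]@h2SE[1],
                          fits[[j]]@lrtP))
  list(grm = grm, phenotypes = trans, covariates = covar, gremlFits = fits,
       eig = eig, log = log)
}

# config snapshot + log + per-path and derived TSVs
writeStageOutputs <- function(config, fit, derived, log, stage) {
  dir <- file.path(config$outDir, stage)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$spec <- if (!is.null(config$spec)) specAsList(config$spec) else NULL
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "config.yaml"))
  writeLines(log, file.path(dir, "run.log"))
  writePathTable(fit, file.path(dir, "paths_full.tsv"))
  writePathTable(fit, file.path(dir, "paths_significant.tsv"), alpha = 0.05)
  writeDerivedReport(derived, dir, prefix = "derived")
  writeLines(pathDiagramText(fit), file.path(dir, "path_diagram.txt"))
  invisible(dir)
}

specAsList <- function(spec) {
  list(nIndividuals = spec@nIndividuals, nSnps = spec@nSnps,
       mafRange = spec@mafRange, gamma = apply(spec@gamma, 1, paste,
                                               collapse = ","),
       epsilon = apply(round(spec@epsilon, 6), 1, paste, collapse = ","),
       traitNames = spec@traitNames,
       missingFraction = spec@missingFraction, seed = spec@seed)
}

#' Per-path estimate table of a fitted model
#'
#' One row per free path (genetic triangle then residual triangle) with
#' estimate, SE and Wald p. With `alpha` set, only paths with p < alpha are
#' retained (the "significant paths" view); the full table keeps everything.
#'
#' @param fit a [GsemFit-class].
#' @param path optional TSV output file.
#' @param alpha optional Wald p threshold for the filtered view.
#' @return data.frame (invisibly when writing).
#' @export
writePathTable <- function(fit, path = NULL, alpha = NULL) {
  m <- nTraits(fit)
  g <- gammaPaths(fit); e <- epsilonPaths(fit)
  rows <- NULL
  for (i in seq_len(m)) for (j in seq_len(i)) {
    rows <- rbind(rows,
      data.frame(path = sprintf("a%d%d", i, j), trait = rownames(g)[i] %||% i,
                 factor = paste0("A", j), estimate = g[i, j],
                 se = fit@seGamma[i, j], waldP = fit@waldGamma[i, j]),
      data.frame(path = sprintf("e%d%d", i, j), trait = rownames(g)[i] %||% i,
                 factor = paste0("E", j), estimate = e[i, j],
                 se = fit@seEpsilon[i, j], waldP = fit@waldEpsilon[i, j]))
  }
  if (!is.null(alpha)) rows <- rows[!is.na(rows$waldP) & rows$waldP < alpha, ]
  if (!is.null(path)) {
    out <- rows
    out$estimate <- sprintf("%.6f", out$estimate)
    out$se <- sprintf("%.6f", out$se)
    out$waldP <- sprintf("%.6g", out$waldP)
    write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
    return(invisible(rows))
  }
  rows
}

#' Plain-text path diagram of a fitted Cholesky model
#'
#' Keyed A1..Am / E1..Em, one line per nonzero path.
#'
#' @param fit a [GsemFit-class].
#' @return character vector of lines.
#' @export
pathDiagramText <- function(fit) {
  m <- nTraits(fit)
  g <- gammaPaths(fit); e <- epsilonPaths(fit)
  traits <- rownames(g) %||% paste0("P", seq_len(m))
  lines <- sprintf("Cholesky model: %d traits, logL = %.4f", m, fit@loglik)
  for (j in seq_len(m)) for (i in j:m)
    lines <- c(lines, sprintf("A%d -> %-20s %7.4f", j, traits[i], g[i, j]))
  for (j in seq_len(m)) for (i in j:m)
    lines <- c(lines, sprintf("E%d -> %-20s %7.4f", j, traits[i], e[i, j]))
  lines
}
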