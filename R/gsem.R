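# Cholesky GSEM: maximum likelihood for the stacked multivariate phenotype
# with covariance (GG' x A) + (EE' x I), where G and E are lower-triangular
# genetic and residual path matrices, A the GRM and x the Kronecker product
# over (trait, individual). Two evaluation routes:
#   * complete data: rotate by the GRM eigenbasis; the likelihood factorizes
#     over eigenvalues into m-dimensional Gaussians, O(n m^2) per evaluation
#     after simultaneous diagonalization of EE' and GG';
#   * missing data: select observed rows/columns of the dense stacked
#     covariance (all available observations enter; no casewise deletion).

lowerTriIndex <- function(m) which(lower.tri(diag(m), diag = TRUE))

modelToPar <- function(model) {
  idx <- lowerTriIndex(nrow(model@gamma))
  c(model@gamma[idx], model@epsilon[idx])
}

parToModel <- function(par, m, traitNames = NULL) {
  idx <- lowerTriIndex(m)
  k <- length(idx)
  gamma <- matrix(0, m, m); epsilon <- matrix(0, m, m)
  gamma[idx] <- par[seq_len(k)]
  epsilon[idx] <- par[k + seq_len(k)]
  choleskyModel(gamma, epsilon, traitNames)
}

#' GSEM log-likelihood
#'
#' Gaussian log-likelihood (mean fixed at zero) of the observed entries of a
#' standardized multivariate phenotype under the Cholesky model: covariance
#' formed by selecting observed rows/columns of
#' (gamma gamma' over the GRM) + (epsilon epsilon' over the identity).
#' Returns `-Inf` (optimizer-safe) when the implied covariance is not
#' positive definite at the evaluation point.
#'
#' @param model a [CholeskyModel-class].
#' @param grm a [GRM-class] (or NULL with `eig` supplied for complete data).
#' @param phenotypes a [PhenotypeTable-class], trait order matching the
#'   model; individuals matched to the GRM by ID.
#' @param eig optional cached [grmEigen()].
#' @return scalar log-likelihood.
#' @export
gsemLoglik <- function(model, grm, phenotypes, eig = NULL) {
  stopifnot(is(model, "CholeskyModel"), is(phenotypes, "PhenotypeTable"))
  prep <- gsemPrepare(grm, phenotypes, eig)
  if (prep$complete)
    gsemLoglikFast(model@gamma, model@epsilon, prep)
  else
    gsemLoglikDense(model@gamma, model@epsilon, prep)
}

# Align phenotypes to the GRM, choose the evaluation route, precompute.
gsemPrepare <- function(grm, phenotypes, eig = NULL) {
  Y <- phenoValues(phenotypes)
  ids <- rownames(Y)
  if (!is.null(eig) && length(ids) == length(eig$ids) && all(ids == eig$ids)) {
    lam <- eig$values; U <- eig$vectors; A <- NULL
  } else {
    if (is.null(grm)) stop("grm required when no matching eigendecomposition is supplied")
    if (!all(ids %in% grm@ids)) stop("GRM/phenotype ID mismatch")
    sub <- subsetGRM(grm, ids)
    A <- grmValues(sub)
    lam <- NULL; U <- NULL
  }
  complete <- !anyNA(Y)
  if (complete && is.null(lam)) {
    e <- eigen(A, symmetric = TRUE)
    lam <- e$values; U <- e$vectors
  }
  if (complete) {
    list(complete = TRUE, lam = lam, Z = crossprod(U, Y), n = nrow(Y),
         m = ncol(Y), nObs = colSums(!is.na(Y)),
         flatSpectrum = sd(lam) < 1e-8)
  } else {
    if (is.null(A)) {
      # reconstruct the aligned GRM from the eigendecomposition
      A <- U %*% (lam * t(U))
    }
    obs <- !is.na(Y)
    idxList <- lapply(seq_len(ncol(Y)), function(j) which(obs[, j]))
    yStack <- unlist(lapply(seq_len(ncol(Y)), function(j) Y[idxList[[j]], j]))
    list(complete = FALSE, A = A, idxList = idxList, yStack = yStack,
         n = nrow(Y), m = ncol(Y), nObs = colSums(obs),
         flatSpectrum = {
           ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
           sd(ev) < 1e-8
         })
  }
}

# Complete-data route: simultaneous diagonalization of EE' and GG'.
gsemLoglikFast <- function(gamma, epsilon, prep) {
  m <- prep$m; n <- prep$n
  G <- tcrossprod(gamma); E <- tcrossprod(epsilon)
  chE <- tryCatch(chol(E), error = function(e) NULL)
  if (is.null(chE)) return(-Inf)
  L <- t(chE)
  Li <- forwardsolve(L, diag(m))
  Mmat <- Li %*% G %*% t(Li)
  Mmat <- (Mmat + t(Mmat)) / 2
  ed <- eigen(Mmat, symmetric = TRUE)
  mu <- ed$values
  D <- 1 + outer(prep$lam, mu)
  if (any(D <= 0)) return(-Inf)
  W <- prep$Z %*% t(Li) %*% ed$vectors
  -0.5 * (n * m * log(2 * pi) + 2 * n * sum(log(diag(L))) + sum(log(D)) +
            sum(W^2 / D))
}

# Missing-data route: dense observed-block covariance.
gsemLoglikDense <- function(gamma, epsilon, prep) {
  G <- tcrossprod(gamma); E <- tcrossprod(epsilon)
  m <- prep$m
  idx <- prep$idxList
  sizes <- lengths(idx)
  N <- sum(sizes)
  off <- cumsum(c(0, sizes))
  V <- matrix(0, N, N)
  for (j in seq_len(m)) for (k in j:m) {
    blk <- G[j, k] * prep$A[idx[[j]], idx[[k]], drop = FALSE]
    same <- outer(idx[[j]], idx[[k]], "==")
    blk <- blk + E[j, k] * same
    rj <- (off[j] + 1):off[j + 1]; ck <- (off[k] + 1):off[k + 1]
    V[rj, ck] <- blk
    if (k > j) V[ck, rj] <- t(blk)
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  u <- backsolve(ch, prep$yStack, transpose = TRUE)
  -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
}

#' Fit a Cholesky GSEM by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization over the m(m+1) free paths. Default
#' starting values put sqrt(h2) and sqrt(1 - h2) from univariate GREML (or a
#' phenotypic fallback) on the diagonals and a small positive value (0.05)
#' on the off-diagonals to avoid the saddle at zero. Standard errors come
#' from the inverse numerical Hessian of the negative log-likelihood
#' (central differences, relative step 1e-4); Wald p-values are two-sided
#' normal. Sign identification: every whole-column sign flip leaves the
#' likelihood invariant, so fitted factors are reported with non-negative
#' diagonals.
#'
#' @param grm a [GRM-class].
#' @param phenotypes a [PhenotypeTable-class] of standardized residual
#'   traits in model (chronological) order.
#' @param start optional [CholeskyModel-class] of starting paths.
#' @param eig optional cached [grmEigen()] (complete data only).
#' @param se compute standard errors (numerical Hessian).
#' @param maxit optimizer iteration cap.
#' @return a [GsemFit-class].
#' @export
fitGsem <- function(grm, phenotypes, start = NULL, eig = NULL, se = TRUE,
                    maxit = 2000) {
  stopifnot(is(phenotypes, "PhenotypeTable"))
  m <- ncol(phenoValues(phenotypes))
  if (m < 1) stop("at least one trait required")
  prep <- gsemPrepare(grm, phenotypes, eig)
  if (prep$flatSpectrum)
    warning("GRM has a flat eigenvalue spectrum (identity-like); only the ",
            "total covariance is identified, not the genetic/residual split")
  labels <- colnames(phenoValues(phenotypes))

  if (is.null(start)) {
    h2 <- startingH2(grm, phenotypes, eig)
    gamma <- diag(sqrt(h2), m)
    epsilon <- diag(sqrt(1 - h2), m)
    lowOff <- lower.tri(gamma)
    gamma[lowOff] <- 0.05
    epsilon[lowOff] <- 0.05
    start <- choleskyModel(gamma, epsilon, labels)
  }
  par0 <- modelToPar(start)
  negll <- if (prep$complete)
    function(p) {
      md <- parToModel(p, m)
      -gsemLoglikFast(md@gamma, md@epsilon, prep)
    }
  else
    function(p) {
      md <- parToModel(p, m)
      -gsemLoglikDense(md@gamma, md@epsilon, prep)
    }
  if (!is.finite(negll(par0)))
    stop("starting model has a non-positive-definite implied covariance")
  gradll <- function(p) {
    k <- length(p)
    g <- numeric(k)
    h <- 1e-6 * pmax(abs(p), 1e-2)
    for (i in seq_len(k)) {
      pp <- p; pp[i] <- p[i] + h[i]
      pm <- p; pm[i] <- p[i] - h[i]
      g[i] <- (negll(pp) - negll(pm)) / (2 * h[i])
    }
    g
  }
  opt <- optim(par0, negll, gr = gradll, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0) {
    opt2 <- optim(opt$par, negll, gr = gradll, method = "BFGS",
                  control = list(maxit = maxit, reltol = 1e-14))
    if (opt2$value <= opt$value) opt <- opt2
  }
  par <- signFix(opt$par, m)
  model <- parToModel(par, m, labels)

  seG <- matrix(NA_real_, m, m); seE <- matrix(NA_real_, m, m)
  wG <- matrix(NA_real_, m, m); wE <- matrix(NA_real_, m, m)
  vc <- NULL; hcond <- NA_real_
  if (se) {
    H <- numericHessian(negll, par)
    hcond <- kappa(H, exact = FALSE)
    vc <- tryCatch({
      ch <- chol(H)
      chol2inv(ch)
    }, error = function(e) NULL)
    if (!is.null(vc)) {
      ses <- sqrt(pmax(diag(vc), 0))
      idx <- lowerTriIndex(m); k <- length(idx)
      seG[idx] <- ses[seq_len(k)]
      seE[idx] <- ses[k + seq_len(k)]
      zG <- model@gamma / seG; zE <- model@epsilon / seE
      wG[idx] <- 2 * pnorm(-abs(zG[idx]))
      wE[idx] <- 2 * pnorm(-abs(zE[idx]))
    } else {
      warning("Hessian not positive definite; standard errors suppressed")
    }
  }
  dimnames(seG) <- dimnames(wG) <- dimnames(model@gamma)
  dimnames(seE) <- dimnames(wE) <- dimnames(model@epsilon)
  new("GsemFit", model = model, seGamma = seG, seEpsilon = seE,
      waldGamma = wG, waldEpsilon = wE, vcov = vc,
      loglik = -opt$value, nObs = prep$nObs,
      converged = opt$convergence == 0,
      identifiable = !prep$flatSpectrum, hessianCondition = hcond)
}

# univariate GREML h2 per trait for starting values; phenotypic fallback
startingH2 <- function(grm, phenotypes, eig = NULL) {
  Y <- phenoValues(phenotypes)
  vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]; names(y) <- rownames(Y)
    h <- tryCatch({
      f <- fitUnivariateGreml(grm, y, eig = if (anyNA(y)) NULL else eig)
      if (is.na(f@h2[1])) 0.2 else f@h2[1]
    }, error = function(e) 0.2)
    min(max(h, 0.02), 0.95)
  }, numeric(1))
}

# flip whole factor columns so diagonals are non-negative
signFix <- function(par, m) {
  idx <- lowerTriIndex(m); k <- length(idx)
  gamma <- matrix(0, m, m); epsilon <- matrix(0, m, m)
  gamma[idx] <- par[seq_len(k)]; epsilon[idx] <- par[k + seq_len(k)]
  for (j in seq_len(m)) {
    if (gamma[j, j] < 0) gamma[, j] <- -gamma[, j]
    if (epsilon[j, j] < 0) epsilon[, j] <- -epsilon[, j]
  }
  c(gamma[idx], epsilon[idx])
}

# central-difference Hessian, relative step
numericHessian <- function(f, p, rel = 1e-4) {
  k <- length(p)
  h <- rel * pmax(abs(p), 1e-2)
  H <- matrix(0, k, k)
  f0 <- f(p)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        pp <- p; pp[i] <- p[i] + h[i]; fp <- f(pp)
        pm <- p; pm[i] <- p[i] - h[i]; fm <- f(pm)
        H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
      } else {
        ppp <- p; ppp[c(i, j)] <- p[c(i, j)] + h[c(i, j)]
        ppm <- p; ppm[i] <- p[i] + h[i]; ppm[j] <- p[j] - h[j]
        pmp <- p; pmp[i] <- p[i] - h[i]; pmp[j] <- p[j] + h[j]
        pmm <- p; pmm[c(i, j)] <- p[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(ppp) - f(ppm) - f(pmp) + f(pmm)) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' Extend a fitted context with a later-life outcome
#'
#' Appends the outcome as the last trait (chronological order) and refits the
#' full (m+1)-variate Cholesky model from scratch -- a fresh saturated fit,
#' not a constrained update of the earlier model.
#'
#' @param grm a [GRM-class].
#' @param phenotypes the earlier-trait [PhenotypeTable-class].
#' @param outcome named numeric vector (NA = missing) for the appended trait.
#' @param outcomeName trait label for the outcome.
#' @param ... passed to [fitGsem()].
#' @return a [GsemFit-class] over m + 1 traits.
#' @export
stage2Extend <- function(grm, phenotypes, outcome, outcomeName = "outcome",
                         ...) {
  Y <- phenoValues(phenotypes)
  if (is.null(names(outcome))) {
    if (length(outcome) != nrow(Y)) stop("unnamed outcome must match phenotype rows")
    names(outcome) <- rownames(Y)
  }
  newcol <- outcome[match(rownames(Y), names(outcome))]
  Y2 <- cbind(Y, newcol)
  colnames(Y2) <- c(colnames(Y), outcomeName)
  pt <- phenotypeTable(Y2, traitAges = c(traitAges(phenotypes), NA_real_))
  fitGsem(grm, pt, ...)
}

#' Model-implied genetic and residual covariance
#'
#' @param model a [CholeskyModel-class] or [GsemFit-class].
#' @return list with `genetic` (gamma gamma'), `residual`
#'   (epsilon epsilon') and `phenotypic` (their sum).
#' @export
impliedCovariance <- function(model) {
  g <- gammaPaths(model); e <- epsilonPaths(model)
  G <- tcrossprod(g); E <- tcrossprod(e)
  list(genetic = G, residual = E, phenotypic = G + E)
}
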