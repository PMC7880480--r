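# Average-information REML for variance components on a GRM.
#
# Univariate fits work in the GRM eigenbasis: with A = U D U' the covariance
# V = sgA + seI is diagonal after rotating by U', so each iteration is O(n)
# and an eigendecomposition can be shared across phenotype replicates.
# Bivariate fits use the dense stacked covariance (missingness-tolerant).

#' Univariate GREML fit
#'
#' Restricted maximum likelihood for V = varG * A + varE * I with fixed
#' effects X (default: intercept), by average-information iterations with
#' step-halving and boundary projection (varG constrained >= 0 unless
#' `constrain = FALSE`). Standard errors come from the inverse AI matrix at
#' the optimum; the h2 SE by the delta method; the p-value for varG = 0 from
#' the boundary likelihood-ratio test (0.5:0.5 mixture of a point mass and
#' chi-square 1).
#'
#' @param grm a [GRM-class] (may be NULL when `eig` is supplied and `y` is
#'   complete).
#' @param y named numeric vector of (standardized residual) trait values;
#'   names are individual IDs; NAs allowed (those individuals are dropped).
#' @param X optional fixed-effect design matrix (rows aligned to `y` after
#'   NA removal); default intercept only.
#' @param eig optional cached [grmEigen()] result for complete-data fits.
#' @param constrain keep varG, varE >= 1e-6 * phenotypic variance.
#' @param maxit,tol iteration cap and relative log-likelihood tolerance.
#' @return a [GremlFit-class].
#' @export
fitUnivariateGreml <- function(grm = NULL, y, X = NULL, eig = NULL,
                               constrain = TRUE, maxit = 100, tol = 1e-8) {
  if (is.null(names(y))) {
    ids <- if (!is.null(grm)) grm@ids else eig$ids
    if (length(y) != length(ids)) stop("unnamed y must match GRM length")
    names(y) <- ids
  }
  obs <- names(y)[!is.na(y)]
  if (length(obs) < 50) stop("univariate GREML needs n >= 50")
  useCache <- !is.null(eig) && length(obs) == length(eig$ids) &&
    all(obs == eig$ids)
  if (!useCache) {
    if (is.null(grm)) stop("grm required when eigendecomposition cache does not match")
    if (!all(obs %in% grm@ids)) stop("GRM/phenotype ID mismatch")
    eig <- grmEigen(subsetGRM(grm, obs))
  }
  yv <- as.numeric(y[obs])
  n <- length(yv)
  lam <- eig$values
  U <- eig$vectors
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  yt <- crossprod(U, yv)
  Xt <- crossprod(U, X)
  vp <- var(yv)
  floorVal <- 1e-6 * vp

  identifiable <- sd(lam) > 1e-8
  ll <- function(th) remlLoglikDiag(th[1] * lam + th[2], yt, Xt)
  # null model: V = varE I; REML variance from GLS( = OLS) residuals
  fit0 <- lm.fit(X, yv)
  s0 <- sum(fit0$residuals^2) / (n - q)
  l0 <- ll(c(0, s0))$loglik

  if (!identifiable) {
    warning("GRM has a (numerically) flat eigenvalue spectrum; ",
            "genetic and residual variance are not separately identifiable")
    return(new("GremlFit",
               components = c(varG = NA_real_, varE = s0),
               se = c(varG = NA_real_, varE = NA_real_),
               h2 = NA_real_, h2SE = NA_real_, rg = NA_real_,
               rgSE = NA_real_, loglik = l0, loglik0 = l0, lrtP = NA_real_,
               converged = TRUE, iterations = 0, identifiable = FALSE,
               n = n))
  }

  aiPieces <- function(th) {
    d <- th[1] * lam + th[2]
    Py <- projPDiag(yt, Xt, d)
    zg <- lam * Py
    Pzg <- projPDiag(zg, Xt, d)
    PPy <- projPDiag(Py, Xt, d)
    grad <- 0.5 * c(sum(zg * Py) - trPDiag(lam, Xt, d),
                    sum(Py * Py) - trPDiag(rep(1, n), Xt, d))
    AI <- 0.5 * rbind(c(sum(zg * Pzg), sum(zg * PPy)),
                      c(sum(zg * PPy), sum(Py * PPy)))
    list(grad = grad, AI = AI)
  }
  project <- function(th) if (constrain) pmax(th, floorVal) else pmax(th, 1e-12)

  th <- project(c(vp / 2, vp / 2))
  cur <- ll(th)
  iter <- 0; conv <- FALSE
  AI <- diag(2)
  for (iter in seq_len(maxit)) {
    pieces <- aiPieces(th)
    AI <- pieces$AI
    step <- tryCatch(solve(AI, pieces$grad),
                     error = function(e) pieces$grad / n)
    hl <- 0; trial <- NULL; newth <- th
    repeat {
      newth <- project(th + step / 2^hl)
      trial <- ll(newth)
      if (is.finite(trial$loglik) && trial$loglik >= cur$loglik - 1e-10) break
      hl <- hl + 1
      if (hl > 30) break
    }
    if (hl > 30) { conv <- TRUE; break }  # no uphill step left
    done <- abs(trial$loglik - cur$loglik) < tol * (abs(cur$loglik) + 1)
    th <- newth; cur <- trial
    if (done) { conv <- TRUE; break }
  }

  AI <- aiPieces(th)$AI
  covTh <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(covTh), 0))
  s <- th[1] + th[2]
  h2 <- th[1] / s
  gradH <- c(th[2], -th[1]) / s^2
  h2SE <- sqrt(max(0, drop(t(gradH) %*% covTh %*% gradH)))
  lrt <- max(0, 2 * (cur$loglik - l0))
  lrtP <- if (lrt > 0) 0.5 * pchisq(lrt, 1, lower.tail = FALSE) else 1

  new("GremlFit",
      components = c(varG = th[1], varE = th[2]),
      se = c(varG = se[1], varE = se[2]),
      h2 = h2, h2SE = h2SE, rg = NA_real_, rgSE = NA_real_,
      loglik = cur$loglik, loglik0 = l0, lrtP = lrtP,
      converged = conv, iterations = iter, identifiable = TRUE, n = n)
}

# REML log-likelihood for diagonal V (eigenbasis), fixed effects Xt.
remlLoglikDiag <- function(d, yt, Xt) {
  if (any(d <= 0)) return(list(loglik = -Inf))
  n <- length(d); q <- ncol(Xt)
  Xd <- Xt / d
  XtVX <- crossprod(Xt, Xd)
  cholX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cholX)) return(list(loglik = -Inf))
  beta <- backsolve(cholX, forwardsolve(t(cholX), crossprod(Xd, yt)))
  r <- yt - Xt %*% beta
  quad <- sum(yt * (r / d))
  loglik <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(cholX))) + quad +
                      (n - q) * log(2 * pi))
  list(loglik = loglik)
}

# P z in the eigenbasis with diagonal V = diag(d).
projPDiag <- function(z, Xt, d) {
  Xd <- Xt / d
  XtVX <- crossprod(Xt, Xd)
  z / d - Xd %*% solve(XtVX, crossprod(Xd, z))
}

# tr(P diag(a)) with diagonal V.
trPDiag <- function(a, Xt, d) {
  Xd <- Xt / d
  XtVX <- crossprod(Xt, Xd)
  sum(a / d) - sum(diag(solve(XtVX, crossprod(Xd, Xd * a))))
}

#' Bivariate GREML fit
#'
#' Six-component REML (two genetic variances, a genetic covariance, and
#' residual analogues) on the stacked covariance of two traits that may be
#' observed on different, overlapping individual sets. Average-information
#' iterations with step-halving; the genetic correlation and its
#' delta-method SE are reported.
#'
#' @param grm a [GRM-class].
#' @param y1,y2 named numeric vectors (NA = missing).
#' @param maxit,tol iteration controls.
#' @return a [GremlFit-class] with components varG1, varG2, covG12, varE1,
#'   varE2, covE12 and per-trait h2.
#' @export
fitBivariateGreml <- function(grm, y1, y2, maxit = 100, tol = 1e-8) {
  stopifnot(is(grm, "GRM"))
  ids1 <- names(y1)[!is.na(y1)]; ids2 <- names(y2)[!is.na(y2)]
  if (is.null(ids1) || is.null(ids2)) stop("y1 and y2 must carry individual IDs")
  if (!length(intersect(ids1, ids2))) stop("no overlapping individuals between traits")
  if (!all(c(ids1, ids2) %in% grm@ids)) stop("GRM/phenotype ID mismatch")
  i1 <- match(ids1, grm@ids); i2 <- match(ids2, grm@ids)
  A <- grmValues(grm)
  A11 <- A[i1, i1]; A22 <- A[i2, i2]; A12 <- A[i1, i2]
  J12 <- outer(ids1, ids2, "==") * 1
  n1 <- length(i1); n2 <- length(i2); N <- n1 + n2
  yy <- c(as.numeric(y1[ids1]), as.numeric(y2[ids2]))
  X <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))
  q <- 2
  vp1 <- var(yy[1:n1]); vp2 <- var(yy[(n1 + 1):N])
  floor1 <- 1e-6 * vp1; floor2 <- 1e-6 * vp2

  buildV <- function(th) {
    V <- matrix(0, N, N)
    V[1:n1, 1:n1] <- th[1] * A11 + th[4] * diag(n1)
    V[(n1 + 1):N, (n1 + 1):N] <- th[2] * A22 + th[5] * diag(n2)
    C <- th[3] * A12 + th[6] * J12
    V[1:n1, (n1 + 1):N] <- C
    V[(n1 + 1):N, 1:n1] <- t(C)
    V
  }
  derivs <- function() {
    z1 <- matrix(0, n1, n1); z2 <- matrix(0, n2, n2); z12 <- matrix(0, n1, n2)
    blk <- function(B11, B22, B12) {
      V <- matrix(0, N, N)
      V[1:n1, 1:n1] <- B11; V[(n1 + 1):N, (n1 + 1):N] <- B22
      V[1:n1, (n1 + 1):N] <- B12; V[(n1 + 1):N, 1:n1] <- t(B12)
      V
    }
    list(blk(A11, z2, z12), blk(z1, A22, z12), blk(z1, z2, A12),
         blk(diag(n1), z2, z12), blk(z1, diag(n2), z12), blk(z1, z2, J12))
  }
  Ak <- derivs()
  nPar <- 6

  remlPieces <- function(th) {
    V <- buildV(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViXi <- solve(XtViX)
    P <- Vi - ViX %*% XtViXi %*% t(ViX)
    Py <- P %*% yy
    loglik <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
                        sum(yy * Py) + (N - q) * log(2 * pi))
    list(loglik = as.numeric(loglik), P = P, Py = Py)
  }

  # start from per-trait phenotypic variance halves, small covariances
  th <- c(vp1 / 2, vp2 / 2, 0.1 * sqrt(vp1 * vp2), vp1 / 2, vp2 / 2,
          0.1 * sqrt(vp1 * vp2))
  clamp <- function(th) {
    th[1] <- max(th[1], floor1); th[2] <- max(th[2], floor2)
    th[4] <- max(th[4], floor1); th[5] <- max(th[5], floor2)
    bG <- 0.9999 * sqrt(th[1] * th[2]); th[3] <- min(max(th[3], -bG), bG)
    bE <- 0.9999 * sqrt(th[4] * th[5]); th[6] <- min(max(th[6], -bE), bE)
    th
  }
  th <- clamp(th)
  cur <- remlPieces(th)
  if (is.null(cur)) stop("starting covariance not positive definite")
  conv <- FALSE; iter <- 0; AI <- NULL
  for (iter in seq_len(maxit)) {
    grad <- numeric(nPar)
    w <- vector("list", nPar)
    for (k in seq_len(nPar)) {
      APy <- Ak[[k]] %*% cur$Py
      w[[k]] <- APy
      grad[k] <- -0.5 * (sum(cur$P * Ak[[k]]) - sum(cur$Py * APy))
    }
    AI <- matrix(0, nPar, nPar)
    for (k in seq_len(nPar)) for (l in k:nPar) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(w[[k]] * (cur$P %*% w[[l]]))
    }
    step <- tryCatch(solve(AI, grad), error = function(e) grad / N)
    hl <- 0; trial <- NULL; newth <- th
    repeat {
      newth <- clamp(th + step / 2^hl)
      trial <- remlPieces(newth)
      if (!is.null(trial) && is.finite(trial$loglik) &&
          trial$loglik >= cur$loglik - 1e-10) break
      hl <- hl + 1
      if (hl > 30) break
    }
    if (hl > 30) { conv <- TRUE; break }
    done <- abs(trial$loglik - cur$loglik) < tol * (abs(cur$loglik) + 1)
    th <- newth; cur <- trial
    if (done) { conv <- TRUE; break }
  }

  covTh <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, nPar, nPar))
  se <- sqrt(pmax(diag(covTh), 0))
  h2 <- c(th[1] / (th[1] + th[4]), th[2] / (th[2] + th[5]))
  g1 <- th[1]; g2 <- th[2]; g12 <- th[3]
  rg <- g12 / sqrt(g1 * g2)
  # delta method: d rg / d(g1, g2, g12)
  gr <- c(-0.5 * g12 / (g1^1.5 * sqrt(g2)), -0.5 * g12 / (sqrt(g1) * g2^1.5),
          1 / sqrt(g1 * g2))
  covG <- covTh[c(1, 2, 3), c(1, 2, 3)]
  rgSE <- sqrt(max(0, drop(t(gr) %*% covG %*% gr)))
  h2SE <- c(
    deltaRatioSE(th[1], th[4], covTh[c(1, 4), c(1, 4)]),
    deltaRatioSE(th[2], th[5], covTh[c(2, 5), c(2, 5)]))

  new("GremlFit",
      components = c(varG1 = th[1], varG2 = th[2], covG12 = th[3],
                     varE1 = th[4], varE2 = th[5], covE12 = th[6]),
      se = setNames(se, c("varG1", "varG2", "covG12", "varE1", "varE2",
                          "covE12")),
      h2 = h2, h2SE = h2SE, rg = rg, rgSE = rgSE,
      loglik = cur$loglik, loglik0 = NA_real_, lrtP = NA_real_,
      converged = conv, iterations = iter, identifiable = TRUE,
      n = c(n1, n2))
}

# SE of g/(g+e) from the 2x2 covariance of (g, e)
deltaRatioSE <- function(g, e, covGE) {
  s <- g + e
  gr <- c(e, -g) / s^2
  sqrt(max(0, drop(t(gr) %*% covGE %*% gr)))
}

#' Screen traits on univariate heritability evidence
#'
#' Retains traits whose boundary-LRT p-value for varG = 0 is below `alpha`;
#' excluded traits are reported with their p-values in attribute
#' `excluded`.
#'
#' @param fits named list of univariate [GremlFit-class] objects (names =
#'   trait labels).
#' @param alpha significance level (default 0.05).
#' @return character vector of retained trait labels.
#' @export
screenHeritability <- function(fits, alpha = 0.05) {
  p <- vapply(fits, function(f) f@lrtP, numeric(1))
  keep <- names(fits)[!is.na(p) & p < alpha]
  out <- keep
  attr(out, "excluded") <- data.frame(trait = names(fits)[!(names(fits) %in% keep)],
                                      lrtP = p[!(names(fits) %in% keep)],
                                      row.names = NULL)
  out
}

#' Write an hsq-style variance-component report
#'
#' Plain-text table (component, estimate, SE rows) in the style of GREML
#' output files.
#'
#' @param fit a [GremlFit-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeHsq <- function(fit, path) {
  rows <- data.frame(Source = names(fit@components),
                     Variance = fit@components, SE = fit@se)
  extra <- data.frame(Source = character(0), Variance = numeric(0),
                      SE = numeric(0))
  for (k in seq_along(fit@h2))
    extra <- rbind(extra, data.frame(
      Source = if (length(fit@h2) > 1) sprintf("h2_trait%d", k) else "h2",
      Variance = fit@h2[k], SE = fit@h2SE[k]))
  if (!is.na(fit@rg))
    extra <- rbind(extra, data.frame(Source = "rG", Variance = fit@rg,
                                     SE = fit@rgSE))
  out <- rbind(rows, extra)
  out$Variance <- sprintf("%.6f", out$Variance)
  out$SE <- sprintf("%.6f", out$SE)
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  cat(sprintf("logL\t%.6f\n", fit@loglik), file = path, append = TRUE)
  if (!is.na(fit@lrtP))
    cat(sprintf("Pval\t%.6g\n", fit@lrtP), file = path, append = TRUE)
  invisible(path)
}
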