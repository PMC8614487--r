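## Restricted maximum likelihood for univariate and bivariate animal models:
## average-information updates with expectation-maximisation warm-up and
## fallback, and the relative-change convergence criterion
## C = sum_i (theta_i - theta_i*)^2 / sum_i theta_i^2.

#' Restricted log-likelihood of an animal model
#'
#' Evaluates the REML log-likelihood
#' \eqn{-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py] - \tfrac{n-p}{2}\log 2\pi}
#' through mixed-model-equations identities (the dense V is never formed).
#' For bivariate models with unequal records the residual covariance is
#' restricted to each record's observed-trait pattern.
#'
#' @param vc a [VarianceComponents-class] (must be positive definite).
#' @param dm design matrices from [buildDesign()].
#' @param rel relationship structure from [buildAInverse()].
#' @return the restricted log-likelihood (scalar).
#' @export
remlLogLik <- function(vc, dm, rel) {
  su <- .mmeSetup(dm, rel)
  .checkTraits(vc, su)
  .mmeSystem(su, vc@G, vc@R)$logL
}

.checkTraits <- function(vc, su) {
  if (length(vc@traits) != su$t)
    stop("variance components are for ", length(vc@traits),
         " trait(s), design for ", su$t)
}

#' One expectation-maximisation REML update
#'
#' Standard EM-REML: the additive matrix is updated from BLUP solutions and
#' prediction-error (co)variance traces, the residual matrix from expected
#' residual cross-products with missing-trait residuals treated as missing
#' data (conditional-normal E step). The restricted log-likelihood never
#' decreases along EM updates.
#'
#' @inheritParams remlLogLik
#' @param constraint \code{"none"}, \code{"no-genetic-cov"} (genetic
#'   covariance fixed at 0) or \code{"no-cov"} (genetic and residual
#'   covariances fixed at 0).
#' @return updated [VarianceComponents-class]
#' @export
emUpdate <- function(vc, dm, rel, constraint = "none") {
  su <- .mmeSetup(dm, rel)
  .checkTraits(vc, su)
  sys <- .mmeSystem(su, vc@G, vc@R)
  si <- .mmeSelInv(su, sys)
  .emStep(su, sys, si, constraint)
}

.emStep <- function(su, sys, si, constraint = "none") {
  t <- su$t; q <- su$q; p <- su$p
  Tuu <- .traceTuu(su, si)
  U <- matrix(sys$gamma[p + seq_len(t * q)], q, t)
  AinvU <- as.matrix(su$Ainv %*% U)
  Gnew <- (crossprod(U, AinvU) + Tuu) / q
  corr <- .eeCorrections(su, si)
  e <- sys$ehat
  if (t == 1L) {
    Rnew <- matrix((sum(e^2) + sum(corr)) / su$n, 1, 1)
  } else {
    nb <- su$nBoth
    n1 <- length(su$only1); n2 <- length(su$only2)
    i11 <- seq_len(nb); i12 <- nb + i11; i22 <- 2L * nb + i11
    E11 <- e[su$r1]^2 + corr[i11]
    E12 <- e[su$r1] * e[su$r2] + corr[i12]
    E22 <- e[su$r2]^2 + corr[i22]
    Eo1 <- e[su$only1]^2 + corr[3L * nb + seq_len(n1)]
    Eo2 <- e[su$only2]^2 + corr[3L * nb + n1 + seq_len(n2)]
    R <- sys$R
    b21 <- R[2, 1] / R[1, 1]; c2 <- R[2, 2] - R[2, 1]^2 / R[1, 1]
    b12 <- R[1, 2] / R[2, 2]; c1 <- R[1, 1] - R[1, 2]^2 / R[2, 2]
    nAn <- nb + n1 + n2
    s11 <- sum(E11) + sum(Eo1) + n2 * c1 + b12^2 * sum(Eo2)
    s22 <- sum(E22) + sum(Eo2) + n1 * c2 + b21^2 * sum(Eo1)
    s12 <- sum(E12) + b21 * sum(Eo1) + b12 * sum(Eo2)
    Rnew <- matrix(c(s11, s12, s12, s22), 2, 2) / nAn
  }
  if (t == 2L) {
    if (constraint %in% c("no-genetic-cov", "no-cov"))
      Gnew[1, 2] <- Gnew[2, 1] <- 0
    if (constraint == "no-cov") Rnew[1, 2] <- Rnew[2, 1] <- 0
  }
  Gnew <- (Gnew + Matrix::t(Gnew)) / 2
  Rnew <- (Rnew + Matrix::t(Rnew)) / 2
  new("VarianceComponents", G = as.matrix(Gnew), R = as.matrix(Rnew),
      traits = su$traits)
}

#' One average-information REML update
#'
#' Proposes \eqn{\theta + AI^{-1} \nabla\ell}; if the step leaves the
#' positive-definite region or decreases the restricted log-likelihood it is
#' halved (up to \code{max_halving}) and finally replaced by an EM step.
#'
#' @inheritParams emUpdate
#' @param max_halving maximum number of step halvings.
#' @return list with elements \code{vc} (updated components), \code{AI}
#'   (average-information matrix), \code{grad} (score vector) and
#'   \code{step} (\code{"AI"} or \code{"EM"}).
#' @export
aiUpdate <- function(vc, dm, rel, constraint = "none", max_halving = 10L) {
  su <- .mmeSetup(dm, rel)
  .checkTraits(vc, su)
  params <- .paramList(su$t, constraint)
  sys <- .mmeSystem(su, vc@G, vc@R)
  si <- .mmeSelInv(su, sys)
  der <- .mmeDeriv(su, sys, params, si)
  st <- .aiStep(su, sys, si, der, params, constraint, max_halving,
                varFloor = 1e-10 * su$phenVar)
  list(vc = st$vc, AI = der$AI, grad = der$grad, step = st$type,
       bent = st$bent)
}

## propose and safeguard one AI step; returns the accepted new components
.aiStep <- function(su, sys, si, der, params, constraint, max_halving,
                    varFloor) {
  theta <- .thetaFromVC(
    new("VarianceComponents", G = sys$G, R = sys$R, traits = su$traits),
    params)
  delta <- tryCatch(solve(der$AI, der$grad), error = function(e) NULL)
  if (is.null(delta)) {
    ridge <- der$AI + diag(1e-8 * max(abs(diag(der$AI)), 1),
                           length(theta))
    delta <- tryCatch(solve(ridge, der$grad), error = function(e) NULL)
    if (is.null(delta)) {
      warning("average-information matrix singular; falling back to EM")
      return(list(vc = .emStep(su, sys, si, constraint), type = "EM",
                  bent = FALSE))
    }
  }
  for (h in 0:max_halving) {
    prop <- theta + delta / 2^h
    vcp <- .vcFromTheta(prop, params, su$t, su$traits)
    G <- vcp@G; R <- vcp@R
    diag(G) <- pmax(diag(G), varFloor)
    diag(R) <- pmax(diag(R), varFloor)
    bG <- .bendPD(G)
    bR <- .bendPD(R)
    G <- bG$M; R <- bR$M
    ok <- suppressWarnings(tryCatch({
      l <- .mmeSystem(su, G, R)$logL
      l >= sys$logL - 1e-8
    }, error = function(e) FALSE))
    if (ok)
      return(list(vc = new("VarianceComponents", G = G, R = R,
                           traits = su$traits),
                  type = "AI", bent = bG$bent || bR$bent))
  }
  list(vc = .emStep(su, sys, si, constraint), type = "EM", bent = FALSE)
}

## floor eigenvalues of a symmetric matrix at 1e-8 of its trace
.bendPD <- function(M) {
  if (nrow(M) == 1L) return(list(M = M, bent = FALSE))
  ee <- eigen(M, symmetric = TRUE)
  floor <- 1e-8 * max(sum(abs(diag(M))), .Machine$double.eps)
  if (min(ee$values) >= floor * 0.999) return(list(M = M, bent = FALSE))
  vals <- pmax(ee$values, floor)
  list(M = ee$vectors %*% diag(vals) %*% Matrix::t(ee$vectors), bent = TRUE)
}

#' Relative-change convergence criterion
#'
#' \eqn{C = \sum_i (\theta_i - \theta_i^*)^2 / \sum_i \theta_i^2}, where
#' \eqn{\theta} and \eqn{\theta^*} are the current and previous parameter
#' vectors. Iteration stops when C drops below the tolerance (default
#' 1e-12).
#'
#' @param theta current parameter vector (not all zero).
#' @param theta_prev previous parameter vector, same length.
#' @return non-negative scalar.
#' @export
convergenceCriterion <- function(theta, theta_prev) {
  if (length(theta) != length(theta_prev))
    stop("theta and theta_prev must have the same length")
  den <- sum(theta^2)
  if (den == 0) stop("convergence criterion undefined for all-zero theta")
  sum((theta - theta_prev)^2) / den
}

#' Fit an animal model by AI-REML
#'
#' Average-information REML with EM warm-up and fallback. Start values
#' default to G = 0.4 diag(sample phenotypic variances), R = 0.6 diag(same),
#' zero covariances. Variances are floored at 1e-10 of the sample
#' phenotypic variance and the additive matrix is eigenvalue-bent when a
#' step leaves the positive-definite cone (flagged in the fit).
#'
#' @inheritParams emUpdate
#' @param start optional [VarianceComponents-class] start values.
#' @param tol convergence tolerance on the relative parameter change
#'   (default 1e-12).
#' @param max_iter maximum iterations (default 200).
#' @param em_warmup number of initial EM iterations before switching to
#'   average-information steps.
#' @param verbose print per-iteration progress.
#' @return a [REMLFit-class]
#' @export
airemlFit <- function(dm, rel, start = NULL, tol = 1e-12, max_iter = 200L,
                      constraint = c("none", "no-genetic-cov", "no-cov"),
                      em_warmup = 3L, verbose = FALSE) {
  constraint <- match.arg(constraint)
  su <- .mmeSetup(dm, rel)
  if (su$t == 1L && constraint != "none")
    stop("covariance constraints apply to bivariate models only")
  params <- .paramList(su$t, constraint)
  varFloor <- 1e-10 * su$phenVar
  if (is.null(start)) {
    G <- diag(0.4 * su$phenVar, su$t)
    R <- diag(0.6 * su$phenVar, su$t)
  } else {
    .checkTraits(start, su)
    G <- start@G; R <- start@R
    if (constraint %in% c("no-genetic-cov", "no-cov") && su$t == 2L)
      G[1, 2] <- G[2, 1] <- 0
    if (constraint == "no-cov" && su$t == 2L) R[1, 2] <- R[2, 1] <- 0
  }
  vc <- new("VarianceComponents", G = as.matrix(G), R = as.matrix(R),
            traits = su$traits)
  theta <- .thetaFromVC(vc, params)
  traceRows <- list()
  converged <- FALSE
  boundary <- FALSE
  sys <- .mmeSystem(su, vc@G, vc@R)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    si <- .mmeSelInv(su, sys)
    if (iter <= em_warmup) {
      vcNew <- .emStep(su, sys, si, constraint)
      stepType <- "EM"
    } else {
      der <- .mmeDeriv(su, sys, params, si)
      st <- .aiStep(su, sys, si, der, params, constraint, 10L, varFloor)
      vcNew <- st$vc
      stepType <- st$type
      if (st$bent) boundary <- TRUE
    }
    G <- vcNew@G
    diag(G) <- pmax(diag(G), varFloor)
    R <- vcNew@R
    diag(R) <- pmax(diag(R), varFloor)
    vcNew <- new("VarianceComponents", G = G, R = R, traits = su$traits)
    thetaNew <- .thetaFromVC(vcNew, params)
    C <- convergenceCriterion(thetaNew, theta)
    sysNew <- .mmeSystem(su, vcNew@G, vcNew@R)
    traceRows[[iter]] <- data.frame(iter = iter, t(thetaNew), C = C,
                                    logL = sysNew$logL, step = stepType,
                                    check.names = FALSE)
    if (verbose)
      message(sprintf("iter %3d [%s] logL = %.6f  C = %.3e", iter,
                      stepType, sysNew$logL, C))
    theta <- thetaNew
    vc <- vcNew
    sys <- sysNew
    if (C < tol) { converged <- TRUE; break }
  }
  if (any(diag(vc@G) <= varFloor * 1.01) ||
      any(diag(vc@R) <= varFloor * 1.01)) boundary <- TRUE
  ## asymptotic covariance from the AI matrix at the final estimates
  si <- .mmeSelInv(su, sys)
  der <- .mmeDeriv(su, sys, params, si)
  thetaCov <- tryCatch(solve(der$AI), error = function(e) {
    warning("AI matrix singular at convergence; theta-cov from ",
            "ridge-regularized inverse")
    solve(der$AI + diag(1e-8 * max(abs(diag(der$AI)), 1), length(theta)))
  })
  thetaCov <- (thetaCov + Matrix::t(thetaCov)) / 2
  trace <- do.call(rbind, traceRows)
  names(trace)[2:(1 + length(theta))] <- names(params)
  new("REMLFit", vc = vc, theta = setNames(theta, names(params)),
      thetaNames = names(params), thetaCov = as.matrix(thetaCov),
      logL = sys$logL, trace = trace, converged = converged,
      niter = iter, boundary = boundary, constraint = constraint)
}

#' Fit a bivariate model with covariance parameters fixed at zero
#'
#' The reduced models of the likelihood-ratio tests: with
#' \code{"no-genetic-cov"} the genetic covariance is fixed at 0 (G
#' diagonal); with \code{"no-cov"} both the genetic and the residual
#' covariances are fixed at 0 (G and R diagonal). The fixed parameters are
#' excluded from theta and from theta-cov.
#'
#' @inheritParams airemlFit
#' @param constraint \code{"no-genetic-cov"} or \code{"no-cov"}.
#' @return a [REMLFit-class]
#' @export
fitConstrained <- function(dm, rel, constraint = c("no-genetic-cov",
                                                   "no-cov"), ...) {
  constraint <- match.arg(constraint)
  if (length(dm$traits) != 2L)
    stop("constrained fits are defined for bivariate models only")
  airemlFit(dm, rel, constraint = constraint, ...)
}
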