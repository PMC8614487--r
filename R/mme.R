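## Internal mixed-model-equations machinery shared by the REML routines.
##
## The coefficient matrix C = W' Rn^-1 W + diag(0_p, Ginv (x) Ainv) is kept
## sparse and factorized with CHOLMOD. Its symbolic pattern is completed
## with explicit zeros ("union pattern": dense-R residual coupling and
## dense-G kronecker coupling) so that the Cholesky factor pattern covers
## every inverse entry the trace formulas need even while a covariance
## estimate is exactly zero. Selected entries of C^-1 come from a Takahashi
## recursion on the factor (src/takahashi.cpp).

.mmeSetup <- function(dm, rel) {
  stopifnot(inherits(dm, "DesignMatrices"), is(rel, "RelationshipStructure"))
  Ainv <- relAinv(rel)
  q <- dm$q
  if (nrow(Ainv) != q) stop("relationship structure does not match design")
  t <- length(dm$traits)
  blocks <- dm$blocks
  ntau <- vapply(blocks, function(b) length(b$y), integer(1))
  n <- sum(ntau)
  off <- cumsum(c(0L, ntau))
  y <- unlist(lapply(blocks, `[[`, "y"), use.names = FALSE)
  recTrait <- rep(seq_len(t), ntau)
  recAnimal <- unlist(lapply(blocks, `[[`, "animal"), use.names = FALSE)
  X <- if (t == 1L) methods::as(blocks[[1L]]$X, "CsparseMatrix") else
    Matrix::bdiag(lapply(blocks, function(b)
      methods::as(b$X, "CsparseMatrix")))
  p <- ncol(X)
  Z <- sparseMatrix(i = seq_len(n),
                    j = (recTrait - 1L) * q + recAnimal,
                    x = 1, dims = c(n, t * q))
  W <- cbind(X, Z)

  ## residual pattern bookkeeping
  if (t == 2L) {
    common <- intersect(blocks[[1L]]$animal, blocks[[2L]]$animal)
    r1 <- match(common, blocks[[1L]]$animal)
    r2 <- ntau[1L] + match(common, blocks[[2L]]$animal)
    only1 <- setdiff(seq_len(ntau[1L]), r1)
    only2 <- setdiff(ntau[1L] + seq_len(ntau[2L]), r2)
  } else {
    r1 <- r2 <- integer(0)
    only1 <- seq_len(ntau[1L]); only2 <- integer(0)
  }
  nBoth <- length(r1)

  ## symbolic union pattern of C (no cancellation: all-positive weights)
  onesR <- .rinvSparse(n, r1, r2, only1, only2,
                       matrix(1, 2, 2), c(1, 1), ones = TRUE)
  Wabs <- abs(W)
  Cpat <- crossprod(Wabs, onesR %*% Wabs)
  A1 <- methods::as(methods::as(Ainv, "generalMatrix"), "CsparseMatrix")
  A1@x[] <- 1
  uPat <- kronecker(matrix(1, t, t), A1)
  patFull <- methods::as(methods::as(Cpat, "generalMatrix"),
                         "TsparseMatrix")
  uT <- methods::as(uPat, "TsparseMatrix")
  patI <- c(patFull@i + 1L, uT@i + p + 1L)
  patJ <- c(patFull@j + 1L, uT@j + p + 1L)

  chA <- Cholesky(forceSymmetric(Ainv), LDL = FALSE, super = FALSE,
                  perm = TRUE)
  logdetA <- -2 * as.numeric(determinant(chA, logarithm = TRUE,
                                         sqrt = TRUE)$modulus)

  ## Ainv triplets (general pattern) for trace lookups against Cuu blocks
  At <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")

  ## per-record W row supports, for E[ee'] corrections (w_r' Cinv w_s)
  Wt <- Matrix::t(W)
  wcols <- split(Wt@i + 1L, rep(seq_len(n), diff(Wt@p)))
  wvals <- split(Wt@x, rep(seq_len(n), diff(Wt@p)))
  pairR <- c(r1, r1, r2, only1, only2)
  pairS <- c(r1, r2, r2, only1, only2)
  pairKind <- c(rep(c("b11", "b12", "b22"), each = nBoth),
                rep("s1", length(only1)), rep("s2", length(only2)))
  eeA <- eeB <- integer(0); eeW <- numeric(0); eeP <- integer(0)
  if (length(pairR)) {
    gl <- lapply(seq_along(pairR), function(k) {
      a <- wcols[[pairR[k]]]; b <- wcols[[pairS[k]]]
      va <- wvals[[pairR[k]]]; vb <- wvals[[pairS[k]]]
      la <- length(a); lb <- length(b)
      list(a = rep(a, times = lb), b = rep(b, each = la),
           w = rep(va, times = lb) * rep(vb, each = la),
           p = rep.int(k, la * lb))
    })
    eeA <- unlist(lapply(gl, `[[`, "a"), use.names = FALSE)
    eeB <- unlist(lapply(gl, `[[`, "b"), use.names = FALSE)
    eeW <- unlist(lapply(gl, `[[`, "w"), use.names = FALSE)
    eeP <- unlist(lapply(gl, `[[`, "p"), use.names = FALSE)
  }

  phenVar <- vapply(blocks, function(b) stats::var(b$y), numeric(1))

  list(t = t, q = q, n = n, p = p, ntau = ntau, traits = dm$traits,
       y = y, recTrait = recTrait, recAnimal = recAnimal,
       X = X, Z = Z, W = W, Ainv = Ainv, chA = chA, logdetA = logdetA,
       At = At, r1 = r1, r2 = r2, only1 = only1, only2 = only2,
       nBoth = nBoth, patI = patI, patJ = patJ,
       eeA = eeA, eeB = eeB, eeW = eeW, eeP = eeP,
       pairR = pairR, pairS = pairS, pairKind = pairKind,
       phenVar = phenVar)
}

## sparse record-level R^-1 (or pattern of ones)
.rinvSparse <- function(n, r1, r2, only1, only2, Rinv2, rinvDiag,
                        ones = FALSE) {
  if (ones) { Rinv2 <- matrix(1, 2, 2); rinvDiag <- c(1, 1) }
  i <- c(r1, r2, r1, r2, only1, only2)
  j <- c(r1, r2, r2, r1, only1, only2)
  x <- c(rep(Rinv2[1, 1], length(r1)), rep(Rinv2[2, 2], length(r2)),
         rep(Rinv2[1, 2], length(r1)), rep(Rinv2[2, 1], length(r2)),
         rep(rinvDiag[1], length(only1)), rep(rinvDiag[2], length(only2)))
  sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

.checkPD <- function(M, label) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(label, " is not positive definite; consider bending or better ",
         "start values")
  invisible(ev)
}

## assemble + factorize the MME at (G, R); returns likelihood pieces and
## solutions. Takahashi inversion is done lazily by .mmeSelInv().
.mmeSystem <- function(su, G, R) {
  t <- su$t; n <- su$n; p <- su$p; q <- su$q
  .checkPD(R, "residual covariance R")
  .checkPD(G, "genetic covariance G")
  Rinv2 <- if (t == 2L) solve(R) else matrix(0, 2, 2)
  rinvDiag <- c(1 / R[1, 1], if (t == 2L) 1 / R[2, 2] else 0)
  Rn <- .rinvSparse(su$n, su$r1, su$r2, su$only1, su$only2, Rinv2, rinvDiag)
  logdetRn <- su$nBoth * as.numeric(determinant(R, logarithm = TRUE)$modulus) +
    length(su$only1) * log(R[1, 1]) +
    (if (t == 2L) length(su$only2) * log(R[2, 2]) else 0)
  Ginv <- solve(G)
  GA <- kronecker(Ginv, su$Ainv)
  Cnum <- crossprod(su$W, Rn %*% su$W)
  CT <- methods::as(methods::as(Cnum, "generalMatrix"), "TsparseMatrix")
  uT <- methods::as(GA, "TsparseMatrix")
  i <- c(CT@i + 1L, uT@i + p + 1L, su$patI)
  j <- c(CT@j + 1L, uT@j + p + 1L, su$patJ)
  x <- c(CT@x, uT@x, numeric(length(su$patI)))
  Cfull <- sparseMatrix(i = i, j = j, x = x, dims = rep(p + t * q, 2L))
  Csym <- forceSymmetric(Cfull, uplo = "L")
  ch <- Cholesky(Csym, LDL = FALSE, super = FALSE, perm = TRUE)
  rhs <- as.numeric(crossprod(su$W, Rn %*% su$y))
  gamma <- as.numeric(solve(ch, rhs, system = "A"))
  yRy <- as.numeric(crossprod(su$y, Rn %*% su$y))
  yPy <- yRy - sum(rhs * gamma)
  logdetC <- 2 * as.numeric(determinant(ch, logarithm = TRUE,
                                        sqrt = TRUE)$modulus)
  logdetG <- as.numeric(determinant(G, logarithm = TRUE)$modulus)
  logL <- -0.5 * (logdetRn + q * logdetG + t * su$logdetA + logdetC + yPy) -
    0.5 * (n - p) * log(2 * pi)
  ehat <- su$y - as.numeric(su$W %*% gamma)
  Py <- as.numeric(Rn %*% ehat)
  list(G = G, R = R, Ginv = Ginv, Rinv2 = Rinv2, rinvDiag = rinvDiag,
       Rn = Rn, ch = ch, gamma = gamma, ehat = ehat, Py = Py,
       yPy = yPy, logL = logL)
}

## Takahashi selected inverse of the MME coefficient matrix
.mmeSelInv <- function(su, sys) {
  L <- expand(sys$ch)$L
  Sx <- takahashi_inverse(L@p, L@i, L@x)
  ndim <- su$p + su$t * su$q
  pos <- integer(ndim)
  pos[sys$ch@perm + 1L] <- seq_len(ndim)
  list(Lp = L@p, Li = L@i, Sx = Sx, pos = pos)
}

## entries of C^-1 at (rows, cols) in the original ordering
.cinv <- function(si, rows, cols) {
  v <- selected_entries(si$Lp, si$Li, si$Sx, si$pos[rows], si$pos[cols])
  if (anyNA(v))
    stop("internal error: selected inverse does not cover a requested entry")
  v
}

## Tuu[i,j] = tr(Ainv %*% Cuu_ij), t x t
.traceTuu <- function(su, si) {
  t <- su$t; p <- su$p; q <- su$q
  av <- su$At@i + 1L; bv <- su$At@j + 1L; xv <- su$At@x
  Tuu <- matrix(0, t, t)
  for (i in seq_len(t)) for (j in seq_len(i)) {
    v <- .cinv(si, p + (i - 1L) * q + bv, p + (j - 1L) * q + av)
    Tuu[i, j] <- Tuu[j, i] <- sum(xv * v)
  }
  Tuu
}

## per-pair residual corrections (W Cinv W')_{r,s} for the E[ee'] step
.eeCorrections <- function(su, si) {
  if (!length(su$eeP)) return(numeric(0))
  v <- .cinv(si, su$eeA, su$eeB)
  as.numeric(rowsum(su$eeW * v, su$eeP))
}

## free-parameter bookkeeping ------------------------------------------------

.paramList <- function(t, constraint) {
  g <- list(list(mat = "G", i = 1L, j = 1L))
  if (t == 2L) {
    if (constraint == "none")
      g <- c(g, list(list(mat = "G", i = 2L, j = 1L)))
    g <- c(g, list(list(mat = "G", i = 2L, j = 2L)))
  }
  r <- list(list(mat = "R", i = 1L, j = 1L))
  if (t == 2L) {
    if (constraint != "no-cov")
      r <- c(r, list(list(mat = "R", i = 2L, j = 1L)))
    r <- c(r, list(list(mat = "R", i = 2L, j = 2L)))
  }
  pl <- c(g, r)
  nm <- vapply(pl, function(p)
    sprintf("%s[%d,%d]", tolower(p$mat), p$i, p$j), character(1))
  nm <- sub("g", "sigma_g", sub("r", "sigma_e", nm))
  names(pl) <- nm
  pl
}

.thetaFromVC <- function(vc, params) {
  vapply(params, function(p)
    (if (p$mat == "G") vc@G else vc@R)[p$i, p$j], numeric(1))
}

.vcFromTheta <- function(theta, params, t, traits) {
  G <- matrix(0, t, t); R <- matrix(0, t, t)
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (p$mat == "G") G[p$i, p$j] <- G[p$j, p$i] <- theta[k]
    else R[p$i, p$j] <- R[p$j, p$i] <- theta[k]
  }
  new("VarianceComponents", G = G, R = R, traits = traits)
}

.Jbasis <- function(p, t) {
  J <- matrix(0, t, t)
  J[p$i, p$j] <- J[p$j, p$i] <- 1
  J
}

## score vector and average-information matrix at the current system state
.mmeDeriv <- function(su, sys, params, si = .mmeSelInv(su, sys)) {
  t <- su$t; q <- su$q; n <- su$n
  Tuu <- .traceTuu(su, si)
  ## s[, tau] = Z_tau' Py ; As = A s
  s <- matrix(0, q, t)
  agg <- rowsum(sys$Py, group = (su$recTrait - 1L) * q + su$recAnimal)
  idx <- as.integer(rownames(agg))
  s[cbind((idx - 1L) %% q + 1L, (idx - 1L) %/% q + 1L)] <- agg[, 1L]
  As <- as.matrix(solve(su$chA, s, system = "A"))  # A %*% s
  Ms <- crossprod(s, As)                           # s' A s, t x t
  np <- length(params)
  grad <- numeric(np)
  fvec <- vector("list", np)
  for (k in seq_len(np)) {
    pk <- params[[k]]
    J <- .Jbasis(pk, t)
    if (pk$mat == "G") {
      ## tr(P Vdot) = q tr(J Ginv) - tr[Cuu (Ginv J Ginv (x) Ainv)],
      ## from Z'PZ = Ginv_u (G_u - Cuu) Ginv_u with G_u = G (x) A
      B <- sys$Ginv %*% J %*% sys$Ginv
      trPV <- q * sum(diag(J %*% sys$Ginv)) - sum(B * Tuu)
      quad <- sum(J * Ms)
      vtrait <- As %*% J   # column i = sum_j J_ij A s_j
      f <- vtrait[cbind(su$recAnimal, su$recTrait)]
    } else {
      M <- .rMdot(su, J)
      trRinvM <- .trRinvM(su, sys, pk)
      Q <- sys$Rn %*% M %*% sys$Rn
      Sw <- crossprod(su$W, Q %*% su$W)
      SwT <- methods::as(methods::as(Sw, "generalMatrix"), "TsparseMatrix")
      trC <- sum(SwT@x * .cinv(si, SwT@j + 1L, SwT@i + 1L))
      trPV <- trRinvM - trC
      quad <- as.numeric(crossprod(sys$Py, M %*% sys$Py))
      f <- as.numeric(M %*% sys$Py)
    }
    grad[k] <- -0.5 * (trPV - quad)
    fvec[[k]] <- f
  }
  ## average information: AI_kl = 0.5 f_k' P f_l
  AI <- matrix(0, np, np)
  for (l in seq_len(np)) {
    fl <- fvec[[l]]
    Rf <- as.numeric(sys$Rn %*% fl)
    sol <- as.numeric(solve(sys$ch, as.numeric(crossprod(su$W, Rf)),
                            system = "A"))
    Pf <- as.numeric(sys$Rn %*% (fl - as.numeric(su$W %*% sol)))
    for (k in seq_len(l)) AI[k, l] <- AI[l, k] <-
        0.5 * sum(fvec[[k]] * Pf)
  }
  AI <- (AI + Matrix::t(AI)) / 2
  list(grad = grad, AI = AI, Tuu = Tuu, s = s, As = As, si = si)
}

## record-space dV/dr_kl
.rMdot <- function(su, J) {
  i <- j <- integer(0)
  if (J[1, 1] == 1) { i <- c(i, su$r1, su$only1); j <- c(j, su$r1, su$only1) }
  if (su$t == 2L && J[2, 2] == 1) {
    i <- c(i, su$r2, su$only2); j <- c(j, su$r2, su$only2)
  }
  if (su$t == 2L && J[1, 2] == 1 && J[1, 1] == 0) {
    i <- c(i, su$r1, su$r2); j <- c(j, su$r2, su$r1)
  }
  sparseMatrix(i = i, j = j, x = 1, dims = c(su$n, su$n))
}

.trRinvM <- function(su, sys, pk) {
  if (su$t == 1L) return(su$n * sys$rinvDiag[1])
  if (pk$i == pk$j) {
    tt <- pk$i
    su$nBoth * sys$Rinv2[tt, tt] +
      (if (tt == 1L) length(su$only1) * sys$rinvDiag[1]
       else length(su$only2) * sys$rinvDiag[2])
  } else {
    2 * su$nBoth * sys$Rinv2[1, 2]
  }
}
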