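## Numerator relationship matrix: dense tabular A, inbreeding coefficients
## (Meuwissen & Luo style recursion), and Henderson's sparse A-inverse with
## inbreeding. Unknown parents are treated as unrelated non-inbred founders.

#' Dense numerator relationship matrix by the tabular method
#'
#' a(i,j) = 0.5 (a(j, sire_i) + a(j, dam_i)) for j < i and
#' a(i,i) = 1 + 0.5 a(sire_i, dam_i); unknown parents contribute zero.
#' Intended for pedigrees below \code{dense_limit}; larger pedigrees should
#' use [buildAInverse()].
#'
#' @param ped a [Pedigree-class]
#' @param dense_limit refuse to build a dense A beyond this many animals.
#' @return a [RelationshipStructure-class] with \code{A} and \code{F} filled.
#' @export
buildA <- function(ped, dense_limit = 2000L) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  if (n > dense_limit)
    stop("pedigree has ", n, " animals, above the dense limit (",
         dense_limit, "); use buildAInverse() for the sparse inverse route")
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (!is.na(s)) aj <- aj + A[j, s]
      if (!is.na(d)) aj <- aj + A[j, d]
      aj <- 0.5 * aj
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new("RelationshipStructure", ped = ped, A = A,
      Ainv = sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                          dims = c(0L, 0L), symmetric = TRUE),
      F = unname(diag(A)) - 1)
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' F_i = 0.5 a(sire_i, dam_i), computed without forming the full A via the
#' L D L' decomposition of A (Meuwissen & Luo 1992). Founders and animals
#' with any unknown parent have F = 0.
#'
#' @param ped a [Pedigree-class]
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreedingCoef <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  F <- numeric(n)
  if (!n) return(setNames(F, character(0)))
  s <- ped@sire; d <- ped@dam
  for (i in seq_len(n)) {
    if (is.na(s[i]) || is.na(d[i])) next  # F = 0
    F[i] <- 0.5 * .pairRel(s[i], d[i], s, d, F)
  }
  setNames(F, ped@id)
}

## additive relationship a(x, y) from A = L D L': a(x,y) = sum_j Lx_j Ly_j d_j
## where Lx_j is x's expected genome fraction from ancestor j and d_j the
## Mendelian-sampling variance. F must be filled for all ancestors of x, y.
.pairRel <- function(x, y, s, d, F) {
  top <- max(x, y)
  Lx <- numeric(top); Ly <- numeric(top)
  Lx[x] <- 1; Ly[y] <- 1
  rel <- 0
  for (j in top:1) {
    if (Lx[j] == 0 && Ly[j] == 0) next
    ## with the -1 sentinel for an unknown parent this evaluates to 1 for
    ## founders and 0.75 - 0.25 F_known with one parent known
    Fs <- if (is.na(s[j])) -1 else F[s[j]]
    Fd <- if (is.na(d[j])) -1 else F[d[j]]
    dj <- 0.5 - 0.25 * (Fs + Fd)
    rel <- rel + Lx[j] * Ly[j] * dj
    if (!is.na(s[j])) { Lx[s[j]] <- Lx[s[j]] + 0.5 * Lx[j]
                        Ly[s[j]] <- Ly[s[j]] + 0.5 * Ly[j] }
    if (!is.na(d[j])) { Lx[d[j]] <- Lx[d[j]] + 0.5 * Lx[j]
                        Ly[d[j]] <- Ly[d[j]] + 0.5 * Ly[j] }
  }
  rel
}

#' Mendelian-sampling variances given parental inbreeding
#'
#' d_i = 0.5 - 0.25 (F_sire + F_dam) with both parents known,
#' 0.75 - 0.25 F_known with one parent known, and 1 for founders.
#' @param ped a [Pedigree-class]
#' @param F inbreeding coefficients (computed if missing).
#' @return numeric vector of variances.
#' @export
mendelianVariance <- function(ped, F = inbreedingCoef(ped)) {
  s <- ped@sire; d <- ped@dam
  Fs <- ifelse(is.na(s), NA, F[s])
  Fd <- ifelse(is.na(d), NA, F[d])
  ifelse(!is.na(s) & !is.na(d), 0.5 - 0.25 * (Fs + Fd),
  ifelse(!is.na(s), 0.75 - 0.25 * Fs,
  ifelse(!is.na(d), 0.75 - 0.25 * Fd, 1)))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: each animal contributes
#' 1/d_i to at most 9 cells (itself, its known parents and their crosses),
#' with d_i the Mendelian-sampling variance from [mendelianVariance()].
#'
#' @param ped a [Pedigree-class]
#' @return a [RelationshipStructure-class] with \code{Ainv} and \code{F}.
#' @export
buildAInverse <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  F <- unname(inbreedingCoef(ped))
  dvec <- mendelianVariance(ped, F)
  b <- 1 / dvec
  s <- ped@sire; d <- ped@dam
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, pmax(i, j)); jj <<- c(jj, pmin(i, j)); xx <<- c(xx, v)
  }
  seqn <- seq_len(n)
  add(seqn, seqn, b)
  hs <- !is.na(s); hd <- !is.na(d)
  if (any(hs)) {
    add(seqn[hs], s[hs], -0.5 * b[hs])
    add(s[hs], s[hs], 0.25 * b[hs])
  }
  if (any(hd)) {
    add(seqn[hd], d[hd], -0.5 * b[hd])
    add(d[hd], d[hd], 0.25 * b[hd])
  }
  both <- hs & hd
  if (any(both)) add(s[both], d[both], 0.25 * b[both])
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       symmetric = TRUE)
  dimnames(Ainv) <- list(ped@id, ped@id)
  new("RelationshipStructure", ped = ped,
      A = matrix(numeric(0), 0, 0), Ainv = Ainv, F = F)
}

#' Export a sparse A-inverse as coordinate-format text
#'
#' Writes the lower triangle as whitespace-separated \code{i j value} lines
#' with 1-based indices (the order of [animalIds()]).
#'
#' @param rel a [RelationshipStructure-class] with Ainv built.
#' @param path output file.
#' @export
writeAInverse <- function(rel, path) {
  Ainv <- relAinv(rel)
  tm <- as(as(Ainv, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i >= tm@j
  df <- data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                   x = tm@x[keep])
  df <- df[order(df$j, df$i), ]
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
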