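#' @import methods
#' @importFrom Matrix sparseMatrix Cholesky Diagonal forceSymmetric crossprod t diag solve determinant expand
#' @importFrom stats model.matrix rnorm qchisq sd var quantile setNames complete.cases optim aggregate
#' @useDynLib pedREML, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("data.frame")

#' Pedigree of animals with parent links
#'
#' An S4 container for a validated, topologically ordered pedigree. Animals
#' are identified by arbitrary character labels; internally every animal has
#' an integer code equal to its position in the (parent-before-offspring)
#' order. Unknown parents are coded \code{NA_integer_}.
#'
#' @slot id character vector of animal identifiers, in topological order.
#' @slot sire integer codes of sires (index into \code{id}), \code{NA} if
#'   unknown.
#' @slot dam integer codes of dams, \code{NA} if unknown.
#' @slot depth integer generation depth per animal: 0 for base (childless)
#'   animals, k for an animal whose closest descendant path to a base animal
#'   involves k meioses.
#'
#' @seealso [readPedigree()], [buildA()], [buildAInverse()]
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer",
                 depth = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    return(sprintf("duplicate animal id: %s",
                   object@id[duplicated(object@id)][1L]))
  idx <- seq_len(n)
  ok <- function(p) all(is.na(p) | (p >= 1L & p < idx))
  if (!ok(object@sire) || !ok(object@dam))
    return("parents must precede offspring (topological order violated)")
  TRUE
})

#' Numerator relationship structure
#'
#' Holds the additive (numerator) relationship matrix A and/or its sparse
#' inverse, together with per-animal inbreeding coefficients F. The dense A
#' is only populated for pedigrees below the dense limit; the sparse inverse
#' (Henderson's rules, inbreeding accounted for) is always available from
#' [buildAInverse()].
#'
#' @slot ped the [Pedigree-class] the matrices are indexed by.
#' @slot A dense symmetric relationship matrix (may be 0x0 if not built).
#' @slot Ainv sparse symmetric inverse of A (may be 0x0 if not built).
#' @slot F numeric vector of inbreeding coefficients, one per animal.
#' @export
setClass("RelationshipStructure",
  representation(ped = "Pedigree", A = "matrix", Ainv = "Matrix",
                 F = "numeric"))

setValidity("RelationshipStructure", function(object) {
  n <- length(object@ped@id)
  if (length(object@F) != n) return("F must have one entry per animal")
  if (any(object@F < 0)) return("inbreeding coefficients must be >= 0")
  if (nrow(object@A) && !isTRUE(all.equal(object@A, t(object@A),
                                          tolerance = 1e-10)))
    return("A must be symmetric")
  TRUE
})

#' Additive-genetic and residual (co)variance components
#'
#' t x t symmetric matrices G (additive genetic) and R (residual) for a
#' univariate (t = 1) or bivariate (t = 2) animal model. The phenotypic
#' (co)variance matrix is G + R.
#'
#' @slot G additive genetic (co)variance matrix, trait units squared.
#' @slot R residual (co)variance matrix.
#' @slot traits character names of the traits.
#' @export
setClass("VarianceComponents",
  representation(G = "matrix", R = "matrix", traits = "character"))

setValidity("VarianceComponents", function(object) {
  t <- length(object@traits)
  if (!t %in% 1:2) return("only 1- or 2-trait models are supported")
  if (!all(dim(object@G) == t) || !all(dim(object@R) == t))
    return("G and R must be t x t with t = number of traits")
  if (max(abs(object@G - t(object@G))) > 1e-10 ||
      max(abs(object@R - t(object@R))) > 1e-10)
    return("G and R must be symmetric")
  TRUE
})

#' A converged (or attempted) REML fit
#'
#' @slot vc the estimated [VarianceComponents-class].
#' @slot theta free parameter vector (unique elements of G then R).
#' @slot thetaNames names of the free parameters.
#' @slot thetaCov asymptotic covariance of theta (inverse average-information
#'   matrix at convergence).
#' @slot logL restricted log-likelihood at the final estimates.
#' @slot trace data.frame with one row per iteration: the parameter values,
#'   the relative-change convergence criterion, the log-likelihood and the
#'   step type (\code{"EM"} or \code{"AI"}).
#' @slot converged logical flag.
#' @slot niter number of iterations performed.
#' @slot boundary logical; TRUE if any variance was pinned at its floor or G
#'   needed eigenvalue bending on the way.
#' @slot constraint character: \code{"none"}, \code{"no-genetic-cov"} or
#'   \code{"no-cov"}.
#' @export
setClass("REMLFit",
  representation(vc = "VarianceComponents", theta = "numeric",
                 thetaNames = "character", thetaCov = "matrix",
                 logL = "numeric", trace = "data.frame",
                 converged = "logical", niter = "integer",
                 boundary = "logical", constraint = "character"))

setValidity("REMLFit", function(object) {
  k <- length(object@theta)
  if (length(object@thetaNames) != k) return("thetaNames length mismatch")
  if (!all(dim(object@thetaCov) == k)) return("thetaCov dimension mismatch")
  TRUE
})

#' Full-study report
#'
#' Output of [runStudy()]: descriptive statistics, per-trait heritability
#' table (univariate fits) and genetic/phenotypic correlation tables
#' (bivariate fits with likelihood-ratio tests).
#'
#' @slot descriptives data.frame (trait, n, mean, se, min, max, sd, cv).
#' @slot heritability data.frame (trait, h2, se_h2, sigma2_g, sigma2_e,
#'   sigma2_p, cvg).
#' @slot correlations data.frame, one row per fitted trait pair (trait_x,
#'   trait_y, rg, se_rg, sig_rg, rp, se_rp, sig_rp, m2ll_df1, m2ll_df2,
#'   converged).
#' @slot diagnostics data.frame of bivariate-implied per-trait variance
#'   estimates next to the univariate ones.
#' @slot manifest list of run metadata (seed, tolerance, iteration counts).
#' @export
setClass("StudyReport",
  representation(descriptives = "data.frame", heritability = "data.frame",
                 correlations = "data.frame", diagnostics = "data.frame",
                 manifest = "list"))
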