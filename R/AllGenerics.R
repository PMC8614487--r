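#' @describeIn Pedigree number of animals
#' @param x,object a \code{Pedigree}
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @export
setMethod("nAnimals", "Pedigree", function(x) length(x@id))

#' Animal identifiers in topological order
#' @param x a [Pedigree-class]
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)

#' Per-animal generation depth
#'
#' 0 marks base animals (animals that are nobody's parent); an ancestor's
#' depth is the minimum number of meioses separating it from a base animal.
#' @param x a [Pedigree-class]
#' @export
setGeneric("generationDepth", function(x) standardGeneric("generationDepth"))

#' @export
setMethod("generationDepth", "Pedigree",
          function(x) setNames(x@depth, x@id))

#' Inbreeding coefficients stored in a relationship structure
#' @param x a [RelationshipStructure-class]
#' @export
setGeneric("inbreedingF", function(x) standardGeneric("inbreedingF"))

#' @export
setMethod("inbreedingF", "RelationshipStructure",
          function(x) setNames(x@F, x@ped@id))

#' Dense numerator relationship matrix
#' @param x a [RelationshipStructure-class]
#' @export
setGeneric("relA", function(x) standardGeneric("relA"))

#' @export
setMethod("relA", "RelationshipStructure", function(x) {
  if (!nrow(x@A)) stop("dense A was not built for this structure; ",
                       "use buildA() on a small pedigree")
  x@A
})

#' Sparse inverse of the numerator relationship matrix
#' @param x a [RelationshipStructure-class]
#' @export
setGeneric("relAinv", function(x) standardGeneric("relAinv"))

#' @export
setMethod("relAinv", "RelationshipStructure", function(x) {
  if (!nrow(x@Ainv)) stop("A-inverse was not built; use buildAInverse()")
  x@Ainv
})

#' Additive genetic (co)variance matrix of a fit or component set
#' @param x a [VarianceComponents-class] or [REMLFit-class]
#' @export
setGeneric("vcG", function(x) standardGeneric("vcG"))

#' Residual (co)variance matrix of a fit or component set
#' @param x a [VarianceComponents-class] or [REMLFit-class]
#' @export
setGeneric("vcR", function(x) standardGeneric("vcR"))

#' @export
setMethod("vcG", "VarianceComponents", function(x) x@G)
#' @export
setMethod("vcR", "VarianceComponents", function(x) x@R)
#' @export
setMethod("vcG", "REMLFit", function(x) x@vc@G)
#' @export
setMethod("vcR", "REMLFit", function(x) x@vc@R)

#' Restricted log-likelihood of a fit
#' @param x a [REMLFit-class]
#' @export
setGeneric("logLik2", function(x) standardGeneric("logLik2"))

#' @export
setMethod("logLik2", "REMLFit", function(x) x@logL)

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  cat("Pedigree with", n, "animals\n")
  cat("  founders (both parents unknown):",
      sum(is.na(object@sire) & is.na(object@dam)), "\n")
  cat("  max generation depth:", if (n) max(object@depth) else 0L, "\n")
})

setMethod("show", "RelationshipStructure", function(object) {
  cat("RelationshipStructure over", length(object@ped@id), "animals\n")
  cat("  dense A built:", nrow(object@A) > 0L,
      "| sparse A-inverse built:", nrow(object@Ainv) > 0L, "\n")
  cat("  mean F:", format(mean(object@F), digits = 4),
      "| max F:", format(max(object@F), digits = 4), "\n")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents for traits:",
      paste(object@traits, collapse = ", "), "\n")
  cat("G (additive):\n"); print(round(object@G, 6))
  cat("R (residual):\n"); print(round(object@R, 6))
})

setMethod("show", "REMLFit", function(object) {
  cat("REMLFit (", ifelse(object@converged, "converged", "NOT converged"),
      ", ", object@niter, " iterations, constraint = ", object@constraint,
      ")\n", sep = "")
  cat("  logL =", format(object@logL, digits = 10), "\n")
  show(object@vc)
  if (object@boundary)
    cat("  note: boundary/bending occurred during fitting\n")
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport:", nrow(object@descriptives), "traits,",
      nrow(object@correlations), "bivariate fits\n")
  cat("Heritability table:\n")
  print(object@heritability, digits = 3)
})
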