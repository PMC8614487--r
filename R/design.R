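## Fixed-effect / random-effect design assembly for one- and two-trait
## animal models with unequal record patterns.

#' Model specification for an animal-model fit
#'
#' @param traits character vector of 1 or 2 trait column names.
#' @param class_effects character vector of categorical fixed-effect columns
#'   (e.g. slaughter date); applied to every trait.
#' @param covariates continuous fixed effects. Either a character vector
#'   (applied to all traits) or a named list mapping trait name to its
#'   covariate columns, so a covariate can enter one trait's model only.
#' @param outlier_k if non-NULL, pre-filter each trait by flagging values
#'   beyond \code{k} interquartile ranges outside the quartiles.
#' @return a list with class \code{"ModelSpec"}.
#' @export
modelSpec <- function(traits, class_effects = character(),
                      covariates = character(), outlier_k = NULL) {
  stopifnot(length(traits) %in% 1:2, is.character(traits))
  if (is.character(covariates))
    covariates <- setNames(rep(list(covariates), length(traits)), traits)
  if (!all(traits %in% names(covariates)))
    covariates[setdiff(traits, names(covariates))] <- list(character())
  structure(list(traits = traits, class_effects = class_effects,
                 covariates = covariates[traits], outlier_k = outlier_k),
            class = "ModelSpec")
}

#' Read a phenotype table from CSV
#'
#' Columns: \code{animal}, any fixed-effect columns (e.g.
#' \code{slaughter_date}, \code{slaughter_age}), then one column per trait.
#' Missing values are empty cells.
#' @param path file path.
#' @return data.frame with \code{animal} as character.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        na.strings = c("", "NA"))
  if (!"animal" %in% names(df)) stop("phenotype file must have an 'animal' column")
  df$animal <- as.character(df$animal)
  df
}

#' Flag trait values outside k IQRs from the quartiles
#'
#' The optional pre-filter used before model fitting: a value is an outlier
#' for a trait if it lies below Q1 - k IQR or above Q3 + k IQR. Flagged
#' values are set to NA (the record is kept for other traits).
#'
#' @param ph phenotype data.frame.
#' @param traits trait columns to screen.
#' @param k multiplier of the interquartile range (default 3).
#' @return the data.frame with outliers blanked; attribute
#'   \code{"n_outliers"} counts removals per trait.
#' @export
screenOutliers <- function(ph, traits, k = 3) {
  removed <- setNames(integer(length(traits)), traits)
  for (tr in traits) {
    v <- ph[[tr]]
    if (all(is.na(v))) next
    q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    bad <- !is.na(v) & (v < q[1] - k * iqr | v > q[2] + k * iqr)
    ph[[tr]][bad] <- NA
    removed[tr] <- sum(bad)
  }
  attr(ph, "n_outliers") <- removed
  ph
}

#' Assemble design matrices for an animal model
#'
#' Builds, per trait, the fixed-effect incidence matrix X (intercept, class
#' effects one-hot with the first level dropped, covariates centred at their
#' sample mean) and the observation-to-animal map used for Z. Records with a
#' missing value for a trait are excluded from that trait's block only
#' (bivariate unequal design).
#'
#' @param ph phenotype data.frame (see [readPhenotypes()]).
#' @param ped a [Pedigree-class] containing every phenotyped animal.
#' @param spec a [modelSpec()].
#' @return an object of class \code{"DesignMatrices"}: a list with per-trait
#'   elements \code{y} (values), \code{animal} (integer pedigree codes),
#'   \code{X} (dense fixed-effect matrix), plus \code{traits}, \code{q}
#'   (number of pedigree animals) and \code{mask} (logical matrix of record
#'   availability per input row).
#' @export
buildDesign <- function(ph, ped, spec) {
  stopifnot(is(ped, "Pedigree"), inherits(spec, "ModelSpec"))
  traits <- spec$traits
  miss <- setdiff(traits, names(ph))
  if (length(miss)) stop("trait column(s) not in phenotype table: ",
                         paste(miss, collapse = ", "))
  if (!is.null(spec$outlier_k))
    ph <- screenOutliers(ph, traits, spec$outlier_k)
  keep <- rowSums(!is.na(as.data.frame(ph[, traits, drop = FALSE]))) > 0
  ph <- ph[keep, , drop = FALSE]
  code <- match(ph$animal, ped@id)
  if (anyNA(code))
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(utils::head(ph$animal[is.na(code)], 5L), collapse = ", "))
  mask <- !is.na(as.matrix(ph[, traits, drop = FALSE]))
  colnames(mask) <- traits
  blocks <- list()
  for (tr in traits) {
    sel <- mask[, tr]
    dat <- ph[sel, , drop = FALSE]
    terms <- character()
    for (ce in spec$class_effects) {
      if (!ce %in% names(dat)) stop("class effect column missing: ", ce)
      dat[[ce]] <- droplevels(factor(dat[[ce]]))
      if (nlevels(dat[[ce]]) < 2L) {
        warning("class effect '", ce, "' has a single level for trait '",
                tr, "'; dropped")
      } else terms <- c(terms, ce)
    }
    for (cv in spec$covariates[[tr]]) {
      if (!cv %in% names(dat)) stop("covariate column missing: ", cv)
      if (!is.numeric(dat[[cv]])) stop("covariate '", cv, "' is not numeric")
      if (stats::var(dat[[cv]]) == 0)
        stop("covariate '", cv, "' has zero variance for trait '", tr, "'")
      dat[[cv]] <- dat[[cv]] - mean(dat[[cv]])
      terms <- c(terms, cv)
    }
    fml <- stats::as.formula(paste(
      "~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
    X <- model.matrix(fml, dat)
    ## drop aliased columns, keep full column rank
    qr_ <- qr(X)
    if (qr_$rank < ncol(X)) {
      drop <- qr_$pivot[-seq_len(qr_$rank)]
      warning("dropping ", length(drop), " aliased fixed-effect column(s) ",
              "for trait '", tr, "'")
      X <- X[, -drop, drop = FALSE]
    }
    attr(X, "assign") <- NULL
    attr(X, "contrasts") <- NULL
    blocks[[tr]] <- list(y = dat[[tr]], animal = code[sel], X = X)
  }
  structure(list(blocks = blocks, traits = traits, q = length(ped@id),
                 mask = mask, animal = code),
            class = "DesignMatrices")
}
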