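## Study orchestration: descriptive statistics, univariate fits per trait,
## pairwise bivariate fits with likelihood-ratio tests, report tables.

#' Descriptive statistics per trait
#'
#' n (non-missing), mean, SE of the mean (SD / sqrt(n)), min, max, sample
#' SD (n - 1 denominator) and CV\% (SD / mean x 100).
#'
#' @param ph phenotype data.frame.
#' @param traits trait columns (default: every numeric column except
#'   \code{slaughter_age}).
#' @return data.frame with one row per trait.
#' @export
descriptives <- function(ph, traits = NULL) {
  if (!nrow(ph)) stop("empty phenotype table")
  if (is.null(traits)) {
    num <- vapply(ph, is.numeric, logical(1))
    traits <- setdiff(names(ph)[num], c("slaughter_age"))
  }
  rows <- lapply(traits, function(tr) {
    v <- ph[[tr]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (!n)
      return(data.frame(trait = tr, n = 0L, mean = NA_real_, se = NA_real_,
                        min = NA_real_, max = NA_real_, sd = NA_real_,
                        cv = NA_real_))
    s <- if (n > 1L) stats::sd(v) else 0
    data.frame(trait = tr, n = n, mean = mean(v), se = s / sqrt(n),
               min = min(v), max = max(v), sd = s,
               cv = if (mean(v) != 0) s / mean(v) * 100 else 0)
  })
  do.call(rbind, rows)
}

#' Default composite-trait definitions
#'
#' High-value cuts HVC = CHK + SLN + STLN + TLN, medium-value cuts
#' MVC = BSK + TRD + BRD + RB, low-value cuts LVC = FK + SK.
#' @export
compositeDefs <- function() {
  list(HVC = c("CHK", "SLN", "STLN", "TLN"),
       MVC = c("BSK", "TRD", "BRD", "RB"),
       LVC = c("FK", "SK"))
}

#' Add composite-trait columns to a phenotype table
#'
#' Each composite is the sum of its member cuts where all members are
#' non-missing, and missing otherwise.
#'
#' @param ph phenotype data.frame.
#' @param defs named list mapping composite name to member columns
#'   (default [compositeDefs()]).
#' @return the data.frame with composite columns appended.
#' @export
makeComposites <- function(ph, defs = compositeDefs()) {
  for (nm in names(defs)) {
    members <- defs[[nm]]
    miss <- setdiff(members, names(ph))
    if (length(miss))
      stop("composite ", nm, " needs missing column(s): ",
           paste(miss, collapse = ", "))
    M <- as.matrix(ph[, members, drop = FALSE])
    v <- rowSums(M)
    v[rowSums(is.na(M)) > 0L] <- NA
    ph[[nm]] <- v
  }
  ph
}

#' Read a study/model configuration file (YAML)
#'
#' Recognised fields: \code{traits}, \code{class_effects},
#' \code{covariates} (string vector, or map trait -> vector),
#' \code{outlier_k}, \code{composites} (map name -> members), \code{pairs}
#' (list of two-element trait pairs).
#' @param path YAML file.
#' @return named list.
#' @export
readModelConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run a full genetic-parameter study
#'
#' Computes descriptive statistics, a univariate AI-REML fit per trait
#' (heritability table) and bivariate fits with both reduced models for
#' every requested trait pair (correlation table with likelihood-ratio
#' significance tests). Heritabilities and variance components are
#' reported from the univariate fits and correlations from the bivariate
#' fits; bivariate-implied per-trait variances go to the diagnostics table.
#'
#' @param ph phenotype data.frame (composites are added first if
#'   \code{composites} is non-NULL).
#' @param ped a [Pedigree-class].
#' @param traits trait columns to analyse.
#' @param class_effects,covariates,outlier_k model structure passed to
#'   [modelSpec()].
#' @param pairs list of 2-element character vectors naming the bivariate
#'   fits; default every pairwise combination of \code{traits}.
#' @param composites optional named list of composite definitions.
#' @param n_se_samples draws for the sampling-based standard errors.
#' @param seed seed for the sampling SEs.
#' @param tol,max_iter REML convergence controls.
#' @param verbose print progress.
#' @return a [StudyReport-class]
#' @export
runStudy <- function(ph, ped, traits, class_effects = "slaughter_date",
                     covariates = character(), outlier_k = NULL,
                     pairs = NULL, composites = NULL,
                     n_se_samples = 10000L, seed = 1L, tol = 1e-12,
                     max_iter = 200L, verbose = FALSE) {
  if (!is.null(composites)) ph <- makeComposites(ph, composites)
  rel <- buildAInverse(ped)
  if (is.null(pairs))
    pairs <- utils::combn(traits, 2L, simplify = FALSE)
  desc <- descriptives(ph, traits)
  ## univariate fits
  uniFits <- list()
  heriRows <- list()
  for (tr in traits) {
    if (verbose) message("univariate fit: ", tr)
    spec <- modelSpec(tr, class_effects, covariates, outlier_k)
    dm <- buildDesign(ph, ped, spec)
    fit <- airemlFit(dm, rel, tol = tol, max_iter = max_iter)
    uniFits[[tr]] <- fit
    h2 <- heritability(fit@vc, 1L)
    seh2 <- tryCatch(
      as.numeric(seBySampling(fit, function(v) heritability(v, 1L),
                              n_samples = n_se_samples, seed = seed)),
      error = function(e) NA_real_)
    mu <- desc$mean[desc$trait == tr]
    heriRows[[tr]] <- data.frame(
      trait = tr, h2 = h2, se_h2 = seh2,
      sigma2_g = fit@vc@G[1, 1], sigma2_e = fit@vc@R[1, 1],
      sigma2_p = fit@vc@G[1, 1] + fit@vc@R[1, 1],
      cvg = if (mu > 0) cvGenetic(fit@vc@G[1, 1], mu) else NA_real_,
      converged = fit@converged, boundary = fit@boundary)
  }
  ## bivariate fits
  corRows <- list()
  diagRows <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = ":")
    if (verbose) message("bivariate fit: ", key)
    spec <- modelSpec(pr, class_effects, covariates, outlier_k)
    dm <- buildDesign(ph, ped, spec)
    row <- tryCatch({
      full <- airemlFit(dm, rel, tol = tol, max_iter = max_iter)
      red1 <- airemlFit(dm, rel, constraint = "no-genetic-cov", tol = tol,
                        max_iter = max_iter)
      red2 <- airemlFit(dm, rel, constraint = "no-cov", tol = tol,
                        max_iter = max_iter)
      l1 <- lrtCorrelation(full, red1)
      l2 <- lrtCorrelation(full, red2)
      rg <- vcCorrelation(full@vc, "genetic")
      rp <- vcCorrelation(full@vc, "phenotypic")
      serg <- tryCatch(as.numeric(
        seBySampling(full, function(v) vcCorrelation(v, "genetic"),
                     n_samples = n_se_samples, seed = seed)),
        error = function(e) NA_real_)
      serp <- tryCatch(as.numeric(
        seBySampling(full, function(v) vcCorrelation(v, "phenotypic"),
                     n_samples = n_se_samples, seed = seed)),
        error = function(e) NA_real_)
      diagRows[[key]] <- data.frame(
        pair = key, trait = pr,
        sigma2_g_biv = diag(full@vc@G),
        sigma2_g_uni = vapply(pr, function(x)
          uniFits[[x]]@vc@G[1, 1], numeric(1)),
        sigma2_e_biv = diag(full@vc@R),
        sigma2_e_uni = vapply(pr, function(x)
          uniFits[[x]]@vc@R[1, 1], numeric(1)))
      data.frame(trait_x = pr[1], trait_y = pr[2], rg = rg, se_rg = serg,
                 sig_rg = l1$significant, rp = rp, se_rp = serp,
                 sig_rp = l2$significant,
                 m2ll_df1 = l1$minus2logLambda,
                 m2ll_df2 = l2$minus2logLambda,
                 converged = full@converged && red1@converged &&
                   red2@converged,
                 boundary = full@boundary)
    }, error = function(e) {
      warning("bivariate fit ", key, " failed: ", conditionMessage(e))
      data.frame(trait_x = pr[1], trait_y = pr[2], rg = NA_real_,
                 se_rg = NA_real_, sig_rg = NA, rp = NA_real_,
                 se_rp = NA_real_, sig_rp = NA, m2ll_df1 = NA_real_,
                 m2ll_df2 = NA_real_, converged = FALSE, boundary = NA)
    })
    corRows[[key]] <- row
  }
  manifest <- list(seed = seed, tol = tol, max_iter = max_iter,
                   n_se_samples = n_se_samples,
                   n_univariate = length(traits),
                   n_bivariate = length(pairs),
                   class_effects = class_effects,
                   date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   iterations = vapply(uniFits, function(f) f@niter,
                                       integer(1)))
  new("StudyReport",
      descriptives = desc,
      heritability = do.call(rbind, c(heriRows,
                                      list(make.row.names = FALSE))),
      correlations = do.call(rbind, c(corRows,
                                      list(make.row.names = FALSE))),
      diagnostics = if (length(diagRows))
        do.call(rbind, c(diagRows, list(make.row.names = FALSE)))
      else data.frame(),
      manifest = manifest)
}

#' Write a study report as CSV tables plus a YAML manifest
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
writeStudyReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(descriptives = file.path(dir, "descriptives.csv"),
             heritability = file.path(dir, "heritability.csv"),
             correlations = file.path(dir, "correlations.csv"),
             diagnostics = file.path(dir, "diagnostics.csv"),
             manifest = file.path(dir, "manifest.yaml"))
  utils::write.csv(report@descriptives, paths["descriptives"],
                   row.names = FALSE)
  utils::write.csv(report@heritability, paths["heritability"],
                   row.names = FALSE)
  utils::write.csv(report@correlations, paths["correlations"],
                   row.names = FALSE)
  utils::write.csv(report@diagnostics, paths["diagnostics"],
                   row.names = FALSE)
  yaml::write_yaml(report@manifest, paths["manifest"])
  invisible(paths)
}

#' Correlation matrix view of a study report
#'
#' Square matrix over the traits of the report's bivariate fits with
#' genetic correlations above the diagonal, phenotypic below and unit
#' diagonal.
#' @param report a [StudyReport-class].
#' @return numeric matrix.
#' @export
correlationMatrix <- function(report) {
  cr <- report@correlations
  traits <- unique(c(cr$trait_x, cr$trait_y))
  M <- diag(1, length(traits))
  dimnames(M) <- list(traits, traits)
  for (k in seq_len(nrow(cr))) {
    i <- match(cr$trait_x[k], traits); j <- match(cr$trait_y[k], traits)
    M[min(i, j), max(i, j)] <- cr$rg[k]
    M[max(i, j), min(i, j)] <- cr$rp[k]
  }
  M
}
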