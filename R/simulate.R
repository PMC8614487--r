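## Gene-dropping simulator: pedigrees, breeding values and phenotypes with
## exactly the covariance structure the animal model assumes
## (Var(u) = G (x) A via gene dropping, Var(e) = R (x) I with per-record
## observed-trait patterns, slaughter-date contemporary groups and a
## slaughter-age covariate).

#' Configuration for the phenotype simulator
#'
#' Defaults emulate a progeny-test carcass study at desk scale: discrete
#' generations, slaughter-date contemporary groups, slaughter age about
#' 23.71 months (SD 0.64) recorded in days, and an optional fraction of
#' animals carrying only the first block of traits (the carcass-only
#' subset of a nested design).
#'
#' @param n_founders founder animals (half used as sires, half as dams).
#' @param n_generations number of discrete offspring generations.
#' @param offspring_per_mating offspring produced per dam and generation.
#' @param mating_scheme \code{"random"} (every male a candidate sire) or
#'   \code{"half-sib"} (only \code{n_sires} males sire a generation,
#'   giving large paternal half-sib families).
#' @param n_sires number of active sires per generation under
#'   \code{"half-sib"}.
#' @param G,R true additive-genetic and residual (co)variance matrices
#'   (t x t, positive definite).
#' @param trait_names,trait_means per-trait names and means (intercepts).
#' @param n_phenotyped number of phenotyped animals, drawn from the
#'   youngest birth cohorts; defaults to all animals of the final
#'   generation.
#' @param n_slaughter_dates total slaughter-date levels, split across the
#'   phenotyped birth cohorts (animals of one cohort share a date block,
#'   echoing batched slaughter).
#' @param date_effect_sd per-trait SD of the i.i.d. normal slaughter-date
#'   effects (recycled to t).
#' @param age_mean_months,age_sd_months slaughter-age distribution; ages
#'   are recorded in days (1 month = 30.4375 days).
#' @param age_slope per-trait regression of phenotype on slaughter age
#'   (units per day, recycled to t).
#' @param missingness fraction of phenotyped animals whose
#'   \code{missing_traits} are unrecorded (0 = complete records).
#' @param missing_traits indices of the traits subject to missingness.
#' @param seed default RNG seed used when the simulation functions are not
#'   given one explicitly.
#' @return a list with class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_founders = 200L, n_generations = 4L,
                             offspring_per_mating = 2L,
                             mating_scheme = c("random", "half-sib"),
                             n_sires = 25L,
                             G = matrix(0.4), R = matrix(0.6),
                             trait_names = paste0("trait", seq_len(nrow(G))),
                             trait_means = rep(10, nrow(G)),
                             n_phenotyped = NULL,
                             n_slaughter_dates = 20L,
                             date_effect_sd = 0.25,
                             age_mean_months = 23.71,
                             age_sd_months = 0.64,
                             age_slope = 0,
                             missingness = 0,
                             missing_traits = integer(0),
                             seed = 1L) {
  mating_scheme <- match.arg(mating_scheme)
  G <- as.matrix(G); R <- as.matrix(R)
  t <- nrow(G)
  stopifnot(all(dim(R) == t), length(trait_means) == t,
            n_founders >= 2L, n_generations >= 0L,
            offspring_per_mating >= 1L,
            missingness >= 0, missingness <= 1,
            age_sd_months >= 0, all(date_effect_sd >= 0))
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("true G and R must be positive definite")
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    mating_scheme = mating_scheme, n_sires = as.integer(n_sires),
    G = G, R = R, trait_names = trait_names, trait_means = trait_means,
    n_phenotyped = n_phenotyped,
    n_slaughter_dates = as.integer(n_slaughter_dates),
    date_effect_sd = rep_len(date_effect_sd, t),
    age_mean_months = age_mean_months, age_sd_months = age_sd_months,
    age_slope = rep_len(age_slope, t),
    missingness = missingness, missing_traits = missing_traits,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Birth cohort (discrete generation) of every animal
#'
#' Founders are cohort 0; an offspring's cohort is one above its youngest
#' known parent.
#' @param ped a [Pedigree-class]
#' @return named integer vector.
#' @export
birthCohort <- function(ped) {
  n <- length(ped@id)
  g <- integer(n)
  for (i in seq_len(n)) {
    ps <- c(ped@sire[i], ped@dam[i])
    ps <- ps[!is.na(ps)]
    g[i] <- if (length(ps)) max(g[ps]) + 1L else 0L
  }
  setNames(g, ped@id)
}

#' Simulate a multi-generation pedigree
#'
#' @param cfg a [simulationConfig()].
#' @param seed RNG seed (default from the config).
#' @return a [Pedigree-class]
#' @export
simulatePedigree <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$n_founders < 2L) stop("at least 2 founders are required")
  set.seed(seed)
  id <- sprintf("F%04d", seq_len(cfg$n_founders))
  sire <- dam <- rep(NA_character_, cfg$n_founders)
  sex <- rep_len(c("M", "F"), cfg$n_founders)
  prevIds <- id; prevSex <- sex
  for (g in seq_len(cfg$n_generations)) {
    males <- prevIds[prevSex == "M"]
    females <- prevIds[prevSex == "F"]
    if (!length(males) || !length(females))
      stop("a generation ran out of sires or dams")
    sires <- if (cfg$mating_scheme == "half-sib")
      sample(males, min(cfg$n_sires, length(males))) else males
    nOff <- length(females) * cfg$offspring_per_mating
    offId <- sprintf("G%d_%04d", g, seq_len(nOff))
    offDam <- rep(females, each = cfg$offspring_per_mating)
    ## each dam is mated to a single (random) sire per generation
    damSire <- sample(sires, length(females), replace = TRUE)
    offSire <- rep(damSire, each = cfg$offspring_per_mating)
    offSex <- sample(c("M", "F"), nOff, replace = TRUE)
    id <- c(id, offId); sire <- c(sire, offSire); dam <- c(dam, offDam)
    prevIds <- offId; prevSex <- offSex
  }
  Pedigree(id, sire, dam)
}

#' Gene-drop breeding values down a pedigree
#'
#' Founders receive Normal(0, G); an offspring's value is the parental
#' average plus a Mendelian-sampling deviation with (co)variance
#' G d_i, where d_i = 0.5 - 0.25(F_sire + F_dam) (0.75 - 0.25 F_known with
#' one known parent, 1 for founders). Across replicates
#' Cov(u_i, u_j) = a(i,j) G.
#'
#' @param ped a [Pedigree-class]
#' @param G t x t positive-definite additive covariance.
#' @param seed RNG seed.
#' @return q x t matrix of breeding values (rows follow [animalIds()]).
#' @export
dropBreedingValues <- function(ped, G, seed = 1L) {
  stopifnot(is(ped, "Pedigree"))
  G <- as.matrix(G)
  t <- nrow(G)
  .checkPD(G, "G")
  q <- length(ped@id)
  Lg <- chol(G)  # upper: t(Lg) %*% Lg = G
  dvec <- mendelianVariance(ped)
  set.seed(seed)
  Zm <- matrix(rnorm(q * t), q, t) %*% Lg  # rows ~ N(0, G)
  u <- matrix(0, q, t)
  s <- ped@sire; d <- ped@dam
  for (i in seq_len(q)) {
    base <- 0
    if (!is.na(s[i])) base <- base + 0.5 * u[s[i], ]
    if (!is.na(d[i])) base <- base + 0.5 * u[d[i], ]
    u[i, ] <- base + sqrt(dvec[i]) * Zm[i, ]
  }
  rownames(u) <- ped@id
  colnames(u) <- colnames(G)
  u
}

#' Simulate phenotypes on top of breeding values
#'
#' phenotype = trait mean + slaughter-date effect + age slope x (age - mean
#' age) + breeding value + residual, with residuals drawn from R and the
#' configured fraction of animals missing the \code{missing_traits} block.
#'
#' @param ped a [Pedigree-class]
#' @param u breeding-value matrix from [dropBreedingValues()].
#' @param cfg a [simulationConfig()].
#' @param seed RNG seed.
#' @return list: \code{phenotypes} (data.frame: animal, slaughter_date,
#'   slaughter_age, one column per trait), and \code{truth} (list of the
#'   exact generative components: breeding values, date effects, residuals,
#'   ages) so every record can be reconstructed.
#' @export
simulatePhenotypes <- function(ped, u, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "SimulationConfig"), is(ped, "Pedigree"))
  t <- nrow(cfg$G)
  q <- length(ped@id)
  stopifnot(nrow(u) == q, ncol(u) == t)
  cohort <- birthCohort(ped)
  nPhe <- if (is.null(cfg$n_phenotyped))
    sum(cohort == max(cohort)) else cfg$n_phenotyped
  if (nPhe > q)
    stop("requested ", nPhe, " phenotyped animals but the pedigree has ",
         q)
  ## youngest cohorts first, oldest animals of the cut cohort dropped
  ord <- order(-cohort, seq_len(q))
  phe <- sort(ord[seq_len(nPhe)])
  set.seed(seed)
  ## slaughter dates in cohort blocks
  cohPhe <- cohort[phe]
  cohLevels <- sort(unique(cohPhe))
  nDates <- max(cfg$n_slaughter_dates, length(cohLevels))
  datesPerCoh <- diff(round(seq(0, nDates, length.out =
                                  length(cohLevels) + 1L)))
  dateBlocks <- split(seq_len(nDates),
                      rep(seq_along(cohLevels), datesPerCoh))
  date <- integer(nPhe)
  for (k in seq_along(cohLevels)) {
    inCoh <- which(cohPhe == cohLevels[k])
    date[inCoh] <- sample(dateBlocks[[k]], length(inCoh), replace = TRUE)
  }
  dateEffects <- matrix(rnorm(nDates * t), nDates, t) %*%
    diag(cfg$date_effect_sd, t)
  ageDays <- rnorm(nPhe, cfg$age_mean_months, cfg$age_sd_months) * 30.4375
  meanAgeDays <- cfg$age_mean_months * 30.4375
  resid <- matrix(rnorm(nPhe * t), nPhe, t) %*% chol(cfg$R)
  Y <- matrix(cfg$trait_means, nPhe, t, byrow = TRUE) +
    dateEffects[date, , drop = FALSE] +
    outer(ageDays - meanAgeDays, cfg$age_slope) +
    u[phe, , drop = FALSE] + resid
  colnames(Y) <- cfg$trait_names
  ## nested missingness: a fraction of animals lacks the cut-trait block
  missRow <- rep(FALSE, nPhe)
  if (cfg$missingness > 0 && length(cfg$missing_traits)) {
    missRow <- as.logical(stats::rbinom(nPhe, 1L, cfg$missingness))
    Y[missRow, cfg$missing_traits] <- NA
  }
  ph <- data.frame(animal = ped@id[phe],
                   slaughter_date = sprintf("d%03d", date),
                   slaughter_age = ageDays, Y,
                   check.names = FALSE)
  list(phenotypes = ph,
       truth = list(phenotyped = ped@id[phe], u = u,
                    date_effects = dateEffects, date = date,
                    age_days = ageDays, mean_age_days = meanAgeDays,
                    residuals = resid, missing_row = missRow))
}

#' Simulate a complete dataset (pedigree, breeding values, phenotypes)
#'
#' Deterministic given the config and seed: derived seeds for the three
#' stages are fixed offsets of \code{seed}.
#'
#' @param cfg a [simulationConfig()].
#' @param seed master RNG seed (default from the config).
#' @return list: \code{ped}, \code{u}, \code{phenotypes}, \code{truth}.
#' @export
simulateDataset <- function(cfg, seed = cfg$seed) {
  ped <- simulatePedigree(cfg, seed = seed)
  u <- dropBreedingValues(ped, cfg$G, seed = seed + 1000L)
  sim <- simulatePhenotypes(ped, u, cfg, seed = seed + 2000L)
  list(ped = ped, u = u, phenotypes = sim$phenotypes, truth = sim$truth)
}

#' Write a simulated dataset to CSV files
#'
#' Emits the pedigree and phenotype CSV dialects the design module reads,
#' plus a truth file of breeding values for recovery diagnostics.
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pped <- file.path(dir, "pedigree.csv")
  pphe <- file.path(dir, "phenotypes.csv")
  ptru <- file.path(dir, "breeding_values.csv")
  writePedigree(sim$ped, pped)
  utils::write.csv(sim$phenotypes, pphe, row.names = FALSE)
  utils::write.csv(data.frame(animal = rownames(sim$u), sim$u,
                              check.names = FALSE),
                   ptru, row.names = FALSE)
  invisible(c(pedigree = pped, phenotypes = pphe, truth = ptru))
}
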