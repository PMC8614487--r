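test_that("simulated pedigrees are deterministic and well-formed", {
  cfg <- simulationConfig(n_founders = 30L, n_generations = 3L, seed = 4L)
  p1 <- simulatePedigree(cfg)
  p2 <- simulatePedigree(cfg)
  expect_identical(animalIds(p1), animalIds(p2))
  expect_identical(p1@sire, p2@sire)
  ## zero generations: founders only
  cfg0 <- simulationConfig(n_founders = 12L, n_generations = 0L)
  p0 <- simulatePedigree(cfg0)
  expect_equal(nAnimals(p0), 12L)
  expect_true(all(is.na(p0@sire)))
  expect_error(simulationConfig(n_founders = 0L), "n_founders")
})

test_that("half-sib scheme produces the configured family sizes", {
  cfg <- simulationConfig(n_founders = 2000L, n_generations = 1L,
                          offspring_per_mating = 1L,
                          mating_scheme = "half-sib", n_sires = 50L,
                          seed = 10L)
  ## 1000 dams, 50 active sires: mean paternal family size near 20
  ped <- simulatePedigree(cfg)
  off <- which(!is.na(ped@sire))
  fam <- table(ped@sire[off])
  expect_equal(sum(fam), 1000)
  expect_gt(mean(fam), 17)
  expect_lt(mean(fam), 23)
})

test_that("gene-dropped values have covariance a(i,j) G", {
  ## founders: sample variance matches G within MC error
  f <- Pedigree(c("x", "y"), c(NA, NA), c(NA, NA))
  G <- matrix(c(2, 0.8, 0.8, 1), 2)
  reps <- 4000L
  us <- vapply(seq_len(reps), function(r)
    dropBreedingValues(f, G, seed = r)[1L, ], numeric(2))
  emp <- stats::cov(t(us))
  mcse <- sqrt(2 / reps) * max(diag(G))
  expect_lt(max(abs(emp - G)), 3 * mcse)

  ## parent-offspring correlation 0.5 for unit G
  trio <- Pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
  u <- vapply(seq_len(reps), function(r)
    dropBreedingValues(trio, matrix(1), seed = 10000L + r)[, 1L],
    numeric(3))
  r_so <- stats::cor(u["s", ], u["o", ])
  expect_lt(abs(r_so - 0.5), 3 / sqrt(reps))

  ## diagonal G: traits uncorrelated
  u2 <- vapply(seq_len(reps), function(r)
    dropBreedingValues(f, diag(c(1, 2)), seed = 20000L + r)[1L, ],
    numeric(2))
  expect_lt(abs(stats::cor(u2[1, ], u2[2, ])), 3 / sqrt(reps))

  ## full-sib-mating pedigree: replicate covariance matches A entrywise
  ped <- fullSibPedigree()
  A <- relA(buildA(ped))
  u3 <- vapply(seq_len(reps), function(r)
    dropBreedingValues(ped, matrix(1), seed = 30000L + r)[, 1L],
    numeric(5))
  empA <- stats::cov(t(u3))
  expect_lt(max(abs(empA - A)), 3 * sqrt(2 / reps) * max(A))
})

test_that("phenotypes decompose exactly into their stored components", {
  cfg <- simulationConfig(n_founders = 30L, n_generations = 2L,
                          G = diag(c(1, 2)), R = diag(c(2, 1)),
                          trait_names = c("y1", "y2"),
                          trait_means = c(5, 50), n_slaughter_dates = 6L,
                          date_effect_sd = c(0.4, 0.6),
                          age_slope = c(0.1, -0.2), seed = 3L)
  sim <- simulateDataset(cfg)
  tr <- sim$truth
  ph <- sim$phenotypes
  for (tt in 1:2) {
    expct <- cfg$trait_means[tt] +
      tr$date_effects[tr$date, tt] +
      cfg$age_slope[tt] * (tr$age_days - tr$mean_age_days) +
      sim$u[tr$phenotyped, tt] + tr$residuals[, tt]
    expect_equal(ph[[cfg$trait_names[tt]]], unname(expct),
                 tolerance = 1e-12)
  }
  ## noise-free limit: phenotype minus mean equals the breeding value
  cfg0 <- simulationConfig(n_founders = 20L, n_generations = 1L,
                           G = matrix(1), R = matrix(1e-12),
                           trait_names = "y", trait_means = 7,
                           date_effect_sd = 0, age_slope = 0, seed = 5L)
  sim0 <- simulateDataset(cfg0)
  expect_equal(sim0$phenotypes$y - 7,
               unname(sim0$u[sim0$truth$phenotyped, 1L]),
               tolerance = 1e-4)
})

test_that("configured missingness reproduces the nested record design", {
  cfg <- simulationConfig(n_founders = 400L, n_generations = 1L,
                          offspring_per_mating = 5L,
                          G = diag(2), R = diag(2),
                          trait_names = c("carc", "cut"),
                          trait_means = c(1, 1), missingness = 0.38,
                          missing_traits = 2L, seed = 8L)
  sim <- simulateDataset(cfg)
  n <- nrow(sim$phenotypes)
  fmiss <- mean(is.na(sim$phenotypes$cut))
  ## binomial 3-sigma interval around 0.38
  expect_lt(abs(fmiss - 0.38), 3 * sqrt(0.38 * 0.62 / n))
  expect_true(!anyNA(sim$phenotypes$carc))
})

test_that("simulated trait means land on their configured targets", {
  cfg <- hanwooConfig(traits = c("CW", "BFT"), n_founders = 300L,
                      n_generations = 2L, offspring_per_mating = 3L,
                      n_phenotyped = 900L, missingness = 0, seed = 12L)
  sim <- simulateDataset(cfg)
  d <- descriptives(sim$phenotypes, c("CW", "BFT"))
  tgt <- hanwooTargets()
  nDates <- length(unique(sim$phenotypes$slaughter_date))
  for (tr in c("CW", "BFT")) {
    mu <- tgt$mean[tgt$trait == tr]
    row <- d[d$trait == tr, ]
    dsd <- cfg$date_effect_sd[match(tr, cfg$trait_names)]
    ## date effects are shared across a date's animals, so the realized
    ## mean carries a date-level variance term on top of the record-level one
    se <- sqrt(row$sd^2 / row$n + dsd^2 / nDates)
    expect_lt(abs(row$mean - mu), 3 * se)
  }
})

test_that("datasets round-trip through the CSV writers", {
  cfg <- simulationConfig(n_founders = 20L, n_generations = 1L, seed = 2L)
  sim <- simulateDataset(cfg)
  dir <- withr::local_tempdir()
  paths <- writeDataset(sim, dir)
  ped <- readPedigree(paths["pedigree"])
  expect_equal(sort(animalIds(ped)), sort(animalIds(sim$ped)))
  ph <- readPhenotypes(paths["phenotypes"])
  expect_equal(nrow(ph), nrow(sim$phenotypes))
  expect_equal(ph$trait1, sim$phenotypes$trait1, tolerance = 1e-12)
})

test_that("hanwoo emulation config is internally consistent", {
  cfg <- hanwooConfig()
  expect_equal(length(cfg$trait_names), 14L)
  expect_gt(min(eigen(cfg$G, symmetric = TRUE, only.values = TRUE)$values),
            0)
  expect_gt(min(eigen(cfg$R, symmetric = TRUE, only.values = TRUE)$values),
            0)
  ## genetic correlations preserved where published (sampled entries)
  Cg <- stats::cov2cor(cfg$G)
  expect_equal(Cg["TRD", "BRD"], 0.93, tolerance = 0.05)
  expect_equal(Cg["CW", "RB"], 0.82, tolerance = 0.06)
  expect_equal(Cg["BFT", "TLN"], -0.46, tolerance = 0.05)
  ## per-trait variances preserved
  tgt <- hanwooTargets()
  expect_equal(unname(diag(cfg$G)), tgt$sigma2_g, tolerance = 1e-8)
  expect_equal(unname(diag(cfg$R)), tgt$sigma2_e, tolerance = 1e-8)
})
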