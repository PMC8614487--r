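mkVC <- function(G, R, traits = paste0("t", seq_len(nrow(as.matrix(G)))))
  new("VarianceComponents", G = as.matrix(G), R = as.matrix(R),
      traits = traits)

test_that("heritability is the additive fraction of phenotypic variance", {
  expect_equal(round(heritability(mkVC(7.20, 5.48)), 2), 0.57)
  expect_equal(round(heritability(mkVC(1.44, 1.01)), 2), 0.59)
  expect_equal(heritability(mkVC(0 + 1e-300, 2)), 0, tolerance = 1e-12)
  expect_error(heritability(mkVC(0, 0)), "zero phenotypic variance")
  ## bivariate trait selection by name
  vc <- mkVC(diag(c(2, 1)), diag(c(2, 3)), c("a", "b"))
  expect_equal(heritability(vc, "b"), 0.25)
})

test_that("correlations follow the covariance-ratio formulas", {
  vc <- mkVC(matrix(c(2, 0, 0, 3), 2), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(vcCorrelation(vc, "genetic"), 0)
  ## perfect genetic correlation
  g <- matrix(c(2, sqrt(2 * 3), sqrt(2 * 3), 3), 2)
  vc2 <- mkVC(g + diag(1e-9, 2), diag(2))
  expect_equal(vcCorrelation(vc2, "genetic"), 1, tolerance = 1e-6)
  ## random PD components match direct arithmetic
  set.seed(2)
  for (k in 1:10) {
    L1 <- matrix(rnorm(4), 2); L2 <- matrix(rnorm(4), 2)
    G <- crossprod(L1) + diag(0.1, 2); R <- crossprod(L2) + diag(0.1, 2)
    vc3 <- mkVC(G, R)
    expect_equal(vcCorrelation(vc3, "genetic"),
                 G[1, 2] / sqrt(G[1, 1] * G[2, 2]))
    P <- G + R
    expect_equal(vcCorrelation(vc3, "phenotypic"),
                 P[1, 2] / sqrt(P[1, 1] * P[2, 2]))
  }
  expect_error(vcCorrelation(mkVC(2, 3)), "bivariate")
})

test_that("genetic coefficient of variation matches the printed cells", {
  expect_equal(round(cvGenetic(7.20, 9.92), 2), 27.05)
  expect_equal(round(cvGenetic(1.44, 3.53), 2), 33.99)
  expect_equal(round(cvGenetic(29.06, 81.62), 2), 6.60)
  expect_equal(cvGenetic(0, 5), 0)
  expect_error(cvGenetic(1, 0), "positive")
  expect_error(cvGenetic(-1, 5), "non-negative")
})

test_that("sampling SEs match closed forms", {
  toyFit <- function() {
    hd <- halfSibData(40L, 12L, h2 = 0.4, vp = 10, seed = 13L)
    dm <- buildDesign(hd$ph, hd$ped, modelSpec("y"))
    airemlFit(dm, buildAInverse(hd$ped))
  }
  fit <- toyFit()
  ## linear function a'theta: SE = sqrt(a' V a)
  a <- c(0.7, -0.3)
  seS <- seBySampling(fit, function(th) sum(a * th), n_samples = 10000L,
                      seed = 5L, raw = TRUE)
  seC <- sqrt(drop(t(a) %*% fit@thetaCov %*% a))
  expect_lt(abs(seS - seC) / seC, 0.03)
  ## zero covariance: SE exactly 0
  fit0 <- fit
  fit0@thetaCov <- matrix(0, 2, 2)
  expect_equal(as.numeric(seBySampling(fit0, function(th) sum(a * th),
                                       n_samples = 500L, raw = TRUE)), 0)
  ## h2: sampled SE within 10% of the delta-method SE
  seH <- seBySampling(fit, function(vc) heritability(vc, 1L),
                      n_samples = 10000L, seed = 7L)
  g <- fit@vc@G[1, 1]; r <- fit@vc@R[1, 1]; p <- g + r
  grad <- c(r / p^2, -g / p^2)
  seD <- sqrt(drop(t(grad) %*% fit@thetaCov %*% grad))
  expect_lt(abs(seH - seD) / seD, 0.10)
  ## MC stability: two seeds within 5% relative at 10,000 draws
  seH2 <- seBySampling(fit, function(vc) heritability(vc, 1L),
                       n_samples = 10000L, seed = 8L)
  expect_lt(abs(seH - seH2) / seH, 0.05)
  ## determinism given the seed
  expect_identical(
    as.numeric(seBySampling(fit, function(vc) heritability(vc, 1L),
                            n_samples = 2000L, seed = 3L)),
    as.numeric(seBySampling(fit, function(vc) heritability(vc, 1L),
                            n_samples = 2000L, seed = 3L)))
})

test_that("likelihood-ratio tests use the chi-squared thresholds", {
  expect_equal(round(qchisq(0.95, 1), 2), 3.84)
  expect_equal(round(qchisq(0.95, 2), 2), 5.99)
  sb <- smallBivariate(seed = 31L)
  full <- airemlFit(sb$dm, sb$rel)
  red1 <- fitConstrained(sb$dm, sb$rel, "no-genetic-cov")
  red2 <- fitConstrained(sb$dm, sb$rel, "no-cov")
  l1 <- lrtCorrelation(full, red1)
  expect_equal(l1$df, 1L)
  expect_equal(round(l1$threshold, 2), 3.84)
  expect_gte(l1$minus2logLambda, -1e-6)
  l2 <- lrtCorrelation(full, red2)
  expect_equal(l2$df, 2L)
  expect_equal(round(l2$threshold, 2), 5.99)
  ## equal likelihoods: statistic 0, not significant
  lEq <- lrtCorrelation(full, {
    r <- red1; r@logL <- full@logL; r
  })
  expect_equal(lEq$minus2logLambda, 0)
  expect_false(lEq$significant)
  ## non-nested pairs are rejected
  expect_error(lrtCorrelation(full, full), "not nested")
  expect_error(lrtCorrelation(red1, full), "unconstrained")
  expect_error(lrtCorrelation(full, red2, df = 1), "inconsistent")
})

test_that("h2 and correlations are invariant to phenotype rescaling", {
  set.seed(6)
  for (k in 1:5) {
    L1 <- matrix(rnorm(4), 2); L2 <- matrix(rnorm(4), 2)
    G <- crossprod(L1) + diag(0.1, 2); R <- crossprod(L2) + diag(0.1, 2)
    cc <- exp(rnorm(1))
    vc <- mkVC(G, R); vcS <- mkVC(G * cc^2, R * cc^2)
    expect_equal(heritability(vcS, 1), heritability(vc, 1))
    expect_equal(vcCorrelation(vcS, "genetic"),
                 vcCorrelation(vc, "genetic"))
    expect_equal(vcCorrelation(vcS, "phenotypic"),
                 vcCorrelation(vc, "phenotypic"))
  }
})
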