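test_that("MME log-likelihood equals the dense-formula oracle", {
  toy <- toyUnivariate()
  vc <- new("VarianceComponents", G = matrix(2.3), R = matrix(4.1),
            traits = "y")
  expect_equal(remlLogLik(vc, toy$dm, toy$rel),
               denseREMLLogLik(vc, toy$dm, toy$ped), tolerance = 1e-9)

  ## bivariate with unequal records
  sb <- smallBivariate(seed = 31L)
  vc2 <- new("VarianceComponents", G = matrix(c(1.5, .4, .4, 1.1), 2),
             R = matrix(c(2.4, .5, .5, 1.7), 2), traits = c("y1", "y2"))
  expect_equal(remlLogLik(vc2, sb$dm, sb$rel),
               denseREMLLogLik(vc2, sb$dm, sb$sim$ped), tolerance = 1e-8)

  ## non-PD components are rejected with advice
  bad <- new("VarianceComponents", G = matrix(c(1, 2, 2, 1), 2),
             R = matrix(c(1, 0, 0, 1), 2), traits = c("y1", "y2"))
  expect_error(remlLogLik(bad, sb$dm, sb$rel), "positive definite")
})

test_that("adding a constant to y leaves the REML likelihood unchanged", {
  toy <- toyUnivariate()
  vc <- new("VarianceComponents", G = matrix(2), R = matrix(3),
            traits = "y")
  l0 <- remlLogLik(vc, toy$dm, toy$rel)
  ph2 <- toy$ph
  ph2$y <- ph2$y + 57.3
  dm2 <- buildDesign(ph2, toy$ped, modelSpec("y"))
  expect_equal(remlLogLik(vc, dm2, toy$rel), l0, tolerance = 1e-8)
})

test_that("block likelihood factorizes over disjoint-support traits", {
  ped <- Pedigree(sprintf("a%d", 1:16), rep(NA, 16), rep(NA, 16))
  set.seed(17)
  ph <- data.frame(animal = sprintf("a%d", 1:16),
                   y1 = c(rnorm(8, 5, 1), rep(NA, 8)),
                   y2 = c(rep(NA, 8), rnorm(8, 9, 2)))
  rel <- buildAInverse(ped)
  dmB <- buildDesign(ph, ped, modelSpec(c("y1", "y2")))
  vcB <- new("VarianceComponents", G = diag(c(1.2, 0.9)),
             R = diag(c(2.1, 1.4)), traits = c("y1", "y2"))
  lB <- remlLogLik(vcB, dmB, rel)
  l1 <- remlLogLik(new("VarianceComponents", G = matrix(1.2),
                       R = matrix(2.1), traits = "y1"),
                   buildDesign(ph[1:8, c("animal", "y1")], ped,
                               modelSpec("y1")), rel)
  l2 <- remlLogLik(new("VarianceComponents", G = matrix(0.9),
                       R = matrix(1.4), traits = "y2"),
                   buildDesign(ph[9:16, c("animal", "y2")], ped,
                               modelSpec("y2")), rel)
  expect_equal(lB, l1 + l2, tolerance = 1e-8)
})

test_that("convergence criterion is the relative squared parameter change", {
  expect_equal(convergenceCriterion(c(1, 2), c(1, 2)), 0)
  expect_equal(convergenceCriterion(2, 1), 0.25)
  expect_equal(convergenceCriterion(c(1, 1), c(0, 0)), 1)
  expect_error(convergenceCriterion(c(0, 0), c(1, 1)), "all-zero")
  expect_error(convergenceCriterion(1:3, 1:2), "same length")
})

test_that("EM updates are monotone and fix the REML optimum", {
  toy <- toyUnivariate()
  ## monotone increase from inflated start over 5 iterations
  vc <- new("VarianceComponents", G = matrix(30), R = matrix(30),
            traits = "y")
  lPrev <- remlLogLik(vc, toy$dm, toy$rel)
  for (k in 1:5) {
    vc <- emUpdate(vc, toy$dm, toy$rel)
    l <- remlLogLik(vc, toy$dm, toy$rel)
    expect_gte(l, lPrev - 1e-9)
    lPrev <- l
  }
  ## fixed point at the converged optimum
  fit <- airemlFit(toy$dm, toy$rel)
  expect_true(fit@converged)
  up <- emUpdate(fit@vc, toy$dm, toy$rel)
  move <- abs(c(up@G - fit@vc@G, up@R - fit@vc@R)) /
    max(abs(fit@theta))
  expect_lt(max(move), 1e-6)
})

test_that("pure-noise founder data drives the EM additive variance to 0", {
  ped <- Pedigree(sprintf("f%d", 1:40), rep(NA, 40), rep(NA, 40))
  set.seed(12)
  ph <- data.frame(animal = sprintf("f%d", 1:40), y = rnorm(40))
  dm <- buildDesign(ph, ped, modelSpec("y"))
  rel <- buildAInverse(ped)
  vc <- new("VarianceComponents", G = matrix(1), R = matrix(1),
            traits = "y")
  g <- numeric(6)
  for (k in 1:6) {
    vc <- emUpdate(vc, dm, rel)
    g[k] <- vc@G[1, 1]
  }
  expect_true(all(diff(g) < 0))
})

test_that("AI update is stationary at the oracle optimum", {
  toy <- toyUnivariate()
  ## independent oracle: derivative-free maximization of the dense logL
  fn <- function(p) -denseREMLLogLik(
    new("VarianceComponents", G = matrix(exp(p[1])), R = matrix(exp(p[2])),
        traits = "y"), toy$dm, toy$ped)
  o <- stats::optim(log(c(2, 4)), fn, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 5000))
  vcStar <- new("VarianceComponents", G = matrix(exp(o$par[1])),
                R = matrix(exp(o$par[2])), traits = "y")
  up <- aiUpdate(vcStar, toy$dm, toy$rel)
  scale <- max(abs(c(vcStar@G, vcStar@R)))
  expect_lt(max(abs(up$grad)), 1e-3)
  step <- abs(c(up$vc@G - vcStar@G, up$vc@R - vcStar@R)) / scale
  expect_lt(max(step), 1e-3)
  ## AI matrix is symmetric PD at the optimum
  expect_equal(up$AI, t(up$AI))
  expect_gt(min(eigen(up$AI, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("AI iteration reaches 1e-12 where pure EM crawls", {
  hd <- halfSibData(25L, 8L, h2 = 0.4, vp = 10, seed = 55L)
  dm <- buildDesign(hd$ph, hd$ped, modelSpec("y"))
  rel <- buildAInverse(hd$ped)
  fAI <- airemlFit(dm, rel, em_warmup = 2L)
  expect_true(fAI@converged)
  expect_lte(fAI@niter, 15L)
  fEM <- airemlFit(dm, rel, em_warmup = 1000L, max_iter = 100L)
  expect_false(fEM@converged)
  ## both walk the same hill
  expect_equal(fEM@logL, fAI@logL, tolerance = 1e-4)
})

test_that("the fit matches a grid-plus-refinement oracle on toy data", {
  toy <- toyUnivariate()
  fit <- airemlFit(toy$dm, toy$rel)
  expect_true(fit@converged)
  ## coarse grid on (sigma2_g, sigma2_e), then local refinement -- all on
  ## the dense-formula likelihood
  grid <- expand.grid(g = seq(0.5, 12, length.out = 14),
                      e = seq(0.5, 12, length.out = 14))
  lg <- apply(grid, 1, function(r) denseREMLLogLik(
    new("VarianceComponents", G = matrix(r[1]), R = matrix(r[2]),
        traits = "y"), toy$dm, toy$ped))
  best <- grid[which.max(lg), ]
  o <- stats::optim(log(as.numeric(best)), function(p) -denseREMLLogLik(
    new("VarianceComponents", G = matrix(exp(p[1])), R = matrix(exp(p[2])),
        traits = "y"), toy$dm, toy$ped), method = "Nelder-Mead",
    control = list(reltol = 1e-15, maxit = 5000))
  oracle <- exp(o$par)
  est <- c(fit@vc@G[1, 1], fit@vc@R[1, 1])
  expect_lt(max(abs(est - oracle) / oracle), 1e-4)
})

test_that("half-sib heritability agrees with the ANOVA sire estimator", {
  ns <- 50L; np <- 20L
  hd <- halfSibData(ns, np, h2 = 0.4, vp = 10, seed = 77L)
  dm <- buildDesign(hd$ph, hd$ped, modelSpec("y"))
  rel <- buildAInverse(hd$ped)
  fit <- airemlFit(dm, rel)
  h2REML <- heritability(fit@vc)
  ## closed-form ANOVA: sire variance from expected mean squares
  sire <- rep(seq_len(ns), each = np)
  av <- stats::aov(hd$ph$y ~ factor(sire))
  ms <- summary(av)[[1]]$`Mean Sq`
  s2s <- (ms[1] - ms[2]) / np
  tIC <- s2s / (s2s + ms[2])            # intraclass correlation
  h2ANOVA <- 4 * tIC
  ## empirical SE of the half-sib h2 estimate (Falconer)
  seANOVA <- 4 * sqrt(2 * (1 - tIC)^2 * (1 + (np - 1) * tIC)^2 /
                        (np * (np - 1) * (ns - 1)))
  expect_lt(abs(h2REML - h2ANOVA), 2 * seANOVA)
})

test_that("constrained fits drop the right parameters and factorize", {
  ## disjoint supports + no-cov constraint = two univariate fits
  ped <- Pedigree(sprintf("a%d", 1:30), rep(NA, 30), rep(NA, 30))
  set.seed(23)
  ph <- data.frame(animal = sprintf("a%d", 1:30),
                   y1 = c(rnorm(15, 5, 1.5), rep(NA, 15)),
                   y2 = c(rep(NA, 15), rnorm(15, 9, 2)))
  rel <- buildAInverse(ped)
  dmB <- buildDesign(ph, ped, modelSpec(c("y1", "y2")))
  ## founders-only data cannot separate sigma2_g from sigma2_e, so the
  ## AI matrix is singular at convergence (warned); the factorization
  ## property under test holds regardless
  fB <- suppressWarnings(fitConstrained(dmB, rel, "no-cov"))
  f1 <- suppressWarnings(airemlFit(buildDesign(ph[1:15, c("animal", "y1")],
                                               ped, modelSpec("y1")), rel))
  f2 <- suppressWarnings(airemlFit(buildDesign(ph[16:30, c("animal", "y2")],
                                               ped, modelSpec("y2")), rel))
  expect_equal(fB@logL, f1@logL + f2@logL, tolerance = 1e-6)
  expect_equal(fB@vc@G[1, 1], f1@vc@G[1, 1], tolerance = 1e-6)
  expect_equal(fB@vc@R[2, 2], f2@vc@R[1, 1], tolerance = 1e-6)
  ## theta excludes the fixed parameters
  expect_equal(length(fB@theta), 4L)
  expect_equal(dim(fB@thetaCov), c(4L, 4L))
  f1c <- suppressWarnings(fitConstrained(dmB, rel, "no-genetic-cov"))
  expect_equal(length(f1c@theta), 5L)
  expect_equal(f1c@vc@G[1, 2], 0)
  ## constraint on a univariate model errors
  dmU <- buildDesign(ph[1:15, c("animal", "y1")], ped, modelSpec("y1"))
  expect_error(airemlFit(dmU, rel, constraint = "no-cov"), "bivariate")
})

test_that("fits are invariant to record order and animal relabeling", {
  sb <- smallBivariate(seed = 41L, missingness = 0.25)
  f0 <- airemlFit(sb$dm, sb$rel)
  ## record order
  ph <- sb$sim$phenotypes
  set.seed(1); perm <- sample(nrow(ph))
  dmP <- buildDesign(ph[perm, ], sb$sim$ped,
                     modelSpec(c("y1", "y2"),
                               class_effects = "slaughter_date",
                               covariates = "slaughter_age"))
  fP <- airemlFit(dmP, sb$rel)
  expect_equal(fP@theta, f0@theta, tolerance = 1e-8)
  ## relabeling
  ped <- sb$sim$ped
  relabel <- function(x) ifelse(is.na(x), NA, paste0("zz_", x))
  pedR <- Pedigree(relabel(ped@id),
                   relabel(ifelse(is.na(ped@sire), NA, ped@id[ped@sire])),
                   relabel(ifelse(is.na(ped@dam), NA, ped@id[ped@dam])))
  phR <- ph
  phR$animal <- paste0("zz_", phR$animal)
  dmR <- buildDesign(phR, pedR,
                     modelSpec(c("y1", "y2"),
                               class_effects = "slaughter_date",
                               covariates = "slaughter_age"))
  fR <- airemlFit(dmR, buildAInverse(pedR))
  expect_equal(fR@theta, f0@theta, tolerance = 1e-8)
})

test_that("scaling y scales variances by c^2, leaving ratios fixed", {
  sb <- smallBivariate(seed = 43L, missingness = 0)
  f0 <- airemlFit(sb$dm, sb$rel)
  cc <- 3.7
  ph <- sb$sim$phenotypes
  ph$y1 <- ph$y1 * cc; ph$y2 <- ph$y2 * cc
  dmS <- buildDesign(ph, sb$sim$ped,
                     modelSpec(c("y1", "y2"),
                               class_effects = "slaughter_date",
                               covariates = "slaughter_age"))
  fS <- airemlFit(dmS, sb$rel)
  expect_equal(fS@vc@G, f0@vc@G * cc^2, tolerance = 1e-5)
  expect_equal(fS@vc@R, f0@vc@R * cc^2, tolerance = 1e-5)
  expect_equal(heritability(fS@vc, 1), heritability(f0@vc, 1),
               tolerance = 1e-6)
  expect_equal(vcCorrelation(fS@vc, "genetic"),
               vcCorrelation(f0@vc, "genetic"), tolerance = 1e-6)
  ## theta-cov sanity on the base fit
  expect_true(all(diag(f0@thetaCov) >= 0))
  cm <- stats::cov2cor(f0@thetaCov)
  expect_true(all(abs(cm) <= 1 + 1e-8))
})

test_that("hitting max_iter flags the fit as not converged", {
  toy <- toyUnivariate()
  f <- airemlFit(toy$dm, toy$rel, max_iter = 2L)
  expect_false(f@converged)
  expect_equal(f@niter, 2L)
})
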