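## Shared fixtures: small pedigrees, a random-pedigree generator, and an
## independent dense-matrix REML oracle used to validate the sparse engine.

## founders A, B; C = A x B; D = A x B; E = C x D (full-sib mating)
fullSibPedigree <- function() {
  Pedigree(c("A", "B", "C", "D", "E"),
           c(NA, NA, "A", "A", "C"),
           c(NA, NA, "B", "B", "D"))
}

## random valid pedigree: parents always have smaller index than offspring
randomPedigree <- function(n, n_founders = max(5L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  id <- sprintf("R%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pick <- sample(seq_len(i - 1L), 2L)
    sire[i] <- id[pick[1L]]
    if (stats::runif(1) > 0.1) dam[i] <- id[pick[2L]]
  }
  Pedigree(id, sire, dam)
}

## paternal half-sib design: n_sires sires, each with n_prog progeny from
## unrelated dams; phenotypes on the progeny
halfSibData <- function(n_sires, n_prog, h2 = 0.4, vp = 10, mu = 50,
                        seed = 1L) {
  sires <- sprintf("S%03d", seq_len(n_sires))
  nd <- n_sires * n_prog
  dams <- sprintf("D%04d", seq_len(nd))
  off <- sprintf("O%04d", seq_len(nd))
  ped <- Pedigree(c(sires, dams, off),
                  c(rep(NA, n_sires + nd), rep(sires, each = n_prog)),
                  c(rep(NA, n_sires + nd), dams))
  G <- matrix(h2 * vp); R <- matrix((1 - h2) * vp)
  u <- dropBreedingValues(ped, G, seed = seed)
  set.seed(seed + 1L)
  y <- mu + u[off, 1L] + rnorm(nd, 0, sqrt(R[1, 1]))
  list(ped = ped, ph = data.frame(animal = off, y = y), u = u,
       G = G, R = R)
}

## dense-formula restricted log-likelihood (the independent oracle):
## builds V = Z (G x A) Z' + Rn explicitly and evaluates
## -0.5 [log|V| + log|X'Vinv X| + y'Py] - 0.5 (n - p) log 2pi
denseREMLLogLik <- function(vc, dm, ped) {
  A <- relA(buildA(ped))
  q <- nAnimals(ped)
  t <- length(dm$traits)
  blocks <- dm$blocks
  ns <- vapply(blocks, function(b) length(b$y), integer(1))
  n <- sum(ns)
  X <- as.matrix(Matrix::bdiag(lapply(blocks, function(b) b$X)))
  Z <- matrix(0, n, t * q)
  off <- cumsum(c(0L, ns))
  for (tt in seq_len(t))
    Z[cbind(off[tt] + seq_len(ns[tt]), (tt - 1L) * q +
              blocks[[tt]]$animal)] <- 1
  y <- unlist(lapply(blocks, `[[`, "y"), use.names = FALSE)
  Rn <- matrix(0, n, n)
  for (tt in seq_len(t))
    diag(Rn)[off[tt] + seq_len(ns[tt])] <- vc@R[tt, tt]
  if (t == 2L) {
    common <- intersect(blocks[[1L]]$animal, blocks[[2L]]$animal)
    for (a in common) {
      i <- which(blocks[[1L]]$animal == a)
      j <- off[2L] + which(blocks[[2L]]$animal == a)
      Rn[i, j] <- Rn[j, i] <- vc@R[1, 2]
    }
  }
  V <- Z %*% kronecker(vc@G, A) %*% t(Z) + Rn
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XVX)$modulus +
                       t(y) %*% P %*% y) -
               0.5 * (n - ncol(X)) * log(2 * pi))
}

## small simulated bivariate dataset with design structure
smallBivariate <- function(seed = 1L, n_founders = 60L, missingness = 0.3,
                           G = matrix(c(2, 0.8, 0.8, 1.5), 2),
                           R = matrix(c(3, 0.6, 0.6, 2), 2),
                           n_generations = 3L, n_phenotyped = 150L) {
  cfg <- simulationConfig(n_founders = n_founders,
                          n_generations = n_generations,
                          offspring_per_mating = 2L,
                          G = G, R = R, trait_names = c("y1", "y2"),
                          trait_means = c(10, 20), n_slaughter_dates = 5L,
                          date_effect_sd = c(0.5, 0.4),
                          missingness = missingness,
                          missing_traits = 2L, seed = seed,
                          n_phenotyped = n_phenotyped)
  sim <- simulateDataset(cfg)
  spec <- modelSpec(c("y1", "y2"), class_effects = "slaughter_date",
                    covariates = "slaughter_age")
  dm <- buildDesign(sim$phenotypes, sim$ped, spec)
  list(sim = sim, dm = dm, rel = buildAInverse(sim$ped), cfg = cfg)
}

## fixed 8-record toy dataset (4 sires x 2 progeny) with genuine additive
## signal and an interior REML optimum
toyUnivariate <- function(seed = 104L) {
  hd <- halfSibData(4L, 2L, h2 = 0.6, vp = 8, seed = seed)
  dm <- buildDesign(hd$ph, hd$ped, modelSpec("y"))
  list(dm = dm, rel = buildAInverse(hd$ped), ped = hd$ped, ph = hd$ph)
}
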