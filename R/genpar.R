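## Derived genetic parameters and their uncertainty.

#' Heritability from variance components
#'
#' h^2 = sigma^2_g / (sigma^2_g + sigma^2_e): the proportion of phenotypic
#' variance attributable to additive genetic variance. The phenotypic
#' variance is the sum of the additive and residual variances (no other
#' components exist in the model).
#'
#' @param vc a [VarianceComponents-class]
#' @param trait trait index (1 or 2) or trait name.
#' @return scalar in [0, 1].
#' @examples
#' vc <- new("VarianceComponents", G = matrix(7.20), R = matrix(5.48),
#'           traits = "BFT")
#' heritability(vc)   # 0.568
#' @export
heritability <- function(vc, trait = 1L) {
  i <- .traitIndex(vc, trait)
  s2g <- vc@G[i, i]; s2e <- vc@R[i, i]
  if (s2g + s2e <= 0) stop("zero phenotypic variance for trait ", trait)
  h2 <- s2g / (s2g + s2e)
  min(max(h2, 0), 1)
}

.traitIndex <- function(vc, trait) {
  if (is.character(trait)) {
    i <- match(trait, vc@traits)
    if (is.na(i)) stop("unknown trait: ", trait)
    i
  } else as.integer(trait)
}

#' Genetic or phenotypic correlation between two traits
#'
#' r_g = sigma_g(X,Y) / sqrt(sigma^2_gX sigma^2_gY); the phenotypic
#' correlation uses the phenotypic (co)variances P = G + R.
#'
#' @param vc a bivariate [VarianceComponents-class]
#' @param kind \code{"genetic"} or \code{"phenotypic"}.
#' @return scalar in [-1, 1].
#' @export
vcCorrelation <- function(vc, kind = c("genetic", "phenotypic")) {
  kind <- match.arg(kind)
  if (length(vc@traits) != 2L)
    stop("correlations require a bivariate component set")
  M <- if (kind == "genetic") vc@G else vc@G + vc@R
  if (M[1, 1] <= 0 || M[2, 2] <= 0)
    stop("zero variance trait: ", kind, " correlation undefined")
  r <- M[1, 2] / sqrt(M[1, 1] * M[2, 2])
  if (abs(r) > 1 + 1e-10)
    stop("correlation outside [-1, 1]: non-PSD components")
  min(max(r, -1), 1)
}

#' Genetic coefficient of variation
#'
#' CVg\% = sqrt(sigma^2_g) / mean x 100: the additive genetic standard
#' deviation as a percentage of the trait mean, a scale-free measure of
#' evolvability.
#'
#' @param sigma2g additive genetic variance (>= 0).
#' @param mean trait mean (> 0).
#' @return percentage.
#' @examples
#' cvGenetic(7.20, 9.92)   # 27.05
#' @export
cvGenetic <- function(sigma2g, mean) {
  if (any(mean <= 0)) stop("trait mean must be positive for CVg")
  if (any(sigma2g < 0)) stop("additive variance must be non-negative")
  sqrt(sigma2g) / mean * 100
}

#' Sampling-based standard error of a parameter function
#'
#' Draws \code{n_samples} parameter vectors from
#' Normal(theta, theta-cov) and returns the standard deviation of
#' \code{fn} over the draws. Draws for which \code{fn} is undefined -- e.g.
#' negative variances making a correlation undefined -- are redrawn; their
#' count is reported in the \code{"n_redrawn"} attribute.
#'
#' @param fit a [REMLFit-class]
#' @param fn function taking a [VarianceComponents-class] and returning a
#'   scalar (e.g. \code{function(vc) heritability(vc, 1)}), or a function
#'   of the raw theta vector when \code{raw = TRUE}.
#' @param n_samples number of draws (default 10000).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @param raw if TRUE, \code{fn} receives the theta vector itself.
#' @return the sampled standard error, with attribute \code{"n_redrawn"}.
#' @export
seBySampling <- function(fit, fn, n_samples = 10000L, seed = 1L,
                         raw = FALSE) {
  stopifnot(is(fit, "REMLFit"))
  k <- length(fit@theta)
  V <- fit@thetaCov
  ee <- eigen(V, symmetric = TRUE)
  if (min(ee$values) < -1e-8 * max(abs(ee$values), 1))
    stop("theta-cov is not positive semi-definite")
  Lhalf <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), k)
  params <- .paramList(length(fit@vc@traits), fit@constraint)
  evalDraw <- function(th) {
    if (raw) return(fn(th))
    vcd <- .vcFromTheta(th, params, length(fit@vc@traits), fit@vc@traits)
    fn(vcd)
  }
  set.seed(seed)
  vals <- numeric(n_samples)
  filled <- 0L
  redrawn <- 0L
  while (filled < n_samples) {
    m <- n_samples - filled
    Zm <- matrix(rnorm(m * k), k, m)
    draws <- fit@theta + Lhalf %*% Zm
    for (c in seq_len(m)) {
      v <- tryCatch(suppressWarnings(evalDraw(draws[, c])),
                    error = function(e) NA_real_)
      if (is.finite(v)) {
        filled <- filled + 1L
        vals[filled] <- v
      } else redrawn <- redrawn + 1L
    }
    if (redrawn > n_samples)
      stop("more than half the sampled parameter vectors were invalid; ",
           "theta is too near a boundary for the sampling SE")
  }
  se <- stats::sd(vals)
  attr(se, "n_redrawn") <- redrawn
  se
}

#' Likelihood-ratio test for (co)variance parameters
#'
#' Compares a full bivariate fit with a reduced fit in which the genetic
#' covariance (df = 1) or both the genetic and residual covariances
#' (df = 2) are fixed at zero:
#' \eqn{-2\log\Lambda = -2(\ell_{reduced} - \ell_{full})}, compared with
#' the chi-squared 95th percentile (3.84 at df 1, 5.99 at df 2).
#'
#' @param full unconstrained [REMLFit-class].
#' @param reduced constrained fit nested in \code{full}.
#' @param df degrees of freedom, 1 or 2; defaults to the number of
#'   parameters the reduced fit fixed.
#' @param alpha significance level (default 0.05).
#' @return list with \code{minus2logLambda}, \code{df}, \code{threshold},
#'   \code{significant}.
#' @export
lrtCorrelation <- function(full, reduced, df = NULL, alpha = 0.05) {
  stopifnot(is(full, "REMLFit"), is(reduced, "REMLFit"))
  if (full@constraint != "none")
    stop("the full model must be unconstrained")
  expectDf <- switch(reduced@constraint, "no-genetic-cov" = 1L,
                     "no-cov" = 2L,
                     stop("reduced model is not nested in the full model"))
  if (is.null(df)) df <- expectDf
  if (df != expectDf)
    stop("df = ", df, " inconsistent with the reduced model's constraint")
  stat <- -2 * (reduced@logL - full@logL)
  if (stat < -1e-6)
    warning("reduced model has higher likelihood than the full model; ",
            "check convergence")
  thr <- qchisq(1 - alpha, df)
  list(minus2logLambda = stat, df = df, threshold = thr,
       significant = stat > thr)
}
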