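---
title: "Pedigree-based animal models by average-information REML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based animal models by average-information REML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedREML)
```

## The model

`pedREML` estimates genetic parameters for quantitative traits measured on
pedigreed animals — the setting of beef-cattle progeny tests such as the
Korean Hanwoo carcass and primal-cut evaluations the package's simulator
emulates. The core is the animal model

$$ y = Xb + Zu + e, $$

where $y$ stacks the phenotypes of one or two traits, $b$ holds fixed
effects (a slaughter-date contemporary group per trait and, where
configured, a slaughter-age covariate), and $u$ holds one additive-genetic
effect per pedigree animal and trait. The random terms are multivariate
normal with

$$ \mathrm{Var}(u) = G \otimes A, \qquad \mathrm{Var}(e) = R \otimes I, $$

with $A$ the numerator relationship matrix implied by the pedigree and $G$,
$R$ the $t \times t$ additive and residual (co)variance matrices
($t \in \{1, 2\}$). For bivariate models with unequal record patterns the
residual covariance is restricted to each record's observed-trait pattern:
an animal recorded for only one trait contributes a univariate residual,
an animal recorded for both contributes the full $2 \times 2$ block. This
is the only coherent reading of $R \otimes I$ under a nested record design
in which part of the herd lacks the second trait block.

Derived parameters follow the standard definitions: heritability
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$; genetic correlation
$r_g = \sigma_{g,XY} / \sqrt{\sigma^2_{gX}\sigma^2_{gY}}$ and its
phenotypic analogue with $P = G + R$; genetic coefficient of variation
$\mathrm{CV_g} = \sqrt{\sigma^2_g}/\bar x \times 100$.

## Pedigree machinery

`buildA()` fills the dense tabular relationship matrix (small pedigrees
only; the dense limit defaults to 2,000 animals). `inbreedingCoef()` uses
the Meuwissen–Luo style $A = LDL'$ recursion, so inbreeding never requires
the dense matrix. `buildAInverse()` applies Henderson's rules with
inbreeding: each animal contributes $1/d_i$ to at most 9 cells, with
Mendelian-sampling variance $d_i = 0.5 - 0.25(F_s + F_d)$ when both
parents are known, $0.75 - 0.25 F_{known}$ with one known parent, and 1
for founders. Unknown parents are treated as unrelated, non-inbred
founders (the common BLUPF90 convention); unknown-parent groups are out of
scope. Identifiers are opaque strings mapped to consecutive integer codes
in a parent-before-offspring order; the constructor reorders stably and
reports a cycle if the input contains one.

`traceBack()` exposes the tracing horizon (how many meioses above the base
animals to keep) as a parameter: whether a published "11 generations"
counts from phenotyped animals or from their parents is a convention the
caller chooses, not something the package fixes.

## REML estimation

The restricted log-likelihood
$-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py] - \tfrac{n-p}{2}\log 2\pi$
is evaluated through the mixed-model equations: with
$C = W'R_n^{-1}W + \mathrm{diag}(0, G^{-1}\otimes A^{-1})$ and a sparse
Cholesky factorization of $C$ (CHOLMOD via the Matrix package),
$\log|V| + \log|X'V^{-1}X| = \log|R_n| + q\log|G| + t\log|A| + \log|C|$
and $y'Py$ comes from the solutions. The dense $V$ is never formed; a
dense-formula oracle in the test suite checks the identity on small data.

Maximization uses the average-information algorithm: the AI matrix
$\mathrm{AI}_{kl} = \tfrac12 (\dot V_k Py)' P (\dot V_l Py)$ and the exact
score vector give Newton-type steps $\theta \mathrel{+}= \mathrm{AI}^{-1}
\nabla\ell$. The score's trace terms need selected entries of $C^{-1}$
(prediction-error variances on the pattern of $A^{-1}$, plus small
projections for the residual parameters). These come from a Takahashi
selected-inverse recursion over the sparse Cholesky factor, implemented in
C++ at a cost comparable to the factorization itself. Because a covariance
estimate can be exactly zero while its derivative still requires inverse
entries at the corresponding positions, the coefficient matrix is
assembled with a pattern-complete set of explicit zeros (dense-$R$,
dense-$G$ symbolic coupling), so the factor pattern always covers the
required entries.

Iteration starts with a few EM steps (default 3) from
$G = 0.4\,\mathrm{diag}(\hat\sigma^2_p)$,
$R = 0.6\,\mathrm{diag}(\hat\sigma^2_p)$, zero covariances — a common
heuristic that stays away from boundaries. The EM update is the exact
expectation-maximisation: $G$ from BLUP cross-products plus
prediction-error traces, $R$ from expected residual cross-products in
which a missing trait's residual is treated as missing data
(conditional-normal E step). This keeps EM monotone in the restricted
likelihood, which the test suite asserts on every fit it checks. AI steps
are safeguarded: a proposal that leaves the positive-definite cone or
decreases the likelihood is halved up to 10 times and finally replaced by
an EM step; $G$ is eigenvalue-bent (floor $10^{-8}$ of its trace) when
needed and variances are floored at $10^{-10}$ of the sample phenotypic
variance, both flagged on the fit. Convergence uses the relative-change
criterion $C = \sum_i(\theta_i - \theta_i^*)^2 / \sum_i \theta_i^2$ with
tolerance $10^{-12}$ and at most 200 iterations by default. On
well-conditioned problems the AI phase converges quadratically (about 10
iterations at study scale); near a boundary (e.g. an estimated
$|r_g| \to 1$ on very small datasets) the optimum lies on the edge of the
parameter space, progress is sublinear, and the fit honestly reports
`converged = FALSE` when the iteration cap is reached.

Reduced models for the likelihood-ratio tests fix the genetic covariance
(df = 1) or both covariances (df = 2) at zero and drop them from the
parameter vector; $-2(\ell_{reduced} - \ell_{full})$ is compared with the
$\chi^2$ 95th percentile (3.84 / 5.99). The published formula for this
statistic reads as the log of a likelihood *difference*; the package
implements the standard difference of log-likelihoods, the only reading
consistent with the likelihood-ratio definition.

Standard errors of derived parameters use repeated sampling: 10,000 draws
from $N(\hat\theta, \widehat{\mathrm{Cov}}(\hat\theta))$ with the
covariance taken as the inverse AI matrix at convergence, the function of
interest evaluated per draw, and the SE taken as the SD over draws. Draws
where the function is undefined (negative variances, undefined
correlations) are redrawn and counted; more than 50% invalid draws aborts
with an error, since the estimate is then too close to a boundary for
this SE method to mean anything.

## The synthetic-data generator

`simulatePedigree()` builds discrete generations: each dam of the previous
generation is mated to one randomly chosen sire (either any male, or one
of `n_sires` active sires under the half-sib-heavy scheme) and produces
`offspring_per_mating` offspring. `dropBreedingValues()` gene-drops
$u \sim N(0, G \otimes A)$ exactly: founders draw $N(0, G)$, offspring
take the parental average plus a Mendelian deviation with covariance
$G \cdot d_i$, using the same $d_i$ convention as the estimator — the
simulator and estimator are internally coherent by construction.
`simulatePhenotypes()` adds the trait mean, an i.i.d. normal
slaughter-date effect (dates assigned in birth-cohort blocks, echoing
batched slaughter), a slaughter-age covariate effect (ages
$\approx 23.71 \pm 0.64$ months, recorded in days), and a residual drawn
from $R$; a configured fraction of animals carries only the first trait
block, reproducing nested record designs (about 38% in the emulated
study, i.e. 5,622 carcass records vs 3,467 cut records). Every record
decomposes exactly into its stored components, and the test suite asserts
the reconstruction.

`hanwooConfig()` assembles a 14-trait configuration (4 carcass traits, 10
primal-cut yields) whose means, additive and residual variances and
genetic/phenotypic correlations target the published Hanwoo tables.
Three kinds of quantity have no published value and are synthetic,
documented defaults: carcass-by-carcass correlations (set to moderate
values typical of the breed literature), slaughter-date effect SDs (set
so the simulated raw phenotypic SD matches the published one, i.e.
$\mathrm{date\ var} = \mathrm{SD}^2_{published} - \sigma^2_p$), and
slaughter-age slopes (scaled to trait means). Because tables rounded to
two decimals are not jointly positive definite, correlation matrices are
projected to the nearest PD correlation matrix (Higham projection via
`Matrix::nearPD`); entries can move by up to about 0.04 in the process.
Marbling score is simulated as a continuous trait, since the emulated
analysis models the 1–9 score linearly.

What passing the recovery tests shows — and what it does not: the
generator produces data satisfying *exactly* the model's assumptions, so
parameter recovery validates the estimation machinery, not the model's
adequacy for real carcass data (real slaughter-date effects are not
i.i.d., real marbling is ordinal, real pedigrees carry errors and
selection).

## Problem sizes and test design

The package's own validation uses desk-scale problems chosen to keep the
full suite quick while leaving the statistics meaningful: oracle
equivalences on 8–300-animal pedigrees (dense-formula likelihoods, grid
search, gene-dropping Monte Carlo, ANOVA sire estimator); parameter
recovery on a bivariate design with 3,000 phenotyped animals over 4
generations across 10 seeds (true $h^2 = 0.40$, $r_g = 0.60$,
$r_p = 0.50$); and null calibration of the df-1 likelihood-ratio test on
200 replicates of a 120-record bivariate design, where the iteration cap
is 60 because the log-likelihood difference stabilizes long before the
$10^{-12}$ parameter criterion. The emulated full study (17 traits, 97
bivariate fits) runs at any scale through `runStudy()`; the acceptance
script exercises a three-trait slice at 1,500 phenotyped animals.

## Known limitations

At most two traits per fit (the full study is assembled from univariate
and pairwise bivariate fits, as in the emulated analysis); no maternal,
permanent-environment or dominance components; no genomic relationships
or single-step methods; no unknown-parent groups; homogeneous residual
variance within trait. Estimates on the boundary of the parameter space
are reported with flags rather than silently clipped, and their
sampling-based SEs should be read with care.
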