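---
title: "Stability analysis for multi-environment yield trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability analysis for multi-environment yield trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

A multi-environment trial (MET) grows the same set of genotypes at several
site-year combinations, each laid out as a randomized complete block design,
and asks two questions at once: which genotypes yield most, and which yield
*reliably* across environments. The non-additive part of the genotype x
environment means table — the genotype-by-environment interaction (GEI) —
is what makes the second question hard: a genotype that wins in a wet, cool
site-year can lose badly in a dry, hot one. This package implements four
complementary routes through that problem for rainfed pulse-crop trials of
the 10–20 genotype, 5–10 environment scale: AMMI with seven stability
indices and simultaneous selection, BLUP-based harmonic-mean statistics,
factorial regression on climate covariates, and partial least squares
regression.

## The additive decomposition and AMMI

Every analysis starts from the genotype x environment cell means
$\bar y_{ij}$ and their least-squares split

$$\bar y_{ij} = \mu + \alpha_i + \beta_j + ge_{ij},$$

where $\mu$ is the grand mean, $\alpha_i$ and $\beta_j$ are centered
genotype and environment main effects and $ge_{ij}$ is the doubly-centered
interaction (every row and column sums to zero). `compute_ge_means()`
enforces these identities to floating-point accuracy and refuses incomplete
two-way tables: imputation of missing cells would silently bias every
downstream statistic, so absence is an error.

AMMI (additive main effects and multiplicative interaction) takes the
singular value decomposition $ge_{ij} = \sum_n \lambda_n \gamma_{in}
\delta_{jn}$ and reads the leading axes as interpretable interaction
patterns. `ammi_decompose()` works on the means matrix, not plot data; the
axis sum of squares is put back on the plot scale as $r\lambda_n^2$, which
makes $r\sum_n\lambda_n^2$ equal the interaction SS of the combined ANOVA
exactly (a conservation law the tests assert at 1e-8 relative). Scores are
symmetrically scaled — $\sqrt{\lambda_n}\gamma_{in}$ for genotypes,
$\sqrt{\lambda_n}\delta_{jn}$ for environments — so each axis carries
$\lambda_n$ on both sides, the convention under which the stability indices
below are defined. Because SVD signs are arbitrary, each axis is flipped so
the genotype with the largest eigenvector entry is positive; without a fixed
convention, reports would not be reproducible across BLAS implementations.

Axis significance uses Gollob's F-test: axis $n$ gets $g + e - 1 - 2n$
degrees of freedom and mean square $r\lambda_n^2/\mathrm{df}$, tested
against the pooled error. The number of significant axes $N'$ is found by
scanning axes in order and stopping at the first non-significant one (axes
are ordered by explained SS, so skipping past a dead axis has no
justification), with a floor of $N' = 1$ so every index stays defined. The
combined ANOVA itself tests genotype and interaction against pooled error
and environment against replicate-within-environment, the appropriate
denominator when blocks are the replication unit for environments.

## The stability indices and simultaneous selection

Seven per-genotype indices summarize the scaled scores $s_{in}$; for all of
them, smaller is more stable.

* **ASV** $= \sqrt{((SS_1/SS_2)\,s_{i1})^2 + s_{i2}^2}$ — distance from the
  origin with the first axis stretched by its SS advantage.
* **SIPC** $= \sum_{n \le N} |s_{in}|$ — absolute score sum; shipped with
  all retained axes (the SIPC-F variant), with an argument to restrict.
* **EV** $= \sum_{n \le N'} \gamma_{in}^2 / N'$ — averaged squared
  eigenvector entries (unit-norm scale).
* **Za** $= \sum_{n \le N'} |\theta_n \gamma_{in}|$ — eigenvector entries
  weighted by the axis share $\theta_n$ of interaction SS (as proportions).
* **MASV** $= \sqrt{\sum_{n<N'} ((SS_n/SS_{n+1})\,s_{in})^2 + s_{iN'}^2}$ —
  the ASV construction over $N'$ axes. We use the form in which the SS
  ratio stretches the score *before* squaring: this is the only reading
  under which MASV collapses exactly to ASV at $N' = 2$, which we treat as
  the defining property of the "modified" index (the alternative reading,
  ratio applied to the squared score, breaks that collapse).
* **D** $= \sqrt{\sum_{n \le N'} s_{in}^2}$ — plain Euclidean distance from
  the biplot origin.
* **WAAS** $= \sum_k |s_{ik}|\theta_k / \sum_k \theta_k$ — weighted average
  of absolute scores. The normalization makes percentages and proportions
  interchangeable as weights. WAAS defaults to all axes, since its own
  weights already discount minor ones; the other multi-axis indices default
  to the Gollob $N'$. Every index accepts an explicit axis count.

`rank_and_ssi()` converts each index to ranks (1 = most stable), ranks mean
yield descending (RY = 1 for the top yielder), and forms the simultaneous
selection index $ssi_X = \mathrm{rank}_X + RY$. Ties get the minimum
("competition") rank so the ssi sums remain integer and comparable. Ranks,
not index magnitudes, are the deliverable: they are invariant to rescaling
all yields, which the tests check.

## The BLUP route

`fit_met_mixed_model()` fits

$$y_{ijk} = \mathrm{env}_j + \mathrm{rep(env)}_{jk} + g_i + ge_{ij} +
\varepsilon_{ijk}, \qquad g_i \sim N(0, \sigma^2_g),\; ge_{ij} \sim N(0,
\sigma^2_{ge}),$$

with environment and block fixed and genotype and interaction random, by
REML through `lme4::lmer()`. Fixed blocks keep the model identifiable with
the two-to-four replicates typical of these trials. The genotypic value
$GV_{ij} = u_j + g_i + ge_{ij}$ combines the fixed environment mean with
the shrunken genotype and interaction predictions; shrinkage is the point —
a genotype's apparent advantage in one noisy environment is discounted in
proportion to the noise.

Three statistics condense $GV$ (larger = better for all three):

* **HMGV**: harmonic mean of $GV_{ij}$ over environments, in kg/ha. The
  harmonic mean penalizes any environment where the value collapses, so it
  reads as yield-plus-stability.
* **RPGV**: mean of $GV_{ij}/u_j$, dimensionless relative performance,
  invariant to rescaling yields.
* **HMRPGV**: harmonic mean of the ratios $GV_{ij}/u_j$ — stability,
  adaptability and yield in one number; multiplied by the grand mean it
  returns to kg/ha.

All three require positive genotypic values; a non-positive $GV$ (possible
only with pathological synthetic input, not field yields) is a named error
rather than a silent NaN.

## Climate covariates: factorial regression and PLSR

Factorial regression explains the interaction from measured environment
covariates $z_{jk}$ (here: seasonal rainfall totals in mm and seasonal mean
temperatures in °C): $ge_{ij} \approx \sum_k \xi_{ik} \tilde z_{jk}$ with
covariates centered to mean zero and per-genotype sensitivities $\xi_{ik}$
estimated by least squares. Covariates enter by forward selection on
$\mathrm{AIC} = N\ln(\mathrm{RSS}/N) + 2P$ with $N = ge$ interaction cells
and $P$ the count of fitted sensitivity parameters ($g$ per covariate);
selection stops when no addition lowers AIC, with a first-in-column-order
tie-break and a guard that stops cleanly if the fit becomes numerically
perfect. Per-variable explained SS is decomposed sequentially in selection
order so contributions plus residual always equal the total interaction SS.
FR covariates are centered but *not* scaled (the sensitivities then keep
interpretable units, kg/ha per mm or per °C).

PLSR treats the transposed interaction (environments x genotypes) as the
response and the covariates as predictors, extracting paired latent factors
by the classical NIPALS iteration (weight from the response projection,
score, X- and Y-loadings, deflation of both matrices). Here the covariates
*are* standardized: rainfall in mm and temperature in °C would otherwise
carry incommensurate weight. The response is the doubly-centered
interaction rather than raw yields because factor shares are reported as
percent of interaction SS — with raw yields the environment main effect
would swamp every factor. Each factor's sign is fixed so the
largest-loading covariate is positive. The hand-written NIPALS is
cross-checked in the tests against an independent PLS implementation
(mixOmics) on a fixed instance.

One property worth stating precisely: a rank-one response built from a
single predictor direction loads entirely on factor 1 only when that
direction is an eigenvector of $X^\top X$ — for instance when predictor
columns are orthogonal, or there is a single predictor. With correlated
predictors the first factor provably captures less than 100%. The
round-trip validations therefore use orthogonalized predictors (or one
covariate) where they assert near-total first-factor recovery.

## The synthetic-data generator

No field data ships with the package, so every claim is validated against
a generator with known ground truth:

$$y_{ijk} = \mu + \alpha_i + \beta_j + \textstyle\sum_n \lambda_n
\gamma_{in}\delta_{jn} + b_{jk} + \varepsilon_{ijk}.$$

Design choices that matter:

* **Exact truth, not expected truth.** The interaction axes
  $\gamma_{\cdot n}, \delta_{\cdot n}$ are QR-orthonormalized standard
  normal draws made orthogonal to the ones vector, so the requested
  singular values are the matrix's exact singular values. Likewise the
  drawn main effects are rescaled to the exact requested sample standard
  deviation. With only 16 genotypes, a random draw's realized variance has
  a coefficient of variation near 37%, which would make any ±25%
  recovery check meaningless; pinning the realized truth makes
  variance-component recovery a test of the estimator, not of the draw.
  For a target interaction variance $\sigma^2_{ge}$ the Frobenius norm is
  set to $(g-1)(e-1)\sigma^2_{ge}$, the expectation for a doubly-centered
  matrix.
* **Defaults are the study conditions.** 16 genotypes, 8 environments, 3
  blocks, grand mean 1069.25 kg/ha; effect scales (genotype sd 135,
  environment sd 200, singular values 1900 and 660, plot noise sd 150
  kg/ha) chosen so the expected SS shares of environment, genotype and
  interaction sit near 37/17/31% of the total and the two leading
  interaction axes carry roughly 85% and 10% of the interaction — the
  regime of a real rainfed chickpea MET.
* **Covariate-linked variant.** `generate_covariate_linked()` builds
  $ge_{ij} = \sum_k \xi_{ik}\tilde z_{jk}$ (+ optional doubly-centered
  residual) from drawn covariates whose means and sds default to plausible
  seasonal rainfall (mm) and temperature (°C) values, with the true
  sensitivity matrix returned for recovery checks.
* **One seed, fixed draw order** (genotype effects, environment effects,
  axes, blocks, noise), so a spec is bit-reproducible. Block effects
  default to sd 0 and are centered within environment when enabled.

What the generator does *not* emulate: spatial field trend, heteroscedastic
residuals across environments, missing plots, non-normal yields, and
weather as a time series (covariates are drawn values). Tests passing on
this generator therefore certify the algebra and the estimators under the
stated model, not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Double-centering and effect identities are asserted at 1e-9 relative to
  the grand mean; SVD conservation identities at 1e-8 to 1e-10 relative.
* An exactly additive trial (interaction numerically zero, detected at
  1e-9 of the grand mean per cell) short-circuits: all singular values and
  indices report 0 with a flag, the Gollob scan floors at $N' = 1$, AIC
  selection returns the empty model, and PLSR reports 0% via an explicit
  response floor rather than dividing rounding noise by rounding noise.
* ASV and MASV are undefined on rank-1 interactions (the SS ratio divides
  by zero) and error rather than fabricate; `stability_indices()` then
  omits them with a message.
* NIPALS converges on the score vector at 1e-10 with a 10^4 iteration cap;
  single-factor and exhausted-response cases exit cleanly with zero
  factors.
* AIC uses the Gaussian profile form $N\ln(\mathrm{RSS}/N) + 2P$; only AIC
  differences matter, so the dropped constant is immaterial.

## Problem sizes used in validation

The shipped tests and the reproduction script run the full pipeline at the
study scale (16 x 8 x 3, six covariates), recovery simulations at 200
seeds for the REML and AIC-selection operating characteristics, and
smaller toys (2x2 up to 10x7) wherever a closed-form oracle exists. A full
pipeline run takes a few seconds on one core; the complete suite runs in
well under a minute.

## Known limitations

* Within-environment balance is required; unbalanced site-years are
  handled only as distinct environments with their own replicate count.
* No heterogeneous residual variances, no pedigree/kinship, no
  cross-validated axis selection (Gauch's F_R), and no GGE biplot — the
  AMMI family plus the BLUP statistics above are the scope.
* Factorial regression admits only environmental covariates, not genotypic
  ones.
* The Gollob test is liberal compared to resampling-based axis tests; we
  use it because it is the convention in this analysis lineage, and expose
  `n_axes` overrides everywhere so a stricter choice can be imposed.
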