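---
title: "Locating a thermal transition in CRISPR-Cas abundance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating a thermal transition in CRISPR-Cas abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtherm)
```

## The scientific question

CRISPR-Cas systems are adaptive immune systems of prokaryotes, yet they are
absent from more than half of bacterial genomes. Their per-genome abundance
(number of CRISPR arrays, spacers, *cas* genes, *cas* gene clusters) has long
been known to be higher in thermophiles. The sharper claim this package is
built to examine is that the relationship with optimal growth temperature
(Topt) is not a smooth trend but a *step*: genomes of species growing below
roughly 40 °C are mostly CRISPR-poor, genomes above roughly 45–50 °C are
mostly CRISPR-rich, and essentially all of the association is concentrated
in a narrow band around 45 °C.

Three statistical difficulties shape the toolkit:

1. **The signal is a step, not a slope.** Global correlation or regression
   statistics dilute a localized transition. The package therefore provides
   a dedicated contrast statistic, sliding-window regressions, and
   derivative-based localization of a smooth fit.
2. **Species are not independent.** Related species resemble each other in
   both Topt and defence-system content, so naive tests overstate evidence.
   Phylogenetic signal is quantified with Pagel's λ, and regressions are
   generalized least squares under the λ model.
3. **Counts are zero-heavy and overdispersed.** Most genomes carry zero
   systems; the genomes that do carry them vary widely. Medians are used
   for display summaries, means for the contrast statistic (a median-based
   ratio would be 0/0 for these data), and the synthetic generator
   reproduces this structure so calibration can be checked.

## The contrast statistic and its permutation null

With integer temperatures `T_j` and abundances `a_j`, for every integer
threshold *i* strictly above the minimum and up to the maximum observed
temperature,

\[ D_i \;=\; \frac{\operatorname{mean}\{a_j : T_j \ge i\}}
                 {\operatorname{mean}\{a_j : T_j < i\}}. \]

A flat thermal profile gives \(D_i \approx 1\) for all *i*; a step up at
\(T^\*\) inflates \(D_i\) near \(T^\*\). Both means become unstable where
one side of the split holds a handful of species, so the maximum
\(D_{\max}\) is taken over a restricted window, 20–64 °C by default
(`d_max()`). Ratios with a zero denominator are flagged infinite, reported,
and excluded from the maximum; ties break toward the smaller temperature.

The null hypothesis of `permutation_test()` is that species are randomly
arranged along the temperature axis — formally, that abundance is
*exchangeable* with respect to Topt. Each replicate shuffles the abundance
vector against the fixed temperatures and recomputes \(D_{\max}\) in the
same window. The default p-value is the strictly-greater count divided by
the number of shuffles; a conservative \((k+1)/(n+1)\) variant is available
(`p_variant = "conservative"`). For tiny two-block designs the null can be
enumerated exactly, and the test suite does so; there the standard
exact-test convention \(P(D_{\max}^{perm} \ge D_{\max}^{obs})\) applies,
since the observed arrangement is itself one of the enumerated ones.

Two caveats are deliberate. First, exchangeability is a stronger assumption
than "no temperature effect": phylogenetically autocorrelated abundance
violates it even when abundance is independent of temperature, which makes
the permutation test anticonservative in that regime. This is precisely why
the package pairs it with phylogenetic regressions, and why the calibration
experiments simulate abundance without a phylogenetic component — they
verify the test against its own null, not against a null it was never
designed for. Second, the windowed maximum is a scan statistic; its p-value
is valid for the maximum as a whole, not for the location of the argmax.

## Phylogenetic signal and PGLS under the λ model

The Brownian covariance of a rooted tree assigns to each pair of tips the
branch length shared from the root to their most recent common ancestor
(`phylo_covariance()`). Pagel's λ rescales the off-diagonal entries by
λ ∈ [0, 1] (`lambda_transform()`): λ = 0 is phylogenetic independence,
λ = 1 the full Brownian structure. λ is bounded to [0, 1] because values
above 1 are not generally valid covariances on non-ultrametric trees such
as taxonomy-database reference trees.

`estimate_lambda_signal()` maximizes the likelihood of the intercept-only
model \(y \sim N(\mu \mathbf{1},\, \sigma^2 V(\lambda))\), profiling μ and
σ² analytically, and tests λ = 0 with a likelihood ratio. Because the null
value sits on the parameter boundary, the default reference distribution is
the 50:50 mixture of a point mass at zero and \(\chi^2_1\); a plain
\(\chi^2_1\) switch is provided since reference implementations differ.
`pgls_fit()` fits \(y = \beta_0 + \beta_1 x + \varepsilon\),
\(\varepsilon \sim N(0, \sigma^2 V(\lambda))\), with closed-form GLS
coefficients at each candidate λ and the same profile search; the slope
p-value uses a t statistic with n − 2 degrees of freedom. Estimation is ML
(not REML), matching the defaults of the implementations this design
follows; abundances enter untransformed on the linear scale, as the
slope-per-degree parameterization implies.

Numerical contract: each candidate V(λ) is Cholesky-factorized once (with a
jitter fallback of \(10^{-10}\) times the mean diagonal if the factorization
fails), never explicitly inverted. The λ search evaluates a 21-point grid
and then refines the bracket around the best point with bounded scalar
optimization; this is deterministic, and the test suite verifies that the
returned profile maximum dominates an independent 101-point grid oracle.
The engine reproduces `nlme::gls` with a Pagel correlation and
`phytools::phylosig` to at least five digits on shared instances — those
packages serve as cross-checks in the tests, not as the implementation.

`segmental_pgls()` sorts species by (Topt, species id) — the secondary key
pins down window membership when many species share a temperature — and
fits a PGLS per window of consecutive species (200 by default), skipping
windows with constant Topt and re-estimating λ per window on the pruned
subtree. No multiple-testing correction is applied across windows, by
design: the scan is presented as a descriptive localization device, and the
original analysis it follows applied none either; readers should interpret
isolated significant windows accordingly. `category_pgls()` fits fixed
temperature categories plus the whole range; `tertile_split()` builds
three nearly equal groups without splitting tied temperatures.

## Smooth fits and derivative localization

`fit_smooth()` fits a cubic regression spline (basis dimension 10, knots at
temperature quantiles, Gaussian identity family by default) with a
second-derivative penalty via `mgcv::gam`, selecting the smoothing
parameter by GCV over an 81-point grid spanning \(10^{-4}\)–\(10^{4}\).
Two numerical rules make degenerate inputs deterministic: GCV ties (within
\(10^{-7}\) of the minimum on the response-variance scale) resolve to the
*largest* smoothing parameter, and while the optimum sits on the grid's
upper edge the grid is extended upward by decades (to \(10^{14}\)), so data
that are exactly linear or constant resolve to the smoothest model that
explains them. The effective degrees of freedom (edf, the trace of the
influence matrix) summarize non-linearity; note that a second-derivative
penalty cannot shrink the linear null space, so the attainable minimum is
2 (intercept + slope), including for constant data. A Poisson-log family is
available but off by default.

`smooth_derivative()` differentiates the fitted curve by finite differences
on a 0.1 °C grid (central in the interior, one-sided at the ends) and
reports the integer temperature of the steepest increase, ties toward the
smaller temperature (within a small relative tolerance, so a flat
derivative reports the grid start rather than floating-point noise). Two
limitations are worth knowing: the argmax can be captured by boundary
wiggle when the data-sparse ends of the temperature range contain large
counts (observed in a minority of simulated replicates), and a 10-dimension
basis over an ~80 °C span cannot represent transitions much sharper than
~10 °C — fitted-value accuracy guarantees in the tests therefore use a
sigmoid of scale 4 °C, and the located transition temperature should be
read as approximate to a couple of degrees.

## The synthetic generator

`simulate_dataset()` produces a pure-birth tree rescaled to unit median
depth, integer temperatures, and zero-inflated negative-binomial counts:

* **Topt**: a latent Gaussian with covariance V(λ_topt) is mapped through
  each tip's normal CDF to [0, 1], affine-mapped to [4, 85] °C and rounded.
  The CDF map preserves the target range exactly while keeping the signal
  tunable; λ_topt defaults to 0.95, mirroring the very strong signal
  reported for growth temperature in real data (≈0.97).
* **Abundance**: the marginal mean follows
  \(\mu(T) = \mu_0 + \Delta \cdot \operatorname{logit}^{-1}((T - T^\*)/s)\)
  with defaults \(\mu_0 = 0.5\), \(\Delta = 3.5\), \(T^\* = 45\),
  \(s = 1\) — a sigmoid rather than a hard step so that s → 0 approximates
  a discontinuous jump while the smooth-fit module stays exercisable. A
  latent Gaussian effect on the log-mean (sd 0.5, signal λ_abund = 0.8,
  centred so its exponential has mean one) carries the phylogenetic
  component reported for real abundances (λ ≈ 0.85–0.92). Counts are
  negative binomial with size 1 — chosen so the count tail stays in the
  tens, as in real per-genome annotation data, rather than the hundreds a
  smaller size parameter produces — and are then zeroed with probability
  0.55, matching the sparsity of the systems across genomes. The
  negative-binomial mean is inflated by 1/(1 − zero-inflation) so the
  *marginal* mean equals μ(T); bin means below the step then approach μ₀
  and above it μ₀ + Δ, which is the property the recovery experiments
  check.

What the generator does *not* emulate: the real, strongly non-uniform
distribution of species along the temperature axis (simulated Topt is
marginally uniform; real datasets are dominated by mesophiles);
Topt measurement error and database conflicts; correlation between the
measures (each simulated measure is an independent draw); isolation-source
structure; and any genome-level realism. Passing recovery tests therefore
demonstrates that the estimators find a transition of the stated size and
shape under the stated noise — not that the real data contain one.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed, and a dataset is
fully determined by (seed, configuration). The verification experiments
use: 20 random 10–50-tip instances for the engine/oracle agreement;
the enumerable toys (4 points; two blocks of 5) for exactness of the ratio
statistic; 500 replicates at 1500 tips with 200 shuffles for null
calibration (fresh tree every 50 replicates); 50 replicates at 1500 tips
for transition recovery; 100 replicates at 300 tips per λ ∈ {0, 0.5, 1}
for signal recovery; and windows of 200 at stride 20 on 400-tip null
datasets for the scan's false-positive rate. These sizes were chosen so
the whole suite re-runs comfortably on a laptop while keeping Monte-Carlo
error well inside the asserted bands.

Pipeline outputs (`run_full_analysis()`) are written as fixed-precision
TSVs with stable ordering, so identical configurations produce
byte-identical files; the manifest records per-stage status, sizes and the
seed, and a failing stage never silently aborts the independent ones.

## Known limitations

* The permutation test's exchangeability null makes it anticonservative
  for phylogenetically clustered abundance; treat it as a screen, with the
  PGLS machinery carrying the inferential weight.
* Derivative-based localization inherits spline boundary behavior; the
  reported transition temperature is reliable to a few degrees, not to the
  degree.
* PGLS assumes Gaussian errors; applied to zero-inflated counts it is a
  quasi-likelihood approximation, adequate for slope screening but not for
  count-level prediction.
* λ is estimated by ML and bounded to [0, 1]; near-boundary estimates have
  skewed sampling distributions, and the LR test's boundary mixture is an
  asymptotic convention.
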