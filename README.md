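# crisprtherm

Tools for asking *where along the temperature axis* prokaryotic defence
systems change, with the phylogeny taken seriously.

CRISPR-Cas adaptive immune systems are present in fewer than half of
bacterial genomes, but their per-genome abundance (CRISPR arrays, spacers,
*cas* genes, *cas* gene clusters) is markedly higher in thermophiles. The
interesting claim is sharper than "more at higher temperatures": the
relationship appears to be a *step* — CRISPR-poor genomes below ~40 °C,
CRISPR-rich above ~50 °C, with essentially all of the association
concentrated near 45 °C. This package implements the statistical toolkit
for testing and localizing such a transition:

* **Trait-table construction** — evidence-level filtering of CRISPR
  annotations (only levels 3–4 count; levels 1–2 are zero), integer
  rounding of growth temperatures (half away from zero, originals kept),
  precedence merging of conflicting temperature sources, tree–table
  matching with exact path-length-preserving pruning, and isolation-source
  stratification.
* **The D statistic** — for each integer temperature *i*,
  `D_i = mean(abundance | Topt >= i) / mean(abundance | Topt < i)`;
  its maximum `D_max` over a restricted window (20–64 °C by default)
  contrasts the two sides of a putative step, with a seeded permutation
  test against the null that species are randomly arranged along the axis.
* **Phylogenetic signal and PGLS** — maximum-likelihood Pagel's λ
  (`y ~ N(μ1, σ²V(λ))`, likelihood-ratio test with boundary correction)
  and generalized least squares regression under the λ model, with
  closed-form GLS per candidate λ and a deterministic profile search.
  The engine agrees with `nlme::gls(corPagel)` and `phytools::phylosig`
  to machine-level tolerances, which the tests verify independently.
* **Window scans** — PGLS per window of 200 neighbouring species along the
  sorted temperature axis (λ re-estimated per window, constant-temperature
  windows skipped), fixed temperature-category fits, tie-preserving
  tertile splits, and a paired Wilcoxon comparison of two domains at
  shared temperatures.
* **Smooth localization** — penalized cubic regression spline of abundance
  vs temperature (GCV-selected smoothing over a log grid), effective
  degrees of freedom as a non-linearity summary, and a finite-difference
  derivative whose argmax is the reported transition temperature.
* **A seeded simulator** — pure-birth trees, phylogenetically
  autocorrelated integer temperatures in [4, 85] °C, and zero-inflated
  negative-binomial counts whose marginal mean follows a sigmoid step
  (0.5 → 4 across 45 °C by default), so every stage is testable and
  calibratable without any external data.

## Worked example

A full simulated study at the default conditions (1500 species, step
0.5 → 4 at 45 °C, zero-inflation 0.55):

```r
library(crisprtherm)

d   <- simulate_dataset(sim_config(), seed = 2024)
tab <- d$table

bin_summaries(tab$topt_c, tab$arrays)[7:11, ]
#>    bin_low bin_high  n median_abundance mean_abundance
#> 7       30       34 80                0      0.2875000
#> 8       35       39 79                0      0.5949367
#> 9       40       44 57                0      0.7017544
#> 10      45       49 68                0      3.5294118
#> 11      50       54 71                0      3.0985915

permutation_test(tab$topt_c, tab$arrays, n_perm = 1000, seed = 1)
#> Permutation test (1000 shuffles, seed 1): observed D_max = 6.677, p = 0

tert <- tertile_split(tab)
category_pgls(tab, d$tree, tert, measures = "arrays")
#>   category measure    n       slope      slope_p lambda_hat     loglik
#> 1      low  arrays  498 0.005585156 6.832104e-01 0.01154648  -805.5839
#> 2      mid  arrays  496 0.074796631 6.044791e-06 0.12365860 -1213.6474
#> 3     high  arrays  506 0.042636519 1.984354e-01 0.03783246 -1705.7558
#> 4      all  arrays 1500 0.049897089 6.384318e-12 0.04588015 -4369.4145

smooth_derivative(fit_smooth(tab$topt_c, tab$arrays))
#> Derivative curve: steepest increase at 44 degC (max slope 0.2112 per degC)
```

Reading the output: bin means jump from ~0.6 to ~3.5 across the 40–49 °C
boundary while every cold-bin median stays 0; the observed `D_max` of 6.7
is never reached in 1000 random arrangements (p = 0, i.e. < 0.001); the
PGLS slope is significant only in the middle temperature tertile (0.075
arrays per °C, p ≈ 6×10⁻⁶) and not in the cold or hot tertiles — the
association is confined to the transition zone; and the smooth fit's
derivative locates the step at 44 °C, one degree from the simulated truth
of 45 °C. `run_full_analysis()` composes all stages from a YAML config and
writes fixed-precision TSVs plus a JSON manifest
(`inst/scripts/run_pipeline.R` is a shell wrapper around it).

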