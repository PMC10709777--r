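---
title: "Small-area estimation of county preterm birth rates: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of county preterm birth rates: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretermsae)
```

## The problem

County-level preterm birth rates are an important surveillance quantity, but
most US counties record few births per year, so crude annual rates per county
and 5-year maternal age group are extremely noisy and often suppressed.
Small-area estimation stabilizes these rates by borrowing strength across
neighbouring counties, adjacent years, and age groups. `pretermsae`
implements that workflow end to end for tabulated vital-statistics panels:
counts of live births and preterm (<37 weeks) or early preterm (<34 weeks)
births by county, maternal age group (15-19 through 40-44) and calendar
year.

Because individual-level birth registration data are restricted, the package
ships a synthetic generator that emulates the tabulated data with known
ground truth. All estimator validation in the test suite is against that
truth.

## The smoothing model

For county $i$, age group $k$ and year $t$, with $n_{ikt}$ live births and
$Y_{ikt}$ outcome births, the estimator fits

$$Y_{ikt} \sim \text{Poisson}\!\left(n_{ikt}\,\lambda_{ikt}/100\right),
\qquad
\log(\lambda_{ikt}/100) = \alpha_k + u_i + v_i + \delta_{ik} + \phi_{it},$$

a Besag-York-Mollié (BYM) convolution extended with age and time structure:

* $\alpha_k$ — age-group intercepts (flat priors), carrying the U-shaped
  maternal-age risk profile;
* $u_i$ — intrinsic conditional autoregressive (ICAR) field over the county
  adjacency graph: spatially structured variation;
* $v_i$ — iid normal county heterogeneity: unstructured variation;
* $\delta_{ik}$ — ICAR-in-space field per age group, exchangeable across
  ages: lets the spatial surface differ by age;
* $\phi_{it}$ — first-order random walk in time per county: county-specific
  temporal trends, smoothed toward their neighbours in time.

A Poisson likelihood with a log offset is the standard disease-mapping
formulation for spatially referenced count data. The underlying counts are
binomial (preterm births are a subset of live births), and the synthetic
generator draws them binomially; with rates around 12 per 100, the Poisson
approximation is benign, and the recovery tests quantify exactly this
combination (95% interval coverage of binomial-truth rates lands at 0.98 in
the acceptance run).

### Priors, constraints, and sampling

Precisions of $u$, $v$, $\delta$ and $\phi$ carry Gamma(0.5, 0.0005)
hyperpriors, a conventional weakly informative disease-mapping choice; both
parameters are configurable in `mcmc_settings()`. The ICAR and random-walk
priors are improper, so after every sweep each flat direction is removed:
$u$ is centred per connected component and $\phi$ per county, with the level
shift absorbed into $v$ so the linear predictor (and hence the likelihood)
is untouched; the per-age component mean of $\delta$ is absorbed into
$\alpha_k$ on a connected graph, and projected out otherwise. Components of
the county graph are handled separately throughout, which keeps the model
identified on disconnected geographies (real county adjacency graphs have
islands).

Sampling is Metropolis-within-Gibbs: conjugate Gibbs draws for the
precisions and adaptive single-site Metropolis for every log-linear effect,
with step sizes adapted during burn-in toward an acceptance rate of 0.44
(the scalar-update optimum). Single-site updates are vectorised over a
proper colouring of the county graph — counties of the same colour share no
edge, so their acceptance decisions are conditionally independent and can be
made simultaneously (a rook lattice is 2-colourable; general graphs get a
greedy colouring). The Poisson mean matrix is maintained multiplicatively
and refreshed every 250 iterations for numerical hygiene. Defaults are 5000
iterations, 2500 burn-in, thinning 5; on a 100-county, 6-age, 13-year panel
a default fit takes on the order of 15 seconds.

Counties with zero births in every cell carry no information and an
undefined offset; they are dropped with a warning before fitting.

### What the posterior provides

Cell rates are summarised by posterior medians with central 95% credible
intervals. Age standardization is applied *per draw*
(`standardize_posterior()`), so the interval of a county's age-standardized
rate reflects the joint posterior across its age groups. The reliability
rule used for mapping — credible-interval width smaller than the point
estimate, and at least 100 births in every study year — is implemented
literally in `reliability_flags()`.

## Direct age standardization and disparity summaries

Reference weights are the national age distribution of live births in the
reference year (the first study year by convention):
$w_k = \sum_i n_{ik,\mathrm{ref}} / \sum_{i,k} n_{ik,\mathrm{ref}}$; the
standardized rate is $\sum_k w_k \lambda_{ik}$. County disparity in a year
is summarised by the distribution of age-standardized rates across reliable
counties: minimum, 10th percentile, median/IQR, 90th percentile, maximum,
the 90th−10th gap, the 90th:10th ratio, and the max−min gap.

Two numerical choices are deliberately pinned down because the summaries
are meant to be reproducible bit-for-bit on fixed input:

* percentiles interpolate order statistics linearly (R quantile type 7, the
  common continuous default);
* report tables round to one decimal, half to even (base `round()`).

Interval estimates for the gap and ratio functionals use a county-resampling
percentile bootstrap (`bootstrap_gap_ci()`, default B = 1000, seeded). An
alternative would be to propagate posterior draws through the percentile
functionals; the bootstrap was chosen because it is agnostic to the
estimation stage and isolates the interval construction in one operation.
Its coverage is checked by simulation against a population with known
quantile gap.

## SVI association models

The CDC Social Vulnerability Index enters at the county level as overall and
four theme percentiles, with the time-varying release mapping (2010 release
for 2007-2011, 2014 for 2012-2015, 2016 for 2016-2017, 2018 for 2018-2019)
resolved by `svi_release_for_year()`. Counties are classified by quartile of
the overall percentile among included counties, ties assigned to the lower
quartile.

Rate ratios by quartile come from negative binomial regression with a log
offset, $\log \mu = \beta_0 + x^\top\beta + \log n$, fit across counties
(one model per year; a continuous-SVI variant is exposed). A per-county
slope on a county-level covariate is not identifiable, so across-county
fitting is the only reading that yields quartile rate ratios. Dispersion is
estimated by maximum likelihood; on equidispersed data the NB fit converges
to the Poisson fit, and if the dispersion search degenerates the
Poisson-limit fit is reported with a note. Wald 95% intervals are used for
the rate ratios, whose simulation size (null coverage between 93% and 97%)
is verified in the tests.

Variance explained by each theme uses ordinary least squares on the
age-standardized point estimates (univariate, sequential, and fully
adjusted models). Uncertainty in the estimated rates is *not* propagated
into this stage — it mirrors the two-stage use of estimated rates — and the
nesting property (sequential $R^2$ never decreases) is tested.

## Trends

Per-county trends are ordinary least squares of $\ln(\lambda_t)$ on the year
index $t = 0,\dots,T-1$ using the smoothed annual rates; total percent
change over the span is $100(e^{(T-1)\beta_1} - 1)$ — the familiar constant
12 appears for a 13-year panel. The 95% interval maps the t-interval for
$(T-1)\beta_1$ through the same exponential transform (equivalent to the
delta method on the log scale, then exponentiated exactly rather than
linearized on the percent scale). A county counts as significantly
increasing (decreasing) when that interval lies entirely above (below) zero.
Two-stage uncertainty — the posterior spread of the estimated rates
feeding the regression — is not propagated into the trend intervals; this is
a known limitation of point-estimate trend regression on smoothed series.

Aggregation to national/state/region units sums counts exactly
(conservation is asserted in the tests), and the same standardization and
trend operations run on the aggregated crude panels.

## The synthetic generator as study conditions

`synthetic_config()` defaults describe the emulated surveillance setting:

* baseline 12.6 preterm births per 100 live births, anchored in the first
  study year, with the early preterm fraction 3.6/12.6 — the national
  scales of the emulated period;
* six 5-year age groups with a U-shaped multiplier profile
  (1.15, 0.95, 0.90, 0.95, 1.10, 1.30 before normalization), normalized so
  the birth-share-weighted mean multiplier is 1; birth shares
  (0.10, 0.25, 0.28, 0.23, 0.11, 0.03) approximate the US maternal-age
  distribution of live births;
* spatially structured county effects (ICAR, marginal SD 0.15 on the log
  scale, scaled so the geometric-mean marginal variance matches) plus iid
  heterogeneity (SD 0.10) — together sized so the 90th:10th county
  percentile ratio sits near 1.6;
* county log-linear slopes with SD 0.01 per year and mean zero;
* county sizes log-uniform between the `births_range` bounds, tilted by the
  age shares, with Poisson annual cell counts;
* a half-variance correction on the log baseline removes the log-normal
  mean bias so the population-weighted crude rate sits on the baseline
  scale;
* an SVI whose overall and theme-1 percentiles couple to the county mean
  log rate with target correlation 0.55; the latent loading carries a 1.055
  compensation for the attenuation introduced by the rank transform and the
  exponentiation of log rates, calibrated so the theme-1 univariate $R^2$
  against age-standardized rates sits near 0.27; themes 2-4 couple at 0.75,
  0.45 and 0.55 of that loading.

Counts are binomial given births (and early preterm binomial given preterm),
matching the subset structure of the real data, which makes the Poisson
likelihood of the estimator a deliberate approximation under test.

What the generator does *not* emulate: real US geography and adjacency
(rook lattices stand in), migration, within-county heterogeneity,
maternal-age distributions varying across counties, reporting artefacts, or
slope distributions with a drifting national mean (slopes are zero-mean by
construction, so on synthetic panels the national percent change centres on
zero and roughly symmetric shares of counties show significant increases and
decreases). Passing the recovery tests therefore shows the estimator is
calibrated under its assumed structure with binomial counts — not that real
birth data satisfy that structure.

## Problem sizes used in the checks

The estimator recovery check runs a 10×10 lattice, 6 age groups, 13 years,
50-500 expected births per cell, and the default 5000-iteration chain — a
desk-scale configuration chosen so a full run of the suite stays within a
couple of minutes while the panel is still dominated by small-count cells,
which is the regime small-area estimation exists for. The NB size check uses
1000 counties per replicate with 200 replicates; the trend size/power check
uses 1000 counties with a 15% planted-increase share; the theme-1 $R^2$
calibration check uses a 30×30 lattice so the sampling error of $R^2$ is
small against its tolerance.

## Degenerate inputs and tie-breaks

* counties with all-zero births: dropped before fitting, with a warning;
* cells with zero births in an otherwise observed county: contribute
  nothing to the likelihood, receive model-based rates;
* all counties sharing one SVI value: every county goes to quartile 1 with
  a warning (ties always break downward);
* constant rate series: slope exactly 0, percent change exactly 0;
* non-positive rates in a trend series: the county is skipped with a
  message (the log-linear model is undefined there);
* fewer than 10 counties: disparity percentiles refuse to compute;
* isolated counties in the adjacency graph: allowed, flagged, and their
  spatial effect is pinned at zero by the per-component centering.
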