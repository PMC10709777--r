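# pretermsae

Small-area estimation of county-level preterm birth rates from tabulated
vital-statistics counts.

Most US counties record too few births for stable annual preterm birth
rates, especially within 5-year maternal age groups. `pretermsae` implements
the full small-area workflow used for this kind of surveillance analysis:

* a **Bayesian space-time-age smoothing model** — a Besag-York-Mollié (BYM)
  conditional autoregressive model fit by MCMC. For county *i*, age group
  *k*, year *t*:

  ```
  Y_ikt ~ Poisson(n_ikt · λ_ikt / 100)
  log(λ_ikt / 100) = α_k + u_i + v_i + δ_ik + φ_it
  ```

  with `u` an intrinsic CAR (ICAR) field on the county adjacency graph, `v`
  iid county heterogeneity, `δ` an ICAR-in-space field per age group, and
  `φ` a first-order random walk in time per county;
* **direct age standardization** of the smoothed rates to a reference
  year's national birth distribution, with credible intervals propagated
  through the posterior draws;
* **percentile-gap disparity statistics** across counties (90th−10th gap,
  90th:10th ratio, max−min gap) with bootstrap CIs, plus the mapping
  reliability rule (credible-interval width < point estimate and ≥100
  births every year);
* **SVI association**: quartile rate ratios via negative binomial
  regression with a log-offset for births, time-varying SVI release
  mapping, variance explained per SVI theme, and SVI profiling of
  extreme-rate counties;
* **trend analysis**: per-county log-linear regression of smoothed rates,
  total percent change `100·(e^((T−1)·β₁) − 1)`, and classification of
  counties into significantly increasing / decreasing / flat;
* a **synthetic vital-statistics generator** with spatially correlated true
  rates, county-specific trends, and an SVI coupled to the rate surface, so
  the whole pipeline is testable with known ground truth and no restricted
  microdata.

## Worked example

```r
library(pretermsae)

# synthetic study panel: 64 counties on a lattice, 2007-2019
cfg <- synthetic_config(n_rows = 8, n_cols = 8, years = 2007:2019,
                        births_range = c(50, 800), seed = 20)
sim <- generate_panel(cfg)
sim$panel
#> Birth-count panel: 64 counties x 6 age groups x 13 years (2007-2019)
#>   total births 1,282,685; outcomes: preterm, early_preterm

# fit the BYM space-time-age model (about 10 s at this size)
post <- fit_bym_st(sim$panel, sim$structure, mcmc = mcmc_settings(seed = 120))
post
#> Posterior rates (preterm): 64 counties x 6 ages x 13 years, 500 saved draws
#>   posterior median rate range: 6.77 - 25.54 per 100

# age-standardize to the 2007 national birth distribution
w <- reference_weights(sim$panel, 2007)
round(w, 3)
#> 15-19 20-24 25-29 30-34 35-39 40-44
#> 0.107 0.242 0.260 0.230 0.117 0.043
std <- standardize_posterior(post, w)
rel <- reliability_flags(std, sim$panel)   # CrI width < point, >=100 births/yr

# county disparity in 2007
keep <- rel$county_id[rel$reliable]
disparity_summary(std$rate[std$year == 2007 & std$county_id %in% keep], 2007)
#>     p10 median  p90 gap_90_10 ratio_90_10
#>   10.56  13.07 15.8      5.24         1.5

# SVI quartile rate ratios (negative binomial with log-offset)
svi <- generate_svi(cfg, sim$truth)
svi_quartile_rate_ratios(post, sim$panel, svi, years = 2007)
#>   year     term   rr   lo   hi
#> 1 2007 Q2_vs_Q1 1.09 0.99 1.21
#> 2 2007 Q3_vs_Q1 1.14 1.03 1.26
#> 3 2007 Q4_vs_Q1 1.23 1.11 1.35

# per-county log-linear trends on the smoothed rates
fits <- fit_county_trends(std[std$county_id %in% keep, ])
classify_counties(fits)[1, c("n_counties", "share_increasing", "share_decreasing")]
#>   n_counties share_increasing share_decreasing
#> 1         64              0.5            0.391
```

Reading the output: the smoothed 2007 county rates run from about 10.6 per
100 live births at the 10th percentile to 15.8 at the 90th — a gap of 5.2
preterm births per 100 and a 1.5-fold ratio. Counties in the top SVI
quartile have rates 1.23 times those in the bottom quartile. Because the
generator draws county slopes symmetrically around zero and the smoothed
series are precise, about half of these synthetic counties show significant
increases — on real data the share reflects the actual slope distribution.

A full pipeline run (simulate → fit → standardize → associate → trends →
aggregate) is driven by one YAML config:

```r
run_pipeline(list(
  seed = 1, outcome = "preterm", output_dir = "run1",
  synthetic = list(n_rows = 8, n_cols = 8, years = 2007:2019),
  mcmc = list(n_iter = 5000, burnin = 2500, thin = 5)
))
```

which writes delimited outputs (`standardized_rates.csv`, `disparity.csv`,
`rate_ratios.csv`, `county_trends.csv`, `aggregate_rates.csv`, …) and a
`manifest.csv` with per-stage input/output hashes; reruns with the same
config and seed are hash-identical. A thin CLI over the same functions is in
`inst/cli/pretermsae.R` (verbs `simulate`, `fit`, `standardize`,
`associate`, `trends`, `aggregate`, `run-all`, `validate`).

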