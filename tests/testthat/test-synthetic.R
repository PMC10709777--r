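test_that("config validation rejects invalid scales and shapes", {
  expect_error(synthetic_config(baseline_rate_per100 = 120), "invalid scale")
  expect_error(synthetic_config(years = c(2007, 2009, 2010)), "consecutive")
  expect_error(synthetic_config(age_effect_shape = rep(1, 5)), "multiplier")
  expect_error(synthetic_config(spatial_sd = -1), "non-negative")
  expect_error(synthetic_config(svi_correlation = 1.5), "\\[-1, 1\\]")
  expect_error(synthetic_config(births_range = c(0, 10)), "births_range")
})

test_that("with all effects switched off every cell sits exactly on the baseline", {
  cfg <- synthetic_config(n_rows = 3, n_cols = 3, spatial_sd = 0,
                          heterogeneity_sd = 0, trend_sd = 0,
                          age_effect_shape = rep(1, 6),
                          baseline_rate_per100 = 12.6, seed = 2)
  sim <- generate_panel(cfg)
  expect_equal(as.vector(sim$truth$true_rate), rep(12.6, 3 * 3 * 6 * 13),
               tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_rows = 10, n_cols = 10, seed = 5)
  s1 <- generate_panel(cfg)
  s2 <- generate_panel(cfg)
  expect_identical(s1$panel$counts, s2$panel$counts)
  expect_identical(s1$truth, s2$truth)
  v1 <- generate_svi(cfg, s1$truth)
  v2 <- generate_svi(cfg, s2$truth)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
})

test_that("counts are coherent and the population-weighted rate is calibrated", {
  cfg <- synthetic_config(n_rows = 10, n_cols = 10, births_range = c(50, 500),
                          seed = 3)
  sim <- generate_panel(cfg)
  cc <- sim$panel$counts
  expect_true(all(cc$preterm <= cc$births))
  expect_true(all(cc$early_preterm <= cc$preterm))
  expect_true(all(cc$births >= 0))
  expect_true(all(cc$preterm == round(cc$preterm)))
  # anchor-year population-weighted crude rate on the 12.6 baseline scale
  y0 <- cc[cc$year == 2007, ]
  crude <- 100 * sum(y0$preterm) / sum(y0$births)
  expect_equal(crude, 12.6, tolerance = 0.6)
  early <- 100 * sum(y0$early_preterm) / sum(y0$births)
  expect_equal(early, 3.6, tolerance = 0.3)
  expect_true(all(sim$truth$true_rate > 0 & sim$truth$true_rate < 100))
})

test_that("configs whose implied rates exceed 100 per 100 are rejected", {
  cfg <- synthetic_config(n_rows = 5, n_cols = 5, baseline_rate_per100 = 90,
                          spatial_sd = 3, seed = 8)
  expect_error(generate_panel(cfg), "exceed 100 per 100")
})

test_that("cell crude rates converge to the truth as births grow (LLN)", {
  base <- synthetic_config(n_rows = 5, n_cols = 5, years = 2007:2009,
                           births_range = c(100, 200), seed = 6)
  big <- synthetic_config(n_rows = 5, n_cols = 5, years = 2007:2009,
                          births_range = c(1000, 2000), seed = 6)
  err <- function(cfg) {
    sim <- generate_panel(cfg)
    arr <- panel_arrays(sim$panel)
    ok <- arr$n > 0
    mean(abs(100 * arr$Y[ok] / arr$n[ok] - sim$truth$true_rate[ok]))
  }
  expect_lt(err(big), err(base))
})

test_that("SVI percentiles are rank grids with the requested rate coupling", {
  cfg0 <- synthetic_config(n_rows = 10, n_cols = 10, svi_correlation = 0,
                           seed = 4)
  sim0 <- generate_panel(cfg0)
  svi0 <- generate_svi(cfg0, sim0$truth)
  s0 <- svi0[svi0$release_year == 2010, ]
  x0 <- apply(log(sim0$truth$true_rate), 1, mean)
  expect_lt(abs(cor(x0, s0$svi_overall)), 0.2)
  # sorted percentile column is the uniform grid 1/N ... 1
  expect_equal(sort(s0$svi_overall), seq_len(100) / 100)

  cfg5 <- synthetic_config(n_rows = 20, n_cols = 20, svi_correlation = 0.5,
                           seed = 4)
  sim5 <- generate_panel(cfg5)
  svi5 <- generate_svi(cfg5, sim5$truth)
  s5 <- svi5[svi5$release_year == 2010, ]
  x5 <- apply(log(sim5$truth$true_rate), 1, mean)
  expect_equal(cor(x5, s5$svi_overall), 0.5, tolerance = 0.1)
  # theme 1 carries the strongest coupling
  cors <- sapply(paste0("theme", 1:4), function(th) abs(cor(x5, s5[[th]])))
  expect_equal(names(which.max(cors)), "theme1")

  one_rel <- generate_svi(cfg0, sim0$truth, release_years = 2010L)
  expect_equal(unique(one_rel$release_year), 2010L)
})

test_that("with trend_sd = 0 fitted per-county slopes centre on zero", {
  cfg <- synthetic_config(n_rows = 8, n_cols = 8, trend_sd = 0,
                          births_range = c(500, 2000), seed = 9)
  sim <- generate_panel(cfg)
  w <- reference_weights(sim$panel, 2007)
  std <- standardize_crude(sim$panel, w)
  fits <- fit_county_trends(std)
  expect_lt(abs(mean(fits$beta1)), 0.003)
  expect_lt(mean(fits$significant_increase), 0.08)
})
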