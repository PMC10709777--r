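make_svi <- function(vals, release = 2010L, years = 2007:2019) {
  ids <- sprintf("%05d", seq_along(vals))
  structure(
    data.frame(county_id = ids, release_year = release, svi_overall = vals,
               theme1 = vals, theme2 = vals, theme3 = vals, theme4 = vals),
    release_map = default_release_map(years, release),
    class = c("svi_table", "data.frame")
  )
}

test_that("quartile assignment splits distinct values evenly with ties to the lower quartile", {
  svi <- make_svi((1:8) / 8)
  q <- assign_svi_quartiles(svi, 2008)
  expect_equal(unname(table(q)), rep(2L, 4), ignore_attr = TRUE)
  # values tied with the break go low: quartile breaks at .25/.5/.75 of 8 pts
  expect_equal(unname(q[order(names(q))][1:2]), c(1L, 1L))

  same <- make_svi(rep(0.5, 8))
  expect_warning(q1 <- assign_svi_quartiles(same, 2008), "quartile 1")
  expect_true(all(q1 == 1L))
})

test_that("the time-varying release map resolves analysis years as published", {
  cfg <- synthetic_config(n_rows = 4, n_cols = 4, seed = 1)
  sim <- generate_panel(cfg)
  svi <- generate_svi(cfg, sim$truth)
  expect_equal(svi_release_for_year(svi, 2013), 2014L) # 2014 release covers 2012-2015
  expect_equal(svi_release_for_year(svi, 2007), 2010L)
  expect_equal(svi_release_for_year(svi, 2011), 2010L)
  expect_equal(svi_release_for_year(svi, 2016), 2016L)
  expect_equal(svi_release_for_year(svi, 2019), 2018L)
  expect_error(svi_release_for_year(svi, 2030), "not covered")
})

test_that("negative binomial rate model recovers coefficients and exposes exp(beta) exactly", {
  set.seed(21)
  n_c <- 400
  births <- round(exp(runif(n_c, log(300), log(3000))))
  svi <- runif(n_c)
  beta1 <- 0.4
  rate <- 0.10 * exp(beta1 * (svi - 0.5) + rnorm(n_c, 0, 0.08))
  Y <- rpois(n_c, births * rate)
  fit <- fit_nb_rate_model(Y, births, svi, design = "continuous")
  expect_equal(unname(fit$coefficients["x"]), beta1, tolerance = 0.12)
  # rate_ratio = exp(beta1) to machine precision
  expect_equal(fit$rate_ratios$rr, unname(exp(fit$coefficients["x"])),
               tolerance = 1e-12)
  expect_true(all(fit$rate_ratios$rr > 0))

  expect_error(fit_nb_rate_model(Y[1:10], births[1:10], svi[1:10]),
               "at least 20")
  expect_error(fit_nb_rate_model(Y, births, rep(0.5, n_c),
                                 design = "continuous"), "zero-variance")
  expect_error(fit_nb_rate_model(Y, c(0, births[-1]), svi,
                                 design = "continuous"), "positive")
})

test_that("identical counts and offsets give a flat SVI slope", {
  n_c <- 50
  fit <- fit_nb_rate_model(rep(30L, n_c), rep(300, n_c), seq(0, 1, length.out = n_c),
                           design = "continuous")
  expect_equal(unname(fit$coefficients["x"]), 0, tolerance = 1e-6)
  expect_equal(fit$rate_ratios$rr, 1, tolerance = 1e-6)
})

test_that("the NB fit approaches the Poisson fit on equidispersed counts", {
  set.seed(22)
  n_c <- 300
  births <- round(runif(n_c, 500, 3000))
  svi <- runif(n_c)
  Y <- rpois(n_c, births * 0.12 * exp(0.3 * svi))
  nb <- fit_nb_rate_model(Y, births, svi, design = "continuous")
  po <- glm(Y ~ svi + offset(log(births)), family = poisson())
  expect_equal(unname(nb$coefficients), unname(coef(po)), tolerance = 1e-3)
})

test_that("OLS variance explained behaves at the noiseless and null extremes and nests", {
  ids <- sprintf("%05d", 1:400)
  set.seed(23)
  th <- replicate(4, rank(rnorm(400)) / 400)
  svi <- structure(
    data.frame(county_id = ids, release_year = 2010L,
               svi_overall = th[, 1], theme1 = th[, 1], theme2 = th[, 2],
               theme3 = th[, 3], theme4 = th[, 4]),
    release_map = default_release_map(2007:2019, 2010L),
    class = c("svi_table", "data.frame")
  )
  # rate an exact linear function of theme 1
  rates <- data.frame(county_id = ids, rate = 8 + 6 * th[, 1])
  r2 <- ols_variance_explained(rates, svi, 2009)
  expect_equal(r2$univariate$r_squared[r2$univariate$term == "theme1"], 1,
               tolerance = 1e-10)
  # independent rates: R^2 near zero at n = 400
  rates0 <- data.frame(county_id = ids, rate = rnorm(400, 12, 1.5))
  r20 <- ols_variance_explained(rates0, svi, 2009)
  expect_true(all(r20$univariate$r_squared < 0.05))
  # nesting: sequential R^2 never decreases, all within [0, 1]
  expect_true(all(diff(r2$sequential$r_squared) >= -1e-12))
  expect_true(all(r20$univariate$r_squared >= 0 & r20$univariate$r_squared <= 1))
})

test_that("extreme-county SVI profiling reflects the rate-SVI coupling", {
  ids <- sprintf("%05d", 1:200)
  set.seed(24)
  svi_vals <- rank(rnorm(200)) / 200
  svi <- structure(
    data.frame(county_id = ids, release_year = 2018L, svi_overall = svi_vals,
               theme1 = svi_vals, theme2 = rank(rnorm(200)) / 200,
               theme3 = rank(rnorm(200)) / 200, theme4 = rank(rnorm(200)) / 200),
    release_map = default_release_map(2007:2019, 2018L),
    class = c("svi_table", "data.frame")
  )
  # monotone coupling: rate increases with SVI
  rates <- data.frame(county_id = ids, rate = 8 + 8 * svi_vals)
  prof <- profile_extreme_counties(rates, svi, 2019)
  ov <- prof[prof$measure == "svi_overall", ]
  expect_lt(ov$median_pct_low, ov$median_pct_high)
  expect_lt(ov$median_pct_low, 0.2)
  expect_gt(ov$median_pct_high, 0.8)
  # group sizes about 10% of counties each
  expect_equal(ov$n_low, 20, tolerance = 2)
  expect_equal(ov$n_high, 20, tolerance = 2)

  # independence: both groups' overall medians near 0.5
  rates0 <- data.frame(county_id = ids, rate = rnorm(200, 12, 2))
  prof0 <- profile_extreme_counties(rates0, svi, 2019)
  ov0 <- prof0[prof0$measure == "svi_overall", ]
  expect_lt(abs(ov0$median_pct_low - 0.5), 0.25)
  expect_lt(abs(ov0$median_pct_high - 0.5), 0.25)
})

test_that("theme-1 coupling of the default generator lands near the calibration target", {
  # 900 counties so the sampling error of R^2 is well inside the band
  cfg <- synthetic_config(n_rows = 30, n_cols = 30, births_range = c(50, 500),
                          seed = 1)
  sim <- generate_panel(cfg)
  svi <- generate_svi(cfg, sim$truth)
  post <- fit_bym_st(sim$panel, sim$structure,
                     mcmc = mcmc_settings(n_iter = 1500, burnin = 750,
                                          thin = 5, seed = 4))
  w <- reference_weights(sim$panel, 2007)
  std <- standardize_posterior(post, w)
  rates <- std[std$year == 2019, c("county_id", "rate")]
  r2 <- ols_variance_explained(rates, svi, 2019)
  expect_equal(r2$univariate$r_squared[r2$univariate$term == "theme1"], 0.27,
               tolerance = 0.05)
})
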