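test_that("model collapses to Poisson rate estimation on a single cell", {
  df <- data.frame(county_id = "00001", age_group = "15-19", year = 2007L,
                   births = 100L, preterm = 12L, early_preterm = 4L)
  panel <- count_panel(df)
  adj <- load_adjacency(matrix(character(0), ncol = 2), "00001")
  post <- fit_bym_st(panel, adj,
                     mcmc = mcmc_settings(n_iter = 6000, burnin = 2000,
                                          thin = 2, seed = 1,
                                          fixed_precisions = list(u = 1e8, v = 1e8,
                                                                  delta = 1e8,
                                                                  phi = 1e8)))
  # flat prior on log-rate: posterior is Gamma(12, 100); its median is 11.67
  expect_equal(post$summary$post_median, 11.67, tolerance = 0.8)
  expect_lt(post$summary$ci_lo, post$summary$post_median)
  expect_gt(post$summary$ci_hi, post$summary$post_median)
})

test_that("an empty county is shrunk strictly between its crude rate and its neighbours", {
  # 3x3 lattice, one age, one year; centre county observes 0/30 while all
  # neighbours sit at 15 per 100
  ids <- sprintf("%05d", 1:9)
  df <- data.frame(county_id = ids, age_group = "25-29", year = 2007L,
                   births = c(rep(400L, 4), 30L, rep(400L, 4)),
                   preterm = c(rep(60L, 4), 0L, rep(60L, 4)))
  panel <- count_panel(df)
  adj <- lattice_adjacency(3, 3)
  post <- fit_bym_st(panel, adj,
                     mcmc = mcmc_settings(n_iter = 4000, burnin = 2000,
                                          thin = 2, seed = 2))
  centre <- post$summary$post_median[post$summary$county_id == "00005"]
  expect_gt(centre, 0)
  expect_lt(centre, 15)
})

test_that("posterior medians stay on the admissible rate scale", {
  cfg <- synthetic_config(n_rows = 5, n_cols = 5, years = 2007:2011, seed = 11)
  sim <- generate_panel(cfg)
  post <- fit_bym_st(sim$panel, sim$structure,
                     mcmc = mcmc_settings(n_iter = 1000, burnin = 500,
                                          thin = 5, seed = 3))
  expect_true(all(post$summary$post_median > 0))
  expect_true(all(post$summary$post_median < 100))
  expect_true(all(post$summary$ci_lo <= post$summary$post_median))
  expect_true(all(post$summary$post_median <= post$summary$ci_hi))
})

test_that("with precisions fixed very large estimates approach pooled age rates", {
  cfg <- synthetic_config(n_rows = 4, n_cols = 4, years = 2007:2010,
                          births_range = c(200, 800), seed = 12)
  sim <- generate_panel(cfg)
  post <- fit_bym_st(sim$panel, sim$structure,
                     mcmc = mcmc_settings(n_iter = 3000, burnin = 1500,
                                          thin = 3, seed = 4,
                                          fixed_precisions = list(u = 1e8, v = 1e8,
                                                                  delta = 1e8,
                                                                  phi = 1e8)))
  arr <- panel_arrays(sim$panel)
  pooled <- 100 * apply(arr$Y, 2, sum) / apply(arr$n, 2, sum)
  for (k in seq_along(post$age_groups)) {
    est_k <- post$summary$post_median[post$summary$age_group == post$age_groups[k]]
    expect_equal(unname(mean(est_k)), unname(pooled[k]), tolerance = 0.05 * pooled[k])
    # smoothing limit: essentially no spread across counties or years
    expect_lt(sd(est_k), 0.05 * pooled[k])
  }
})

test_that("chains with different seeds agree within Monte-Carlo error", {
  cfg <- synthetic_config(n_rows = 5, n_cols = 5, years = 2007:2011,
                          births_range = c(100, 400), seed = 13)
  sim <- generate_panel(cfg)
  fit <- function(s) fit_bym_st(sim$panel, sim$structure,
                                mcmc = mcmc_settings(n_iter = 4000, burnin = 2000,
                                                     thin = 2, seed = s))
  p1 <- fit(101); p2 <- fit(202)
  m1 <- p1$summary$post_median; m2 <- p2$summary$post_median
  mcse <- sqrt(batch_mcse(p1$draws)^2 + batch_mcse(p2$draws)^2)
  frac_within <- mean(abs(m1 - m2) <= 3 * mcse)
  expect_gt(frac_within, 0.90)
  expect_lt(mean(abs(m1 - m2)), 0.25)
})

test_that("counties with zero births everywhere are dropped with a warning", {
  ids <- sprintf("%05d", 1:4)
  df <- expand.grid(county_id = ids, age_group = "20-24", year = 2007:2009,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$births <- ifelse(df$county_id == "00004", 0L, 300L)
  df$preterm <- ifelse(df$county_id == "00004", 0L, 36L)
  panel <- count_panel(df)
  adj <- lattice_adjacency(2, 2)
  expect_warning(
    post <- fit_bym_st(panel, adj,
                       mcmc = mcmc_settings(n_iter = 400, burnin = 200,
                                            thin = 2, seed = 5)),
    "zero births"
  )
  expect_equal(post$dropped_counties, "00004")
  expect_false("00004" %in% post$summary$county_id)
})

test_that("reliability rule reproduces hand-computed flags", {
  # constructed county-year summaries: the rule is (hi - lo) < point in every
  # year AND births >= 100 in every year
  std <- data.frame(
    county_id = rep(c("A", "B", "C"), each = 2),
    year = rep(2007:2008, 3),
    rate = c(5, 5, 12, 12, 12, 12),
    lo = c(2, 2, 10, 10, 10, 10),
    hi = c(8, 8, 14, 14, 14, 14)
  )
  df <- expand.grid(county_id = c("A", "B", "C"), age_group = "20-24",
                    year = 2007:2008, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$births <- c(150, 150, 150, 150, 150, 99)[match(paste(df$county_id, df$year),
    c("A 2007", "B 2007", "C 2007", "A 2008", "B 2008", "C 2008"))]
  df$preterm <- 10
  panel <- count_panel(df)
  fl <- reliability_flags(std, panel, min_births = 100)
  expect_equal(fl$reliable[fl$county_id == "A"], FALSE) # width 6 >= point 5
  expect_equal(fl$reliable[fl$county_id == "B"], TRUE)  # width 4 < 12, births ok
  expect_equal(fl$reliable[fl$county_id == "C"], FALSE) # 99 births in one year
  expect_true(fl$cri_ok[fl$county_id == "C"])
  expect_false(fl$births_ok[fl$county_id == "C"])
})
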