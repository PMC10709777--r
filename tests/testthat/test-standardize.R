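test_that("reference weights are the normalized birth distribution", {
  df <- expand.grid(county_id = c("A", "B"), age_group = AGE_GROUPS_STANDARD,
                    year = 2007L, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$births <- rep(c(100, 300, 300, 200, 80, 20) / 2, each = 2)
  df$preterm <- 0L
  p <- count_panel(df)
  w <- reference_weights(p, 2007)
  expect_equal(unname(w), c(0.1, 0.3, 0.3, 0.2, 0.08, 0.02))

  df$births <- 50
  w_eq <- reference_weights(count_panel(df), 2007)
  expect_equal(unname(w_eq), rep(1 / 6, 6))
  expect_error(reference_weights(p, 1999), "not in the panel")
})

test_that("weights sum to one for random panels", {
  for (s in 1:5) {
    cfg <- synthetic_config(n_rows = 3, n_cols = 3, years = 2007:2008, seed = s)
    sim <- generate_panel(cfg)
    expect_equal(sum(reference_weights(sim$panel, 2007)), 1, tolerance = 1e-12)
  }
})

test_that("direct standardization is the convex combination of age rates", {
  expect_equal(age_standardize(c(10, 20), c(0.5, 0.5)), 15)
  expect_equal(age_standardize(rep(7.3, 6), rep(1 / 6, 6)), 7.3)
  set.seed(1)
  for (rep in 1:10) {
    r <- runif(6, 2, 30)
    w <- runif(6); w <- w / sum(w)
    s <- age_standardize(r, w)
    expect_gte(s, min(r)); expect_lte(s, max(r))
  }
  expect_error(age_standardize(1:5, rep(1 / 6, 6)), "one rate per age group")
  # label-matched: permuting ages with matched weights leaves the result alone
  r <- c(`15-19` = 14, `20-24` = 11, `25-29` = 10, `30-34` = 11,
         `35-39` = 13, `40-44` = 16)
  w <- c(`15-19` = 0.1, `20-24` = 0.25, `25-29` = 0.28, `30-34` = 0.23,
         `35-39` = 0.11, `40-44` = 0.03)
  perm <- sample(6)
  expect_equal(age_standardize(r[perm], w), age_standardize(r, w))
})

test_that("disparity summary uses interpolated order statistics", {
  d <- disparity_summary(0:10, year = 2007)
  expect_equal(d$p10, 1)
  expect_equal(d$p90, 9)
  expect_equal(d$gap_90_10, 8)
  expect_equal(d$gap_max_min, 10)

  same <- disparity_summary(rep(12.5, 20))
  expect_equal(same$gap_90_10, 0)
  expect_equal(same$ratio_90_10, 1)
  expect_error(disparity_summary(1:9), "fewer than 10")
})

test_that("disparity summary is shift-equivariant", {
  set.seed(3)
  x <- rlnorm(60, log(12), 0.2)
  d0 <- disparity_summary(x)
  d1 <- disparity_summary(x + 2)
  expect_equal(d1$p10, d0$p10 + 2)
  expect_equal(d1$p90, d0$p90 + 2)
  expect_equal(d1$gap_90_10, d0$gap_90_10, tolerance = 1e-10)
  expect_equal(d1$gap_max_min, d0$gap_max_min, tolerance = 1e-10)
  expect_equal(d1$ratio_90_10, (d0$p90 + 2) / (d0$p10 + 2))
})

test_that("bootstrap CI is deterministic, degenerate on constants, and converges in B", {
  set.seed(99); x0 <- rnorm(50, 12)
  expect_identical(bootstrap_gap_ci(x0, B = 300, seed = 1),
                   bootstrap_gap_ci(x0, B = 300, seed = 1))
  expect_error(bootstrap_gap_ci(x0, B = 50), "at least 200")
  const <- bootstrap_gap_ci(rep(10, 40), B = 300, seed = 2)
  expect_equal(const$hi - const$lo, c(0, 0))

  set.seed(4)
  x <- rlnorm(150, log(12), 0.2)
  c1 <- bootstrap_gap_ci(x, B = 500, seed = 5)
  c2 <- bootstrap_gap_ci(x, B = 1000, seed = 5)
  c3 <- bootstrap_gap_ci(x, B = 2000, seed = 5)
  # Monte-Carlo convergence: endpoint movement shrinks as B doubles
  move12 <- abs(c2$lo[1] - c1$lo[1]) + abs(c2$hi[1] - c1$hi[1])
  move23 <- abs(c3$lo[1] - c2$lo[1]) + abs(c3$hi[1] - c2$hi[1])
  expect_lt(move23, move12 + 0.05)
  expect_lt(move23, 0.15)
})

test_that("bootstrap gap CI covers a known population quantile gap", {
  # population: lognormal with known 10th/90th quantile gap
  qs <- qlnorm(c(0.1, 0.9), log(12), 0.18)
  true_gap <- qs[2] - qs[1]
  set.seed(6)
  hits <- 0; reps <- 100
  for (r in seq_len(reps)) {
    x <- rlnorm(200, log(12), 0.18)
    ci <- bootstrap_gap_ci(x, B = 300, seed = r)
    hits <- hits + (ci$lo[1] <= true_gap && true_gap <= ci$hi[1])
  }
  expect_gte(hits / reps, 0.85)
  expect_lte(hits / reps, 1.00)
})

test_that("posterior standardization propagates draws and matches the weight algebra", {
  cfg <- synthetic_config(n_rows = 3, n_cols = 3, years = 2007:2009, seed = 14)
  sim <- generate_panel(cfg)
  post <- fit_bym_st(sim$panel, sim$structure,
                     mcmc = mcmc_settings(n_iter = 800, burnin = 400,
                                          thin = 4, seed = 6))
  w <- reference_weights(sim$panel, 2007)
  std <- standardize_posterior(post, w)
  expect_equal(nrow(std), 9 * 3)
  expect_true(all(std$lo <= std$rate & std$rate <= std$hi))
  # oracle: standardize one county-year by hand from the draws
  j <- which(post$summary$county_id == "00003" & post$summary$year == 2008)
  hand <- apply(post$draws[, j] %*% diag(w[post$summary$age_group[j]]), 1, sum)
  got <- std[std$county_id == "00003" & std$year == 2008, ]
  expect_equal(got$rate, median(hand), tolerance = 1e-9)
})
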