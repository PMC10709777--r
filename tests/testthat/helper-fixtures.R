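# Shared fixtures and independent oracles, built in code at test time.

# Dense degree-minus-adjacency quadratic form: the brute-force oracle for the
# ICAR pairwise-difference penalty.
dense_icar_qf <- function(effects, structure) {
  n <- length(structure$county_ids)
  W <- matrix(0, n, n)
  e <- structure$edges
  for (r in seq_len(nrow(e))) {
    W[e[r, 1], e[r, 2]] <- 1
    W[e[r, 2], e[r, 1]] <- 1
  }
  D <- diag(rowSums(W))
  as.numeric(t(effects) %*% (D - W) %*% effects)
}

# A tiny panel built by hand: `rates` is a county x age matrix of true rates
# per 100, constant over years; births per cell constant.
toy_panel <- function(rates, years = 2007:2011, births = 200, seed = 1) {
  set.seed(seed)
  I <- nrow(rates); K <- ncol(rates)
  ids <- sprintf("%05d", seq_len(I))
  ages <- AGE_GROUPS_STANDARD[seq_len(K)]
  grid <- expand.grid(county_id = ids, age_group = ages, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$births <- births
  p <- rates[cbind(match(grid$county_id, ids), match(grid$age_group, ages))] / 100
  grid$preterm <- rbinom(nrow(grid), births, p)
  grid$early_preterm <- rbinom(nrow(grid), grid$preterm, 0.3)
  count_panel(grid, age_groups = ages)
}

# Batch-means Monte-Carlo standard error of a posterior median estimate,
# computed per draw column.
batch_mcse <- function(draws, n_batch = 20) {
  n <- nrow(draws)
  bsize <- n %/% n_batch
  means <- sapply(seq_len(n_batch), function(b) {
    colMeans(draws[((b - 1) * bsize + 1):(b * bsize), , drop = FALSE])
  })
  apply(means, 1, stats::sd) / sqrt(n_batch)
}
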