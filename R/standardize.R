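#' Direct age standardization and percentile-gap disparity statistics
#'
#' Direct age standardization takes a fixed reference age distribution (here
#' the national distribution of live births in the reference year) and forms
#' the weighted average of age-specific rates, so counties and years with
#' different maternal-age structures are comparable. Disparity across
#' counties is summarised by percentiles of the county distribution of
#' age-standardized rates and the gaps and ratios between them.
#'
#' @name standardization
NULL

#' Reference age weights from a panel year
#'
#' Weight for age group k is the share of national births in that group in
#' the reference year: \eqn{w_k = \sum_i n_{ik} / \sum_i \sum_k n_{ik}}.
#'
#' @param panel A [count_panel].
#' @param ref_year Reference year (conventionally the first study year).
#' @return Named numeric vector of weights (non-negative, summing to 1).
#' @export
reference_weights <- function(panel, ref_year) {
  stopifnot(inherits(panel, "count_panel"))
  if (!ref_year %in% panel$years) {
    stop("reference year ", ref_year, " is not in the panel")
  }
  cc <- panel$counts[panel$counts$year == ref_year, ]
  tot <- tapply(cc$births, factor(cc$age_group, levels = panel$age_groups), sum)
  tot[is.na(tot)] <- 0
  if (sum(tot) == 0) stop("no births recorded in reference year ", ref_year)
  w <- as.numeric(tot) / sum(tot)
  stats::setNames(w, panel$age_groups)
}

#' Directly age-standardize a set of age-specific rates
#'
#' @param rates Numeric vector of age-specific rates, or a matrix with one
#'   column per age group (rows standardized independently). Named vectors /
#'   columns are matched to the weight names.
#' @param weights Reference weights from [reference_weights()] (or any
#'   non-negative weights summing to 1).
#' @return Scalar (or per-row vector): \eqn{\sum_k w_k \, r_k}, a convex
#'   combination lying within the range of the input rates.
#' @export
age_standardize <- function(rates, weights) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (is.matrix(rates)) {
    if (ncol(rates) != length(weights)) stop("one rate column per age group required")
    if (!is.null(colnames(rates)) && !is.null(names(weights))) {
      if (!setequal(colnames(rates), names(weights))) {
        stop("rate columns and weight names disagree")
      }
      rates <- rates[, names(weights), drop = FALSE]
    }
    return(as.numeric(rates %*% weights))
  }
  if (length(rates) != length(weights)) {
    stop("one rate per age group required (missing age group?)")
  }
  if (!is.null(names(rates)) && !is.null(names(weights))) {
    if (!setequal(names(rates), names(weights))) stop("missing age group in rates")
    rates <- rates[names(weights)]
  }
  sum(rates * weights)
}

#' Age-standardized county-year rates from posterior draws
#'
#' Standardizes every saved MCMC draw, so the credible interval of the
#' standardized rate propagates the joint posterior uncertainty across age
#' groups rather than combining cell-wise intervals.
#'
#' @param post A `posterior_rates` object from [fit_bym_st()].
#' @param weights Reference weights (one per age group of the fit).
#' @return Data frame `county_id, year, rate, lo, hi` where `rate` is the
#'   posterior median of the age-standardized rate per 100 live births and
#'   `lo`/`hi` its 95% credible bounds.
#' @export
standardize_posterior <- function(post, weights) {
  stopifnot(inherits(post, "posterior_rates"))
  I <- length(post$county_ids); K <- length(post$age_groups)
  T <- length(post$years)
  if (length(weights) != K) stop("one weight per age group required")
  if (!is.null(names(weights))) weights <- weights[post$age_groups]
  # draw columns are ordered county fastest, then age, then year
  cell <- expand.grid(i = seq_len(I), k = seq_len(K), t = seq_len(T))
  S <- Matrix::sparseMatrix(
    i = seq_len(nrow(cell)),
    j = cell$i + (cell$t - 1L) * I,
    x = weights[cell$k],
    dims = c(I * K * T, I * T)
  )
  std_draws <- as.matrix(post$draws %*% S)
  qs <- apply(std_draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  grid <- expand.grid(county_id = post$county_ids, year = post$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(grid, rate = qs[2, ], lo = qs[1, ], hi = qs[3, ],
             stringsAsFactors = FALSE)
}

#' Age-standardize crude panel rates
#'
#' Convenience for aggregated (national/state/region) panels where smoothing
#' is unnecessary: computes crude age-specific rates and standardizes them.
#'
#' @param panel A [count_panel].
#' @param weights Reference weights.
#' @param outcome Outcome column.
#' @return Data frame `county_id, year, rate` (for aggregated panels
#'   `county_id` holds the unit id).
#' @export
standardize_crude <- function(panel, weights, outcome = "preterm") {
  cc <- panel$counts
  rate_cell <- ifelse(cc$births > 0, 100 * cc[[outcome]] / cc$births, 0)
  w <- weights[match(cc$age_group, names(weights))]
  num <- tapply(rate_cell * w, list(cc$county_id, cc$year), sum)
  grid <- expand.grid(county_id = rownames(num), year = as.integer(colnames(num)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(grid, rate = as.vector(num), stringsAsFactors = FALSE)
}

#' Gap and ratio functionals of a rate distribution
#'
#' @param minimum,p10,p90,maximum Percentile values of the county
#'   distribution of age-standardized rates.
#' @return List with `gap_90_10 = p90 - p10`, `ratio_90_10 = p90 / p10`, and
#'   `gap_max_min = maximum - minimum`.
#' @export
disparity_functionals <- function(minimum, p10, p90, maximum) {
  list(gap_90_10 = p90 - p10,
       ratio_90_10 = p90 / p10,
       gap_max_min = maximum - minimum)
}

#' Distribution summary of county age-standardized rates
#'
#' Percentiles use linear interpolation of order statistics (the default
#' continuous quantile rule, R type 7), so summaries of a fixed input are
#' reproducible bit-for-bit.
#'
#' @param county_rates Numeric vector of age-standardized county rates (one
#'   value per reliable county).
#' @param year Calendar year the summary describes (carried through).
#' @return One-row data frame: `year, n_counties, minimum, p10, p25, median,
#'   p75, p90, maximum, gap_90_10, ratio_90_10, gap_max_min`.
#' @export
disparity_summary <- function(county_rates, year = NA_integer_) {
  county_rates <- county_rates[!is.na(county_rates)]
  if (length(county_rates) < 10) {
    stop("fewer than 10 counties: percentile summary is meaningless")
  }
  q <- stats::quantile(county_rates, c(0, 0.10, 0.25, 0.50, 0.75, 0.90, 1),
                       type = 7, names = FALSE)
  fx <- disparity_functionals(q[1], q[2], q[6], q[7])
  data.frame(year = year, n_counties = length(county_rates),
             minimum = q[1], p10 = q[2], p25 = q[3], median = q[4],
             p75 = q[5], p90 = q[6], maximum = q[7],
             gap_90_10 = fx$gap_90_10, ratio_90_10 = fx$ratio_90_10,
             gap_max_min = fx$gap_max_min)
}

#' Percentile-bootstrap CI for the 90th-10th percentile gap and ratio
#'
#' Resamples counties with replacement and reports the 2.5th and 97.5th
#' percentiles of the bootstrap distribution of each functional.
#'
#' @param county_rates Numeric vector of county age-standardized rates.
#' @param B Bootstrap replicates (>= 200).
#' @param seed RNG seed; deterministic given it.
#' @return Data frame with rows `gap_90_10` and `ratio_90_10`, columns
#'   `estimate, lo, hi`.
#' @export
bootstrap_gap_ci <- function(county_rates, B = 1000L, seed = 7L) {
  if (B < 200) stop("B must be at least 200")
  county_rates <- county_rates[!is.na(county_rates)]
  n <- length(county_rates)
  set.seed(seed)
  stat <- function(x) {
    q <- stats::quantile(x, c(0.10, 0.90), type = 7, names = FALSE)
    c(gap = q[2] - q[1], ratio = q[2] / q[1])
  }
  obs <- stat(county_rates)
  boot <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    boot[b, ] <- stat(county_rates[sample.int(n, n, replace = TRUE)])
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(functional = c("gap_90_10", "ratio_90_10"),
             estimate = as.numeric(obs),
             lo = ci[1, ], hi = ci[2, ], row.names = NULL)
}

#' Round for report tables
#'
#' One decimal place, round-half-even (the IEC 60559 behaviour of base
#' `round()`), matching conventional printed precision of rate tables.
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_report <- function(x, digits = 1) round(x, digits)
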