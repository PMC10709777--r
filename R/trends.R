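#' Log-linear trends in county birth-outcome rates
#'
#' Per-county (or per-aggregate) log-linear regression of estimated annual
#' rates on a year index, total percent change over the study span, and
#' classification of counties into significantly increasing / decreasing /
#' flat.
#'
#' @name trend_analysis
NULL

#' Fit a log-linear trend to an annual rate series
#'
#' Ordinary least squares of \eqn{\ln(\lambda_t)} on the year index
#' \eqn{t = 0, \ldots, T-1}. Total percent change over the span is
#' \eqn{100\,(e^{(T-1)\beta_1} - 1)} (the familiar constant 12 for a 13-year
#' panel). The 95% CI transforms the t-interval for \eqn{(T-1)\beta_1}
#' through the same monotone map; a trend is significant when that CI
#' excludes 0.
#'
#' @param rates Positive annual rates, in year order.
#' @param id,age_stratum Optional labels carried into the result.
#' @return One-row data frame of class `trend_fit`: `id, age_stratum, beta0,
#'   beta1, se_beta1, pct_change, ci_lo, ci_hi, significant_increase,
#'   significant_decrease`.
#' @export
fit_loglinear_trend <- function(rates, id = NA_character_, age_stratum = NA_character_) {
  T <- length(rates)
  if (T < 3) stop("at least 3 annual rates are required")
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rates must be positive to fit a log-linear trend")
  }
  t <- seq_len(T) - 1
  y <- log(rates)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  beta1 <- sum(tc * y) / sxx
  beta0 <- mean(y) - beta1 * mean(t)
  resid <- y - (beta0 + beta1 * t)
  df <- T - 2
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 / sxx)
  span <- T - 1
  tq <- stats::qt(0.975, df)
  pct <- 100 * (exp(span * beta1) - 1)
  lo <- 100 * (exp(span * (beta1 - tq * se)) - 1)
  hi <- 100 * (exp(span * (beta1 + tq * se)) - 1)
  structure(
    data.frame(id = id, age_stratum = age_stratum,
               beta0 = beta0, beta1 = beta1, se_beta1 = se,
               pct_change = pct, ci_lo = lo, ci_hi = hi,
               significant_increase = lo > 0,
               significant_decrease = hi < 0,
               stringsAsFactors = FALSE),
    class = c("trend_fit", "data.frame")
  )
}

#' Fit log-linear trends for every county in a rate table
#'
#' @param rates Data frame `county_id, year, rate` (e.g. from
#'   [standardize_posterior()]), one row per county-year.
#' @param age_stratum Optional label.
#' @return Data frame of per-county trend fits (one row per county). Counties
#'   with any non-positive or missing rate are skipped with a message.
#' @export
fit_county_trends <- function(rates, age_stratum = NA_character_) {
  split_rates <- split(rates[order(rates$year), ], rates$county_id[order(rates$year)])
  skipped <- character(0)
  out <- vector("list", length(split_rates))
  for (j in seq_along(split_rates)) {
    s <- split_rates[[j]]
    if (any(!is.finite(s$rate)) || any(s$rate <= 0) || nrow(s) < 3) {
      skipped <- c(skipped, s$county_id[1]); next
    }
    out[[j]] <- fit_loglinear_trend(s$rate, id = s$county_id[1],
                                    age_stratum = age_stratum)
  }
  if (length(skipped)) {
    message(length(skipped), " county(ies) skipped (non-positive or incomplete rates)")
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Classify counties by trend significance
#'
#' @param fits Data frame of trend fits from [fit_county_trends()] (may
#'   contain several age strata).
#' @return Data frame per age stratum (plus `"all"` when strata are present)
#'   with counts and shares of significantly increasing / decreasing / flat
#'   counties and exact binomial 95% CIs for the increasing and decreasing
#'   shares.
#' @export
classify_counties <- function(fits) {
  if (is.null(fits) || nrow(fits) == 0) stop("no trend fits supplied")
  one <- function(f, label) {
    n <- nrow(f)
    inc <- sum(f$significant_increase)
    dec <- sum(f$significant_decrease)
    ci_i <- stats::binom.test(inc, n)$conf.int
    ci_d <- stats::binom.test(dec, n)$conf.int
    data.frame(age_stratum = label, n_counties = n,
               n_increasing = inc, n_decreasing = dec,
               n_flat = n - inc - dec,
               share_increasing = inc / n,
               share_inc_lo = ci_i[1], share_inc_hi = ci_i[2],
               share_decreasing = dec / n,
               share_dec_lo = ci_d[1], share_dec_hi = ci_d[2],
               stringsAsFactors = FALSE)
  }
  strata <- unique(fits$age_stratum)
  rows <- list(one(fits, "all"))
  if (length(strata) > 1 || !all(is.na(strata))) {
    for (s in strata) {
      f <- fits[is.na(fits$age_stratum) == is.na(s) &
                  (is.na(s) | fits$age_stratum == s), ]
      lab <- if (is.na(s)) "unspecified" else s
      rows[[length(rows) + 1L]] <- one(f, lab)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate county counts to larger geographic units
#'
#' Sums outcome and birth counts within units (national, state, region/CSA)
#' preserving the age x year structure, so the same standardization and
#' trend operations apply downstream. Counties absent from the membership
#' column of interest form residual "rest-of-state" units.
#'
#' @param panel A [count_panel].
#' @param membership Data frame `county_id, unit` mapping every panel county
#'   to exactly one unit; or `county_id, state_id, region_id` with
#'   `level = "region"`, where counties with missing `region_id` are pooled
#'   into `<state_id>_rest`.
#' @param level When membership has state/region columns: `"state"`,
#'   `"region"`, or `"national"`.
#' @return A [count_panel] whose `county_ids` are the unit ids. Aggregation
#'   conserves totals exactly.
#' @export
aggregate_crude <- function(panel, membership = NULL,
                            level = c("national", "state", "region")) {
  level <- match.arg(level)
  cc <- panel$counts
  if (level == "national") {
    unit <- rep("US", nrow(cc))
  } else {
    if (is.null(membership)) stop("membership table required for level '", level, "'")
    if (!"unit" %in% names(membership)) {
      if (level == "state") {
        membership$unit <- membership$state_id
      } else {
        membership$unit <- ifelse(
          is.na(membership$region_id) | membership$region_id == "",
          paste0(membership$state_id, "_rest"), membership$region_id
        )
      }
    }
    if (anyDuplicated(membership$county_id)) {
      stop("county mapped to two units in membership table")
    }
    m <- match(cc$county_id, membership$county_id)
    if (anyNA(m)) {
      stop("membership does not cover counties: ",
           paste(utils::head(unique(cc$county_id[is.na(m)]), 5), collapse = ", "))
    }
    unit <- membership$unit[m]
  }
  agg <- stats::aggregate(
    cc[, c("births", panel$outcomes)],
    by = list(county_id = unit, age_group = cc$age_group, year = cc$year),
    FUN = sum
  )
  count_panel(agg, age_groups = panel$age_groups)
}

#' Export county values as a GeoJSON property map
#'
#' Writes a `{county_id: value}` JSON object for joining onto county
#' geometries in external choropleth tooling (no geometry is produced here).
#'
#' @param values Named numeric vector (county id -> value) or a data frame
#'   with columns `county_id` and a single value column.
#' @param path Output path.
#' @export
write_geojson_properties <- function(values, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for GeoJSON property export")
  }
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values), "county_id")[1]
    values <- stats::setNames(values[[vcol]], values$county_id)
  }
  jsonlite::write_json(as.list(values), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write county trend classifications to a delimited file
#'
#' Columns: `county_id, pct_change, ci_lo, ci_hi, class` where class is
#' `increasing`, `decreasing` or `flat`.
#' @param fits Data frame from [fit_county_trends()].
#' @param path Output path.
#' @export
write_trend_classification <- function(fits, path) {
  cls <- ifelse(fits$significant_increase, "increasing",
                ifelse(fits$significant_decrease, "decreasing", "flat"))
  utils::write.csv(
    data.frame(county_id = fits$id, pct_change = fits$pct_change,
               ci_lo = fits$ci_lo, ci_hi = fits$ci_hi, class = cls),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
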