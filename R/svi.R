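#' Social vulnerability and county preterm birth rates
#'
#' Associations between county-level social vulnerability (CDC SVI: an
#' overall percentile plus four themes -- socioeconomic status; household
#' composition and disability; minority status and language; housing and
#' transportation) and smoothed birth-outcome rates: quartile rate ratios
#' from negative binomial regression with a log-offset for births,
#' variance-explained from ordinary least squares, and SVI profiling of
#' counties in the tails of the rate distribution.
#'
#' @name svi_association
NULL

#' Resolve the SVI release used for an analysis year
#'
#' @param svi An `svi_table` (with a `release_map` attribute) or a release
#'   map data frame `year, release_year`.
#' @param year Analysis year.
#' @return Integer release year.
#' @export
svi_release_for_year <- function(svi, year) {
  map <- if (inherits(svi, "svi_table")) attr(svi, "release_map") else svi
  if (is.null(map)) stop("SVI table carries no release map")
  hit <- map$release_year[map$year == year]
  if (!length(hit)) stop("analysis year ", year, " is not covered by the SVI release map")
  as.integer(hit[1])
}

#' Assign counties to overall-SVI quartiles for an analysis year
#'
#' Quartile breaks are the empirical quartiles of the overall SVI percentile
#' among the included counties in the resolved release year. Values tied with
#' a break go to the lower quartile.
#'
#' @param svi An `svi_table`.
#' @param year Analysis year (mapped to a release via the release map).
#' @param counties Optional subset of county ids to include.
#' @return Named integer vector (county id -> quartile 1-4).
#' @export
assign_svi_quartiles <- function(svi, year, counties = NULL) {
  rel <- svi_release_for_year(svi, year)
  tab <- as.data.frame(svi)
  tab <- tab[tab$release_year == rel, ]
  if (!is.null(counties)) tab <- tab[tab$county_id %in% counties, ]
  if (!nrow(tab)) stop("no SVI rows for release year ", rel)
  x <- tab$svi_overall
  if (stats::sd(x) == 0) {
    warning("all counties share the same SVI; assigning every county to quartile 1")
    return(stats::setNames(rep(1L, nrow(tab)), tab$county_id))
  }
  br <- stats::quantile(x, c(0.25, 0.50, 0.75), type = 7, names = FALSE)
  q <- 1L + (x > br[1]) + (x > br[2]) + (x > br[3])
  stats::setNames(as.integer(q), tab$county_id)
}

#' Negative binomial rate-ratio regression with a log-offset
#'
#' Fits \eqn{Y \sim \mathrm{NB}(\mu, \theta)} with
#' \eqn{\log \mu = \beta_0 + x^\top\beta + \log n} across counties, where the
#' design is either the overall SVI quartile (indicator contrasts against
#' quartile 1) or the continuous SVI percentile. Rate ratios are
#' \eqn{e^\beta} with 95% Wald intervals. Dispersion is estimated by maximum
#' likelihood ([MASS::glm.nb()]); on equidispersed data the fit converges to
#' the Poisson fit (theta diverges; a note is recorded).
#'
#' @param Y Integer outcome counts per county.
#' @param n Offset: total births per county (must be positive).
#' @param svi Either a factor/integer of quartiles or a numeric SVI
#'   percentile.
#' @param design `"quartile"` or `"continuous"`.
#' @param year,age_stratum Optional labels carried into the result.
#' @return An `nb_fit`: list with `coefficients`, `se`, `rate_ratios` (data
#'   frame `term, rr, lo, hi`), `theta` (NB size; dispersion = 1/theta),
#'   `converged`, `note`, `model`.
#' @export
fit_nb_rate_model <- function(Y, n, svi, design = c("quartile", "continuous"),
                              year = NA, age_stratum = NA) {
  design <- match.arg(design)
  if (length(Y) < 20) stop("at least 20 counties are required")
  if (any(n <= 0)) stop("offsets (births) must be positive")
  if (length(unique(svi)) == 1L) stop("zero-variance design: SVI is constant")
  df <- data.frame(Y = as.integer(round(Y)), n = n)
  if (design == "quartile") {
    df$x <- factor(svi, levels = sort(unique(svi)))
    form <- Y ~ x + offset(log(n))
  } else {
    df$x <- as.numeric(svi)
    form <- Y ~ x + offset(log(n))
  }
  note <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      MASS::glm.nb(form, data = df, control = stats::glm.control(maxit = 100)),
      error = function(e) e
    ),
    warning = function(w) {
      note <<- c(note, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(fit, "error")) {
    # degenerate (under-dispersed / zero-variance) data break the theta
    # search; the NB likelihood then has its optimum at the Poisson limit
    nb_err <- conditionMessage(fit)
    fit <- tryCatch(
      stats::glm(form, data = df, family = stats::poisson()),
      error = function(e) e
    )
    if (inherits(fit, "error") || !fit$converged) {
      stop("negative binomial fit failed to converge: ", nb_err)
    }
    note <- c(note, paste0("theta search failed (", trimws(nb_err),
                           "); Poisson-limit fit reported"))
    fit$theta <- Inf
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  slope_terms <- setdiff(names(cf), "(Intercept)")
  rr <- data.frame(
    term = if (design == "quartile") {
      paste0("Q", levels(df$x)[-1], "_vs_Q", levels(df$x)[1])
    } else "per_unit_svi",
    rr = exp(cf[slope_terms]),
    lo = exp(cf[slope_terms] - 1.96 * se[slope_terms]),
    hi = exp(cf[slope_terms] + 1.96 * se[slope_terms]),
    row.names = NULL
  )
  structure(
    list(coefficients = cf, se = se, rate_ratios = rr,
         theta = fit$theta, dispersion = 1 / fit$theta,
         converged = fit$converged, note = note,
         year = year, age_stratum = age_stratum, design = design,
         model = fit),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("Negative binomial rate model (%s design%s%s)\n", x$design,
              if (!is.na(x$year)) paste0(", year ", x$year) else "",
              if (!is.na(x$age_stratum)) paste0(", ages ", x$age_stratum) else ""))
  print(transform(x$rate_ratios, rr = round(rr, 3), lo = round(lo, 3),
                  hi = round(hi, 3)))
  cat(sprintf("  theta = %.2f (dispersion %.4f)\n", x$theta, x$dispersion))
  invisible(x)
}

#' Quartile rate ratios by year from posterior rate summaries
#'
#' Convenience wrapper: for each requested year, assigns SVI quartiles with
#' the time-varying release map, forms county-level expected outcome counts
#' from the smoothed rates (pooling age groups: \eqn{\sum_k n_{ik}
#' \hat\lambda_{ik}/100}), and fits the quartile NB model.
#'
#' @param post A `posterior_rates` object.
#' @param panel The [count_panel].
#' @param svi An `svi_table`.
#' @param years Years to fit (default all panel years).
#' @return Data frame `year, term, rr, lo, hi`.
#' @export
svi_quartile_rate_ratios <- function(post, panel, svi, years = NULL) {
  years <- years %||% post$years
  out <- list()
  for (y in years) {
    s <- post$summary[post$summary$year == y, ]
    b <- panel$counts[panel$counts$year == y, ]
    m <- merge(s, b[, c("county_id", "age_group", "births")],
               by = c("county_id", "age_group"))
    m$expected <- m$births * m$post_median / 100
    agg <- stats::aggregate(cbind(expected, births) ~ county_id, data = m, sum)
    agg <- agg[agg$births > 0, ]
    q <- assign_svi_quartiles(svi, y, counties = agg$county_id)
    agg$quartile <- q[agg$county_id]
    fit <- fit_nb_rate_model(agg$expected, agg$births, agg$quartile,
                             design = "quartile", year = y)
    out[[as.character(y)]] <- data.frame(year = y, fit$rate_ratios)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Variance in county rates explained by SVI themes
#'
#' Ordinary least-squares regressions of the county age-standardized rate on
#' SVI: univariate models per theme (and the overall index), sequential
#' models adding themes in order, and the fully adjusted model.
#'
#' @param rates Data frame `county_id, rate` of age-standardized county rates
#'   for one year.
#' @param svi An `svi_table`.
#' @param year Analysis year (resolves the SVI release).
#' @return List with `univariate` (data frame `term, estimate, r_squared`),
#'   `sequential` (data frame `model, r_squared`), and `full` (coefficient
#'   table of the fully adjusted model). Collinear columns are dropped with a
#'   flag in `dropped`.
#' @export
ols_variance_explained <- function(rates, svi, year) {
  rel <- svi_release_for_year(svi, year)
  tab <- as.data.frame(svi)
  tab <- tab[tab$release_year == rel,
             c("county_id", "svi_overall", "theme1", "theme2", "theme3", "theme4")]
  m <- merge(rates, tab, by = "county_id")
  if (nrow(m) < 20) stop("at least 20 counties are required")
  themes <- c("svi_overall", "theme1", "theme2", "theme3", "theme4")
  uni <- do.call(rbind, lapply(themes, function(th) {
    f <- stats::lm(stats::reformulate(th, "rate"), data = m)
    data.frame(term = th, estimate = stats::coef(f)[2],
               r_squared = summary(f)$r.squared, row.names = NULL)
  }))
  seq_terms <- c("theme1", "theme2", "theme3", "theme4")
  dropped <- character(0)
  seqr <- do.call(rbind, lapply(seq_along(seq_terms), function(j) {
    f <- stats::lm(stats::reformulate(seq_terms[seq_len(j)], "rate"), data = m)
    data.frame(model = paste(seq_terms[seq_len(j)], collapse = " + "),
               r_squared = summary(f)$r.squared, row.names = NULL)
  }))
  full <- stats::lm(rate ~ theme1 + theme2 + theme3 + theme4, data = m)
  cf <- summary(full)$coefficients
  if (any(is.na(stats::coef(full)))) {
    dropped <- names(stats::coef(full))[is.na(stats::coef(full))]
    warning("collinear SVI columns dropped from the full model: ",
            paste(dropped, collapse = ", "))
  }
  list(univariate = uni, sequential = seqr,
       full = data.frame(term = rownames(cf), cf, row.names = NULL,
                         check.names = FALSE),
       full_r_squared = summary(full)$r.squared,
       dropped = dropped, n = nrow(m))
}

#' SVI profile of counties in the tails of the rate distribution
#'
#' Identifies counties at or below the 10th and at or above the 90th
#' percentile of the age-standardized rate and reports the median SVI
#' percentile (overall and per theme) within each group. Under independence
#' of SVI and rates both group medians sit near 0.5.
#'
#' @param rates Data frame `county_id, rate` (reliability-filtered).
#' @param svi An `svi_table`.
#' @param year Analysis year.
#' @return Data frame with one row per SVI measure and columns for each
#'   group's size and median percentile.
#' @export
profile_extreme_counties <- function(rates, svi, year) {
  rates <- rates[!is.na(rates$rate), ]
  q <- stats::quantile(rates$rate, c(0.10, 0.90), type = 7, names = FALSE)
  low_ids <- rates$county_id[rates$rate <= q[1]]
  high_ids <- rates$county_id[rates$rate >= q[2]]
  if (!length(low_ids) || !length(high_ids)) stop("empty extreme group")
  rel <- svi_release_for_year(svi, year)
  tab <- as.data.frame(svi)
  tab <- tab[tab$release_year == rel, ]
  measures <- c("svi_overall", "theme1", "theme2", "theme3", "theme4")
  med <- function(ids, mcol) stats::median(tab[[mcol]][tab$county_id %in% ids])
  data.frame(
    measure = measures,
    n_low = length(low_ids), n_high = length(high_ids),
    median_pct_low = vapply(measures, med, numeric(1), ids = low_ids),
    median_pct_high = vapply(measures, med, numeric(1), ids = high_ids),
    row.names = NULL
  )
}
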