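#' Bayesian space-time-age smoothing of county birth outcome rates
#'
#' [fit_bym_st()] fits a Besag-York-Mollie (BYM) convolution model extended
#' with age and time structure to a county x age x year count panel by
#' Metropolis-within-Gibbs MCMC, and returns posterior summaries and draws of
#' the cell rates per 100 live births.
#'
#' @name bym_estimator
NULL

#' MCMC settings for the BYM space-time-age sampler
#'
#' @param n_iter Total iterations.
#' @param burnin Burn-in iterations discarded (adaptation of Metropolis step
#'   sizes happens only here).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed RNG seed; the fit is deterministic given it.
#' @param prior_shape,prior_rate Gamma hyperprior on each random-effect
#'   precision. The default Gamma(0.5, 0.0005) is a conventional
#'   weakly-informative disease-mapping choice.
#' @param fixed_precisions Optional named list (`u`, `v`, `delta`, `phi`)
#'   fixing a block's precision instead of sampling it; useful for collapsing
#'   the model (very large values switch a block off).
#' @param target_accept Target acceptance rate for scalar Metropolis updates.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 5000L, burnin = 2500L, thin = 5L,
                          seed = 42L, prior_shape = 0.5, prior_rate = 0.0005,
                          fixed_precisions = NULL, target_accept = 0.44) {
  stopifnot(n_iter > burnin, burnin >= 0, thin >= 1,
            prior_shape > 0, prior_rate > 0)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_shape = prior_shape, prior_rate = prior_rate,
                 fixed_precisions = fixed_precisions,
                 target_accept = target_accept),
            class = "mcmc_settings")
}

#' Fit the BYM space-time-age model to a count panel
#'
#' The likelihood is Poisson with a log offset for total births:
#' \deqn{Y_{ikt} \sim \mathrm{Poisson}(n_{ikt}\,\lambda_{ikt}/100), \quad
#'  \log(\lambda_{ikt}/100) = \alpha_k + u_i + v_i + \delta_{ik} + \phi_{it}}
#' with \eqn{u} an intrinsic CAR (ICAR) field over the county adjacency
#' graph, \eqn{v} iid normal county heterogeneity (together the BYM
#' convolution), \eqn{\delta} an ICAR-in-space field per age group carrying
#' space-age interaction, and \eqn{\phi} a first-order random walk in time
#' per county carrying county-specific temporal trends. Age intercepts
#' \eqn{\alpha_k} have flat priors; precisions have conjugate gamma
#' hyperpriors sampled by Gibbs; all log-linear effects are updated by
#' adaptive single-site Metropolis, vectorised over a proper colouring of the
#' county graph so that simultaneous updates never touch two neighbours.
#' Sum-to-zero identifiability constraints are enforced by recentering after
#' each block sweep (per connected component for the ICAR fields, per county
#' for the random walk), with level shifts absorbed into the exchangeable
#' county effect or the age intercepts where the likelihood permits.
#'
#' Counties whose births are zero in every cell carry no information and an
#' undefined offset; they are dropped with a warning before fitting.
#'
#' @param panel A [count_panel].
#' @param structure An [adjacency] covering the panel's counties.
#' @param outcome Outcome column to model (`"preterm"` or `"early_preterm"`).
#' @param mcmc An [mcmc_settings] object.
#' @param verbose Print progress every 1000 iterations.
#' @return An object of class `posterior_rates`: `summary` (data frame
#'   `county_id, age_group, year, outcome, post_median, ci_lo, ci_hi`),
#'   `draws` (n_saved x n_cells matrix of rates per 100, columns in the row
#'   order of `summary`), index vectors, acceptance diagnostics, precision
#'   draws, and the settings used.
#' @export
fit_bym_st <- function(panel, structure, outcome = "preterm",
                       mcmc = mcmc_settings(), verbose = FALSE) {
  stopifnot(inherits(panel, "count_panel"), inherits(structure, "adjacency"))
  if (!setequal(panel$county_ids, structure$county_ids)) {
    stop("panel and adjacency structure must cover the same county set")
  }
  arr <- panel_arrays(panel, outcome)
  births_by_county <- apply(arr$n, 1, sum)
  dropped <- panel$county_ids[births_by_county == 0]
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " county(ies) with zero births in all cells: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    keep <- panel$county_ids[births_by_county > 0]
    arr$Y <- arr$Y[match(keep, panel$county_ids), , , drop = FALSE]
    arr$n <- arr$n[match(keep, panel$county_ids), , , drop = FALSE]
    structure <- subset_adjacency(structure, keep)
    ids <- keep
  } else {
    ids <- panel$county_ids
  }

  I <- dim(arr$Y)[1]; K <- dim(arr$Y)[2]; T <- dim(arr$Y)[3]
  # I x (K*T) matrices, column c = (t-1)*K + k  (age fastest)
  Ym <- matrix(arr$Y, I, K * T)
  Nm <- matrix(arr$n, I, K * T)
  kidx <- rep(seq_len(K), T)
  tidx <- rep(seq_len(T), each = K)
  cols_age <- lapply(seq_len(K), function(k) which(kidx == k))
  cols_year <- lapply(seq_len(T), function(t) which(tidx == t))

  rsY <- rowSums(Ym)
  rsYk <- vapply(cols_age, function(ck) rowSums(Ym[, ck, drop = FALSE]), numeric(I))
  rsYt <- vapply(cols_year, function(ct) rowSums(Ym[, ct, drop = FALSE]), numeric(I))
  rsYk <- matrix(rsYk, I, K); rsYt <- matrix(rsYt, I, T)
  csYk <- vapply(cols_age, function(ck) sum(Ym[, ck]), numeric(1))
  csNk <- vapply(cols_age, function(ck) sum(Nm[, ck]), numeric(1))

  W <- adjacency_matrix(structure)
  deg <- structure$n_neighbors
  ncomp <- structure$n_components
  comps <- split(seq_len(I), structure$component)
  edge_a <- structure$edges[, 1]; edge_b <- structure$edges[, 2]
  colr <- graph_coloring(structure)
  color_sets <- split(seq_len(I), colr)

  set.seed(mcmc$seed)
  a0 <- mcmc$prior_shape; b0 <- mcmc$prior_rate
  fixed <- mcmc$fixed_precisions %||% list()

  # state
  alpha <- log(pmax(csYk, 0.5) / pmax(csNk, 1))
  u <- numeric(I); v <- numeric(I)
  delta <- matrix(0, I, K); phi <- matrix(0, I, T)
  tau <- list(u = fixed$u %||% 10, v = fixed$v %||% 10,
              delta = fixed$delta %||% 10, phi = fixed$phi %||% 10)

  eta_matrix <- function() {
    E <- delta[, kidx, drop = FALSE] + phi[, tidx, drop = FALSE] + (u + v)
    sweep(E, 2, alpha[kidx], "+")
  }
  Mu <- Nm * exp(eta_matrix())

  # adaptive step sizes and acceptance counters
  s_alpha <- rep(0.05, K); s_u <- rep(0.1, I); s_v <- rep(0.1, I)
  s_delta <- matrix(0.1, I, K); s_phi <- matrix(0.1, I, T)
  acc_alpha <- numeric(K); acc_u <- numeric(I); acc_v <- numeric(I)
  acc_delta <- matrix(0, I, K); acc_phi <- matrix(0, I, T)
  n_att <- 0L
  tacc <- mcmc$target_accept
  adapt_batch <- 50L

  n_saved <- (mcmc$n_iter - mcmc$burnin) %/% mcmc$thin
  draws <- matrix(NA_real_, n_saved, I * K * T)
  tau_draws <- matrix(NA_real_, n_saved, 4,
                      dimnames = list(NULL, c("tau_u", "tau_v", "tau_delta", "tau_phi")))
  save_row <- 0L
  acc_total <- list(alpha = numeric(K), u = numeric(I), v = numeric(I),
                    delta = matrix(0, I, K), phi = matrix(0, I, T))
  n_total <- 0L

  has_edges <- length(edge_a) > 0

  for (iter in seq_len(mcmc$n_iter)) {
    ## -- age intercepts (flat prior) -----------------------------------
    for (k in seq_len(K)) {
      d <- stats::rnorm(1, 0, s_alpha[k])
      ck <- cols_age[[k]]
      dll <- d * csYk[k] - (exp(d) - 1) * sum(Mu[, ck])
      if (log(stats::runif(1)) < dll) {
        alpha[k] <- alpha[k] + d
        Mu[, ck] <- Mu[, ck] * exp(d)
        acc_alpha[k] <- acc_alpha[k] + 1
        acc_total$alpha[k] <- acc_total$alpha[k] + 1
      }
    }

    ## -- structured spatial effect u (ICAR) ----------------------------
    for (S in color_sets) {
      d <- stats::rnorm(length(S), 0, s_u[S])
      rmu <- rowSums(Mu[S, , drop = FALSE])
      dll <- d * rsY[S] - (exp(d) - 1) * rmu
      if (has_edges) {
        sumne <- as.numeric(W %*% u)[S]
        dlp <- -0.5 * tau$u * (d^2 * deg[S] + 2 * d * (deg[S] * u[S] - sumne))
      } else dlp <- 0
      acc <- log(stats::runif(length(S))) < dll + dlp
      if (any(acc)) {
        rows <- S[acc]
        u[rows] <- u[rows] + d[acc]
        Mu[rows, ] <- Mu[rows, , drop = FALSE] * exp(d[acc])
        acc_u[rows] <- acc_u[rows] + 1
        acc_total$u[rows] <- acc_total$u[rows] + 1
      }
    }
    # sum-to-zero per component; level shift absorbed by the exchangeable
    # effect so the linear predictor is unchanged
    for (cc in comps) {
      m <- mean(u[cc]); u[cc] <- u[cc] - m; v[cc] <- v[cc] + m
    }

    ## -- unstructured county effect v ----------------------------------
    d <- stats::rnorm(I, 0, s_v)
    rmu <- rowSums(Mu)
    dll <- d * rsY - (exp(d) - 1) * rmu
    dlp <- -0.5 * tau$v * ((v + d)^2 - v^2)
    acc <- log(stats::runif(I)) < dll + dlp
    if (any(acc)) {
      rows <- which(acc)
      v[rows] <- v[rows] + d[rows]
      Mu[rows, ] <- Mu[rows, , drop = FALSE] * exp(d[rows])
      acc_v[rows] <- acc_v[rows] + 1
      acc_total$v[rows] <- acc_total$v[rows] + 1
    }

    ## -- county-age interaction delta (ICAR in space per age) ----------
    for (k in seq_len(K)) {
      ck <- cols_age[[k]]
      for (S in color_sets) {
        d <- stats::rnorm(length(S), 0, s_delta[S, k])
        rmu <- rowSums(Mu[S, ck, drop = FALSE])
        dll <- d * rsYk[S, k] - (exp(d) - 1) * rmu
        if (has_edges) {
          sumne <- as.numeric(W %*% delta[, k])[S]
          dlp <- -0.5 * tau$delta *
            (d^2 * deg[S] + 2 * d * (deg[S] * delta[S, k] - sumne))
        } else dlp <- 0
        acc <- log(stats::runif(length(S))) < dll + dlp
        if (any(acc)) {
          rows <- S[acc]
          delta[rows, k] <- delta[rows, k] + d[acc]
          Mu[rows, ck] <- Mu[rows, ck, drop = FALSE] * exp(d[acc])
          acc_delta[rows, k] <- acc_delta[rows, k] + 1
          acc_total$delta[rows, k] <- acc_total$delta[rows, k] + 1
        }
      }
      if (ncomp == 1L) {
        # component mean is a county-constant: absorb into the age intercept,
        # linear predictor unchanged
        m <- mean(delta[, k])
        delta[, k] <- delta[, k] - m
        alpha[k] <- alpha[k] + m
      } else {
        for (cc in comps) {
          m <- mean(delta[cc, k])
          if (m != 0) {
            delta[cc, k] <- delta[cc, k] - m
            Mu[cc, ck] <- Mu[cc, ck, drop = FALSE] * exp(-m)
          }
        }
      }
    }

    ## -- county temporal random walk phi (RW1) -------------------------
    if (T >= 2L) {
      for (par in 0:1) {
        for (t in which(seq_len(T) %% 2L == par)) {
          ct <- cols_year[[t]]
          d <- stats::rnorm(I, 0, s_phi[, t])
          rmu <- rowSums(Mu[, ct, drop = FALSE])
          dll <- d * rsYt[, t] - (exp(d) - 1) * rmu
          nt <- (t > 1L) + (t < T)
          sumne <- (if (t > 1L) phi[, t - 1L] else 0) +
                   (if (t < T) phi[, t + 1L] else 0)
          dlp <- -0.5 * tau$phi * (d^2 * nt + 2 * d * (nt * phi[, t] - sumne))
          acc <- log(stats::runif(I)) < dll + dlp
          if (any(acc)) {
            rows <- which(acc)
            phi[rows, t] <- phi[rows, t] + d[rows]
            Mu[rows, ct] <- Mu[rows, ct, drop = FALSE] * exp(d[rows])
            acc_phi[rows, t] <- acc_phi[rows, t] + 1
            acc_total$phi[rows, t] <- acc_total$phi[rows, t] + 1
          }
        }
      }
      # per-county sum-to-zero over time; county level goes to v
      m <- rowMeans(phi)
      phi <- phi - m
      v <- v + m
    }

    ## -- precisions (conjugate Gibbs) ----------------------------------
    if (is.null(fixed$u) && has_edges) {
      qf <- sum((u[edge_a] - u[edge_b])^2)
      tau$u <- stats::rgamma(1, a0 + 0.5 * (I - ncomp), b0 + 0.5 * qf)
    }
    if (is.null(fixed$v)) {
      tau$v <- stats::rgamma(1, a0 + 0.5 * I, b0 + 0.5 * sum(v^2))
    }
    if (is.null(fixed$delta) && has_edges) {
      qf <- sum((delta[edge_a, , drop = FALSE] - delta[edge_b, , drop = FALSE])^2)
      tau$delta <- stats::rgamma(1, a0 + 0.5 * K * (I - ncomp), b0 + 0.5 * qf)
    }
    if (is.null(fixed$phi) && T >= 2L) {
      qf <- sum((phi[, -1L, drop = FALSE] - phi[, -T, drop = FALSE])^2)
      tau$phi <- stats::rgamma(1, a0 + 0.5 * I * (T - 1L), b0 + 0.5 * qf)
    }

    ## -- step-size adaptation during burn-in ---------------------------
    n_att <- n_att + 1L
    n_total <- n_total + 1L
    if (iter <= mcmc$burnin && n_att == adapt_batch) {
      tune <- function(s, acc) {
        pmin(pmax(s * exp((acc / adapt_batch - tacc)), 1e-4), 5)
      }
      s_alpha <- tune(s_alpha, acc_alpha); acc_alpha[] <- 0
      s_u <- tune(s_u, acc_u); acc_u[] <- 0
      s_v <- tune(s_v, acc_v); acc_v[] <- 0
      s_delta <- tune(s_delta, acc_delta); acc_delta[] <- 0
      s_phi <- tune(s_phi, acc_phi); acc_phi[] <- 0
      n_att <- 0L
    }
    if (iter %% 250L == 0L) Mu <- Nm * exp(eta_matrix()) # numerical hygiene

    ## -- save ----------------------------------------------------------
    if (iter > mcmc$burnin && (iter - mcmc$burnin) %% mcmc$thin == 0L) {
      save_row <- save_row + 1L
      draws[save_row, ] <- as.vector(100 * exp(eta_matrix()))
      tau_draws[save_row, ] <- c(tau$u, tau$v, tau$delta, tau$phi)
    }
    if (verbose && iter %% 1000L == 0L) {
      message("iteration ", iter, "/", mcmc$n_iter)
    }
  }

  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  grid <- expand.grid(county_id = ids, age_group = panel$age_groups,
                      year = panel$years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  summary_df <- data.frame(
    grid, outcome = outcome,
    post_median = qs[2, ], ci_lo = qs[1, ], ci_hi = qs[3, ],
    stringsAsFactors = FALSE
  )
  structure(
    list(summary = summary_df, draws = draws,
         county_ids = ids, age_groups = panel$age_groups, years = panel$years,
         outcome = outcome, dropped_counties = dropped,
         tau_draws = tau_draws,
         acceptance = lapply(acc_total, function(x) x / n_total),
         settings = mcmc),
    class = "posterior_rates"
  )
}

#' @export
print.posterior_rates <- function(x, ...) {
  cat(sprintf(
    "Posterior rates (%s): %d counties x %d ages x %d years, %d saved draws\n",
    x$outcome, length(x$county_ids), length(x$age_groups), length(x$years),
    nrow(x$draws)
  ))
  cat(sprintf("  posterior median rate range: %.2f - %.2f per 100\n",
              min(x$summary$post_median), max(x$summary$post_median)))
  if (length(x$dropped_counties)) {
    cat("  dropped (no births):", length(x$dropped_counties), "counties\n")
  }
  invisible(x)
}

#' Reliability flags for mapped county estimates
#'
#' A county's smoothed estimate is treated as reliable when, in every year of
#' the study period, (i) the 95% credible interval of its age-standardized
#' rate is narrower than the point estimate itself and (ii) the county
#' recorded at least `min_births` total births.
#'
#' @param post A `posterior_rates` object, or a data frame of county-year
#'   summaries with columns `county_id, year, rate, lo, hi` (e.g. from
#'   [standardize_posterior()]).
#' @param panel The [count_panel] supplying annual birth totals.
#' @param min_births Minimum annual births (default 100).
#' @param weights Reference weights used to age-standardize when `post` is a
#'   `posterior_rates`; defaults to the panel's first-year distribution.
#' @return Data frame `county_id, reliable, cri_ok, births_ok` with one row
#'   per county, plus a `per_year` attribute holding the county-year flags.
#' @export
reliability_flags <- function(post, panel, min_births = 100,
                              weights = NULL) {
  if (inherits(post, "posterior_rates")) {
    if (is.null(weights)) weights <- reference_weights(panel, min(panel$years))
    std <- standardize_posterior(post, weights)
  } else {
    std <- post
    stopifnot(all(c("county_id", "year", "rate", "lo", "hi") %in% names(std)))
  }
  births <- stats::aggregate(births ~ county_id + year, data = panel$counts, sum)
  m <- merge(std, births, by = c("county_id", "year"), all.x = TRUE)
  m$births[is.na(m$births)] <- 0
  m$cri_ok <- (m$hi - m$lo) < m$rate
  m$births_ok <- m$births >= min_births
  agg <- function(f) tapply(f, m$county_id, all)
  cri <- agg(m$cri_ok); births_ok <- agg(m$births_ok)
  out <- data.frame(county_id = names(cri),
                    reliable = as.logical(cri & births_ok),
                    cri_ok = as.logical(cri),
                    births_ok = as.logical(births_ok),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_year") <- m
  out
}

#' Write posterior rate summaries to the standard delimited file
#'
#' Columns: `county_id, age_group, year, outcome, post_median, ci_lo, ci_hi`.
#' @param post A `posterior_rates` object.
#' @param path Output path.
#' @export
write_rate_summaries <- function(post, path) {
  utils::write.csv(post$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
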