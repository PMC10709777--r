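#' Pipeline orchestration: simulate, fit, standardize, associate, trends,
#' aggregate
#'
#' A single configuration drives the whole analysis end to end with
#' reproducible seeds. Each stage reads only the serialized outputs of the
#' previous stage from the run directory, so any stage can be re-run in
#' isolation, and a manifest records input/output hashes per stage as the
#' audit trail.
#'
#' @name pipeline_cli
NULL

#' Build and validate a pipeline configuration
#'
#' @param x Path to a YAML configuration file, or a named list with the same
#'   structure. Top-level keys: `seed`, `outcome` (`"preterm"` or
#'   `"early_preterm"`), `reference_year`, `output_dir`, `bootstrap_B`,
#'   exactly one of `synthetic` (arguments for [synthetic_config()]) or
#'   `inputs` (paths `panel`, `adjacency`, `svi`, `membership`), optional
#'   `mcmc` (arguments for [mcmc_settings()]) and `filters` (`min_births`,
#'   `age_specific_min`, `nulliparous_singleton`).
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("configuration must be a YAML file or a list")
  has_syn <- !is.null(cfg$synthetic)
  has_inp <- !is.null(cfg$inputs)
  if (has_syn == has_inp) {
    stop("configuration must contain exactly one of 'synthetic' or 'inputs'")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outcome <- cfg$outcome %||% "preterm"
  if (!cfg$outcome %in% c("preterm", "early_preterm")) {
    stop("outcome must be 'preterm' or 'early_preterm' (field: outcome)")
  }
  cfg$bootstrap_B <- as.integer(cfg$bootstrap_B %||% 1000L)
  f <- cfg$filters %||% list()
  f$min_births <- f$min_births %||% 100
  f$age_specific_min <- f$age_specific_min %||% 0
  f$nulliparous_singleton <- isTRUE(f$nulliparous_singleton)
  if (f$min_births < 0 || f$age_specific_min < 0) {
    stop("filter thresholds must be non-negative")
  }
  cfg$filters <- f
  if (has_syn) {
    syn <- cfg$synthetic
    if (!is.null(syn$years) && length(syn$years) == 2L &&
        diff(unlist(syn$years)) > 1) {
      syn$years <- seq(syn$years[[1]], syn$years[[2]])
    }
    syn$seed <- syn$seed %||% cfg$seed
    cfg$synthetic <- do.call(synthetic_config, syn)
    cfg$years <- cfg$synthetic$years
  } else {
    need <- c("panel", "adjacency")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss)) {
      stop("missing required input path(s): ", paste(miss, collapse = ", "))
    }
  }
  cfg$reference_year <- as.integer(cfg$reference_year %||%
                                     (if (has_syn) min(cfg$years) else NA))
  mc <- cfg$mcmc %||% list()
  mc$seed <- mc$seed %||% (cfg$seed + 100L)
  cfg$mcmc <- do.call(mcmc_settings, mc)
  if (is.null(cfg$output_dir)) stop("output_dir is required")
  structure(cfg, class = "pipeline_config")
}

#' Validate a panel file against the tabulation schema
#'
#' Checks the header, the six allowed 5-year maternal age groups (births to
#' individuals under 15 or 45 and over are excluded from the tabulation),
#' outcome counts not exceeding births, non-negative counts, and duplicate
#' (county, age group, year) keys.
#'
#' @param x Path to a panel file or a data frame.
#' @return Data frame `violation, detail, n_rows`; zero rows when the panel
#'   is well formed.
#' @export
validate_panel <- function(x) {
  df <- if (is.character(x)) {
    utils::read.csv(x, colClasses = c(county_id = "character"))
  } else x
  v <- list()
  add <- function(violation, detail, n) {
    v[[length(v) + 1L]] <<- data.frame(violation = violation, detail = detail,
                                       n_rows = n)
  }
  need <- c("county_id", "age_group", "year", "births")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    add("missing columns", paste(miss, collapse = ", "), NA_integer_)
    return(do.call(rbind, v))
  }
  bad_age <- !df$age_group %in% AGE_GROUPS_STANDARD
  if (any(bad_age)) {
    add("age group outside 15-44",
        paste(unique(df$age_group[bad_age]), collapse = ", "), sum(bad_age))
  }
  key <- paste(df$county_id, df$age_group, df$year)
  if (anyDuplicated(key)) {
    add("duplicate (county, age_group, year) keys",
        paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
        sum(duplicated(key)))
  }
  for (oc in intersect(c("preterm", "early_preterm"), names(df))) {
    bad <- df[[oc]] > df$births
    if (any(bad)) add(paste0(oc, " exceeds births"), "outcome > denominator", sum(bad))
    if (any(df[[oc]] < 0)) add(paste0("negative ", oc), "", sum(df[[oc]] < 0))
  }
  if (any(df$births < 0)) add("negative births", "", sum(df$births < 0))
  if (length(v)) do.call(rbind, v) else {
    data.frame(violation = character(0), detail = character(0),
               n_rows = integer(0))
  }
}

#' Counties with enough births for age-specific reporting
#'
#' Flags counties with more than `min_births` births in every age group and
#' year, the condition for reporting age-specific rates.
#'
#' @param panel A [count_panel].
#' @param min_births Threshold per age-year cell (default 100).
#' @return Named logical vector per county.
#' @export
age_specific_reliable <- function(panel, min_births = 100) {
  arr <- panel_arrays(panel, panel$outcomes[1])
  ok <- apply(arr$n > min_births, 1, all)
  stats::setNames(ok, panel$county_ids)
}

#' Synthetic state / region membership for a lattice panel
#'
#' Splits the lattice into contiguous blocks of rows ("states") and marks a
#' central block of each state as its metro region (CSA stand-in); remaining
#' counties are left unassigned so the residual rest-of-state pooling is
#' exercised.
#'
#' @param config A `synthetic_config`.
#' @param n_states Number of row-block states.
#' @return Data frame `county_id, state_id, region_id` (`region_id` NA for
#'   non-metro counties).
#' @export
synthetic_membership <- function(config, n_states = 4L) {
  I <- config$n_rows * config$n_cols
  ids <- sprintf("%05d", seq_len(I))
  row_of <- (seq_len(I) - 1L) %/% config$n_cols + 1L
  col_of <- (seq_len(I) - 1L) %% config$n_cols + 1L
  n_states <- max(1L, min(n_states, config$n_rows))
  state <- paste0("S", pmin((row_of - 1L) %/% ceiling(config$n_rows / n_states) + 1L,
                            n_states))
  # central columns of each state form its metro region
  lo <- ceiling(config$n_cols / 3); hi <- config$n_cols - lo + 1L
  metro <- col_of >= lo & col_of <= hi
  region <- ifelse(metro, paste0(state, "_metro"), NA_character_)
  data.frame(county_id = ids, state_id = state, region_id = region,
             stringsAsFactors = FALSE)
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  paste(basename(paths), unname(h), sep = ":", collapse = ";")
}

apply_input_filters <- function(panel_df, filters) {
  if (isTRUE(filters$nulliparous_singleton)) {
    ns_cols <- c("births_ns", "preterm_ns", "early_preterm_ns")
    have <- intersect(ns_cols, names(panel_df))
    if (length(have) < 2) {
      stop("nulliparous_singleton filter requested but the panel carries no ",
           "parity/plurality columns (births_ns, preterm_ns, early_preterm_ns)")
    }
    panel_df$births <- panel_df$births_ns
    if ("preterm_ns" %in% have) panel_df$preterm <- panel_df$preterm_ns
    if ("early_preterm_ns" %in% have) panel_df$early_preterm <- panel_df$early_preterm_ns
  }
  panel_df
}

#' Run the full small-area analysis pipeline
#'
#' Executes, in order: `simulate` (or input loading), `fit`, `standardize`,
#' `associate`, `trends`, `aggregate`. Every tabular output is delimited text
#' with a header in the run directory; `manifest.csv` lists, per stage, the
#' input and output file hashes (deterministic given the seed) and wall time.
#'
#' @param config A `pipeline_config` (or something [pipeline_config()]
#'   accepts).
#' @param stages Subset of stages to run (default all, in order). Later
#'   stages read the serialized outputs of earlier ones from the run
#'   directory.
#' @return Invisibly, the run directory path. The manifest is also returned
#'   as the attribute `"manifest"`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit", "standardize",
                                    "associate", "trends", "aggregate")) {
  config <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(strip_config(config), cfg_path)
  manifest <- list()
  note <- function(stage, inputs, outputs, secs) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage,
      config_hash = unname(tools::md5sum(cfg_path)),
      seed = config$seed,
      input_hash = if (length(inputs)) hash_files(inputs) else "",
      output_hash = if (length(outputs)) hash_files(outputs) else "",
      wall_seconds = round(secs, 3)
    )
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    note(name, res$inputs, res$outputs, proc.time()[["elapsed"]] - t0)
    message(sprintf("stage %-12s ok  (%d output file(s))", name,
                    length(res$outputs)))
  }
  for (st in stages) {
    fn <- switch(st,
                 simulate = function() stage_simulate(config, dir),
                 fit = function() stage_fit(config, dir),
                 standardize = function() stage_standardize(config, dir),
                 associate = function() stage_associate(config, dir),
                 trends = function() stage_trends(config, dir),
                 aggregate = function() stage_aggregate(config, dir),
                 stop("unknown stage: ", st))
    run_stage(st, fn)
  }
  mf <- do.call(rbind, manifest)
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  out <- dir
  attr(out, "manifest") <- mf
  invisible(out)
}

# canonical parameter record for hashing: local paths are excluded so the
# config hash identifies the scientific run, not where it was written
# (input file contents are hashed separately in the manifest)
strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  cfg$mcmc <- unclass(cfg$mcmc)
  cfg$output_dir <- NULL
  cfg$inputs <- NULL
  cfg[!vapply(cfg, is.null, logical(1))]
}

stage_simulate <- function(config, dir) {
  if (!is.null(config$synthetic)) {
    sim <- generate_panel(config$synthetic)
    svi <- generate_svi(config$synthetic, sim$truth)
    mem <- synthetic_membership(config$synthetic)
    p_panel <- file.path(dir, "panel.csv")
    p_adj <- file.path(dir, "adjacency.csv")
    p_svi <- file.path(dir, "svi.csv")
    p_mem <- file.path(dir, "membership.csv")
    p_truth <- file.path(dir, "truth_rates.csv")
    write_panel(sim$panel, p_panel)
    write_adjacency(sim$structure, p_adj)
    write_svi(svi, p_svi)
    utils::write.csv(mem, p_mem, row.names = FALSE, quote = FALSE)
    tr <- sim$truth$true_rate
    truth_df <- data.frame(expand.grid(county_id = dimnames(tr)[[1]],
                                       age_group = dimnames(tr)[[2]],
                                       year = as.integer(dimnames(tr)[[3]]),
                                       KEEP.OUT.ATTRS = FALSE,
                                       stringsAsFactors = FALSE),
                           true_rate = as.vector(tr))
    utils::write.csv(truth_df, p_truth, row.names = FALSE, quote = FALSE)
    list(inputs = character(0),
         outputs = c(p_panel, p_adj, p_svi, p_mem, p_truth))
  } else {
    inp <- unlist(config$inputs)
    df <- utils::read.csv(config$inputs$panel,
                          colClasses = c(county_id = "character"))
    viol <- validate_panel(df)
    if (nrow(viol)) {
      stop("panel validation failed: ",
           paste(viol$violation, collapse = "; "))
    }
    df <- apply_input_filters(df, config$filters)
    panel <- count_panel(df)
    write_panel(panel, file.path(dir, "panel.csv"))
    file.copy(config$inputs$adjacency, file.path(dir, "adjacency.csv"),
              overwrite = TRUE)
    outs <- c(file.path(dir, "panel.csv"), file.path(dir, "adjacency.csv"))
    for (nm in c("svi", "membership")) {
      if (!is.null(config$inputs[[nm]])) {
        file.copy(config$inputs[[nm]], file.path(dir, paste0(nm, ".csv")),
                  overwrite = TRUE)
        outs <- c(outs, file.path(dir, paste0(nm, ".csv")))
      }
    }
    list(inputs = inp, outputs = outs)
  }
}

stage_fit <- function(config, dir) {
  p_panel <- file.path(dir, "panel.csv")
  p_adj <- file.path(dir, "adjacency.csv")
  panel <- read_panel(p_panel)
  adj <- load_adjacency(p_adj, panel$county_ids)
  post <- fit_bym_st(panel, adj, outcome = config$outcome, mcmc = config$mcmc)
  p_sum <- file.path(dir, "rates_summary.csv")
  write_rate_summaries(post, p_sum)
  saveRDS(post, file.path(dir, "posterior.rds"))
  list(inputs = c(p_panel, p_adj), outputs = p_sum)
}

stage_standardize <- function(config, dir) {
  panel <- read_panel(file.path(dir, "panel.csv"))
  post <- readRDS(file.path(dir, "posterior.rds"))
  w <- reference_weights(panel, config$reference_year)
  std <- standardize_posterior(post, w)
  rel <- reliability_flags(std, panel, min_births = config$filters$min_births)
  n_rel <- sum(rel$reliable)
  message(sprintf("  reliability filter: %d of %d counties retained",
                  n_rel, nrow(rel)))
  p_std <- file.path(dir, "standardized_rates.csv")
  p_rel <- file.path(dir, "reliability.csv")
  p_disp <- file.path(dir, "disparity.csv")
  utils::write.csv(std, p_std, row.names = FALSE, quote = FALSE)
  utils::write.csv(rel, p_rel, row.names = FALSE, quote = FALSE)
  keep <- rel$county_id[rel$reliable]
  disp <- list()
  for (y in post$years) {
    ry <- std$rate[std$year == y & std$county_id %in% keep]
    if (length(ry) >= 10) {
      row <- disparity_summary(ry, year = y)
      ci <- bootstrap_gap_ci(ry, B = config$bootstrap_B,
                             seed = config$seed + y)
      row$gap_ci_lo <- ci$lo[1]; row$gap_ci_hi <- ci$hi[1]
      row$ratio_ci_lo <- ci$lo[2]; row$ratio_ci_hi <- ci$hi[2]
      disp[[as.character(y)]] <- row
    }
  }
  utils::write.csv(do.call(rbind, disp), p_disp, row.names = FALSE, quote = FALSE)
  list(inputs = file.path(dir, c("panel.csv", "rates_summary.csv")),
       outputs = c(p_std, p_rel, p_disp))
}

stage_associate <- function(config, dir) {
  p_svi <- file.path(dir, "svi.csv")
  if (!file.exists(p_svi)) {
    stop("association requested but no SVI table is available (field: inputs$svi)")
  }
  panel <- read_panel(file.path(dir, "panel.csv"))
  post <- readRDS(file.path(dir, "posterior.rds"))
  svi <- read_svi(p_svi, years = panel$years)
  std <- utils::read.csv(file.path(dir, "standardized_rates.csv"),
                         colClasses = c(county_id = "character"))
  rel <- utils::read.csv(file.path(dir, "reliability.csv"),
                         colClasses = c(county_id = "character"))
  keep <- rel$county_id[rel$reliable]
  rr <- svi_quartile_rate_ratios(post, panel, svi)
  last <- max(panel$years)
  rates_last <- std[std$year == last & std$county_id %in% keep,
                    c("county_id", "rate")]
  r2 <- ols_variance_explained(rates_last, svi, last)
  prof <- profile_extreme_counties(rates_last, svi, last)
  p_rr <- file.path(dir, "rate_ratios.csv")
  p_r2 <- file.path(dir, "r_squared.csv")
  p_prof <- file.path(dir, "svi_extremes.csv")
  utils::write.csv(rr, p_rr, row.names = FALSE, quote = FALSE)
  utils::write.csv(r2$univariate, p_r2, row.names = FALSE, quote = FALSE)
  utils::write.csv(prof, p_prof, row.names = FALSE, quote = FALSE)
  list(inputs = file.path(dir, c("panel.csv", "svi.csv", "standardized_rates.csv")),
       outputs = c(p_rr, p_r2, p_prof))
}

stage_trends <- function(config, dir) {
  std <- utils::read.csv(file.path(dir, "standardized_rates.csv"),
                         colClasses = c(county_id = "character"))
  rel <- utils::read.csv(file.path(dir, "reliability.csv"),
                         colClasses = c(county_id = "character"))
  keep <- rel$county_id[rel$reliable]
  message(sprintf("  trend stage: %d reliable counties of %d",
                  length(keep), nrow(rel)))
  fits <- fit_county_trends(std[std$county_id %in% keep, ])
  cls <- classify_counties(fits)
  p_fit <- file.path(dir, "county_trends.csv")
  p_cls <- file.path(dir, "trend_classes.csv")
  p_sum <- file.path(dir, "classification_summary.csv")
  utils::write.csv(fits, p_fit, row.names = FALSE, quote = FALSE)
  write_trend_classification(fits, p_cls)
  utils::write.csv(cls, p_sum, row.names = FALSE, quote = FALSE)
  list(inputs = file.path(dir, c("standardized_rates.csv", "reliability.csv")),
       outputs = c(p_fit, p_cls, p_sum))
}

stage_aggregate <- function(config, dir) {
  panel <- read_panel(file.path(dir, "panel.csv"))
  w <- reference_weights(panel, config$reference_year)
  p_mem <- file.path(dir, "membership.csv")
  units <- list(national = aggregate_crude(panel, level = "national"))
  inputs <- file.path(dir, "panel.csv")
  if (file.exists(p_mem)) {
    mem <- utils::read.csv(p_mem, colClasses = "character")
    mem$region_id[mem$region_id == "" | mem$region_id == "NA"] <- NA_character_
    units$state <- aggregate_crude(panel, mem, level = "state")
    units$region <- aggregate_crude(panel, mem, level = "region")
    inputs <- c(inputs, p_mem)
  }
  rate_rows <- list(); trend_rows <- list()
  for (lv in names(units)) {
    std <- standardize_crude(units[[lv]], w, outcome = config$outcome)
    std$level <- lv
    names(std)[names(std) == "county_id"] <- "unit"
    rate_rows[[lv]] <- std
    for (un in unique(std$unit)) {
      s <- std[std$unit == un, ]
      s <- s[order(s$year), ]
      if (all(s$rate > 0) && nrow(s) >= 3) {
        f <- fit_loglinear_trend(s$rate, id = un)
        f$level <- lv
        trend_rows[[paste(lv, un)]] <- f
      }
    }
  }
  p_rates <- file.path(dir, "aggregate_rates.csv")
  p_tr <- file.path(dir, "aggregate_trends.csv")
  utils::write.csv(do.call(rbind, rate_rows), p_rates, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(do.call(rbind, trend_rows), p_tr, row.names = FALSE,
                   quote = FALSE)
  list(inputs = inputs, outputs = c(p_rates, p_tr))
}
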