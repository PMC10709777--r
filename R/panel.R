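#' Tabulated county birth-count panels
#'
#' A `count_panel` holds live-birth and preterm-outcome counts tabulated by
#' county, 5-year maternal age group and calendar year -- the aggregation
#' level at which vital-statistics registries release county data. The panel
#' is rectangular: every county x age x year cell is present, with cells that
#' recorded no births stored as `births = 0`.
#'
#' @name count_panel
NULL

AGE_GROUPS_STANDARD <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44")

#' Construct a count panel from a long data frame
#'
#' @param counts Data frame with columns `county_id`, `age_group`, `year`,
#'   `births`, and one or more outcome count columns (`preterm`,
#'   `early_preterm`).
#' @param age_groups Ordered age-group labels. Defaults to the levels found in
#'   the data, ordered as the standard 5-year maternal groups when they match.
#' @return A `count_panel` object: the completed long data frame plus ordered
#'   index vectors `county_ids`, `age_groups`, `years`.
#' @export
count_panel <- function(counts, age_groups = NULL) {
  need <- c("county_id", "age_group", "year", "births")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  outcomes <- intersect(c("preterm", "early_preterm"), names(counts))
  if (!length(outcomes)) stop("panel has no outcome count column (preterm / early_preterm)")
  counts$county_id <- as.character(counts$county_id)
  counts$age_group <- as.character(counts$age_group)
  counts$year <- as.integer(counts$year)
  if (is.null(age_groups)) {
    found <- unique(counts$age_group)
    age_groups <- if (all(found %in% AGE_GROUPS_STANDARD)) {
      AGE_GROUPS_STANDARD[AGE_GROUPS_STANDARD %in% found]
    } else sort(found)
  }
  county_ids <- sort(unique(counts$county_id))
  years <- sort(unique(counts$year))
  key <- paste(counts$county_id, counts$age_group, counts$year)
  if (anyDuplicated(key)) {
    stop("duplicate (county, age_group, year) rows in panel")
  }
  if (any(counts$births < 0)) stop("negative birth counts")
  for (oc in outcomes) {
    if (any(counts[[oc]] < 0)) stop("negative outcome counts for '", oc, "'")
    if (any(counts[[oc]] > counts$births)) {
      stop("outcome counts exceed total births in ", sum(counts[[oc]] > counts$births),
           " cell(s) for outcome '", oc, "'")
    }
  }
  # complete the rectangular index, absent cells as zero counts
  full <- expand.grid(county_id = county_ids, age_group = age_groups,
                      year = years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  m <- match(paste(full$county_id, full$age_group, full$year), key)
  full$births <- ifelse(is.na(m), 0L, counts$births[m])
  for (oc in outcomes) full[[oc]] <- ifelse(is.na(m), 0L, counts[[oc]][m])
  structure(
    list(counts = full, county_ids = county_ids, age_groups = age_groups,
         years = years, outcomes = outcomes),
    class = "count_panel"
  )
}

#' @export
print.count_panel <- function(x, ...) {
  cat(sprintf(
    "Birth-count panel: %d counties x %d age groups x %d years (%d-%d)\n",
    length(x$county_ids), length(x$age_groups), length(x$years),
    min(x$years), max(x$years)
  ))
  cat(sprintf("  total births %s; outcomes: %s\n",
              format(sum(x$counts$births), big.mark = ","),
              paste(x$outcomes, collapse = ", ")))
  invisible(x)
}

#' Extract counts as county x age x year arrays
#'
#' @param panel A `count_panel`.
#' @param outcome Outcome column to extract alongside total births.
#' @return List with arrays `Y` (outcome counts) and `n` (births), dimensions
#'   county x age x year, dimnames from the panel index.
#' @export
panel_arrays <- function(panel, outcome = "preterm") {
  stopifnot(inherits(panel, "count_panel"))
  if (!outcome %in% panel$outcomes) {
    stop("outcome '", outcome, "' not in panel (has: ",
         paste(panel$outcomes, collapse = ", "), ")")
  }
  dims <- c(length(panel$county_ids), length(panel$age_groups), length(panel$years))
  dn <- list(panel$county_ids, panel$age_groups, panel$years)
  cc <- panel$counts
  i <- match(cc$county_id, panel$county_ids)
  k <- match(cc$age_group, panel$age_groups)
  t <- match(cc$year, panel$years)
  pos <- i + (k - 1L) * dims[1] + (t - 1L) * dims[1] * dims[2]
  Y <- array(0, dims, dimnames = dn); Y[pos] <- cc[[outcome]]
  n <- array(0, dims, dimnames = dn); n[pos] <- cc$births
  list(Y = Y, n = n)
}

#' Crude rates per 100 live births
#'
#' @param panel A `count_panel`.
#' @param outcome Outcome column.
#' @return Long data frame `county_id, age_group, year, births, rate` with
#'   `rate = 100 * Y / n` (NA where no births).
#' @export
crude_rates <- function(panel, outcome = "preterm") {
  cc <- panel$counts
  data.frame(
    county_id = cc$county_id, age_group = cc$age_group, year = cc$year,
    births = cc$births,
    rate = ifelse(cc$births > 0, 100 * cc[[outcome]] / cc$births, NA_real_)
  )
}

#' Read / write the standard panel file
#'
#' The standard interchange format is delimited text with header
#' `county_id,age_group,year,births,preterm,early_preterm`.
#'
#' @param path File path.
#' @return `read_panel` returns a `count_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, colClasses = c(county_id = "character"))
  count_panel(df)
}

#' @rdname read_panel
#' @param panel A `count_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel$counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
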