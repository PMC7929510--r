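# Run-level summary artifacts: standalone-importance tables, dataset
# coverage summaries, and the reconciliation report.

#' Standalone importance of zones, split by breeding origin
#'
#' Zones are ranked by total annual time spent; each zone's bird-years are
#' split into the component contributed by its own breeding populations
#' (origin country = zone) and the visiting component. Zones hosting no
#' more than `threshold_pct` percent of the grand total are collapsed into
#' a single `"Other"` row, which conserves the total exactly.
#'
#' @param annual a `juris_annual` from [annual_time()] (carrying the
#'   per-population attribute).
#' @param populations a [juris_populations()] table.
#' @param threshold_pct listing threshold as a percentage of total time
#'   (default 0.1; 0 lists everything).
#' @return data.table (`zone_id`, `T_e`, `pct`, `breeding_T_e`,
#'   `visiting_T_e`), ranked, with `"Other"` last when present.
#' @export
standalone_importance <- function(annual, populations, threshold_pct = 0.1) {
  by_pop <- attr(annual, "by_population", exact = TRUE)
  if (is.null(by_pop)) stop("annual table lacks per-population contributions")
  pops <- data.table::as.data.table(populations)[, .(population_id, origin_country)]
  d <- merge(by_pop, pops, by = "population_id")
  z <- d[, .(T_e = sum(bird_years),
             breeding_T_e = sum(bird_years[origin_country == zone_id]),
             visiting_T_e = sum(bird_years[origin_country != zone_id])),
         by = zone_id]
  total <- sum(z$T_e)
  z[, pct := 100 * T_e / total]
  data.table::setorder(z, -T_e, zone_id)
  small <- z$pct <= threshold_pct
  if (any(small)) {
    other <- z[small, .(zone_id = "Other", T_e = sum(T_e), breeding_T_e = sum(breeding_T_e),
                        visiting_T_e = sum(visiting_T_e), pct = sum(pct))]
    z <- rbind(z[!small], other)
  }
  data.table::setcolorder(z, c("zone_id", "T_e", "pct", "breeding_T_e", "visiting_T_e"))
  z[]
}

#' Dataset-level summary of tracking coverage
#'
#' Totals over species (global population, tracked sites and birds, and
#' tracking days when daily data are supplied) and the across-species means
#' of the coverage percentages. Means are unweighted by default, matching
#' how multi-species tracking syntheses report them; `weighted = TRUE`
#' weights by global population size instead.
#'
#' @param coverage a `juris_coverage` from [coverage_table()].
#' @param daily optional `juris_daily` used for the tracking-day total.
#' @param weighted weight species means by `n_s`?
#' @return one-row data.table: `n_species`, `total_n_s`, `total_sites`,
#'   `total_birds`, `total_tracking_days`, `mean_pct_pop`,
#'   `mean_pct_year_known`, `mean_pct_year_unknown`.
#' @export
summarize_dataset <- function(coverage, daily = NULL, weighted = FALSE) {
  cv <- data.table::as.data.table(coverage)
  w <- if (weighted) cv$n_s else rep(1, nrow(cv))
  data.table::data.table(
    n_species = nrow(cv),
    total_n_s = sum(cv$n_s),
    total_sites = sum(cv$n_sites),
    total_birds = if (all(is.na(cv$n_birds))) NA_integer_ else sum(cv$n_birds, na.rm = TRUE),
    total_tracking_days = if (is.null(daily)) NA_integer_ else nrow(daily),
    mean_pct_pop = stats::weighted.mean(cv$pct_pop, w),
    mean_pct_year_known = stats::weighted.mean(cv$pct_year_known, w),
    mean_pct_year_unknown = stats::weighted.mean(cv$pct_year_unknown, w))
}

#' Assemble a reconciliation report for one pipeline run
#'
#' Counts tracks/fixes entering and leaving each stage and checks that they
#' reconcile (`in = out + removed` at every stage).
#'
#' @param tracks raw [juris_tracks()] (its `rejected` attribute, if any,
#'   counts rows dropped at parse time).
#' @param daily after [subsample_daily()].
#' @param filtered after [filter_gls()] / [truncate_breeding_year()].
#' @param masked after [apply_mask()].
#' @param config configuration echoed into the report.
#' @param variant_id active sovereignty variant.
#' @return a `juris_run_report` list with a `stages` data.table
#'   (`stage`, `n_in`, `n_out`, `n_removed`).
#' @export
run_report <- function(tracks, daily, filtered = NULL, masked = NULL,
                       config = list(), variant_id = "baseline") {
  rej <- attr(tracks, "rejected", exact = TRUE)
  n_rej <- if (is.null(rej)) 0L else sum(rej$n)
  stages <- list(data.table::data.table(
    stage = "ingest", n_in = nrow(tracks) + n_rej, n_out = nrow(tracks), n_removed = n_rej))
  prev <- daily
  stages <- c(stages, list(data.table::data.table(
    stage = "daily_subsample", n_in = nrow(tracks), n_out = nrow(daily),
    n_removed = nrow(tracks) - nrow(daily))))
  if (!is.null(filtered)) {
    stages <- c(stages, list(data.table::data.table(
      stage = "filters", n_in = nrow(prev), n_out = nrow(filtered),
      n_removed = nrow(prev) - nrow(filtered))))
    prev <- filtered
  }
  if (!is.null(masked)) {
    stages <- c(stages, list(data.table::data.table(
      stage = "representativeness", n_in = nrow(prev), n_out = nrow(masked),
      n_removed = nrow(prev) - nrow(masked))))
  }
  st <- data.table::rbindlist(stages)
  stopifnot(all(st$n_in == st$n_out + st$n_removed), all(st$n_removed >= 0L))
  out <- list(stages = st, config = config, variant_id = variant_id,
              version = as.character(utils::packageVersion("juristrack")))
  class(out) <- "juris_run_report"
  out
}

#' @export
print.juris_run_report <- function(x, ...) {
  cat(sprintf("<juris_run_report> variant=%s version=%s\n", x$variant_id, x$version))
  print(x$stages)
  invisible(x)
}
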