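# Population-level occupancy: monthly individual proportions, extrapolation
# to bird-months/bird-years, zone richness, and coverage bookkeeping.

# Shared core: per (population, month, zone) mean over tracked individuals
# of D_ime / D_im, where D_im counts each individual's tracked days in the
# month and D_ime the subset spent in the zone. `dt` must have one row per
# (bird, day, zone-membership); `denom` gives each bird-month's D_im.
eq1_monthly_core <- function(dt, zone_col, denom) {
  d <- dt[, .(D_ime = .N), by = c("population_id", "species_id", "month", "bird_id", zone_col)]
  data.table::setnames(d, zone_col, "zone_id")
  d <- merge(d, denom, by = c("population_id", "month", "bird_id"))
  d[, prop := D_ime / D_im]
  nm <- denom[, .(n_m = .N), by = .(population_id, month)]
  agg <- d[, .(sum_prop = sum(prop), species_id = species_id[1L]),
           by = .(population_id, month, zone_id)]
  agg <- merge(agg, nm, by = c("population_id", "month"))
  agg[, mean_prop := sum_prop / n_m]
  agg[, sum_prop := NULL]
  agg[]
}

#' Monthly occupancy proportions and population-level time spent
#'
#' For each breeding population, calendar month (pooled across years) and
#' zone, computes the mean over tracked individuals of the proportion of
#' that individual's tracked days spent in the zone, and extrapolates it to
#' bird-months by multiplying with the breeding population size:
#' `T_spme = mean_prop * N_p`. Individuals with zero tracked days in a month
#' simply do not enter that month's mean.
#'
#' For `layer = "rfmo"` only high-seas days carry RFMO membership and a day
#' inside several overlapping competence areas counts towards each of them,
#' so RFMO proportions need not sum to one; the denominator `D_im` remains
#' the individual's total tracked days in the month.
#'
#' @param assign a `juris_assign` table from [assign_days()].
#' @param populations a [juris_populations()] table.
#' @param mask optional `juris_mask`; unrepresentative population-months are
#'   dropped before computing proportions.
#' @param layer `"country"` (default) or `"rfmo"`.
#' @return a `juris_occupancy` data.table (`population_id`, `species_id`,
#'   `month`, `zone_id`, `mean_prop`, `n_m`, `T_spme`) with attribute
#'   `layer` (and `multi_assigned = TRUE` for the RFMO layer).
#' @export
monthly_proportions <- function(assign, populations, mask = NULL,
                                layer = c("country", "rfmo")) {
  layer <- match.arg(layer)
  dt <- data.table::as.data.table(assign)
  if (!is.null(mask)) dt <- data.table::as.data.table(apply_mask(dt, mask))
  denom <- dt[, .(D_im = .N), by = .(population_id, month, bird_id)]
  if (layer == "country") {
    agg <- eq1_monthly_core(dt, "country_zone", denom)
  } else {
    hs <- dt[country_zone == HIGH_SEAS_ID & nzchar(rfmo_zones)]
    if (nrow(hs) == 0L) {
      agg <- data.table::data.table(population_id = character(), month = integer(),
                                    zone_id = character(), species_id = character(),
                                    n_m = integer(), mean_prop = numeric())
    } else {
      hs <- hs[, .(rfmo = strsplit(rfmo_zones, ";", fixed = TRUE)[[1L]]),
               by = .(population_id, species_id, month, bird_id, local_day)]
      agg <- eq1_monthly_core(hs, "rfmo", denom)
    }
  }
  agg <- merge(agg, data.table::as.data.table(populations)[, .(population_id, n_p)],
               by = "population_id")
  agg[, T_spme := mean_prop * n_p]
  agg[, n_p := NULL]
  data.table::setcolorder(agg, c("population_id", "species_id", "month", "zone_id",
                                 "mean_prop", "n_m", "T_spme"))
  data.table::setorder(agg, population_id, month, zone_id)
  data.table::setattr(agg, "layer", layer)
  if (layer == "rfmo") data.table::setattr(agg, "multi_assigned", TRUE)
  data.table::setattr(agg, "class", c("juris_occupancy", "data.table", "data.frame"))
  agg
}

#' Extrapolate a mean monthly proportion to bird-months
#'
#' `T_spme = mean_prop * N_p`. Kept unrounded internally; round only on
#' report.
#'
#' @param mean_prop mean individual proportion in `[0, 1]`.
#' @param n_p breeding population size (individuals).
#' @return bird-months.
#' @export
population_monthly_time <- function(mean_prop, n_p) {
  stopifnot(all(mean_prop >= -1e-12 & mean_prop <= 1 + 1e-12), all(n_p > 0))
  mean_prop * n_p
}

#' Annual time spent per zone, in bird-years
#'
#' Monthly bird-month totals are summed over the months with tracking data
#' and divided by 12 — deliberately by 12 and not by the number of tracked
#' months, so that untracked months contribute zero (a conservative
#' underestimate rather than an extrapolation into unsampled periods):
#' `T_e = sum_p sum_m T_spme / 12`.
#'
#' @param occupancy a `juris_occupancy` table (or any table with
#'   `population_id`, `zone_id`, `T_spme`).
#' @return a `juris_annual` data.table (`zone_id`, `T_e`) with attribute
#'   `by_population` (per-population bird-year contributions).
#' @export
annual_time <- function(occupancy) {
  occ <- data.table::as.data.table(occupancy)
  by_pop <- occ[, .(bird_years = sum(T_spme) / 12), by = .(population_id, zone_id)]
  te <- by_pop[, .(T_e = sum(bird_years)), by = zone_id]
  data.table::setorder(te, zone_id)
  data.table::setattr(te, "by_population", by_pop)
  data.table::setattr(te, "layer", attr(occupancy, "layer", exact = TRUE))
  data.table::setattr(te, "class", c("juris_annual", "data.table", "data.frame"))
  te
}

#' Species richness per zone, split into Breeding / Visiting / Both
#'
#' A species breeds in a (country) zone when one of its tracked populations
#' has that zone's country as breeding origin; it visits a zone when at
#' least one retained daily position of a population with a different origin
#' falls there. The three reported categories are disjoint:
#' `breeding_only` (breeds, no visits from elsewhere), `visiting_only`
#' (present, does not breed there), `both` (breeds locally and is visited by
#' conspecifics of other origins). High seas, Antarctic, disputed and RFMO
#' zones host no breeding, so all presence there is visiting.
#'
#' @param assign a `juris_assign` table (after masking).
#' @param populations a [juris_populations()] table (with the active
#'   sovereignty variant applied).
#' @param zones optional character vector of zone ids to force into the
#'   output (e.g. all zones of the layer, or breeding countries never
#'   visited).
#' @return a `juris_richness` data.table: `zone_id`, counts
#'   (`n_breeding_only`, `n_visiting_only`, `n_both`, `n_total`) and
#'   `;`-joined species lists per category.
#' @export
richness_by_zone <- function(assign, populations, zones = NULL) {
  dt <- data.table::as.data.table(assign)
  pops <- data.table::as.data.table(populations)
  origin <- pops[, .(species_id, population_id, origin_country)]
  pres <- unique(dt[, .(species_id, population_id, zone_id = country_zone)])
  pres <- merge(pres, origin, by = c("species_id", "population_id"))
  breed <- unique(origin[, .(species_id, zone_id = origin_country)])
  zone_ids <- sort(unique(c(pres$zone_id, breed$zone_id, zones)))
  out <- data.table::rbindlist(lapply(zone_ids, function(z) {
    b <- breed[zone_id == z, unique(species_id)]
    pz <- pres[zone_id == z]
    visitors <- pz[origin_country != z, unique(species_id)]
    present <- pz[, unique(species_id)]
    both <- intersect(b, visitors)
    breeding_only <- setdiff(b, both)
    visiting_only <- setdiff(union(visitors, setdiff(present, b)), b)
    data.table::data.table(
      zone_id = z,
      n_breeding_only = length(breeding_only), n_visiting_only = length(visiting_only),
      n_both = length(both),
      n_total = length(breeding_only) + length(visiting_only) + length(both),
      breeding_only = paste(sort(breeding_only), collapse = ";"),
      visiting_only = paste(sort(visiting_only), collapse = ";"),
      both = paste(sort(both), collapse = ";"))
  }))
  data.table::setattr(out, "class", c("juris_richness", "data.table", "data.frame"))
  out
}

#' Underestimation of breeding richness per country
#'
#' Tracked breeding richness (from the populations actually in the dataset)
#' is compared against the full known breeding-country lists; the deficit
#' per country, and its mean and SD across countries with known breeders,
#' quantify how far tracked breeding richness understates the truth.
#'
#' @param richness a `juris_richness` table from [richness_by_zone()].
#' @param species a [juris_species()] table with
#'   `known_breeding_countries`.
#' @return data.table (`country`, `known`, `tracked`, `delta`) with
#'   attributes `mean_delta` and `sd_delta`. A country with more tracked
#'   than known breeding species is a data inconsistency and errors.
#' @export
richness_underestimation <- function(richness, species) {
  sp <- data.table::as.data.table(species)
  kn <- sp[, .(country = split_country_list(known_breeding_countries)[[1L]]),
           by = species_id]
  known <- kn[, .(known = data.table::uniqueN(species_id)), by = country]
  rz <- data.table::as.data.table(richness)
  tracked <- rz[, .(country = zone_id, tracked = n_breeding_only + n_both)]
  out <- merge(known, tracked, by = "country", all.x = TRUE)
  out[is.na(tracked), tracked := 0L]
  extra <- setdiff(tracked[tracked > 0, country], known$country)
  if (length(extra)) {
    stop("tracked breeding species in countries with no known breeders: ",
         paste(extra, collapse = ", "))
  }
  if (any(out$tracked > out$known)) {
    stop("tracked breeding richness exceeds known richness for: ",
         paste(out[tracked > known, country], collapse = ", "))
  }
  out[, delta := known - tracked]
  data.table::setorder(out, country)
  data.table::setattr(out, "mean_delta", mean(out$delta))
  data.table::setattr(out, "sd_delta", stats::sd(out$delta))
  out[]
}

#' Tracking coverage per species
#'
#' For each species: the share of the global breeding population covered by
#' tracked sites, `pct_pop = 100 * sum(N_p tracked) / N_s`, and the share of
#' the population-year covered, `pct_year_known = 100 * sum_p(N_p *
#' months_covered_p / 12) / N_s`; `pct_year_unknown` is its complement.
#'
#' @param populations a [juris_populations()] table.
#' @param species a [juris_species()] table.
#' @param mask a `juris_mask`; populations present in the mask with at least
#'   one retained month count as tracked.
#' @param daily optional `juris_daily` table used to report `n_birds`.
#' @return a `juris_coverage` data.table (`species_id`, `n_s`, `n_sites`,
#'   `n_birds`, `pct_pop`, `pct_year_known`, `pct_year_unknown`),
#'   unrounded.
#' @export
coverage_table <- function(populations, species, mask, daily = NULL) {
  pops <- data.table::as.data.table(populations)
  sp <- data.table::as.data.table(species)
  mc <- months_covered(mask)
  pops <- merge(pops, mc, by = "population_id", all.x = TRUE)
  pops[is.na(months_covered), months_covered := 0L]
  per_sp <- pops[, .(
    n_sites = sum(months_covered > 0L),
    pop_tracked = sum(n_p * (months_covered > 0L)),
    pop_year = sum(n_p * months_covered / 12)), by = species_id]
  out <- merge(sp[, .(species_id, n_s)], per_sp, by = "species_id", all.x = TRUE)
  for (cl in c("n_sites", "pop_tracked", "pop_year")) {
    data.table::set(out, which(is.na(out[[cl]])), cl, 0)
  }
  out[, pct_pop := 100 * pop_tracked / n_s]
  out[, pct_year_known := 100 * pop_year / n_s]
  out[, pct_year_unknown := 100 - pct_year_known]
  if (!is.null(daily)) {
    nb <- data.table::as.data.table(daily)[, .(n_birds = data.table::uniqueN(bird_id)),
                                           by = species_id]
    out <- merge(out, nb, by = "species_id", all.x = TRUE)
    out[is.na(n_birds), n_birds := 0L]
  } else {
    out[, n_birds := NA_integer_]
  }
  out[, c("pop_tracked", "pop_year") := NULL]
  data.table::setcolorder(out, c("species_id", "n_s", "n_sites", "n_birds",
                                 "pct_pop", "pct_year_known", "pct_year_unknown"))
  data.table::setorder(out, species_id)
  data.table::setattr(out, "class", c("juris_coverage", "data.table", "data.frame"))
  out
}
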