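# Origin-country to zone connectivity: per-species shares of annual time,
# connection strengths, top-k link selection, and edge-list export.

#' Per-species, per-origin share of annual time spent in each zone
#'
#' Monthly bird-month totals are summed over all months and all tracked
#' populations of a species breeding under one origin country, converted to
#' bird-years, and normalised by the species' global population:
#' `G_soe = sum_p sum_m T_spme / (12 * N_s)`. A proportion in `[0, 1]`;
#' summed over the country layer it reaches 1 only when every population of
#' the species in that origin is tracked through all 12 months.
#'
#' @param occupancy a `juris_occupancy` table from [monthly_proportions()].
#' @param populations a [juris_populations()] table (with the active
#'   sovereignty variant applied).
#' @param species a [juris_species()] table.
#' @return a `juris_shares` data.table (`species_id`, `origin_country`,
#'   `zone_id`, `G_soe`, `n_populations`).
#' @export
species_origin_share <- function(occupancy, populations, species) {
  occ <- data.table::as.data.table(occupancy)
  if ("species_id" %in% names(occ)) occ <- occ[, !"species_id"]
  # the population table is the authoritative population -> species mapping
  pops <- data.table::as.data.table(populations)[, .(population_id, species_id, origin_country)]
  sp <- data.table::as.data.table(species)[, .(species_id, n_s)]
  if (any(sp$n_s <= 0)) stop("species with non-positive global population n_s")
  d <- merge(occ, pops, by = "population_id")
  out <- d[, .(bird_years = sum(T_spme) / 12,
               n_populations = data.table::uniqueN(population_id)),
           by = .(species_id, origin_country, zone_id)]
  out <- merge(out, sp, by = "species_id")
  out[, G_soe := bird_years / n_s]
  out[, c("bird_years", "n_s") := NULL]
  data.table::setorder(out, species_id, origin_country, zone_id)
  data.table::setattr(out, "class", c("juris_shares", "data.table", "data.frame"))
  out
}

#' Connection strength between origin countries and zones
#'
#' `G_oe = 100 * sum_s G_soe`: the percentage of annual time spent in zone
#' `e`, summed across all species breeding in origin country `o` (each
#' species weighted by its own global population).
#'
#' @param shares a `juris_shares` table from [species_origin_share()].
#' @return a `juris_edges` data.table (`origin_country`, `zone_id`,
#'   `G_oe_percent`, `n_species`, `species` `;`-joined).
#' @export
connection_strength <- function(shares) {
  sh <- data.table::as.data.table(shares)
  out <- sh[, .(G_oe_percent = 100 * sum(G_soe),
                n_species = data.table::uniqueN(species_id),
                species = paste(sort(unique(species_id)), collapse = ";")),
            by = .(origin_country, zone_id)]
  data.table::setorder(out, origin_country, zone_id)
  data.table::setattr(out, "class", c("juris_edges", "data.table", "data.frame"))
  out
}

#' Select the strongest connections per origin country
#'
#' Edges are ranked within each origin by `G_oe` descending, ties broken by
#' species count descending, then `zone_id` ascending; the top `k` are
#' retained (5 for the country layer, 3 for the RFMO layer, by
#' convention). By default an origin's own waters are excluded from its
#' "visited areas" ranking.
#'
#' @param edges a `juris_edges` table.
#' @param k number of links kept per origin (>= 1).
#' @param include_self keep self-connections (`zone_id == origin_country`)?
#'   Default `FALSE`.
#' @return ranked subset of `edges` with a `rank` column (1 = strongest per
#'   origin). Stable under shuffling of the input rows.
#' @export
top_connections <- function(edges, k = 5L, include_self = FALSE) {
  if (!is.numeric(k) || k < 1L) stop("k must be >= 1")
  ed <- data.table::as.data.table(edges)
  if (!include_self) ed <- ed[zone_id != origin_country]
  data.table::setorder(ed, origin_country, -G_oe_percent, -n_species, zone_id)
  ed[, rank := seq_len(.N), by = origin_country]
  out <- ed[rank <= k]
  data.table::setattr(out, "class", c("juris_edges", "data.table", "data.frame"))
  out[]
}

#' Export a connectivity network as edge and node tables
#'
#' Writes `edges.csv` (`origin_country`, `zone_id`, `G_oe_percent`,
#' `n_species`, `rank`) and `nodes.csv` (`id`, `role` = origin|visited,
#' `n_breeding`, `n_visiting`), deterministically ordered; reruns are
#' byte-identical.
#'
#' @param edges a (possibly ranked) `juris_edges` table.
#' @param dir output directory.
#' @param richness optional `juris_richness` table supplying per-node
#'   breeding/visiting richness.
#' @return paths of the written files, invisibly.
#' @export
export_network <- function(edges, dir, richness = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  ed <- data.table::as.data.table(edges)
  if (!"rank" %in% names(ed)) ed[, rank := NA_integer_]
  ed <- ed[, .(origin_country, zone_id, G_oe_percent, n_species, rank)]
  data.table::setorder(ed, origin_country, rank, zone_id)
  nodes <- data.table::rbindlist(list(
    data.table::data.table(id = sort(unique(ed$origin_country)), role = "origin"),
    data.table::data.table(id = sort(unique(ed$zone_id)), role = "visited")))
  nodes[, `:=`(n_breeding = NA_integer_, n_visiting = NA_integer_)]
  if (!is.null(richness)) {
    rz <- data.table::as.data.table(richness)
    i <- match(nodes$id, rz$zone_id)
    nodes[, n_breeding := rz$n_breeding_only[i] + rz$n_both[i]]
    nodes[, n_visiting := rz$n_visiting_only[i] + rz$n_both[i]]
  }
  data.table::setorder(nodes, role, id)
  ep <- file.path(dir, "edges.csv"); np <- file.path(dir, "nodes.csv")
  data.table::fwrite(ed, ep)
  data.table::fwrite(nodes, np)
  invisible(c(ep, np))
}
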