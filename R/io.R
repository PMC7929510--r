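# File input/output: tracking CSVs, population/species CSVs, GeoJSON zone
# layers, and the CSV/GeoJSON result bundle.

#' Column mapping for tracking-table imports
#'
#' Archive exports name columns differently; a schema maps the canonical
#' field names onto the columns of a particular file.
#'
#' @param bird_id,species_id,population_id,device,timestamp,lon,lat column
#'   names in the file.
#' @return named character vector (canonical -> file column).
#' @export
track_schema <- function(bird_id = "bird_id", species_id = "species_id",
                         population_id = "population_id", device = "device",
                         timestamp = "timestamp", lon = "lon", lat = "lat") {
  c(bird_id = bird_id, species_id = species_id, population_id = population_id,
    device = device, timestamp = timestamp, lon = lon, lat = lat)
}

#' Read a tracking table from CSV
#'
#' Rows failing validation (unparseable timestamp or coordinate, coordinate
#' out of bounds, unknown device) are dropped and counted in the rejection
#' report attached as attribute `"rejected"`; a missing required column is a
#' hard error naming the column.
#'
#' @param path CSV file (UTF-8, ISO-8601 timestamps).
#' @param schema a [track_schema()] mapping canonical names to file columns.
#' @return a [juris_tracks()] object with attribute `rejected`, a data.table
#'   of per-reason rejection counts.
#' @export
read_tracks <- function(path, schema = track_schema()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, colClasses = list(character = unname(schema[c(
    "bird_id", "species_id", "population_id", "device", "timestamp")])))
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss)) stop("tracking file missing required column(s): ",
                         paste(miss, collapse = ", "))
  dt <- raw[, unname(schema), with = FALSE]
  data.table::setnames(dt, names(schema))
  rej <- list()
  note <- function(reason, bad) {
    if (any(bad)) rej[[reason]] <<- sum(bad)
    bad
  }
  ts <- as.POSIXct(rep(NA_real_, nrow(dt)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(dt$timestamp[todo], fmt, tz = "UTC"))
  }
  lon <- suppressWarnings(as.numeric(dt$lon))
  lat <- suppressWarnings(as.numeric(dt$lat))
  bad <- note("unparseable timestamp", is.na(ts)) |
    note("unparseable coordinate", !is.na(ts) & (is.na(lon) | is.na(lat))) |
    note("latitude out of bounds", !is.na(lat) & (lat < -90 | lat > 90)) |
    note("longitude out of bounds", !is.na(lon) & (lon < -360 | lon > 360)) |
    note("unknown device", !dt$device %in% DEVICE_LEVELS)
  dt[, `:=`(timestamp = ts, lon = lon, lat = lat)]
  kept <- dt[!bad]
  if (nrow(kept) == 0L) stop("no valid rows in ", path)
  out <- juris_tracks(kept)
  report <- data.table::data.table(reason = names(rej),
                                   n = as.integer(unlist(rej %||% list())))
  data.table::setattr(out, "rejected", report)
  out
}

#' Read breeding populations and species metadata from CSV
#'
#' One row per breeding population, with the species-level fields (`n_s`,
#' `biennial`, `known_breeding_countries`) repeated on each of the species'
#' rows. Species rows are deduplicated and cross-checked.
#'
#' @param path CSV with columns `population_id`, `species_id`,
#'   `island_group`, `origin_country`, `colony_lon`, `colony_lat`, `n_p`,
#'   `n_s`, and optionally `biennial`, `known_breeding_countries`,
#'   `scientific_name`.
#' @param pairs_to_individuals if `TRUE`, population sizes in the file are
#'   breeding pairs and are doubled on read.
#' @return list with elements `populations` ([juris_populations()]) and
#'   `species` ([juris_species()]).
#' @export
read_populations <- function(path, pairs_to_individuals = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path)
  req <- c("population_id", "species_id", "island_group", "origin_country",
           "colony_lon", "colony_lat", "n_p", "n_s")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("population file missing column(s): ", paste(miss, collapse = ", "))
  if (pairs_to_individuals) dt[, `:=`(n_p = 2 * n_p, n_s = 2 * n_s)]
  pops <- juris_populations(dt[, .(population_id, species_id, island_group,
                                   origin_country, colony_lon, colony_lat, n_p)])
  sp_cols <- intersect(c("species_id", "scientific_name", "n_s", "biennial",
                         "known_breeding_countries"), names(dt))
  sp <- unique(dt[, sp_cols, with = FALSE])
  if (any(duplicated(sp$species_id))) {
    stop("inconsistent species-level fields across rows of the same species")
  }
  species <- juris_species(sp, populations = pops)
  list(populations = pops, species = species)
}

# ---------------------------------------------------------------------------
# GeoJSON zones
# ---------------------------------------------------------------------------

geojson_to_mp <- function(geom) {
  if (is.null(geom)) return(NULL)
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  }
  poly_part <- function(p) {
    list(outer = ring_mat(p[[1]]),
         holes = if (length(p) > 1L) lapply(p[-1], ring_mat) else list())
  }
  switch(geom$type,
         Polygon = list(poly_part(geom$coordinates)),
         MultiPolygon = lapply(geom$coordinates, poly_part),
         stop("unsupported geometry type: ", geom$type))
}

mp_to_geojson <- function(mp) {
  if (is.null(mp)) return(NULL)
  part_coords <- function(part) {
    rings <- c(list(part$outer), part$holes)
    lapply(rings, function(r) {
      r <- close_ring(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
  }
  list(type = "MultiPolygon", coordinates = lapply(mp, part_coords))
}

#' Read a zone layer from GeoJSON
#'
#' Features must carry properties `zone_id`, `layer`, and where relevant
#' `sovereign`, `claimants` (array or `/`-separated string), `disputed`.
#' Geometries are normalised to `[-180, 180)` with antimeridian-crossing
#' polygons split. A country partition lacking an explicit high-seas feature
#' gains the geometry-free complement automatically.
#'
#' @param path GeoJSON file (RFC 7946).
#' @param layer_kind `"country_partition"` or `"rfmo_overlay"`.
#' @param ... passed to [zone_layer()] (e.g. `overlap_tol`).
#' @return a [zone_layer()].
#' @export
read_zone_layer <- function(path, layer_kind = c("country_partition", "rfmo_overlay"), ...) {
  layer_kind <- match.arg(layer_kind)
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a GeoJSON FeatureCollection")
  zones <- lapply(gj$features, function(f) {
    pr <- f$properties
    if (is.null(pr$zone_id)) stop("feature missing property 'zone_id'")
    mp <- geojson_to_mp(f$geometry)
    if (!is.null(mp)) {
      for (i in seq_along(mp)) {
        mp[[i]]$outer[, 1] <- norm_lon(mp[[i]]$outer[, 1])
        for (j in seq_along(mp[[i]]$holes)) mp[[i]]$holes[[j]][, 1] <- norm_lon(mp[[i]]$holes[[j]][, 1])
      }
      mp <- split_antimeridian(mp)
    }
    claim <- pr$claimants
    claim <- if (is.null(claim)) character(0) else unlist(strsplit(unlist(claim), "/", fixed = TRUE))
    maritime_zone(pr$zone_id, pr$layer %||% "COUNTRY", geometry = mp,
                  sovereign = pr$sovereign %||% NA_character_,
                  claimants = claim, disputed = isTRUE(pr$disputed) || length(claim) >= 2L)
  })
  zone_layer(zones, layer_kind, ...)
}

#' Write a zone layer to GeoJSON
#'
#' @param layer a [zone_layer()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_zone_layer <- function(layer, path) {
  feats <- lapply(layer$zones, function(z) {
    list(type = "Feature",
         properties = list(zone_id = z$zone_id, layer = z$layer,
                           sovereign = if (is.na(z$sovereign)) NULL else z$sovereign,
                           claimants = if (length(z$claimants)) paste(z$claimants, collapse = "/") else NULL,
                           disputed = z$disputed),
         geometry = mp_to_geojson(z$geometry))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result bundle
# ---------------------------------------------------------------------------

#' Write analysis outputs to a directory
#'
#' Writes whichever results are present: `occupancy` (per population x month
#' x zone), `annual` (per-zone bird-years), `richness`, `edges`/`nodes`
#' (connectivity), `coverage`, `mask`, and `grid` (cell centers as a GeoJSON
#' point collection with per-cell statistics). Column order is fixed, rows
#' are sorted, and files round-trip through [data.table::fread()].
#'
#' @param results named list of result tables.
#' @param out_dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  put <- function(dt, name, order_by) {
    dt <- data.table::as.data.table(dt)
    data.table::setorderv(dt, intersect(order_by, names(dt)))
    p <- file.path(out_dir, name)
    data.table::fwrite(dt, p)
    written <<- c(written, p)
  }
  if (!is.null(results$occupancy)) {
    occ <- data.table::as.data.table(results$occupancy)[
      , .(population_id, month, zone_id, mean_prop, n_individuals = n_m, T_spme)]
    put(occ, "occupancy.csv", c("population_id", "month", "zone_id"))
  }
  if (!is.null(results$annual)) {
    put(results$annual, "annual_time.csv", c("zone_id"))
  }
  if (!is.null(results$richness)) put(results$richness, "richness.csv", "zone_id")
  if (!is.null(results$coverage)) put(results$coverage, "coverage.csv", "species_id")
  if (!is.null(results$mask)) put(results$mask, "representativeness.csv", c("population_id", "month"))
  if (!is.null(results$edges)) {
    ed <- data.table::as.data.table(results$edges)
    put(ed, "edges.csv", c("origin_country", "rank", "zone_id"))
  }
  if (!is.null(results$nodes)) put(results$nodes, "nodes.csv", c("role", "id"))
  if (!is.null(results$grid)) {
    g <- results$grid
    feats <- lapply(seq_len(nrow(g$cells)), function(i) {
      list(type = "Feature",
           properties = as.list(g$cells[i, !c("lon", "lat")]),
           geometry = list(type = "Point", coordinates = c(g$cells$lon[i], g$cells$lat[i])))
    })
    p <- file.path(out_dir, "grid.geojson")
    jsonlite::write_json(list(type = "FeatureCollection", features = feats), p,
                         auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, p)
  }
  invisible(written)
}
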