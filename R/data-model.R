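# Core data containers. Tabular objects are data.tables with a light S3
# class carrying validation; geospatial zones are lists of multipolygons.

DEVICE_LEVELS <- c("GLS", "PTT", "GPS")
ZONE_LAYERS <- c("COUNTRY", "HIGH_SEAS", "RFMO", "ANTARCTIC")

#' Identifier of the high-seas complement zone
#' @export
HIGH_SEAS_ID <- "HIGH_SEAS"

#' Identifier of the Antarctic zone (south of the Antarctic cut-off latitude)
#' @export
ANTARCTIC_ID <- "ANTARCTIC"

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
local_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Tracks
# ---------------------------------------------------------------------------

#' Construct a validated set of tracks
#'
#' A `juris_tracks` object is a data.table with one row per position fix and
#' columns `bird_id`, `species_id`, `population_id`, `device`, `timestamp`
#' (POSIXct, UTC), `lon`, `lat`. Fixes are sorted and strictly increasing in
#' time within each bird; longitudes are normalised to `[-180, 180)`.
#'
#' @param df data.frame or data.table with the columns above.
#' @param attachment optional data.table (`bird_id`, `attachment_date`,
#'   class Date) giving device attachment dates; defaults to each bird's
#'   first fix date (UTC).
#' @return a `juris_tracks` data.table.
#' @export
juris_tracks <- function(df, attachment = NULL) {
  dt <- data.table::as.data.table(df)
  req <- c("bird_id", "species_id", "population_id", "device", "timestamp", "lon", "lat")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("tracks missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) stop("tracks are empty")
  if (!inherits(dt$timestamp, "POSIXct")) {
    dt[, timestamp := as.POSIXct(timestamp, tz = "UTC")]
  }
  attr(dt$timestamp, "tzone") <- "UTC"
  if (anyNA(dt$timestamp)) stop("tracks contain unparseable timestamps")
  if (!all(dt$device %in% DEVICE_LEVELS)) {
    stop("device must be one of ", paste(DEVICE_LEVELS, collapse = "/"))
  }
  if (any(dt$lat < -90 | dt$lat > 90)) stop("latitude out of [-90, 90]")
  dt[, lon := norm_lon(lon)]
  data.table::setorder(dt, bird_id, timestamp)
  dup <- dt[, any(duplicated(timestamp)), by = bird_id]$V1
  if (any(dup)) stop("fix timestamps must be strictly increasing within a bird")
  one_pop <- dt[, data.table::uniqueN(population_id) == 1L &
                    data.table::uniqueN(species_id) == 1L, by = bird_id]$V1
  if (!all(one_pop)) stop("a bird must belong to exactly one species and population")
  if (is.null(attachment)) {
    attachment <- dt[, .(attachment_date = as.Date(min(timestamp), tz = "UTC")), by = bird_id]
  } else {
    attachment <- data.table::as.data.table(attachment)
    stopifnot(all(c("bird_id", "attachment_date") %in% names(attachment)))
    attachment[, attachment_date := as.Date(attachment_date)]
  }
  data.table::setattr(dt, "attachment", attachment)
  data.table::setattr(dt, "class", c("juris_tracks", class(dt)))
  dt
}

#' @export
print.juris_tracks <- function(x, ...) {
  cat(sprintf("<juris_tracks> %d fixes, %d birds, %d populations, %d species\n",
              nrow(x), data.table::uniqueN(x$bird_id),
              data.table::uniqueN(x$population_id), data.table::uniqueN(x$species_id)))
  NextMethod()
}

# ---------------------------------------------------------------------------
# Populations and species
# ---------------------------------------------------------------------------

#' Construct a validated breeding-population table
#'
#' One row per breeding population ("island group" colony aggregation):
#' `population_id`, `species_id`, `island_group`, `origin_country`,
#' `colony_lon`, `colony_lat`, `n_p` (breeding adults, individuals).
#'
#' @param df data.frame with the columns above.
#' @return a `juris_populations` data.table.
#' @export
juris_populations <- function(df) {
  dt <- data.table::as.data.table(df)
  req <- c("population_id", "species_id", "island_group", "origin_country",
           "colony_lon", "colony_lat", "n_p")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("populations missing column(s): ", paste(miss, collapse = ", "))
  if (any(duplicated(dt$population_id))) stop("duplicate population_id")
  bad <- dt[n_p <= 0 | !is.finite(n_p), population_id]
  if (length(bad)) stop("population size n_p must be > 0 for: ", paste(bad, collapse = ", "))
  if (any(dt$colony_lat < -90 | dt$colony_lat > 90)) stop("invalid colony latitude")
  dt[, colony_lon := norm_lon(colony_lon)]
  data.table::setattr(dt, "class", c("juris_populations", class(dt)))
  dt
}

#' Construct a validated species table
#'
#' One row per species: `species_id`, `scientific_name` (optional),
#' `n_s` (global breeding population, individuals), `biennial` (logical),
#' `known_breeding_countries` (character, `;`-separated sovereign ids).
#'
#' @param df data.frame with the columns above.
#' @param populations optional `juris_populations`; when given, the
#'   cross-reference invariants are checked (every population's species
#'   exists; per species, sum of `n_p` does not exceed `n_s`).
#' @return a `juris_species` data.table.
#' @export
juris_species <- function(df, populations = NULL) {
  dt <- data.table::as.data.table(df)
  req <- c("species_id", "n_s")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("species missing column(s): ", paste(miss, collapse = ", "))
  if (any(duplicated(dt$species_id))) stop("duplicate species_id")
  if (any(dt$n_s <= 0)) stop("global population n_s must be > 0")
  if (!"biennial" %in% names(dt)) dt[, biennial := FALSE]
  if (!"known_breeding_countries" %in% names(dt)) dt[, known_breeding_countries := NA_character_]
  if (!is.null(populations)) {
    unk <- setdiff(populations$species_id, dt$species_id)
    if (length(unk)) stop("population references unknown species: ", paste(unk, collapse = ", "))
    tot <- populations[, .(tot = sum(n_p)), by = species_id]
    chk <- merge(tot, dt[, .(species_id, n_s)], by = "species_id")
    over <- chk[tot > n_s, species_id]
    if (length(over)) {
      stop("sum of population sizes exceeds global population n_s for species: ",
           paste(over, collapse = ", "))
    }
  }
  data.table::setattr(dt, "class", c("juris_species", class(dt)))
  dt
}

#' Parse a `;`-separated known-breeding-country field into a list
#' @param x character vector.
#' @return list of character vectors.
#' @export
split_country_list <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

# ---------------------------------------------------------------------------
# Maritime zones
# ---------------------------------------------------------------------------

#' Construct a maritime zone
#'
#' @param zone_id unique zone identifier. Country zones use the sovereign id;
#'   disputed areas use `"disputed - A/B"` with claimants sorted.
#' @param layer one of `"COUNTRY"`, `"HIGH_SEAS"`, `"RFMO"`, `"ANTARCTIC"`.
#' @param geometry a multipolygon, or `NULL` for the high-seas complement
#'   (membership is defined as "in no other country-layer zone").
#' @param sovereign sovereign country id, or `NA` for high seas / disputed /
#'   RFMO zones.
#' @param claimants character vector of claimant ids (disputed zones only).
#' @param disputed logical.
#' @return a `maritime_zone` list.
#' @export
maritime_zone <- function(zone_id, layer, geometry = NULL, sovereign = NA_character_,
                          claimants = character(0), disputed = FALSE) {
  layer <- match.arg(layer, ZONE_LAYERS)
  if (disputed && length(claimants) < 2L) stop("disputed zone needs >= 2 claimants")
  if (!disputed && length(claimants)) stop("claimants only allowed on disputed zones")
  if (layer == "COUNTRY" && !disputed && is.na(sovereign)) {
    stop("COUNTRY zone '", zone_id, "' needs a sovereign")
  }
  z <- list(zone_id = as.character(zone_id), layer = layer, geometry = geometry,
            sovereign = as.character(sovereign), claimants = as.character(claimants),
            disputed = isTRUE(disputed),
            bbox = if (!is.null(geometry)) mp_bbox(geometry) else NULL)
  class(z) <- "maritime_zone"
  z
}

#' Construct a validated zone layer
#'
#' Two kinds exist: `"country_partition"` (COUNTRY/ANTARCTIC/disputed zones
#' plus exactly one geometry-free HIGH_SEAS complement; zones must be
#' pairwise non-overlapping) and `"rfmo_overlay"` (RFMO zones restricted to
#' the high seas; overlaps between RFMO zones are legitimate and preserved).
#'
#' @param zones list of [maritime_zone()] objects.
#' @param layer_kind `"country_partition"` or `"rfmo_overlay"`.
#' @param check_overlap for country partitions, verify by deterministic
#'   point sampling that no two zones overlap beyond `overlap_tol`.
#' @param overlap_tol maximum tolerated overlapping fraction of the sphere
#'   (default `1e-3`).
#' @param n_check number of deterministic sample points used for the check.
#' @return a `zone_layer` object.
#' @export
zone_layer <- function(zones, layer_kind = c("country_partition", "rfmo_overlay"),
                       check_overlap = TRUE, overlap_tol = 1e-3, n_check = 2000L) {
  layer_kind <- match.arg(layer_kind)
  ids <- vapply(zones, `[[`, "", "zone_id")
  if (any(duplicated(ids))) stop("duplicate zone_id in layer")
  if (layer_kind == "country_partition") {
    lay <- vapply(zones, `[[`, "", "layer")
    if (any(lay == "RFMO")) stop("RFMO zones do not belong in a country partition")
    if (sum(lay == "HIGH_SEAS") != 1L) {
      zones <- c(zones, list(maritime_zone(HIGH_SEAS_ID, "HIGH_SEAS")))
      lay <- c(lay, "HIGH_SEAS")
    }
    if (check_overlap) {
      # ANTARCTIC membership overrides national claims by rule, so only
      # COUNTRY/disputed zones north of the cut-off can genuinely overlap
      geom <- zones[lay == "COUNTRY"]
      geom <- Filter(function(z) !is.null(z$geometry), geom)
      ant <- zones[lay == "ANTARCTIC"]
      ant_lat <- if (length(ant)) max(vapply(ant, function(z) z$bbox[["ymax"]], 0)) else -90
      if (length(geom) > 1L) {
        pts <- local_rng(770501L, sphere_sample(n_check))
        pts <- pts[pts$lat >= ant_lat, , drop = FALSE]
        hits <- integer(nrow(pts))
        for (z in geom) {
          hits <- hits + as.integer(zone_contains(z, pts$lon, pts$lat))
        }
        frac <- mean(hits > 1L)
        if (frac > overlap_tol) {
          stop(sprintf("country-partition zones overlap on ~%.2f%% of the sphere (tolerance %.2f%%)",
                       100 * frac, 100 * overlap_tol))
        }
      }
    }
  } else {
    lay <- vapply(zones, `[[`, "", "layer")
    if (!all(lay == "RFMO")) stop("rfmo_overlay may contain only RFMO zones")
  }
  obj <- list(zones = zones, layer_kind = layer_kind)
  class(obj) <- "zone_layer"
  obj
}

#' @export
print.zone_layer <- function(x, ...) {
  cat(sprintf("<zone_layer:%s> %d zones: %s\n", x$layer_kind, length(x$zones),
              paste(utils::head(vapply(x$zones, `[[`, "", "zone_id"), 8), collapse = ", ")))
  invisible(x)
}

#' Test whether points fall inside a zone's own geometry
#'
#' Raw geometric containment (bounding-box pre-filter plus winding-number
#' test). The high-seas complement has no geometry and always returns
#' `FALSE`; complement semantics live in [assign_days()].
#'
#' @param zone a [maritime_zone()].
#' @param lon,lat point coordinates (lon normalised).
#' @return logical vector.
#' @export
zone_contains <- function(zone, lon, lat) {
  if (is.null(zone$geometry)) return(logical(length(lon)))
  bb <- zone$bbox
  cand <- lon >= bb["xmin"] & lon <= bb["xmax"] & lat >= bb["ymin"] & lat <= bb["ymax"]
  out <- logical(length(lon))
  if (any(cand)) {
    out[cand] <- point_in_multipolygon(lon[cand], lat[cand], zone$geometry)
  }
  out
}

#' Find a zone by id within a layer
#' @param layer a [zone_layer()].
#' @param zone_id zone identifier.
#' @return the `maritime_zone`, or error if absent.
#' @export
layer_zone <- function(layer, zone_id) {
  for (z in layer$zones) if (z$zone_id == zone_id) return(z)
  stop("no zone '", zone_id, "' in layer")
}
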