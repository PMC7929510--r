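# Building the country/high-seas partition and the RFMO overlay, assigning
# daily positions to zones, and the disputed-sovereignty variants.

#' Build the country/high-seas partition layer
#'
#' Each sovereign country's zone is the union of the land and EEZ polygons of
#' the country itself and of all territories mapped to it; membership is
#' evaluated as "inside any constituent polygon", so no geometric dissolve is
#' performed. Areas south of `antarctic_lat` belong to a dedicated ANTARCTIC
#' zone that overrides any national claim there; everything else not covered
#' by a country polygon is the high seas.
#'
#' @param eez_features list of features, each a list with `territory`
#'   (name), `geometry` (multipolygon), and either `sovereign` or
#'   `claimants` (two or more ids mark a disputed area).
#' @param land_features like `eez_features`, for land polygons; may be empty
#'   when the EEZ product already includes land (unions are by territory
#'   name).
#' @param territory_map optional data.frame (`territory`, `sovereign`)
#'   aggregating dependencies under their sovereign; a feature with neither
#'   a sovereign, claimants, nor a map entry is an error.
#' @param antarctic_lat latitude (degrees) of the Antarctic cut-off
#'   (default -60).
#' @param ... passed to [zone_layer()].
#' @return a country-partition [zone_layer()] with attribute
#'   `antarctic_lat`.
#' @export
build_country_layer <- function(eez_features, land_features = list(),
                                territory_map = NULL, antarctic_lat = -60, ...) {
  feats <- c(eez_features, land_features)
  sov_of <- function(f) {
    if (!is.null(f$sovereign) && !is.na(f$sovereign)) return(f$sovereign)
    if (!is.null(territory_map)) {
      hit <- match(f$territory, territory_map$territory)
      if (!is.na(hit)) return(territory_map$sovereign[hit])
    }
    stop("territory '", f$territory, "' has no sovereign mapping")
  }
  by_sov <- list(); disputed <- list()
  for (f in feats) {
    cl <- f$claimants %||% character(0)
    if (length(cl) >= 2L) {
      key <- paste(sort(cl), collapse = "/")
      disputed[[key]] <- c(disputed[[key]], f$geometry)
    } else {
      s <- sov_of(f)
      by_sov[[s]] <- c(by_sov[[s]], f$geometry)
    }
  }
  zones <- lapply(names(by_sov), function(s) {
    maritime_zone(s, "COUNTRY", geometry = by_sov[[s]], sovereign = s)
  })
  zones <- c(zones, lapply(names(disputed), function(key) {
    maritime_zone(paste0("disputed - ", key), "COUNTRY", geometry = disputed[[key]],
                  claimants = strsplit(key, "/", fixed = TRUE)[[1]], disputed = TRUE)
  }))
  zones <- c(zones, list(
    maritime_zone(ANTARCTIC_ID, "ANTARCTIC",
                  geometry = rect_multipolygon(-180, 180, -90, antarctic_lat)),
    maritime_zone(HIGH_SEAS_ID, "HIGH_SEAS")))
  layer <- zone_layer(zones, "country_partition", ...)
  layer$antarctic_lat <- antarctic_lat
  layer
}

#' Build the RFMO overlay layer
#'
#' RFMO competence areas apply only to the high seas of the country layer.
#' Rather than computing polygon differences, the clip is enforced
#' functionally: [assign_days()] only attributes RFMO membership to
#' positions already assigned to the high seas. The effective (clipped)
#' area of each zone is estimated here by deterministic quasi-Monte-Carlo
#' sampling and stored as `high_seas_area_km2`; a zone entirely inside
#' national jurisdictions gets area 0 and a warning.
#'
#' @param rfmo_features list of features (`zone_id` or `territory` as name,
#'   `geometry` multipolygon).
#' @param country_layer the country partition from [build_country_layer()].
#' @param n_area_samples sample points per zone for the area estimate.
#' @return an rfmo-overlay [zone_layer()].
#' @export
build_rfmo_layer <- function(rfmo_features, country_layer, n_area_samples = 4000L) {
  zones <- lapply(rfmo_features, function(f) {
    id <- f$zone_id %||% f$territory
    maritime_zone(id, "RFMO", geometry = f$geometry)
  })
  for (i in seq_along(zones)) {
    a <- high_seas_clipped_area(zones[[i]], country_layer, n_area_samples)
    zones[[i]]$high_seas_area_km2 <- a
    if (a <= 0) warning("RFMO zone '", zones[[i]]$zone_id,
                        "' has no high-seas area after clipping")
  }
  zone_layer(zones, "rfmo_overlay")
}

#' Estimate the high-seas (clipped) area of a zone
#'
#' Deterministic area-uniform sampling of the zone's bounding box; the
#' returned value is the spherical bbox area times the fraction of points
#' that are both inside the zone and assigned to the high seas.
#'
#' @param zone a [maritime_zone()].
#' @param country_layer country partition.
#' @param n number of sample points.
#' @return area in km^2.
#' @export
high_seas_clipped_area <- function(zone, country_layer, n = 4000L) {
  bb <- zone$bbox
  pts <- local_rng(424243L, {
    lon <- stats::runif(n, bb["xmin"], bb["xmax"])
    s0 <- sin(bb["ymin"] * pi / 180); s1 <- sin(bb["ymax"] * pi / 180)
    lat <- asin(stats::runif(n, s0, s1)) * 180 / pi
    data.frame(lon = lon, lat = lat)
  })
  inside <- zone_contains(zone, pts$lon, pts$lat)
  if (!any(inside)) return(0)
  cz <- assign_country_zone(pts$lon[inside], pts$lat[inside], country_layer)
  to_rad <- pi / 180
  bb_area <- EARTH_RADIUS_KM^2 * (bb["xmax"] - bb["xmin"]) * to_rad *
    (sin(bb["ymax"] * to_rad) - sin(bb["ymin"] * to_rad))
  unname(bb_area * sum(cz == HIGH_SEAS_ID) / n)
}

# Country-layer assignment for bare coordinate vectors. Rules, in order:
# (1) south of the Antarctic cut-off -> ANTARCTIC; (2) inside one or more
# country/disputed polygons -> lexicographically smallest zone_id (boundary
# tie-break); (3) otherwise HIGH_SEAS.
assign_country_zone <- function(lon, lat, country_layer) {
  stopifnot(inherits(country_layer, "zone_layer"),
            country_layer$layer_kind == "country_partition")
  ant <- country_layer$antarctic_lat %||% -60
  zs <- Filter(function(z) z$layer %in% c("COUNTRY") && !is.null(z$geometry),
               country_layer$zones)
  ids <- vapply(zs, `[[`, "", "zone_id")
  ord <- order(ids)
  zs <- zs[ord]; ids <- ids[ord]
  out <- rep(HIGH_SEAS_ID, length(lon))
  todo <- lat >= ant
  out[!todo] <- ANTARCTIC_ID
  if (any(todo)) {
    res <- rep(NA_character_, sum(todo))
    lon_t <- lon[todo]; lat_t <- lat[todo]
    for (i in seq_along(zs)) {
      un <- is.na(res)
      if (!any(un)) break
      hit <- zone_contains(zs[[i]], lon_t[un], lat_t[un])
      res[which(un)[hit]] <- ids[i]
    }
    res[is.na(res)] <- HIGH_SEAS_ID
    out[todo] <- res
  }
  out
}

#' Assign daily positions to maritime zones
#'
#' Every position receives exactly one country-layer zone (the high seas
#' being the universal complement); positions in the high seas additionally
#' receive the identifiers of every RFMO competence area containing them
#' (competences overlap, so multi-assignment is deliberate and per-RFMO
#' totals are not additive).
#'
#' @param daily a `juris_daily` object (or any table with `lon`, `lat`).
#' @param country_layer country partition.
#' @param rfmo_layer optional RFMO overlay.
#' @return a `juris_assign` data.table: the input columns plus
#'   `country_zone` and `rfmo_zones` (`;`-joined, empty when none apply).
#' @export
assign_days <- function(daily, country_layer, rfmo_layer = NULL) {
  dt <- data.table::as.data.table(daily)
  dt[, country_zone := assign_country_zone(lon, lat, country_layer)]
  dt[, rfmo_zones := ""]
  if (!is.null(rfmo_layer)) {
    stopifnot(rfmo_layer$layer_kind == "rfmo_overlay")
    hs <- which(dt$country_zone == HIGH_SEAS_ID)
    if (length(hs)) {
      zs <- rfmo_layer$zones
      ids <- vapply(zs, `[[`, "", "zone_id")
      ord <- order(ids); zs <- zs[ord]; ids <- ids[ord]
      acc <- rep("", length(hs))
      for (i in seq_along(zs)) {
        hit <- zone_contains(zs[[i]], dt$lon[hs], dt$lat[hs])
        acc[hit] <- ifelse(nzchar(acc[hit]), paste0(acc[hit], ";", ids[i]), ids[i])
      }
      dt[hs, rfmo_zones := acc]
    }
  }
  data.table::setattr(dt, "class", c("juris_assign", "data.table", "data.frame"))
  dt
}

#' Assign a single position
#'
#' @param lon,lat coordinates of one daily position.
#' @inheritParams assign_days
#' @return list with `country_zone` (scalar) and `rfmo_zones` (character
#'   vector, possibly empty).
#' @export
assign_day <- function(lon, lat, country_layer, rfmo_layer = NULL) {
  r <- assign_days(data.table::data.table(lon = norm_lon(lon), lat = lat),
                   country_layer, rfmo_layer)
  list(country_zone = r$country_zone,
       rfmo_zones = if (nzchar(r$rfmo_zones)) strsplit(r$rfmo_zones, ";")[[1]] else character(0))
}

#' Enumerate sovereignty variants for disputed breeding areas
#'
#' Disputed zones hosting a tracked breeding colony force the analysis to be
#' run once per claimant side, with the colonies' origin country switched
#' between the two claimants. Without such colonies a single identity
#' variant is returned. Bilateral disputes only.
#'
#' @param country_layer country partition.
#' @param populations a [juris_populations()] table.
#' @return list of `sovereignty_variant` objects (`variant_id`, `mapping`:
#'   named character, disputed zone_id -> assigned sovereign).
#' @export
make_sovereignty_variants <- function(country_layer, populations) {
  disp <- Filter(function(z) isTRUE(z$disputed), country_layer$zones)
  hosting <- Filter(function(z) {
    any(zone_contains(z, populations$colony_lon, populations$colony_lat))
  }, disp)
  if (!length(hosting)) {
    v <- list(variant_id = "baseline", mapping = stats::setNames(character(0), character(0)))
    class(v) <- "sovereignty_variant"
    return(list(v))
  }
  bad <- Filter(function(z) length(z$claimants) != 2L, hosting)
  if (length(bad)) {
    stop("disputed zone with tracked colony must have exactly 2 claimants: ",
         paste(vapply(bad, `[[`, "", "zone_id"), collapse = ", "))
  }
  mk <- function(side) {
    mapping <- vapply(hosting, function(z) sort(z$claimants)[side], "")
    names(mapping) <- vapply(hosting, `[[`, "", "zone_id")
    v <- list(variant_id = paste0("claimant", side, ":",
                                  paste(unique(mapping), collapse = "+")),
              mapping = mapping)
    class(v) <- "sovereignty_variant"
    v
  }
  list(mk(1L), mk(2L))
}

#' Apply a sovereignty variant to the population table
#'
#' Populations whose colony lies inside a disputed zone named in the variant
#' mapping get that variant's sovereign as `origin_country`.
#'
#' @param populations a [juris_populations()] table.
#' @param country_layer country partition.
#' @param variant a `sovereignty_variant` from [make_sovereignty_variants()].
#' @return modified copy of `populations`.
#' @export
apply_variant <- function(populations, country_layer, variant) {
  out <- data.table::copy(data.table::as.data.table(populations))
  for (zid in names(variant$mapping)) {
    z <- layer_zone(country_layer, zid)
    inside <- zone_contains(z, out$colony_lon, out$colony_lat)
    out[inside, origin_country := variant$mapping[[zid]]]
  }
  juris_populations(out)
}
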