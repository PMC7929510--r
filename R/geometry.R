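# Spherical / planar geometry primitives used throughout the package.
#
# All geometries are stored in WGS84 decimal degrees with longitudes
# normalised to [-180, 180). Polygon edges are straight lines in (lon, lat)
# space ("plate carree" edges), matching how EEZ and RFMO boundary products
# are digitised; rings crossing the antimeridian must be split at read time
# (see split_antimeridian_ring()), after which all predicates are planar-safe.

#' Mean Earth radius (km) used for all great-circle and area computations
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Normalise longitudes to [-180, 180)
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector in `[-180, 180)`.
#' @export
norm_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius [EARTH_RADIUS_KM]. Vectorised and
#' recycled over the two point sets.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distances in km.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# ---------------------------------------------------------------------------
# Rings and multipolygons
#
# ring:          numeric matrix, columns (lon, lat), implicitly closed.
# polygon part:  list(outer = ring, holes = list(ring, ...))
# multipolygon:  list of parts
# ---------------------------------------------------------------------------

#' Build a rectangular (lon/lat-aligned) multipolygon
#'
#' Convenience constructor for box-shaped zones; used heavily by the
#' synthetic-world generator and tests.
#'
#' @param lon_min,lon_max,lat_min,lat_max box edges in degrees. `lon_min` may
#'   exceed `lon_max`, in which case the box wraps the antimeridian and is
#'   split into two parts.
#' @return a multipolygon (list of parts).
#' @export
rect_multipolygon <- function(lon_min, lon_max, lat_min, lat_max) {
  stopifnot(lat_min < lat_max)
  mk <- function(x0, x1) {
    list(outer = cbind(
      lon = c(x0, x1, x1, x0),
      lat = c(lat_min, lat_min, lat_max, lat_max)
    ), holes = list())
  }
  if (lon_min <= lon_max) {
    list(mk(lon_min, lon_max))
  } else {
    list(mk(lon_min, 180), mk(-180, lon_max))
  }
}

close_ring <- function(ring) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  if (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2]) {
    ring <- rbind(ring, ring[1, , drop = FALSE])
  }
  ring
}

open_ring <- function(ring) {
  n <- nrow(ring)
  if (n > 1L && ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) {
    ring <- ring[-n, , drop = FALSE]
  }
  ring
}

#' Winding number of points with respect to a ring
#'
#' Sunday's winding-number algorithm, vectorised over points. Nonzero winding
#' means "inside"; points exactly on an edge get an implementation-defined
#' (but deterministic) result, resolved at zone level by the boundary
#' tie-break rule.
#'
#' @param px,py point coordinates.
#' @param ring matrix of ring vertices (lon, lat), open or closed.
#' @return integer winding numbers, same length as `px`.
#' @keywords internal
ring_winding <- function(px, py, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  wn <- integer(length(px))
  x <- ring[, 1]; y <- ring[, 2]
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- (y1 <= py) & (y2 > py) & (is_left > 0)
    dn <- (y1 > py) & (y2 <= py) & (is_left < 0)
    wn <- wn + as.integer(up) - as.integer(dn)
  }
  wn
}

#' Point-in-multipolygon test
#'
#' A point is inside a part if it winds the outer ring and none of the holes;
#' inside the multipolygon if inside any part.
#'
#' @param px,py point coordinates in degrees (lon normalised to `[-180,180)`).
#' @param mp multipolygon.
#' @return logical vector.
#' @export
point_in_multipolygon <- function(px, py, mp) {
  inside <- logical(length(px))
  for (part in mp) {
    hit <- ring_winding(px, py, part$outer) != 0L
    if (any(hit) && length(part$holes)) {
      for (h in part$holes) {
        hit <- hit & (ring_winding(px, py, h) == 0L)
      }
    }
    inside <- inside | hit
  }
  inside
}

#' Bounding box of a multipolygon
#' @keywords internal
mp_bbox <- function(mp) {
  xs <- unlist(lapply(mp, function(p) p$outer[, 1]))
  ys <- unlist(lapply(mp, function(p) p$outer[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# ---------------------------------------------------------------------------
# Antimeridian handling
# ---------------------------------------------------------------------------

# Unwrap ring longitudes to a continuous sequence (successive deltas mapped
# into (-180, 180]) so that antimeridian crossings become excursions outside
# [-180, 180).
unwrap_lons <- function(lon) {
  d <- diff(lon)
  d <- ((d + 180) %% 360) - 180
  cumsum(c(lon[1], d))
}

# Sutherland-Hodgman clip of a ring against the half-plane x <= x0 (side = 1)
# or x >= x0 (side = -1). Exact for simple polygons; output may contain
# degenerate zero-width bridges, which are area- and membership-neutral.
clip_halfplane_x <- function(ring, x0, side = 1) {
  ring <- open_ring(ring)
  n <- nrow(ring)
  if (n < 3L) return(NULL)
  keep <- function(x) if (side > 0) x <= x0 else x >= x0
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    in1 <- keep(x1); in2 <- keep(x2)
    if (in1) { out_x <- c(out_x, x1); out_y <- c(out_y, y1) }
    if (in1 != in2) {
      t <- (x0 - x1) / (x2 - x1)
      out_x <- c(out_x, x0); out_y <- c(out_y, y1 + t * (y2 - y1))
    }
  }
  if (length(out_x) < 3L) return(NULL)
  cbind(lon = out_x, lat = out_y)
}

#' Split a ring crossing the antimeridian into rings within [-180, 180)
#'
#' Longitudes are unwrapped to a continuous sequence, the ring is clipped to
#' each 360-degree window it touches, and the pieces are shifted back into
#' `[-180, 180)`. Rings that do not cross are returned unchanged (as a
#' one-element list). Spherical area is preserved.
#'
#' @param ring matrix (lon, lat).
#' @return list of rings, each with longitudes in `[-180, 180)`.
#' @export
split_antimeridian_ring <- function(ring) {
  ring <- open_ring(ring)
  lon_u <- unwrap_lons(ring[, 1])
  ru <- cbind(lon = lon_u, lat = ring[, 2])
  lo <- floor((min(lon_u) + 180) / 360)
  hi <- floor((max(lon_u) - (-180)) / 360 - 1e-12)
  ks <- seq.int(lo, max(lo, hi))
  if (length(ks) == 1L && ks == 0) {
    return(list(cbind(lon = norm_lon(lon_u), lat = ring[, 2])))
  }
  out <- list()
  for (k in ks) {
    piece <- clip_halfplane_x(ru, k * 360 - 180, side = -1)
    if (!is.null(piece)) piece <- clip_halfplane_x(piece, k * 360 + 180, side = 1)
    if (!is.null(piece)) {
      piece[, 1] <- pmin(piece[, 1] - k * 360, 180 - 1e-9)
      piece[, 1] <- pmax(piece[, 1], -180)
      out <- c(out, list(piece))
    }
  }
  out
}

#' Split every ring of a multipolygon at the antimeridian
#' @param mp multipolygon.
#' @return multipolygon with all rings inside `[-180, 180)`.
#' @export
split_antimeridian <- function(mp) {
  out <- list()
  for (part in mp) {
    outers <- split_antimeridian_ring(part$outer)
    holes <- unlist(lapply(part$holes, split_antimeridian_ring), recursive = FALSE)
    if (is.null(holes)) holes <- list()
    for (o in outers) {
      bb <- range(o[, 1])
      hs <- Filter(function(h) min(h[, 1]) >= bb[1] - 1e-9 && max(h[, 1]) <= bb[2] + 1e-9, holes)
      out <- c(out, list(list(outer = o, holes = hs)))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Spherical area
# ---------------------------------------------------------------------------

# Signed spherical area (km^2) enclosed by a ring whose edges are straight in
# (lon, lat). By Green's theorem, area = R^2 * contour integral of sin(phi)
# d(lambda), which has the closed form below for edges linear in (lon, lat).
ring_area_signed_km2 <- function(ring) {
  ring <- close_ring(ring)
  to_rad <- pi / 180
  lam <- ring[, 1] * to_rad
  phi <- ring[, 2] * to_rad
  n <- nrow(ring) - 1L
  s <- 0
  for (i in seq_len(n)) {
    dl <- lam[i + 1L] - lam[i]
    dp <- phi[i + 1L] - phi[i]
    s <- s + if (abs(dp) < 1e-12) {
      dl * sin((phi[i] + phi[i + 1L]) / 2)
    } else {
      dl * (cos(phi[i]) - cos(phi[i + 1L])) / dp
    }
  }
  s * EARTH_RADIUS_KM^2
}

#' Spherical area of a multipolygon in square kilometres
#'
#' Exact for polygon edges that are straight in (lon, lat) space. Hole areas
#' are subtracted. Rings must not cross the antimeridian.
#'
#' @param mp multipolygon.
#' @return area in km^2.
#' @export
mp_area_km2 <- function(mp) {
  a <- 0
  for (part in mp) {
    a <- a + abs(ring_area_signed_km2(part$outer))
    for (h in part$holes) a <- a - abs(ring_area_signed_km2(h))
  }
  a
}

# ---------------------------------------------------------------------------
# Deterministic point sets on the sphere
# ---------------------------------------------------------------------------

#' Uniform random points on the sphere
#'
#' Area-uniform sampling (longitude uniform, sine-distributed latitude) using
#' the current RNG stream.
#'
#' @param n number of points.
#' @return data.frame with columns `lon`, `lat` in degrees.
#' @export
sphere_sample <- function(n) {
  lon <- stats::runif(n, -180, 180)
  lat <- asin(stats::runif(n, -1, 1)) * 180 / pi
  data.frame(lon = lon, lat = lat)
}
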