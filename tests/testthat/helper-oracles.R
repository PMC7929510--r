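# Independent oracles and small fixture builders shared across tests.

# Even-odd ray-casting point-in-polygon, written independently of the
# package's winding-number implementation (crossing count of a horizontal
# ray to +infinity).
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  if (ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_point_in_mp <- function(px, py, mp) {
  for (part in mp) {
    if (oracle_point_in_ring(px, py, part$outer)) {
      in_hole <- any(vapply(part$holes, function(h) oracle_point_in_ring(px, py, h), TRUE))
      if (!in_hole) return(TRUE)
    }
  }
  FALSE
}

# Spherical area of a lon/lat-aligned box (exact closed form), used as the
# independent area oracle for rectangles.
oracle_box_area_km2 <- function(lon_min, lon_max, lat_min, lat_max) {
  R <- 6371.0088
  to_rad <- pi / 180
  R^2 * (lon_max - lon_min) * to_rad * (sin(lat_max * to_rad) - sin(lat_min * to_rad))
}

# Two-country toy world: A (with an overseas dependency) and B, all boxes.
two_country_features <- function() {
  list(
    list(territory = "country_A", sovereign = "country_A",
         geometry = rect_multipolygon(-60, -20, 0, 30)),
    list(territory = "dependency_of_A", sovereign = NA,
         geometry = rect_multipolygon(0, 20, 0, 20)),
    list(territory = "country_B", sovereign = "country_B",
         geometry = rect_multipolygon(40, 80, -30, 10)))
}

two_country_layer <- function() {
  build_country_layer(
    two_country_features(),
    territory_map = data.frame(territory = "dependency_of_A", sovereign = "country_A"))
}

mp_to_geojson_test <- function(mp) juristrack:::mp_to_geojson(mp)

local_rng_test <- function(seed, expr) juristrack:::local_rng(seed, expr)

# Minimal hand-built assignment table: one row per (bird, day).
fake_assign <- function(bird, pop, sp, month, zone, ndays, start_day = 1L) {
  data.table::data.table(
    bird_id = bird, species_id = sp, population_id = pop, device = "GPS",
    local_day = as.Date("2015-01-01") + (start_day - 1L) + seq_len(ndays) - 1L,
    month = month, lon = 0, lat = 0, country_zone = zone, rfmo_zones = "")
}

# One shared mid-sized simulation for the expensive property tests (built
# once per test run; ~36k daily fixes).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(seed = 42L, gls_fraction = 0.4,
                                          ptt_fraction = 0.3))
    }
    cache
  }
})
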