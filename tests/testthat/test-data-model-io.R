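write_track_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "bird_id,species_id,population_id,device,timestamp,lon,lat"
  writeLines(c(header, rows), path)
  path
}

test_that("read_tracks parses, validates, and groups by bird", {
  p <- write_track_csv(c(
    "b1,sp1,pop1,GPS,2015-01-01T06:00:00,10,20",
    "b1,sp1,pop1,GPS,2015-01-01T12:00:00,11,21",
    "b1,sp1,pop1,GPS,2015-01-02T12:00:00,12,22"))
  tr <- read_tracks(p)
  expect_s3_class(tr, "juris_tracks")
  expect_equal(nrow(tr), 3L)
  expect_equal(data.table::uniqueN(tr$bird_id), 1L)
  expect_equal(nrow(attr(tr, "rejected")), 0L)

  # invalid rows are dropped and counted, not fatal
  p2 <- write_track_csv(c(
    "b1,sp1,pop1,GPS,2015-01-01T06:00:00,10,20",
    "b1,sp1,pop1,GPS,2015-01-02T06:00:00,10,95",
    "b1,sp1,pop1,GPS,not-a-time,10,20",
    "b1,sp1,pop1,TAG,2015-01-04T06:00:00,10,20"))
  tr2 <- read_tracks(p2)
  expect_equal(nrow(tr2), 1L)
  rej <- attr(tr2, "rejected")
  expect_equal(sum(rej$n), 3L)
  expect_setequal(rej$reason,
                  c("latitude out of bounds", "unparseable timestamp", "unknown device"))

  # interleaved birds come out as two time-sorted tracks
  p3 <- write_track_csv(c(
    "b2,sp1,pop1,PTT,2015-01-03T00:00:00,1,1",
    "b1,sp1,pop1,GPS,2015-01-02T00:00:00,2,2",
    "b2,sp1,pop1,PTT,2015-01-01T00:00:00,3,3",
    "b1,sp1,pop1,GPS,2015-01-04T00:00:00,4,4"))
  tr3 <- read_tracks(p3)
  expect_equal(data.table::uniqueN(tr3$bird_id), 2L)
  expect_true(all(tr3[, !is.unsorted(timestamp, strictly = TRUE), by = bird_id]$V1))
  expect_equal(tr3[bird_id == "b2", format(timestamp[1], "%d")], "01")

  # missing required column is a hard, named error
  bad <- tempfile(fileext = ".csv")
  writeLines(c("bird_id,species_id,population_id,device,timestamp,lon",
               "b1,sp1,pop1,GPS,2015-01-01,0"), bad)
  expect_error(read_tracks(bad), "lat")

  # schema remapping
  p4 <- tempfile(fileext = ".csv")
  writeLines(c("tag,sp,site,sensor,date_time,x,y",
               "b1,sp1,pop1,GLS,2015-01-01T12:00:00,5,6"), p4)
  tr4 <- read_tracks(p4, track_schema(bird_id = "tag", species_id = "sp",
                                      population_id = "site", device = "sensor",
                                      timestamp = "date_time", lon = "x", lat = "y"))
  expect_equal(tr4$lon, 5)
})

test_that("read_populations cross-references populations and species", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(
    "population_id,species_id,island_group,origin_country,colony_lon,colony_lat,n_p,n_s,biennial,known_breeding_countries",
    "p1,sp1,isl1,A,-40,15,100,300,FALSE,A;B",
    "p2,sp1,isl2,B,60,-10,150,300,FALSE,A;B",
    "p3,sp2,isl3,A,-45,18,50,80,TRUE,A"), p)
  ps <- read_populations(p)
  expect_equal(nrow(ps$populations), 3L)
  expect_equal(nrow(ps$species), 2L)
  expect_true(ps$species[species_id == "sp2", biennial])
  expect_equal(split_country_list(ps$species$known_breeding_countries)[[1]], c("A", "B"))

  # n_p = 0 rejected
  p0 <- sub("p3,sp2,isl3,A,-45,18,50", "p3,sp2,isl3,A,-45,18,0", readLines(p))
  f0 <- tempfile(fileext = ".csv"); writeLines(p0, f0)
  expect_error(read_populations(f0), "n_p")

  # sum(N_p) > N_s names the offending species
  p1 <- sub("p2,sp1,isl2,B,60,-10,150", "p2,sp1,isl2,B,60,-10,250", readLines(p))
  f1 <- tempfile(fileext = ".csv"); writeLines(p1, f1)
  expect_error(read_populations(f1), "sp1")

  # pairs-to-individuals doubling
  ps2 <- read_populations(p, pairs_to_individuals = TRUE)
  expect_equal(ps2$populations$n_p, c(200, 300, 100))
  expect_equal(ps2$species[species_id == "sp1", n_s], 600)
})

test_that("zone layers round-trip through GeoJSON with antimeridian splitting", {
  layer <- two_country_layer()
  f <- tempfile(fileext = ".geojson")
  write_zone_layer(layer, f)
  back <- read_zone_layer(f, "country_partition")
  expect_setequal(vapply(back$zones, `[[`, "", "zone_id"),
                  vapply(layer$zones, `[[`, "", "zone_id"))
  za <- layer_zone(back, "country_A")
  expect_equal(mp_area_km2(za$geometry), mp_area_km2(layer_zone(layer, "country_A")$geometry),
               tolerance = 1e-9)

  # two-country toy file gains the high-seas complement on read
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(zone_id = "country_A", layer = "COUNTRY", sovereign = "country_A"),
         geometry = mp_to_geojson_test(rect_multipolygon(-60, -20, 0, 30))),
    list(type = "Feature",
         properties = list(zone_id = "country_B", layer = "COUNTRY", sovereign = "country_B"),
         geometry = mp_to_geojson_test(rect_multipolygon(40, 80, -30, 10)))))
  f2 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f2, auto_unbox = TRUE, digits = NA)
  l2 <- read_zone_layer(f2, "country_partition")
  expect_length(l2$zones, 3L)
  expect_equal(sum(vapply(l2$zones, function(z) z$layer == "HIGH_SEAS", TRUE)), 1L)

  # a feature crossing the antimeridian is split on read, area preserved
  ring <- cbind(lon = c(170, -170, -170, 170), lat = c(-10, -10, 10, 10))
  gj3 <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(zone_id = "country_X", layer = "COUNTRY", sovereign = "country_X"),
         geometry = mp_to_geojson_test(list(list(outer = ring, holes = list()))))))
  f3 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj3, f3, auto_unbox = TRUE, digits = NA)
  l3 <- read_zone_layer(f3, "country_partition")
  zx <- layer_zone(l3, "country_X")
  expect_length(zx$geometry, 2L)
  expect_equal(mp_area_km2(zx$geometry), oracle_box_area_km2(170, 190, -10, 10),
               tolerance = 1e-6 * oracle_box_area_km2(170, 190, -10, 10))

  # overlapping country zones beyond tolerance are rejected
  bad <- list(
    list(territory = "A", sovereign = "A", geometry = rect_multipolygon(-20, 20, 0, 30)),
    list(territory = "B", sovereign = "B", geometry = rect_multipolygon(0, 40, 0, 30)))
  expect_error(build_country_layer(bad), "overlap")
})

test_that("write_outputs produces round-trippable CSVs", {
  occ <- data.table::data.table(
    population_id = "p1", species_id = "sp1", month = 1:2, zone_id = "A",
    mean_prop = c(0.123456789123, 1 / 3), n_m = 5L, T_spme = c(12.3456789, 1000 / 3))
  ann <- data.table::data.table(zone_id = c("A", "HIGH_SEAS"), T_e = c(1234.5678, 1 / 7))
  d <- tempfile()
  paths <- write_outputs(list(occupancy = occ, annual = ann), d)
  occ2 <- data.table::fread(file.path(d, "occupancy.csv"))
  ann2 <- data.table::fread(file.path(d, "annual_time.csv"))
  expect_equal(occ2$T_spme, occ$T_spme, tolerance = 1e-9)
  expect_equal(occ2$mean_prop, occ$mean_prop, tolerance = 1e-9)
  expect_equal(ann2$T_e, ann$T_e, tolerance = 1e-9)
  expect_named(occ2, c("population_id", "month", "zone_id", "mean_prop",
                       "n_individuals", "T_spme"))
})

test_that("country-partition zones cover the sphere with no gaps", {
  layer <- two_country_layer()
  pts <- local({
    set.seed(7)
    sphere_sample(10000)
  })
  cz <- assign_days(data.table::data.table(lon = pts$lon, lat = pts$lat), layer)$country_zone
  expect_equal(sum(is.na(cz)), 0L)
  expect_true(all(nzchar(cz)))
})
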