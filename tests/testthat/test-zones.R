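test_that("country layer unions dependencies under their sovereign", {
  layer <- two_country_layer()
  ids <- vapply(layer$zones, `[[`, "", "zone_id")
  expect_setequal(ids, c("country_A", "country_B", "ANTARCTIC", "HIGH_SEAS"))
  # dependency box (0..20, 0..20) answers to country_A
  expect_equal(assign_day(10, 10, layer)$country_zone, "country_A")
  expect_equal(assign_day(-40, 15, layer)$country_zone, "country_A")
  expect_equal(assign_day(60, -10, layer)$country_zone, "country_B")
  expect_equal(assign_day(120, 0, layer)$country_zone, "HIGH_SEAS")
  # unmapped territory is a hard error
  expect_error(build_country_layer(list(
    list(territory = "orphan", geometry = rect_multipolygon(0, 10, 0, 10)))),
    "sovereign")
})

test_that("Antarctic rule overrides nominal claims south of the cut-off", {
  feats <- c(two_country_features(), list(
    list(territory = "claim_S", sovereign = "country_B",
         geometry = rect_multipolygon(100, 120, -80, -65))))
  layer <- build_country_layer(
    feats, territory_map = data.frame(territory = "dependency_of_A", sovereign = "country_A"))
  expect_equal(assign_day(110, -70, layer)$country_zone, "ANTARCTIC")
  expect_equal(assign_day(0, -75, layer)$country_zone, "ANTARCTIC")
})

test_that("disputed zones are named by sorted claimants and drive variants", {
  feats <- c(two_country_features(), list(
    list(territory = "rocks", claimants = c("country_B", "country_A"),
         geometry = rect_multipolygon(25, 35, 5, 15))))
  layer <- build_country_layer(
    feats, territory_map = data.frame(territory = "dependency_of_A", sovereign = "country_A"))
  ids <- vapply(layer$zones, `[[`, "", "zone_id")
  expect_true("disputed - country_A/country_B" %in% ids)
  expect_equal(assign_day(30, 10, layer)$country_zone, "disputed - country_A/country_B")

  pops <- juris_populations(data.frame(
    population_id = c("pd", "pa"), species_id = "sp1", island_group = c("ig1", "ig2"),
    origin_country = c("country_A", "country_A"),
    colony_lon = c(30, -40), colony_lat = c(10, 15), n_p = c(10, 10)))
  vs <- make_sovereignty_variants(layer, pops)
  expect_length(vs, 2L)
  p1 <- apply_variant(pops, layer, vs[[1]])
  p2 <- apply_variant(pops, layer, vs[[2]])
  expect_equal(p1[population_id == "pd", origin_country], "country_A")
  expect_equal(p2[population_id == "pd", origin_country], "country_B")
  # non-disputed colony untouched
  expect_equal(p2[population_id == "pa", origin_country], "country_A")

  # no disputed colonies: a single identity variant
  vs0 <- make_sovereignty_variants(two_country_layer(), pops[2])
  expect_length(vs0, 1L)
  expect_equal(vs0[[1]]$variant_id, "baseline")

  # >2 claimants hosting a colony is unsupported
  feats3 <- c(two_country_features(), list(
    list(territory = "rocks3", claimants = c("country_A", "country_B", "country_C"),
         geometry = rect_multipolygon(25, 35, 5, 15))))
  layer3 <- build_country_layer(
    feats3, territory_map = data.frame(territory = "dependency_of_A", sovereign = "country_A"))
  expect_error(make_sovereignty_variants(layer3, pops), "2 claimants")
})

test_that("RFMO layer is functionally clipped to the high seas", {
  layer <- two_country_layer()
  # half inside country_B's box (40..80, -30..10): high-seas half only
  rfmo <- list(list(zone_id = "rfmo_half", geometry = rect_multipolygon(60, 100, -30, 10)))
  rl <- build_rfmo_layer(rfmo, layer)
  z <- layer_zone(rl, "rfmo_half")
  full <- oracle_box_area_km2(60, 100, -30, 10)
  expect_lt(abs(z$high_seas_area_km2 - full / 2), 0.05 * full)
  # assignment: a point in the EEZ half gets no RFMO, the high-seas half does
  expect_equal(assign_day(70, 0, layer, rl)$rfmo_zones, character(0))
  expect_equal(assign_day(90, 0, layer, rl)$rfmo_zones, "rfmo_half")

  # overlapping RFMOs are both retained and multi-assigned
  rl2 <- build_rfmo_layer(list(
    list(zone_id = "rfmo_1", geometry = rect_multipolygon(90, 130, -40, 0)),
    list(zone_id = "rfmo_2", geometry = rect_multipolygon(110, 150, -40, 0))), layer)
  a <- assign_day(120, -20, layer, rl2)
  expect_equal(a$country_zone, "HIGH_SEAS")
  expect_equal(a$rfmo_zones, c("rfmo_1", "rfmo_2"))

  # an RFMO wholly inside EEZs has zero area and warns
  expect_warning(
    rl3 <- build_rfmo_layer(list(
      list(zone_id = "rfmo_dry", geometry = rect_multipolygon(45, 55, -20, 0))), layer),
    "no high-seas area")
  expect_equal(layer_zone(rl3, "rfmo_dry")$high_seas_area_km2, 0)

  # clipping conservation: clipped area never exceeds the input area
  for (z in rl2$zones) expect_lte(z$high_seas_area_km2, mp_area_km2(z$geometry) * 1.05)
})

test_that("country partition assigns every point exactly once", {
  sim <- shared_sim()
  layer <- sim$world$country_layer
  pts <- local({ set.seed(99); sphere_sample(10000) })
  cz <- assign_days(data.table::data.table(lon = pts$lon, lat = pts$lat), layer)$country_zone
  expect_equal(sum(is.na(cz) | !nzchar(cz)), 0L)

  # no point north of the Antarctic cut-off sits in two country polygons
  north <- pts[pts$lat >= layer$antarctic_lat, ]
  geom_zones <- Filter(function(z) z$layer == "COUNTRY", layer$zones)
  hits <- Reduce(`+`, lapply(geom_zones, function(z)
    as.integer(zone_contains(z, north$lon, north$lat))))
  expect_equal(sum(hits > 1L), 0L)
  # and assignment agrees with raw membership everywhere
  expect_equal(sum((hits >= 1L) != (assign_days(
    data.table::data.table(lon = north$lon, lat = north$lat), layer)$country_zone
    %in% vapply(geom_zones, `[[`, "", "zone_id"))), 0L)
})

test_that("zone assignment matches the ray-casting oracle", {
  sim <- shared_sim()
  layer <- sim$world$country_layer
  pts <- local({ set.seed(1234); sphere_sample(1000) })
  geom_zones <- Filter(function(z) !is.null(z$geometry), layer$zones)
  for (z in geom_zones) {
    got <- zone_contains(z, pts$lon, pts$lat)
    want <- vapply(seq_len(nrow(pts)), function(i)
      oracle_point_in_mp(pts$lon[i], pts$lat[i], z$geometry), TRUE)
    expect_identical(got, want)
  }
})
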