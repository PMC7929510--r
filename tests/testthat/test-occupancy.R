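test_that("monthly proportions average individual day shares (Eq. 1 core)", {
  # one bird: 10 of 31 January days in the high seas
  a <- rbind(fake_assign("b1", "p1", "sp1", 1L, "HIGH_SEAS", ndays = 10L),
             fake_assign("b1", "p1", "sp1", 1L, "country_A", ndays = 21L, start_day = 11L))
  pops <- juris_populations(data.frame(
    population_id = "p1", species_id = "sp1", island_group = "i", origin_country = "country_A",
    colony_lon = 0, colony_lat = 10, n_p = 66080))
  occ <- monthly_proportions(a, pops)
  hs <- occ[zone_id == "HIGH_SEAS"]
  expect_equal(hs$mean_prop, 10 / 31, tolerance = 1e-12)
  expect_equal(round(100 * hs$mean_prop), 32)
  expect_equal(occ[, sum(mean_prop), by = month]$V1, 1)

  # all days in one zone
  a1 <- fake_assign("b9", "p1", "sp1", 2L, "country_A", ndays = 28L, start_day = 32L)
  occ1 <- monthly_proportions(a1, pops)
  expect_equal(occ1$mean_prop, 1)

  # two individuals with proportions 0.2 and 0.4 average to 0.3
  a2 <- rbind(
    fake_assign("b1", "p1", "sp1", 1L, "HIGH_SEAS", ndays = 2L),
    fake_assign("b1", "p1", "sp1", 1L, "country_A", ndays = 8L, start_day = 3L),
    fake_assign("b2", "p1", "sp1", 1L, "HIGH_SEAS", ndays = 4L),
    fake_assign("b2", "p1", "sp1", 1L, "country_A", ndays = 6L, start_day = 5L))
  occ2 <- monthly_proportions(a2, pops)
  expect_equal(occ2[zone_id == "HIGH_SEAS", mean_prop], 0.3, tolerance = 1e-12)
  expect_equal(occ2[zone_id == "HIGH_SEAS", n_m], 2L)
  expect_equal(occ2[zone_id == "HIGH_SEAS", T_spme], 0.3 * 66080, tolerance = 1e-9)
})

test_that("extrapolation to bird-months needs unrounded means", {
  expect_equal(population_monthly_time(0.5, 100), 50)
  expect_equal(population_monthly_time(0, 100), 0)
  # a mean printed as 17% reproduces the published 11,284 bird-months only
  # when carried unrounded: the rounded mean gives 11,233.6
  expect_equal(population_monthly_time(0.17, 66080), 11233.6)
  expect_false(isTRUE(all.equal(population_monthly_time(0.17, 66080), 11284)))
})

test_that("annual time divides by 12, not by months tracked (Eq. 2)", {
  mk_occ <- function(months, prop, np, pop = "p1", zone = "Z") {
    occ <- data.table::data.table(
      population_id = pop, species_id = "sp1", month = months, zone_id = zone,
      mean_prop = prop, n_m = 3L, T_spme = prop * np)
    data.table::setattr(occ, "class", c("juris_occupancy", "data.table", "data.frame"))
    occ
  }
  expect_equal(annual_time(mk_occ(1:12, 0.5, 1000))$T_e, 500)
  expect_equal(annual_time(mk_occ(1:6, 1.0, 1200))$T_e, 600)
  # per-population bird-month sums for one zone combine additively
  occ3 <- rbind(mk_occ(1:12, 1, 1), mk_occ(1:12, 1, 1, pop = "p2"))
  data.table::setattr(occ3, "class", c("juris_occupancy", "data.table", "data.frame"))
  out <- annual_time(occ3)
  expect_equal(out$T_e, 2)
  expect_equal(attr(out, "by_population")$bird_years, c(1, 1))
})

test_that("time-spent conservation holds end to end on synthetic data", {
  sim <- shared_sim()
  daily <- sim$true_daily
  mask <- representativeness_mask(daily)
  a <- assign_days(daily, sim$world$country_layer)
  occ <- monthly_proportions(a, sim$populations, mask = mask)
  # per population-month the country-layer proportions sum to exactly 1
  sums <- occ[, sum(mean_prop), by = .(population_id, month)]
  expect_equal(sums$V1, rep(1, nrow(sums)), tolerance = 1e-12)
  # sum of T_e equals sum_p N_p * months_covered / 12
  te <- annual_time(occ)
  mc <- months_covered(mask)
  pops <- merge(data.table::as.data.table(sim$populations), mc, by = "population_id")
  expect_equal(sum(te$T_e), pops[, sum(n_p * months_covered / 12)], tolerance = 1e-9)
})

test_that("adding a tracked month never decreases totals or coverage", {
  pops <- juris_populations(data.frame(
    population_id = "p1", species_id = "sp1", island_group = "i", origin_country = "A",
    colony_lon = 0, colony_lat = 10, n_p = 120))
  sp <- juris_species(data.frame(species_id = "sp1", n_s = 240), pops)
  a_few <- rbind(fake_assign("b1", "p1", "sp1", 1L, "A", 15L),
                 fake_assign("b1", "p1", "sp1", 2L, "HIGH_SEAS", 15L, start_day = 32L))
  a_more <- rbind(a_few, fake_assign("b1", "p1", "sp1", 3L, "A", 15L, start_day = 61L))
  run <- function(a) {
    m <- representativeness_mask(a)
    list(te = annual_time(monthly_proportions(a, pops, mask = m)),
         cov = coverage_table(pops, sp, m, daily = a))
  }
  r1 <- run(a_few); r2 <- run(a_more)
  expect_gt(sum(r2$te$T_e), sum(r1$te$T_e))
  expect_gt(r2$cov$pct_year_known, r1$cov$pct_year_known)
})

test_that("richness categories are disjoint and follow origin semantics", {
  pops <- juris_populations(data.frame(
    population_id = c("pA", "pB"), species_id = c("sp1", "sp1"),
    island_group = c("iA", "iB"), origin_country = c("A", "B"),
    colony_lon = 0, colony_lat = 0, n_p = 10))
  # sp1 breeds in A and B; the B-origin birds visit A's waters
  a <- rbind(fake_assign("a1", "pA", "sp1", 1L, "A", 10L),
             fake_assign("b1", "pB", "sp1", 1L, "A", 10L),
             fake_assign("b1", "pB", "sp1", 2L, "HIGH_SEAS", 10L, start_day = 32L))
  r <- richness_by_zone(a, pops)
  expect_equal(r[zone_id == "A", both], "sp1")
  expect_equal(r[zone_id == "A", n_total], 1L)
  # B hosts breeding sp1 (tracked pop pB) but no visits from elsewhere
  expect_equal(r[zone_id == "B", breeding_only], "sp1")
  # the high seas never host breeding: presence is visiting
  expect_equal(r[zone_id == "HIGH_SEAS", visiting_only], "sp1")

  # a species tracked only in its own country is breeding-only there
  pops1 <- juris_populations(data.frame(
    population_id = "pA", species_id = "sp9", island_group = "i", origin_country = "A",
    colony_lon = 0, colony_lat = 0, n_p = 5))
  r1 <- richness_by_zone(fake_assign("x1", "pA", "sp9", 1L, "A", 5L), pops1)
  expect_equal(r1[zone_id == "A", breeding_only], "sp9")
  expect_equal(r1[zone_id == "A", n_visiting_only + n_both], 0L)

  # disjointness on the shared simulation
  sim <- shared_sim()
  a2 <- assign_days(sim$true_daily, sim$world$country_layer)
  rs <- richness_by_zone(a2, sim$populations)
  splits <- rs[, .(ok = {
    s <- c(strsplit(breeding_only, ";")[[1]], strsplit(visiting_only, ";")[[1]],
           strsplit(both, ";")[[1]])
    !anyDuplicated(s[nzchar(s)])
  }), by = zone_id]
  expect_true(all(splits$ok))
})

test_that("breeding-richness underestimation is quantified per country", {
  pops <- juris_populations(data.frame(
    population_id = "pA", species_id = "sp1", island_group = "i", origin_country = "A",
    colony_lon = 0, colony_lat = 0, n_p = 5))
  rich <- richness_by_zone(fake_assign("x", "pA", "sp1", 1L, "A", 10L), pops)
  sp <- juris_species(data.frame(
    species_id = c("sp1", "sp2", "sp3"), n_s = 10,
    known_breeding_countries = c("A;B", "A", "A")))
  out <- richness_underestimation(rich, sp)
  expect_equal(out[country == "A", known], 3L)
  expect_equal(out[country == "A", tracked], 1L)
  expect_equal(out[country == "A", delta], 2L)
  expect_equal(out[country == "B", delta], 1L)

  # full tracking: delta 0
  sp0 <- juris_species(data.frame(species_id = "sp1", n_s = 10,
                                  known_breeding_countries = "A"))
  expect_equal(richness_underestimation(rich, sp0)$delta, 0L)

  # inconsistent data (tracked breeder not in the known list) errors
  spX <- juris_species(data.frame(species_id = c("sp1", "spZ"), n_s = 10,
                                  known_breeding_countries = c("B", "B")))
  expect_error(richness_underestimation(rich, spX), "known")

  # 22-country synthetic audit with mean deficit 1.0 (deltas alternate 0, 2)
  deltas <- rep(c(0L, 2L), length.out = 22L)
  countries <- sprintf("C%02d", 1:22)
  max_k <- 3L
  sp_rows <- list(); rich_rows <- list(); pop_rows <- list()
  sid <- 0L
  for (i in seq_along(countries)) {
    known_k <- deltas[i] + 1L # 1..3 known species, tracked = known - delta = 1
    ids <- sprintf("sp%03d", sid + seq_len(known_k)); sid <- sid + known_k
    sp_rows[[i]] <- data.frame(species_id = ids, n_s = 10,
                               known_breeding_countries = countries[i])
    pop_rows[[i]] <- data.frame(population_id = paste0("p", ids[1]), species_id = ids[1],
                                island_group = "i", origin_country = countries[i],
                                colony_lon = 0, colony_lat = 0, n_p = 5)
  }
  pops22 <- juris_populations(do.call(rbind, pop_rows))
  sp22 <- juris_species(do.call(rbind, sp_rows), pops22)
  assign22 <- data.table::rbindlist(lapply(seq_len(nrow(pops22)), function(i)
    fake_assign(paste0("b", i), pops22$population_id[i], pops22$species_id[i], 1L,
                pops22$origin_country[i], 10L)))
  rich22 <- richness_by_zone(assign22, pops22)
  out22 <- richness_underestimation(rich22, sp22)
  expect_equal(nrow(out22), 22L)
  expect_equal(attr(out22, "mean_delta"), 1.0, tolerance = 1e-12)
  expect_equal(out22$delta, deltas[order(countries)])
})

test_that("coverage table reproduces the population-year identities", {
  pops <- juris_populations(data.frame(
    population_id = c("p1", "p2"), species_id = c("spA", "spB"),
    island_group = "i", origin_country = "A",
    colony_lon = 0, colony_lat = 0, n_p = c(1000, 78)))
  sp <- juris_species(data.frame(species_id = c("spA", "spB", "spC"),
                                 n_s = c(1000, 100, 500)))
  # spA tracked all 12 months; spB 8 of 12 months; spC untracked
  a <- data.table::rbindlist(c(
    lapply(1:12, function(m) fake_assign("b1", "p1", "spA", m, "A", 12L,
                                         start_day = (m - 1L) * 30L + 1L)),
    lapply(1:8, function(m) fake_assign("b2", "p2", "spB", m, "A", 12L,
                                        start_day = (m - 1L) * 30L + 1L))))
  mask <- representativeness_mask(a)
  cov <- coverage_table(pops, sp, mask, daily = a)
  expect_equal(unlist(cov[species_id == "spA", .(pct_pop, pct_year_known, pct_year_unknown)]),
               c(pct_pop = 100, pct_year_known = 100, pct_year_unknown = 0))
  expect_equal(cov[species_id == "spB", pct_pop], 78)
  expect_equal(cov[species_id == "spB", pct_year_known], 78 * 8 / 12)
  expect_equal(cov[species_id == "spB", pct_year_known], 52)
  expect_equal(unlist(cov[species_id == "spC", .(pct_pop, pct_year_known, pct_year_unknown)]),
               c(pct_pop = 0, pct_year_known = 0, pct_year_unknown = 100))
  expect_equal(cov$pct_year_unknown, 100 - cov$pct_year_known)
  expect_true(all(cov$pct_year_known <= cov$pct_pop + 1e-12))
})
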