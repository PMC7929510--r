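# Synthetic worlds, populations, and tracks with known ground-truth
# occupancy. The movement model is a stand-in (central-place breeding
# scatter, waypoint migration into the high seas, return to the colony)
# tuned so that monthly zone mixes are nondegenerate; it makes no claim of
# behavioural realism.

KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180

#' Simulation configuration
#'
#' Defaults describe the stated world of the package's validation suite: a
#' breeding year of daily positions (365 days), geolocator error of SD 186
#' km for GLS birds, EEZ-scale country zones, and RFMO boxes confined to
#' the high seas with a deliberate overlap.
#'
#' @param seed integer seed; everything downstream is a pure function of the
#'   config including this seed.
#' @param n_countries,n_rfmos,n_species world dimensions.
#' @param pops_per_species breeding populations per species (spread over
#'   distinct countries).
#' @param n_p_range range of breeding-population sizes (individuals); every
#'   individual is simulated.
#' @param untracked_n_s_factor global population `n_s` = factor * sum of the
#'   species' `n_p` (1 = the whole species is in the dataset).
#' @param study_days tracking days per bird (365 = one breeding year).
#' @param start_date first tracking day.
#' @param breeding_frac fraction of the study spent central-place foraging
#'   at the colony before migration.
#' @param trip_radius_km scatter (SD) of breeding-phase positions around
#'   the colony.
#' @param step_noise_km daily positional jitter (SD) along the migration
#'   path.
#' @param gls_fraction,ptt_fraction device mix (remainder GPS).
#' @param gls_error_km SD of the isotropic position error added to reported
#'   GLS positions (default 186).
#' @param disputed add a disputed zone with two claimants between the first
#'   two countries.
#' @param country_width_deg longitudinal width of each country box in
#'   degrees (default: 60% of the per-country longitude slot, capped at 40);
#'   used by sensitivity analyses that vary zone size.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_countries = 3L, n_rfmos = 2L, n_species = 2L,
                       pops_per_species = 2L, n_p_range = c(18L, 30L),
                       untracked_n_s_factor = 1, study_days = 365L,
                       start_date = as.Date("2015-01-01"), breeding_frac = 0.41,
                       trip_radius_km = 300, step_noise_km = 60,
                       gls_fraction = 0.5, ptt_fraction = 0.25,
                       gls_error_km = 186, disputed = FALSE,
                       country_width_deg = NULL) {
  stopifnot(n_countries >= 1L, n_rfmos >= 1L, n_species >= 1L,
            gls_error_km >= 0, study_days >= 30L,
            pops_per_species >= 1L, pops_per_species <= n_countries)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy world: country partition plus RFMO overlay
#'
#' Countries are lon/lat boxes in a northern band (5-40 deg N) partitioning
#' part of the globe, with the high seas as complement; RFMO competence
#' boxes sit in a southern band (-45 to -5 deg) wholly in the high seas and
#' adjacent boxes deliberately overlap. Optionally a disputed box with two
#' claimants lies between the first two countries. Pure function of the
#' config.
#'
#' @param config a [sim_config()].
#' @return list with `country_layer` and `rfmo_layer` ([zone_layer()]s).
#' @export
make_world <- function(config) {
  nc <- config$n_countries
  slot <- 360 / nc
  width <- config$country_width_deg %||% min(40, slot * 0.6)
  if (width >= slot) stop("country zones would overlap: reduce country_width_deg")
  eez <- lapply(seq_len(nc), function(i) {
    id <- paste0("country_", LETTERS[i])
    lon0 <- -180 + (i - 1) * slot + (slot - width) / 2
    list(territory = id, sovereign = id,
         geometry = rect_multipolygon(lon0, lon0 + width, 5, 40))
  })
  if (config$disputed) {
    if (nc < 2L) stop("a disputed zone needs at least 2 countries")
    a <- eez[[1]]$geometry[[1]]$outer
    gap0 <- max(a[, "lon"]) + 2
    eez <- c(eez, list(list(
      territory = "disputed", claimants = c("country_A", "country_B"),
      geometry = rect_multipolygon(gap0, min(gap0 + 8, -180 + slot), 10, 35))))
  }
  country_layer <- build_country_layer(eez, antarctic_lat = -60)
  nr <- config$n_rfmos
  rslot <- 360 / nr
  rwidth <- if (nr > 1L) min(rslot * 1.3, 350) else 120
  rfmo <- lapply(seq_len(nr), function(i) {
    lon0 <- norm_lon(-180 + (i - 1) * rslot)
    list(zone_id = paste0("rfmo_", i),
         geometry = rect_multipolygon(lon0, norm_lon(lon0 + rwidth), -45, -5))
  })
  rfmo_layer <- suppressWarnings(build_rfmo_layer(rfmo, country_layer))
  list(country_layer = country_layer, rfmo_layer = rfmo_layer)
}

#' Generate breeding populations and species for a toy world
#'
#' Each species gets `pops_per_species` populations in distinct countries
#' (cycling over countries), colonies placed near the country centre, and
#' population sizes drawn from `n_p_range`. `n_s` is the species' summed
#' `n_p` times `untracked_n_s_factor`.
#'
#' @param config a [sim_config()].
#' @param world from [make_world()].
#' @return list with `populations` and `species`.
#' @export
make_populations <- function(config, world) {
  local_rng(config$seed + 1L, {
    rows <- list(); k <- 0L
    for (s in seq_len(config$n_species)) {
      sp <- paste0("species_", s)
      for (j in seq_len(config$pops_per_species)) {
        k <- k + 1L
        ci <- ((s - 1L) * config$pops_per_species + j - 1L) %% config$n_countries + 1L
        cid <- paste0("country_", LETTERS[ci])
        z <- layer_zone(world$country_layer, cid)
        bb <- z$bbox
        rows[[k]] <- data.frame(
          population_id = paste0("pop_", sp, "_", cid),
          species_id = sp, island_group = paste0("isles_", k),
          origin_country = cid,
          colony_lon = mean(bb[c("xmin", "xmax")]) + stats::runif(1, -3, 3),
          colony_lat = mean(bb[c("ymin", "ymax")]) + stats::runif(1, -3, 3),
          n_p = sample(seq(config$n_p_range[1], config$n_p_range[2]), 1L))
      }
    }
    pops <- juris_populations(do.call(rbind, rows))
    spt <- data.table::as.data.table(pops)[
      , .(n_s = sum(n_p) * config$untracked_n_s_factor,
          known_breeding_countries = paste(sort(unique(origin_country)), collapse = ";")),
      by = species_id]
    spt[, biennial := FALSE]
    list(populations = pops, species = juris_species(spt, populations = pops))
  })
}

# Daily path of one bird: colony residence, outbound transit to a wintering
# waypoint in the southern high seas, dwell, and return. Linear anchors in
# (lon, lat) with Gaussian daily jitter.
simulate_bird_path <- function(days, colony_lon, colony_lat, wp_lon, wp_lat,
                               breeding_frac, noise_km, trip_radius_km = 0) {
  f <- pmin(cumsum(c(breeding_frac, 0.12, 0.35, 0.12)), 1)
  anchors_d <- pmin(c(1, round(f * days)), days)
  anchors_d[length(anchors_d)] <- days
  anchors_d <- cummax(anchors_d)
  lons <- c(colony_lon, colony_lon, wp_lon, wp_lon, colony_lon)
  lats <- c(colony_lat, colony_lat, wp_lat, wp_lat, colony_lat)
  d <- seq_len(days)
  lon <- stats::approx(anchors_d, lons, xout = d, rule = 2, ties = "ordered")$y
  lat <- stats::approx(anchors_d, lats, xout = d, rule = 2, ties = "ordered")$y
  # central-place foraging scatter while resident at the colony or the
  # wintering waypoint; transit days carry only the path noise
  dwell <- d <= anchors_d[2] | (d >= anchors_d[3] & d <= anchors_d[4])
  sd_day <- sqrt(noise_km^2 + ifelse(dwell, (trip_radius_km / 2)^2, 0))
  lat_j <- lat + stats::rnorm(days, 0, 1) * sd_day / KM_PER_DEG
  lon_j <- lon + stats::rnorm(days, 0, 1) * sd_day / (KM_PER_DEG * pmax(0.2, cos(lat * pi / 180)))
  cbind(lon = norm_lon(lon_j), lat = pmin(89.9, pmax(-89.9, lat_j)))
}

#' Simulate a complete tracking study with known ground truth
#'
#' Builds the world and populations from the config, simulates every
#' individual of every population daily for the study period, records true
#' daily positions, and produces reported tracks in which GLS birds carry
#' isotropic Gaussian position error (SD `gls_error_km`; PTT/GPS exact).
#' Byte-identical across runs with the same config.
#'
#' @param config a [sim_config()].
#' @return a `juris_sim` list: `config`, `world`, `populations`, `species`,
#'   `tracks` (reported, [juris_tracks()]), `true_daily` (error-free
#'   `juris_daily`), and `truth` (list with ground-truth `occupancy` and
#'   `annual` country-layer tables computed from the true positions of all
#'   individuals).
#' @export
simulate_study <- function(config = sim_config()) {
  world <- make_world(config)
  ps <- make_populations(config, world)
  pops <- data.table::as.data.table(ps$populations)
  days <- config$study_days
  dates <- config$start_date + seq_len(days) - 1L
  ts <- as.POSIXct(paste(dates, "12:00:00"), tz = "UTC")
  rows <- local_rng(config$seed + 2L, {
    lapply(seq_len(nrow(pops)), function(pi) {
      p <- pops[pi]
      wp_lon0 <- p$colony_lon + stats::runif(1, -25, 25)
      wp_lat0 <- stats::runif(1, -38, -18)
      n <- p$n_p
      dev <- sample(c("GLS", "PTT", "GPS"), n, replace = TRUE,
                    prob = c(config$gls_fraction, config$ptt_fraction,
                             max(0, 1 - config$gls_fraction - config$ptt_fraction)))
      data.table::rbindlist(lapply(seq_len(n), function(b) {
        path <- simulate_bird_path(
          days, p$colony_lon, p$colony_lat,
          wp_lon0 + stats::rnorm(1, 0, 100) / KM_PER_DEG,
          wp_lat0 + stats::rnorm(1, 0, 100) / KM_PER_DEG,
          config$breeding_frac, config$step_noise_km, config$trip_radius_km)
        data.table::data.table(
          bird_id = sprintf("%s_b%03d", p$population_id, b),
          species_id = p$species_id, population_id = p$population_id,
          device = dev[b], timestamp = ts,
          lon = path[, "lon"], lat = path[, "lat"])
      }))
    })
  })
  true_dt <- data.table::rbindlist(rows)
  reported <- local_rng(config$seed + 3L, {
    out <- data.table::copy(true_dt)
    g <- out$device == "GLS"
    if (any(g) && config$gls_error_km > 0) {
      err <- perturb_positions(out$lon[g], out$lat[g], config$gls_error_km)
      out[g, `:=`(lon = err$lon, lat = err$lat)]
    }
    out
  })
  tracks <- juris_tracks(reported)
  true_daily <- subsample_daily(juris_tracks(true_dt))
  truth_assign <- assign_days(true_daily, world$country_layer)
  truth_occ <- monthly_proportions(truth_assign, ps$populations)
  sim <- list(config = config, world = world, populations = ps$populations,
              species = ps$species, tracks = tracks, true_daily = true_daily,
              truth = list(occupancy = truth_occ, annual = annual_time(truth_occ)))
  class(sim) <- "juris_sim"
  sim
}

#' Add isotropic Gaussian position error to coordinates
#'
#' Error is drawn in kilometres in a local equirectangular frame at each
#' fix's latitude (an explicit simplification of geolocator error
#' structure). With SD `error_km` the mean radial displacement is
#' `error_km * sqrt(pi/2)`.
#'
#' @param lon,lat coordinates in degrees.
#' @param error_km standard deviation of each error component.
#' @return list with perturbed `lon`, `lat`.
#' @export
perturb_positions <- function(lon, lat, error_km) {
  n <- length(lon)
  dx <- stats::rnorm(n, 0, error_km)
  dy <- stats::rnorm(n, 0, error_km)
  lat2 <- lat + dy / KM_PER_DEG
  lat2 <- pmin(89.9, pmax(-89.9, lat2))
  lon2 <- norm_lon(lon + dx / (KM_PER_DEG * pmax(0.2, cos(lat * pi / 180))))
  list(lon = lon2, lat = lat2)
}

#' Parameter recovery under partial individual sampling
#'
#' Runs the full pipeline (assignment, representativeness mask, monthly
#' proportions, annual time) on error-free tracks of random subsets of
#' individuals and reports the mean relative error of per-zone `T_e`
#' against the simulation's ground truth, per sampling fraction. With every
#' individual tracked the error is exactly zero; it should shrink as the
#' tracked share grows.
#'
#' @param sim a `juris_sim` from [simulate_study()].
#' @param fractions individual sampling fractions to evaluate.
#' @param n_reps random subsets drawn per fraction (averaged).
#' @param seed RNG seed for the subsampling.
#' @param min_days representativeness threshold passed to the mask.
#' @return data.table (`fraction`, `mean_rel_error`): mean over replicates
#'   and over zones with positive true `T_e` of `|est - true| / true`.
#' @export
recover_parameters <- function(sim, fractions = c(0.1, 0.5, 1), n_reps = 5L,
                               seed = 1L, min_days = 10L) {
  truth <- sim$truth$annual
  daily <- sim$true_daily
  birds <- data.table::as.data.table(daily)[, .(bird_id = unique(bird_id)), by = population_id]
  one <- function(frac, rep_seed) {
    sel <- local_rng(rep_seed, {
      birds[, .(bird_id = bird_id[sample.int(.N, max(1L, round(frac * .N)))]),
            by = population_id]$bird_id
    })
    sub <- data.table::as.data.table(daily)[bird_id %in% sel]
    data.table::setattr(sub, "class", class(daily))
    est <- annual_time(monthly_proportions(
      assign_days(sub, sim$world$country_layer), sim$populations,
      mask = representativeness_mask(sub, min_days = min_days)))
    cmp <- merge(truth[T_e > 0], est, by = "zone_id", all.x = TRUE,
                 suffixes = c("_true", "_est"))
    cmp[is.na(T_e_est), T_e_est := 0]
    cmp[, mean(abs(T_e_est - T_e_true) / T_e_true)]
  }
  out <- data.table::rbindlist(lapply(fractions, function(f) {
    errs <- vapply(seq_len(n_reps), function(r) one(f, seed * 1000L + r), 0)
    data.table::data.table(fraction = f, mean_rel_error = mean(errs))
  }))
  out[]
}

#' Sensitivity of zone-level results to geolocator position error
#'
#' Resampling procedure: in each replicate, fresh isotropic Gaussian error
#' (SD `error_km`) is added to every GLS daily position, assignment and
#' occupancy are rerun, and per-zone annual time spent and richness are
#' compared with the unperturbed run.
#'
#' @param daily a `juris_daily` table (post-filtering).
#' @param world list with `country_layer` (and optionally `rfmo_layer`).
#' @param populations a [juris_populations()] table.
#' @param n_reps number of replicates (>= 2).
#' @param error_km error SD in km (default 186).
#' @param seed RNG seed.
#' @param mask optional `juris_mask` applied in every run (default: mask
#'   recomputed per run at 10 days).
#' @return a `juris_sensitivity` list: `per_zone` (data.table with baseline
#'   `T_e`, mean/median absolute delta and mean relative delta over
#'   replicates), `richness_delta` (per-zone mean absolute change in total
#'   richness), `n_reps`, `error_km`.
#' @export
gls_sensitivity <- function(daily, world, populations, n_reps = 10L,
                            error_km = 186, seed = 1L, mask = NULL) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  run <- function(d) {
    m <- mask %||% representativeness_mask(d)
    a <- assign_days(d, world$country_layer)
    occ <- monthly_proportions(a, populations, mask = m)
    list(annual = annual_time(occ),
         rich = richness_by_zone(data.table::as.data.table(apply_mask(a, m)), populations))
  }
  base <- run(daily)
  gls <- data.table::as.data.table(daily)$device == "GLS"
  deltas <- list(); rdeltas <- list()
  for (r in seq_len(n_reps)) {
    pert <- local_rng(seed * 10000L + r, {
      d <- data.table::copy(data.table::as.data.table(daily))
      if (any(gls) && error_km > 0) {
        e <- perturb_positions(d$lon[gls], d$lat[gls], error_km)
        d[gls, `:=`(lon = e$lon, lat = e$lat)]
      }
      data.table::setattr(d, "class", class(daily))
      d
    })
    rep_run <- run(pert)
    cmp <- merge(base$annual, rep_run$annual, by = "zone_id", all = TRUE,
                 suffixes = c("_base", "_rep"))
    cmp[is.na(T_e_base), T_e_base := 0][is.na(T_e_rep), T_e_rep := 0]
    cmp[, rep := r]
    deltas[[r]] <- cmp
    rc <- merge(base$rich[, .(zone_id, n_total)], rep_run$rich[, .(zone_id, n_total)],
                by = "zone_id", all = TRUE, suffixes = c("_base", "_rep"))
    rc[is.na(n_total_base), n_total_base := 0L][is.na(n_total_rep), n_total_rep := 0L]
    rc[, rep := r]
    rdeltas[[r]] <- rc
  }
  dd <- data.table::rbindlist(deltas)
  per_zone <- dd[, .(T_e = T_e_base[1L],
                     mean_abs_delta = mean(abs(T_e_rep - T_e_base)),
                     median_abs_delta = stats::median(abs(T_e_rep - T_e_base)),
                     mean_rel_delta = mean(abs(T_e_rep - T_e_base) / pmax(T_e_base, 1e-12))),
                 by = zone_id]
  rr <- data.table::rbindlist(rdeltas)
  richness_delta <- rr[, .(mean_abs_delta = mean(abs(n_total_rep - n_total_base))),
                       by = zone_id]
  out <- list(per_zone = per_zone[], richness_delta = richness_delta[],
              n_reps = n_reps, error_km = error_km)
  class(out) <- "juris_sensitivity"
  out
}
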