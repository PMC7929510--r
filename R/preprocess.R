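# Track standardisation: one fix per local day, device-specific filtering,
# breeding-year truncation, and the month-representativeness mask.

#' Subsample tracks to one fix per local day
#'
#' Tracking devices report at different rates; the lowest common interval is
#' one position per day. For each bird and local day the fix whose local
#' clock time is nearest local noon is retained (ties: earliest timestamp).
#' "Local" time is solar time derived from the fix longitude
#' (UTC + lon/15 hours); set `mode = "utc"` to use UTC days and UTC noon
#' instead.
#'
#' @param tracks a [juris_tracks()] object.
#' @param mode `"solar"` (default) or `"utc"`.
#' @return a `juris_daily` data.table with one row per bird and local day
#'   (columns `bird_id`, `species_id`, `population_id`, `device`,
#'   `timestamp`, `lon`, `lat`, `local_day`, `month`). Idempotent.
#' @export
subsample_daily <- function(tracks, mode = c("solar", "utc")) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(tracks)
  offset_s <- if (mode == "solar") dt$lon * 240 else 0 # 1 deg lon = 4 min
  local_s <- as.numeric(dt$timestamp) + offset_s
  dt[, local_day := as.Date(floor(local_s / 86400), origin = "1970-01-01")]
  noon_dist <- abs(local_s %% 86400 - 43200)
  dt[, `:=`(.noon = noon_dist)]
  data.table::setorder(dt, bird_id, local_day, .noon, timestamp)
  out <- dt[, .SD[1L], by = .(bird_id, local_day)]
  out[, .noon := NULL]
  out[, month := as.integer(format(local_day, "%m"))]
  data.table::setcolorder(out, c("bird_id", "species_id", "population_id", "device",
                                 "timestamp", "lon", "lat", "local_day", "month"))
  data.table::setorder(out, bird_id, local_day)
  data.table::setattr(out, "attachment", attr(tracks, "attachment"))
  data.table::setattr(out, "class", c("juris_daily", "data.table", "data.frame"))
  out
}

track_date <- function(dt) {
  if ("local_day" %in% names(dt)) dt$local_day else as.Date(dt$timestamp, tz = "UTC")
}

#' Truncate each track to one breeding year after device attachment
#'
#' Only fixes dated within 365 calendar days of the bird's attachment date
#' (attachment day counted as day 1) are retained. Applied to all species;
#' for tracks shorter than a year it is a no-op. This bounds the record of
#' biennial breeders to a single breeding year.
#'
#' @param tracks a [juris_tracks()] or `juris_daily` object carrying an
#'   `attachment` attribute (defaulting to first fix date).
#' @return object of the same class, filtered.
#' @export
truncate_breeding_year <- function(tracks) {
  att <- attr(tracks, "attachment")
  dt <- data.table::as.data.table(tracks)
  if (is.null(att)) {
    att <- dt[, .(attachment_date = min(track_date(.SD))), by = bird_id]
  }
  cls <- class(tracks)
  d <- track_date(dt)
  lim <- att$attachment_date[match(dt$bird_id, att$bird_id)] + 364L
  out <- dt[d <= lim]
  data.table::setattr(out, "attachment", att)
  data.table::setattr(out, "class", cls)
  out
}

equinox_doy <- function(equinox_dates, year = 2001L) {
  as.integer(format(as.Date(paste0(year, "-", equinox_dates)), "%j"))
}

#' Filter GLS tracks for light-level geolocation artefacts
#'
#' A configurable filter chain applied, in order, to GLS birds only (other
#' devices pass through untouched):
#' \enumerate{
#'   \item \emph{equinox filter}: light-level latitudes are unreliable near
#'     the equinoxes, so fixes within `equinox_days` days of either equinox
#'     are dropped;
#'   \item \emph{speed filter}: a fix implying a displacement rate above
#'     `max_km_day` km/day from the previously retained fix of the same bird
#'     is dropped.
#' }
#' Either filter can be disabled by setting its parameter to `NULL`. The
#' applied chain is recorded in the `"filters"` attribute of the result.
#' Defaults are package defaults, not field-calibrated constants.
#'
#' @param tracks a [juris_tracks()] or `juris_daily` object.
#' @param equinox_days half-width (days) of the equinox exclusion window, or
#'   `NULL` to disable. Default 15.
#' @param max_km_day maximum plausible displacement rate (km/day), or `NULL`
#'   to disable. Default 1000.
#' @param equinox_dates month-day strings of the two equinoxes.
#' @return filtered object of the same class.
#' @export
filter_gls <- function(tracks, equinox_days = 15, max_km_day = 1000,
                       equinox_dates = c("03-20", "09-22")) {
  dt <- data.table::as.data.table(tracks)
  cls <- class(tracks); att <- attr(tracks, "attachment")
  if (!any(dt$device == "GLS")) {
    warning("no GLS fixes present; tracks returned unchanged")
    return(tracks)
  }
  keep <- rep(TRUE, nrow(dt))
  gls <- dt$device == "GLS"
  if (!is.null(equinox_days)) {
    doy <- as.integer(format(track_date(dt), "%j"))
    near <- rep(FALSE, nrow(dt))
    for (eq in equinox_doy(equinox_dates)) {
      d <- abs(doy - eq)
      near <- near | pmin(d, 365L - d) <= equinox_days
    }
    keep <- keep & !(gls & near)
  }
  if (!is.null(max_km_day)) {
    t_num <- as.numeric(track_date(dt))
    for (b in unique(dt$bird_id[gls])) {
      idx <- which(dt$bird_id == b & gls & keep)
      if (length(idx) < 2L) next
      ref <- idx[1L]
      for (i in idx[-1L]) {
        ddays <- max(t_num[i] - t_num[ref], 0.5)
        v <- gc_distance_km(dt$lon[ref], dt$lat[ref], dt$lon[i], dt$lat[i]) / ddays
        if (v > max_km_day) keep[i] <- FALSE else ref <- i
      }
    }
  }
  out <- dt[keep]
  data.table::setattr(out, "attachment", att)
  data.table::setattr(out, "class", cls)
  data.table::setattr(out, "filters", list(
    chain = c(if (!is.null(equinox_days)) "equinox",
              if (!is.null(max_km_day)) "speed"),
    equinox_days = equinox_days, max_km_day = max_km_day,
    equinox_dates = equinox_dates))
  out
}

#' Representativeness mask over population-months
#'
#' Months are pooled across calendar years within each population. A
#' population-month is representative when it has at least `min_days`
#' tracking days (bird-days) and, in conservative mode, at least
#' `min_individuals` distinct birds.
#'
#' @param daily a `juris_daily` object (see [subsample_daily()]).
#' @param min_days minimum tracking days per population-month (default 10).
#' @param min_individuals minimum distinct individuals (default 0; the
#'   conservative variant uses 5).
#' @return a `juris_mask` data.table with columns `population_id`, `month`,
#'   `n_tracking_days`, `n_individuals`, `retained`.
#' @export
representativeness_mask <- function(daily, min_days = 10L, min_individuals = 0L) {
  dt <- data.table::as.data.table(daily)
  m <- dt[, .(n_tracking_days = .N,
              n_individuals = data.table::uniqueN(bird_id)),
          by = .(population_id, month)]
  m[, retained := n_tracking_days >= min_days & n_individuals >= min_individuals]
  data.table::setorder(m, population_id, month)
  data.table::setattr(m, "thresholds",
                      list(min_days = min_days, min_individuals = min_individuals))
  data.table::setattr(m, "class", c("juris_mask", "data.table", "data.frame"))
  m
}

#' Drop daily fixes falling in unrepresentative population-months
#'
#' @param daily a `juris_daily` object.
#' @param mask a `juris_mask` from [representativeness_mask()].
#' @return filtered `juris_daily`.
#' @export
apply_mask <- function(daily, mask) {
  keep <- data.table::as.data.table(mask)[retained == TRUE, .(population_id, month)]
  dt <- data.table::as.data.table(daily)
  out <- dt[keep, on = c("population_id", "month"), nomatch = NULL]
  data.table::setorder(out, bird_id, local_day)
  data.table::setattr(out, "attachment", attr(daily, "attachment"))
  data.table::setattr(out, "class", class(daily))
  out
}

#' Months covered per population under a mask
#'
#' @param mask a `juris_mask`.
#' @return data.table (`population_id`, `months_covered`): the number of
#'   distinct retained calendar months (0-12).
#' @export
months_covered <- function(mask) {
  data.table::as.data.table(mask)[, .(months_covered = sum(retained)), by = population_id]
}
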