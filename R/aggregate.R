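# Hierarchical field-working-day aggregation: per-soil daily indicators
# averaged to stations, stations averaged (unweighted) to crop districts,
# districts averaged to the state.

#' Aggregate field working days up the spatial hierarchy
#'
#' `station_fwd()` averages per-soil window sums at one station;
#' `district_fwd()` averages station values; `state_fwd()` averages exactly
#' nine district values (the state is defined as the unweighted mean of the
#' nine crop districts). All means are unweighted.
#'
#' @param soil_fwds Numeric vector of per-soil FWD counts in a 7-day window.
#' @param station_fwds,district_fwds Numeric vectors of station / district
#'   FWD values.
#' @param n_districts Required number of districts for the state mean.
#' @return A single FWD value in `[0, 7]`.
#' @export
station_fwd <- function(soil_fwds) {
  if (length(soil_fwds) == 0L) fail_field("soil_fwds", "at least one soil required")
  mean(soil_fwds)
}

#' @rdname station_fwd
#' @export
district_fwd <- function(station_fwds) {
  if (length(station_fwds) == 0L) fail_field("station_fwds", "at least one station required")
  mean(station_fwds)
}

#' @rdname station_fwd
#' @export
state_fwd <- function(district_fwds, n_districts = 9L) {
  if (length(district_fwds) != n_districts)
    fail_field("district_fwds", sprintf("state aggregation requires exactly %d districts",
                                        n_districts))
  mean(district_fwds)
}

#' Assemble the day-level workability table
#'
#' Joins soil-moisture series with their stations' weather into one flat
#' table of (district, station, soil, year, DOY, scaled moisture, mid-range
#' temperature) rows — the common input of report generation, threshold
#' calibration and curve computation.
#'
#' @param weather A single `daily_weather` data.frame (one station) or a
#'   named list of them keyed by station id.
#' @param moisture A single `moisture_series` or a named list keyed by soil
#'   id; each series must align day-for-day with its station's weather on
#'   the years it covers.
#' @param soils A [soil_profile()] or list of them (provides the
#'   soil-station-district links and the plastic limits used for scaling).
#' @return A data.frame of class `fwd_data` with columns `district`,
#'   `station_id`, `soil_id`, `year`, `doy`, `sm` (fraction of PL), `mt`
#'   (deg C).
#' @export
fwd_data <- function(weather, moisture, soils) {
  if (inherits(soils, "soil_profile")) soils <- list(soils)
  if (inherits(weather, "daily_weather")) {
    sid <- unique(vapply(soils, `[[`, "", "station_id"))
    stopifnot(length(sid) == 1L)
    weather <- stats::setNames(list(weather), sid)
  }
  if (inherits(moisture, "moisture_series"))
    moisture <- stats::setNames(list(moisture), attr(moisture, "soil_id"))

  rows <- lapply(soils, function(s) {
    m <- moisture[[s$soil_id]]
    if (is.null(m)) fail_field("moisture", paste("no series for soil", s$soil_id))
    w <- weather[[s$station_id]]
    if (is.null(w)) fail_field("weather", paste("no series for station", s$station_id))
    key_m <- paste(m$year, m$doy)
    key_w <- paste(w$year, w$doy)
    j <- match(key_m, key_w)
    if (anyNA(j)) fail_field("moisture", paste("series misaligned with weather for soil",
                                               s$soil_id))
    data.frame(district = s$district, station_id = s$station_id, soil_id = s$soil_id,
               year = m$year, doy = m$doy,
               sm = scale_moisture(m$vwc, s),
               mt = daily_mean_temperature(w$tmin_c[j], w$tmax_c[j]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fwd_data", "data.frame")
  out
}

#' Weekly report windows
#'
#' Consecutive non-overlapping 7-day windows by start DOY, emulating weekly
#' crop-progress reporting over the spring season.
#'
#' @param first_start,last_start First and last window start DOY.
#' @return A data.frame with `start_doy`, `end_doy` (start + 6).
#' @export
weekly_windows <- function(first_start = 85L, last_start = 169L) {
  starts <- seq(as.integer(first_start), as.integer(last_start), by = 7L)
  data.frame(start_doy = starts, end_doy = starts + 6L)
}

#' Predict weekly FWD counts under a threshold schedule
#'
#' Classifies every day of the workability table under the schedule's
#' DOY-dependent thresholds, sums indicators per soil over each 7-day
#' window, and aggregates soil -> station -> district.
#'
#' @param data A [fwd_data()] table.
#' @param schedule A [threshold_schedule()].
#' @param windows A data.frame of windows (see [weekly_windows()]).
#' @return A data.frame `region, year, start_doy, end_doy, fwd` with one row
#'   per district x year x window (region = district).
#' @export
predict_weekly_fwd <- function(data, schedule, windows) {
  widx <- match_window(data$doy, windows)
  keep <- !is.na(widx)
  d <- data[keep, , drop = FALSE]
  widx <- widx[keep]
  th <- thresholds_at_doy(schedule, d$doy)
  ind <- classify_workday(d$sm, d$mt, th$ts, th$tt)
  # per-soil window sums, then unweighted means up the hierarchy
  d$ind <- ind
  d$widx <- widx
  so <- stats::aggregate(ind ~ district + station_id + soil_id + year + widx, d, sum)
  st <- stats::aggregate(ind ~ district + station_id + year + widx, so, mean)
  di <- stats::aggregate(ind ~ district + year + widx, st, mean)
  names(di)[names(di) == "ind"] <- "fwd"
  out <- data.frame(region = di$district, year = di$year,
                    start_doy = windows$start_doy[di$widx],
                    end_doy = windows$end_doy[di$widx], fwd = di$fwd)
  out[order(out$region, out$year, out$start_doy), ]
}

# window index for each doy, NA when outside all windows
match_window <- function(doy, windows) {
  idx <- rep(NA_integer_, length(doy))
  for (i in seq_len(nrow(windows)))
    idx[doy >= windows$start_doy[i] & doy <= windows$end_doy[i]] <- i
  idx
}
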