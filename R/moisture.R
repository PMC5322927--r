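# Single-layer (10 cm) daily bucket model of volumetric soil moisture:
# a transparent stand-in for a full soil temperature and moisture model,
# driven by daily weather and a Thornthwaite-based daily PET proxy.

#' Daily mid-range temperature
#'
#' @param tmin,tmax Daily minimum / maximum temperature (deg C), `tmax >=
#'   tmin`.
#' @return `(tmin + tmax) / 2`.
#' @export
daily_mean_temperature <- function(tmin, tmax) {
  if (any(tmax < tmin)) fail_field("tmax", "must be >= tmin")
  (tmin + tmax) / 2
}

#' Bucket model settings
#'
#' @param drainage_rate Fraction of storage above field capacity drained per
#'   day, in `(0, 1]`.
#' @param init_mode `"fc"` starts the profile at field capacity; with
#'   `spinup_years > 0` the first year(s) are additionally discarded so the
#'   retained series does not depend on the initial condition.
#' @param snow_on If `TRUE`, precipitation on days with mid-range temperature
#'   below 0 deg C accumulates in a snow store released at `melt_rate` mm/day
#'   on thaw days.
#' @param spinup_years Number of leading years simulated and discarded.
#' @param melt_rate Snow melt release rate (mm/day).
#' @param depth_mm Modelled layer depth (mm); 100 mm = 10 cm.
#' @return A list of settings for [simulate_soil_moisture()].
#' @export
bucket_config <- function(drainage_rate = 0.5, init_mode = "fc", snow_on = TRUE,
                          spinup_years = 1L, melt_rate = 5, depth_mm = 100) {
  stopifnot(drainage_rate > 0, drainage_rate <= 1, spinup_years >= 0,
            melt_rate > 0, depth_mm > 0)
  list(drainage_rate = drainage_rate, init_mode = init_mode, snow_on = snow_on,
       spinup_years = as.integer(spinup_years), melt_rate = melt_rate,
       depth_mm = depth_mm)
}

#' Simulate daily 10 cm volumetric soil moisture
#'
#' Single-layer daily water balance. Each day, in order: snow partitioning
#' (sub-zero mid-range temperature sends precipitation to a snow store,
#' thaw days release it linearly), infiltration of available water up to
#' remaining pore space, drainage of storage above field capacity at a fixed
#' daily rate, then evaporative loss equal to the day's potential
#' evapotranspiration share scaled by relative wetness
#' `(vwc - WP) / (FC - WP)` (clipped to `[0, 1]`) and floored at the wilting
#' point. Deterministic given its inputs.
#'
#' @param weather A `daily_weather` data.frame (see
#'   [generate_daily_weather()]).
#' @param profile A [soil_profile()].
#' @param config A [bucket_config()].
#' @param latitude Latitude used for the PET proxy (decimal degrees).
#' @return A data.frame of class `moisture_series` with columns `year`,
#'   `doy`, `vwc`, plus flux columns `infil_mm`, `drain_mm`, `evap_mm` (the
#'   model's own bookkeeping, enabling exact mass-balance checks) and the
#'   soil id as attribute `soil_id`. Spin-up years are dropped from the
#'   output.
#' @export
simulate_soil_moisture <- function(weather, profile, config = bucket_config(),
                                   latitude = 40) {
  validate_daily_weather(weather)
  stopifnot(inherits(profile, "soil_profile"))
  d <- config$depth_mm
  fc <- profile$fc; wp <- profile$wp; por <- profile$porosity
  pet <- daily_pet_series(weather, latitude)
  mid <- daily_mean_temperature(weather$tmin_c, weather$tmax_c)
  n <- nrow(weather)

  vwc <- numeric(n); infil <- numeric(n); drain <- numeric(n); evap <- numeric(n)
  s <- fc * d # storage, mm; init at field capacity
  snow <- 0
  for (i in seq_len(n)) {
    p <- weather$precip_mm[i]
    avail <- p
    if (config$snow_on) {
      if (mid[i] < 0) { snow <- snow + p; avail <- 0 }
      else if (snow > 0) { melt <- min(snow, config$melt_rate); snow <- snow - melt
                           avail <- avail + melt }
    }
    f <- min(avail, por * d - s)
    s <- s + f
    dr <- if (s > fc * d) config$drainage_rate * (s - fc * d) else 0
    s <- s - dr
    wet <- (s / d - wp) / (fc - wp)
    e <- pet[i] * min(max(wet, 0), 1)
    e <- min(e, s - wp * d) # never draw below wilting point
    e <- max(e, 0)
    s <- s - e
    vwc[i] <- s / d; infil[i] <- f; drain[i] <- dr; evap[i] <- e
  }

  out <- data.frame(year = weather$year, doy = weather$doy, vwc = vwc,
                    infil_mm = infil, drain_mm = drain, evap_mm = evap)
  if (config$spinup_years > 0) {
    drop <- unique(weather$year)[seq_len(min(config$spinup_years,
                                             length(unique(weather$year)) - 1L))]
    out <- out[!out$year %in% drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "soil_id") <- profile$soil_id
  attr(out, "depth_mm") <- d
  class(out) <- c("moisture_series", "data.frame")
  out
}

#' Write or read a moisture series as delimited text
#'
#' Columns: `soil_id, year, doy, vwc`.
#'
#' @param moisture A `moisture_series` data.frame.
#' @param path File path.
#' @export
write_moisture <- function(moisture, path) {
  out <- data.frame(soil_id = attr(moisture, "soil_id"),
                    moisture[c("year", "doy", "vwc")])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_moisture
#' @export
read_moisture <- function(path) {
  m <- utils::read.delim(path)
  out <- m[c("year", "doy", "vwc")]
  attr(out, "soil_id") <- as.character(m$soil_id[1L])
  class(out) <- c("moisture_series", "data.frame")
  out
}
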