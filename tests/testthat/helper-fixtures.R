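# Shared fixtures: all built in code at test time.

# A cool, high-variance climate for threshold-recovery tests: spring
# temperatures straddle the temperature-threshold grid and dry spells are
# long enough that scaled moisture sweeps across the moisture-threshold
# grid, so both thresholds bind in both calibration periods.
recovery_params <- function() weather_params(
  tmax_mean   = c(2, 4, 14, 17, 19, 22, 25, 25, 21, 15, 8, 3),
  tmin_mean   = c(-6, -4, 2, 5, 7, 10, 14, 14, 10, 5, 0, -5),
  temp_sd     = rep(6, 12),
  p_wet_wet   = rep(0.30, 12), p_wet_dry = rep(0.12, 12),
  gamma_shape = rep(0.8, 12), gamma_scale = rep(12, 12))

# the step-mode schedule those recovery tests try to recover; all four
# values lie on the default search grid
recovery_truth <- function() threshold_schedule(0.95, 5.0, 1.02, 7.0, mode = "step")

recovery_config <- function(n_years = 12, districts = c("NW", "C"), seed = 5)
  run_config(districts = districts, params = recovery_params(),
             n_gen = n_years, n_sub = n_years, seed = seed)

# one representative silt-loam profile
test_soil <- function(station = "st_A", district = "A")
  soil_profile("s1", sand = 20, silt = 60, clay = 20, organic_matter = 3,
               station_id = station, district = district)

# hand-built day-level workability table (bypasses the simulators)
manual_fwd_data <- function(district, station, soil, year, doy, sm, mt) {
  d <- data.frame(district = district, station_id = station, soil_id = soil,
                  year = year, doy = doy, sm = sm, mt = mt)
  class(d) <- c("fwd_data", "data.frame")
  d
}

# Independent Thornthwaite reference: loop-based, Cooper's declination
# formula for day length (a different approximation and coding than the
# implementation under test).
oracle_thornthwaite <- function(tmean, lat) {
  mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mid <- cumsum(mdays) - mdays + (mdays - 1) %/% 2 + 1
  I <- 0
  for (t in tmean) if (t > 0) I <- I + (t / 5)^1.514
  out <- numeric(12)
  if (I == 0) return(out)
  a <- 0.49239 + 1.792e-2 * I - 7.71e-5 * I^2 + 6.75e-7 * I^3
  for (m in 1:12) {
    t <- tmean[m]
    if (t > 0) {
      u <- if (t <= 26.5) 16 * (10 * t / I)^a else -415.85 + 32.24 * t - 0.43 * t^2
      decl <- 23.45 * sin(2 * pi * (284 + mid[m]) / 365) * pi / 180
      ws <- acos(min(max(-tan(lat * pi / 180) * tan(decl), -1), 1))
      out[m] <- u * ((24 / pi * ws) / 12) * (mdays[m] / 30)
    }
  }
  out
}

# dry warm weather series: no precipitation, fixed temperatures
dry_weather <- function(n_years = 2, tmin = 10, tmax = 24) {
  w <- data.frame(year = rep(seq_len(n_years), each = 365L),
                  doy = rep(1:365, n_years),
                  tmin_c = tmin, tmax_c = tmax, precip_mm = 0)
  class(w) <- c("daily_weather", "data.frame")
  w
}
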