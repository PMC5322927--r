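# Stochastic daily weather: first-order Markov precipitation occurrence,
# gamma wet-day amounts, and seasonal temperature curves obtained by
# linear interpolation of monthly means to daily values (mid-month
# anchors, wrapping across the year boundary so December-January is
# continuous).

#' Weather generator parameters
#'
#' Bundles the monthly climatology driving [generate_daily_weather()]: mean
#' daily maximum/minimum temperature, the standard deviation of the daily
#' mid-range temperature about its seasonal curve, first-order Markov wet-day
#' occurrence probabilities (conditional on the previous day being wet or
#' dry), and gamma shape/scale for wet-day precipitation amounts.
#'
#' @param tmax_mean,tmin_mean Numeric length-12, monthly means of daily
#'   maximum / minimum temperature (deg C); `tmax_mean >= tmin_mean` monthly.
#' @param temp_sd Numeric length-12, s.d. of the daily mid-range temperature
#'   about the seasonal mean curve (deg C).
#' @param p_wet_wet,p_wet_dry Numeric length-12 in `[0, 1]`: probability a day
#'   is wet given the previous day was wet / dry.
#' @param gamma_shape,gamma_scale Numeric length-12, positive: gamma
#'   parameters of wet-day precipitation (mm).
#' @param range_floor Minimum allowed diurnal range (deg C).
#' @param latitude Site latitude, decimal degrees in `[-90, 90]`.
#' @return An object of class `weather_params`.
#' @seealso [il_weather_params()] for an Illinois-like default climatology.
#' @export
weather_params <- function(tmax_mean, tmin_mean, temp_sd,
                           p_wet_wet, p_wet_dry,
                           gamma_shape, gamma_scale,
                           range_floor = 2, latitude = 40) {
  p <- list(tmax_mean = as.numeric(tmax_mean), tmin_mean = as.numeric(tmin_mean),
            temp_sd = as.numeric(temp_sd),
            p_wet_wet = as.numeric(p_wet_wet), p_wet_dry = as.numeric(p_wet_dry),
            gamma_shape = as.numeric(gamma_shape), gamma_scale = as.numeric(gamma_scale),
            range_floor = as.numeric(range_floor), latitude = as.numeric(latitude))
  class(p) <- "weather_params"
  validate_weather_params(p)
  p
}

validate_weather_params <- function(p) {
  monthly <- c("tmax_mean", "tmin_mean", "temp_sd", "p_wet_wet", "p_wet_dry",
               "gamma_shape", "gamma_scale")
  for (f in monthly) {
    v <- p[[f]]
    if (length(v) != 12L || anyNA(v) || any(!is.finite(v)))
      fail_field(f, "must be 12 finite monthly values")
  }
  for (f in c("p_wet_wet", "p_wet_dry"))
    if (any(p[[f]] < 0 | p[[f]] > 1)) fail_field(f, "probabilities must lie in [0, 1]")
  for (f in c("gamma_shape", "gamma_scale"))
    if (any(p[[f]] <= 0)) fail_field(f, "gamma parameters must be > 0")
  if (any(p$temp_sd < 0)) fail_field("temp_sd", "must be >= 0")
  if (any(p$tmax_mean < p$tmin_mean))
    fail_field("tmax_mean", "monthly mean tmax must be >= mean tmin")
  if (length(p$latitude) != 1L || p$latitude < -90 || p$latitude > 90)
    fail_field("latitude", "must be a single value in [-90, 90]")
  if (p$range_floor < 0) fail_field("range_floor", "must be >= 0")
  invisible(p)
}

#' Illinois-like default climatology
#'
#' A monthly climatology typical of central Illinois (about 40 deg N, annual
#' precipitation near 950 mm, July mean daily maximum near 30 deg C), used as
#' the baseline conditions for the simulation experiments.
#'
#' @param latitude Site latitude (decimal degrees).
#' @return A [weather_params()] object.
#' @export
il_weather_params <- function(latitude = 40) {
  weather_params(
    tmax_mean   = c(0, 3, 10, 17, 23, 28, 30, 29, 26, 19, 10, 2),
    tmin_mean   = c(-9, -6, -1, 5, 11, 16, 18, 17, 13, 6, 0, -6),
    temp_sd     = c(5, 5, 4.5, 4, 3, 2.5, 2, 2, 2.5, 3.5, 4, 4.5),
    p_wet_wet   = c(0.40, 0.40, 0.42, 0.45, 0.45, 0.42, 0.40, 0.38, 0.38, 0.38, 0.40, 0.40),
    p_wet_dry   = c(0.22, 0.22, 0.26, 0.30, 0.30, 0.26, 0.24, 0.20, 0.20, 0.20, 0.24, 0.22),
    gamma_shape = rep(0.75, 12),
    gamma_scale = c(9, 9, 12, 15, 17, 17, 16, 15, 14, 12, 11, 10),
    range_floor = 2,
    latitude    = latitude
  )
}

#' Climate change scenario as a delta-change perturbation
#'
#' Describes a scenario (emulating emissions-scenario projections such as B1,
#' A1B or A2) as monthly perturbations of the weather generator parameters:
#' additive temperature deltas and multiplicative factors on wet-day
#' precipitation scale and on wet-day occurrence probability.
#'
#' @param label Free-text scenario label.
#' @param temp_delta Numeric length-12 additive shift of monthly mean
#'   temperatures (deg C).
#' @param precip_factor Numeric length-12 multiplicative factor (>= 0) on the
#'   gamma scale of wet-day amounts.
#' @param wet_prob_factor Numeric length-12 multiplicative factor (>= 0) on
#'   both Markov wet-day probabilities (results are clipped to 1 by
#'   [apply_scenario()]).
#' @param horizon Free-text time-horizon label (e.g. "mid-century").
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(label, temp_delta = rep(0, 12),
                            precip_factor = rep(1, 12),
                            wet_prob_factor = rep(1, 12),
                            horizon = "") {
  rep12 <- function(x) if (length(x) == 1L) rep(as.numeric(x), 12) else as.numeric(x)
  s <- list(label = as.character(label), temp_delta = rep12(temp_delta),
            precip_factor = rep12(precip_factor),
            wet_prob_factor = rep12(wet_prob_factor),
            horizon = as.character(horizon))
  class(s) <- "scenario_config"
  for (f in c("temp_delta", "precip_factor", "wet_prob_factor"))
    if (length(s[[f]]) != 12L || any(!is.finite(s[[f]])))
      fail_field(f, "must be 12 finite monthly values")
  if (any(s$precip_factor < 0)) fail_field("precip_factor", "must be >= 0")
  if (any(s$wet_prob_factor < 0)) fail_field("wet_prob_factor", "must be >= 0")
  s
}

#' Apply a scenario perturbation to generator parameters
#'
#' Delta-change emulation of statistical downscaling: monthly temperature
#' means are shifted additively, the gamma scale of wet-day amounts and the
#' Markov wet-day probabilities are scaled multiplicatively. Perturbation acts
#' on generator parameters, never on realized series, mirroring how stochastic
#' weather generators ingest scenario changes.
#'
#' @param params A [weather_params()] object.
#' @param scenario A [scenario_config()] object.
#' @return A perturbed `weather_params` object. Wet-day probabilities that
#'   exceed 1 after scaling are clipped to 1 with a warning.
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "weather_params"), inherits(scenario, "scenario_config"))
  p <- params
  p$tmax_mean <- p$tmax_mean + scenario$temp_delta
  p$tmin_mean <- p$tmin_mean + scenario$temp_delta
  p$gamma_scale <- p$gamma_scale * scenario$precip_factor
  for (f in c("p_wet_wet", "p_wet_dry")) {
    v <- p[[f]] * scenario$wet_prob_factor
    if (any(v > 1)) {
      warning(sprintf("scenario '%s': %s clipped to 1 in %d month(s)",
                      scenario$label, f, sum(v > 1)))
      v <- pmin(v, 1)
    }
    p[[f]] <- v
  }
  # a zero precip factor drives the gamma scale to 0; keep it valid but
  # degenerate by suppressing occurrence instead
  zero <- p$gamma_scale <= 0
  if (any(zero)) {
    p$gamma_scale[zero] <- .Machine$double.eps
    p$p_wet_wet[zero] <- 0
    p$p_wet_dry[zero] <- 0
  }
  validate_weather_params(p)
  p
}

# Interpolate 12 monthly values to 365 daily values, linearly between
# mid-month anchors and wrapping across the year boundary.
monthly_to_daily <- function(v) {
  stopifnot(length(v) == 12L)
  x <- c(mid_month_doy(12L) - 365, mid_month_doy(1:12), mid_month_doy(1L) + 365)
  y <- c(v[12L], v, v[1L])
  stats::approx(x, y, xout = 1:365)$y
}

#' Generate daily weather series
#'
#' Simulates `n_years` complete 365-day years of daily minimum/maximum
#' temperature and precipitation. Precipitation occurrence follows a
#' first-order two-state Markov chain with monthly transition probabilities;
#' wet-day amounts are gamma distributed per month. The daily mid-range
#' temperature is the linearly interpolated monthly mean curve plus Gaussian
#' noise; the diurnal range follows its own interpolated curve, floored at
#' `params$range_floor`, which guarantees `tmax >= tmin` every day.
#'
#' @param params A [weather_params()] object.
#' @param n_years Number of years to simulate (>= 1).
#' @param seed Integer seed; identical `(params, n_years, seed)` gives
#'   identical output.
#' @return A data.frame of class `daily_weather` with columns `year`, `doy`,
#'   `tmin_c`, `tmax_c`, `precip_mm`.
#' @export
generate_daily_weather <- function(params, n_years, seed) {
  validate_weather_params(params)
  if (n_years < 1) fail_field("n_years", "must be >= 1")
  n_days <- 365L * as.integer(n_years)
  doy <- rep(1:365, n_years)
  year <- rep(seq_len(n_years), each = 365L)
  mo <- month_of_doy(doy)

  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    expr
  }

  withr_seed({
    # temperature: seasonal curves + mid-range noise
    mid_curve <- monthly_to_daily((params$tmax_mean + params$tmin_mean) / 2)
    rng_curve <- pmax(monthly_to_daily(params$tmax_mean - params$tmin_mean),
                      params$range_floor)
    mid <- mid_curve[doy] + stats::rnorm(n_days, 0, params$temp_sd[mo])
    tmin <- mid - rng_curve[doy] / 2
    tmax <- mid + rng_curve[doy] / 2

    # occurrence: sequential Markov chain over the whole series
    u <- stats::runif(n_days)
    pw <- params$p_wet_wet[mo]
    pd <- params$p_wet_dry[mo]
    wet <- logical(n_days)
    prev <- FALSE
    for (i in seq_len(n_days)) {
      prev <- u[i] < (if (prev) pw[i] else pd[i])
      wet[i] <- prev
    }

    precip <- numeric(n_days)
    if (any(wet))
      precip[wet] <- stats::rgamma(sum(wet), shape = params$gamma_shape[mo[wet]],
                                   scale = params$gamma_scale[mo[wet]])
  })

  out <- data.frame(year = year, doy = doy, tmin_c = tmin, tmax_c = tmax,
                    precip_mm = precip)
  class(out) <- c("daily_weather", "data.frame")
  out
}

validate_daily_weather <- function(w) {
  need <- c("year", "doy", "tmin_c", "tmax_c", "precip_mm")
  if (!all(need %in% names(w))) fail_field("weather", "missing required columns")
  if (anyNA(w[need])) {
    bad <- which(!stats::complete.cases(w[need]))[1L]
    stop(sprintf("NA weather value at year %s, DOY %s", w$year[bad], w$doy[bad]),
         call. = FALSE)
  }
  if (any(w$tmax_c < w$tmin_c)) fail_field("weather", "tmax < tmin")
  if (any(w$precip_mm < 0)) fail_field("weather", "negative precipitation")
  if (any(table(w$year) != 365L)) fail_field("weather", "years must be complete (365 days)")
  invisible(w)
}

#' Randomly subsample whole years from a weather series
#'
#' Selects `k` distinct years (reproducibly under `seed`), preserving the
#' original year order; used to thin large generated ensembles before the
#' comparatively expensive soil-moisture simulation.
#'
#' @param series A `daily_weather` data.frame.
#' @param k Number of years to keep.
#' @param seed Integer seed.
#' @return A `daily_weather` data.frame containing `k` whole years.
#' @export
subsample_years <- function(series, k, seed) {
  yrs <- unique(series$year)
  if (k > length(yrs)) fail_field("k", "more years requested than available")
  keep <- if (k == length(yrs)) yrs else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    sort(sample(yrs, k))
  }
  out <- series[series$year %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("daily_weather", "data.frame")
  out
}

#' Read or write daily weather as delimited text
#'
#' Plain tab-separated files with header `year, doy, tmin_c, tmax_c,
#' precip_mm`.
#'
#' @param series A `daily_weather` data.frame (for writing).
#' @param path File path.
#' @return `read_weather()` returns a validated `daily_weather` data.frame.
#' @export
write_weather <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  w <- utils::read.delim(path)
  validate_daily_weather(w)
  class(w) <- c("daily_weather", "data.frame")
  w
}
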