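# Growing-season metrics: growing degree days with a 10 degC base and
# 30 degC cap, and frost dates (tmin below 0 degC) splitting the year at
# DOY 182 into spring and fall.

#' Daily growing degree days
#'
#' Both temperatures are clamped into `[base, cap]` before averaging, so a
#' day's GDD is `(tmin' + tmax')/2 - base`, never negative and at most
#' `cap - base`.
#'
#' @param tmin,tmax Daily minimum / maximum temperature (deg C),
#'   `tmax >= tmin`.
#' @param base Base temperature (default 10 deg C).
#' @param cap Maximum temperature cap (default 30 deg C).
#' @return GDD (deg C day), vectorized.
#' @export
#' @examples
#' gdd_day(10, 30) # 10
#' gdd_day(12, 35) # 11
#' gdd_day(2, 8)   # 0
gdd_day <- function(tmin, tmax, base = 10, cap = 30) {
  if (any(tmax < tmin)) fail_field("tmax", "must be >= tmin")
  lo <- pmin(pmax(tmin, base), cap)
  hi <- pmin(pmax(tmax, base), cap)
  (lo + hi) / 2 - base
}

#' Frost dates, frost-free length and annual GDD
#'
#' Per year: the last spring frost is the latest DOY at or before 182 with
#' `tmin < 0`, the first fall frost the earliest DOY after 182 with
#' `tmin < 0`; the frost-free length is their difference. Years without a
#' spring (fall) frost are flagged as DOY 0 (366). Annual GDD accumulates
#' [gdd_day()] over all 365 days. The ensemble summary reports the
#' per-tail 90th-percentile frost dates (the spring date later than 90 % of
#' years, and the fall date earlier than 90 % of years — together bounding
#' 90 % of the frost-free seasons) and mean GDD.
#'
#' @param series A `daily_weather` data.frame of whole years.
#' @param base,cap GDD parameters.
#' @param percentile Tail probability for the frost-date summary (default
#'   0.9).
#' @return An object of class `season_metrics`: data.frame `by_year` (year,
#'   spring_frost_doy, fall_frost_doy, frost_free_days, gdd) and list
#'   `summary` (mean_gdd, mean_frost_free, spring_frost_p90,
#'   fall_frost_p90).
#' @export
frost_dates <- function(series, base = 10, cap = 30, percentile = 0.9) {
  validate_daily_weather(series)
  by_year <- do.call(rbind, lapply(split(series, series$year), function(g) {
    g <- g[order(g$doy), ]
    frost <- g$doy[g$tmin_c < 0]
    spring <- if (any(frost <= 182)) max(frost[frost <= 182]) else 0L
    fall <- if (any(frost > 182)) min(frost[frost > 182]) else 366L
    if (spring == 0L || fall == 366L)
      message(sprintf("year %s: no %s frost", g$year[1L],
                      if (spring == 0L) "spring" else "fall"))
    data.frame(year = g$year[1L], spring_frost_doy = spring, fall_frost_doy = fall,
               frost_free_days = fall - spring,
               gdd = sum(gdd_day(g$tmin_c, g$tmax_c, base, cap)))
  }))
  rownames(by_year) <- NULL
  summ <- list(
    mean_gdd = mean(by_year$gdd),
    mean_frost_free = mean(by_year$frost_free_days),
    spring_frost_p90 = unname(stats::quantile(by_year$spring_frost_doy, percentile)),
    fall_frost_p90 = unname(stats::quantile(by_year$fall_frost_doy, 1 - percentile)))
  out <- list(by_year = by_year, summary = summ, percentile = percentile)
  class(out) <- "season_metrics"
  out
}

#' @export
print.season_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Season metrics over %d year(s)\n", nrow(x$by_year)))
  cat(sprintf("  mean GDD: %.0f degC day; mean frost-free length: %.1f days\n",
              s$mean_gdd, s$mean_frost_free))
  cat(sprintf("  %.0fth-pct spring frost DOY %.0f, fall frost DOY %.0f\n",
              100 * x$percentile, s$spring_frost_p90, s$fall_frost_p90))
  invisible(x)
}

#' Scenario-minus-baseline deltas of season metrics
#'
#' Signed differences of ensemble means: GDD and frost-free season length.
#'
#' @param scenario_metrics,baseline_metrics `season_metrics` objects.
#' @return Named numeric vector `c(gdd_delta, frost_free_delta)`.
#' @export
scenario_deltas <- function(scenario_metrics, baseline_metrics) {
  stopifnot(inherits(scenario_metrics, "season_metrics"),
            inherits(baseline_metrics, "season_metrics"))
  c(gdd_delta = scenario_metrics$summary$mean_gdd - baseline_metrics$summary$mean_gdd,
    frost_free_delta = scenario_metrics$summary$mean_frost_free -
      baseline_metrics$summary$mean_frost_free)
}
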