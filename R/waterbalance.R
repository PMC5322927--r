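# Monthly water balance (precipitation minus Thornthwaite PET),
# accumulated from zero each year; months where the accumulation is
# negative are "in deficit". May-August deficit-month counts feed the
# risk odds.

#' Monthly climate summary of a daily weather series
#'
#' @param weather A `daily_weather` data.frame.
#' @return A data.frame `year, month, precip_mm, tmean_c` (tmean is the mean
#'   of daily mid-range temperatures).
#' @export
monthly_climate <- function(weather) {
  validate_daily_weather(weather)
  mo <- month_of_doy(weather$doy)
  mid <- daily_mean_temperature(weather$tmin_c, weather$tmax_c)
  p <- stats::aggregate(weather$precip_mm, list(year = weather$year, month = mo), sum)
  t <- stats::aggregate(mid, list(year = weather$year, month = mo), mean)
  out <- data.frame(year = p$year, month = p$month, precip_mm = p$x, tmean_c = t$x)
  out[order(out$year, out$month), ]
}

#' Cumulative water balance over an ensemble of years
#'
#' For each year: monthly PET from that year's mean temperatures via
#' [thornthwaite_pet()], monthly balance `P - PET`, and the cumulative
#' balance initialized at zero at the start of the year. A month is flagged
#' in deficit when the cumulative balance at its end is below zero. Across
#' years, the per-month mean and 5th/95th quantiles of the cumulative
#' balance are summarized, along with the total count of May-August deficit
#' months (the numerator/denominator of the risk odds).
#'
#' @param weather A `daily_weather` data.frame (ensemble of years), or a
#'   data.frame from [monthly_climate()].
#' @param latitude Latitude for the PET calculation.
#' @return An object of class `water_balance_summary` with components
#'   `monthly` (year, month, precip_mm, pet_mm, balance_mm, cum_balance_mm,
#'   deficit), `by_month` (month, mean, q05, q95), `may_aug_deficit_months`,
#'   and `n_years`.
#' @export
cumulative_water_balance <- function(weather, latitude = 40) {
  mc <- if (all(c("month", "precip_mm", "tmean_c") %in% names(weather))) weather
        else monthly_climate(weather)
  rows <- lapply(split(mc, mc$year), function(g) {
    g <- g[order(g$month), ]
    if (nrow(g) != 12L) fail_field("weather", "each year must have all 12 months")
    pet <- thornthwaite_pet(g$tmean_c, latitude)
    bal <- g$precip_mm - pet
    cum <- cumsum(bal)
    data.frame(year = g$year, month = g$month, precip_mm = g$precip_mm,
               pet_mm = pet, balance_mm = bal, cum_balance_mm = cum,
               deficit = cum < 0)
  })
  monthly <- do.call(rbind, rows)
  rownames(monthly) <- NULL
  by_month <- do.call(rbind, lapply(split(monthly, monthly$month), function(g)
    data.frame(month = g$month[1L], mean = mean(g$cum_balance_mm),
               q05 = unname(stats::quantile(g$cum_balance_mm, 0.05)),
               q95 = unname(stats::quantile(g$cum_balance_mm, 0.95)))))
  out <- list(monthly = monthly, by_month = by_month,
              may_aug_deficit_months = sum(monthly$deficit[monthly$month %in% 5:8]),
              n_years = length(unique(monthly$year)))
  class(out) <- "water_balance_summary"
  out
}

#' @export
print.water_balance_summary <- function(x, ...) {
  cat(sprintf("Water balance over %d year(s)\n", x$n_years))
  cat(sprintf("  May-Aug deficit months: %d\n", x$may_aug_deficit_months))
  cat(sprintf("  December cumulative balance, mean: %.1f mm\n",
              x$by_month$mean[x$by_month$month == 12]))
  invisible(x)
}

#' Daily interpolation of the cumulative balance
#'
#' Linear interpolation between month-end cumulative values, starting from 0
#' at DOY 0, averaged across the ensemble years.
#'
#' @param summary A `water_balance_summary`.
#' @return A data.frame `doy, cum_balance_mm`.
#' @export
interpolate_balance_daily <- function(summary) {
  stopifnot(inherits(summary, "water_balance_summary"))
  m <- summary$by_month[order(summary$by_month$month), ]
  stats::setNames(as.data.frame(stats::approx(c(0, MONTH_END_DOY), c(0, m$mean),
                                              xout = 1:365)),
                  c("doy", "cum_balance_mm"))
}

#' May-August drought risk odds
#'
#' Ratio of May-August deficit-month counts, scenario over baseline, both
#' computed over ensembles of equal size.
#'
#' @param scenario_summary,baseline_summary `water_balance_summary` objects.
#' @return The odds ratio; `Inf` with a warning when the baseline count is 0
#'   and the scenario count is positive, 1 when both are 0.
#' @export
risk_odds <- function(scenario_summary, baseline_summary) {
  s <- scenario_summary$may_aug_deficit_months
  b <- baseline_summary$may_aug_deficit_months
  if (scenario_summary$n_years != baseline_summary$n_years)
    warning("scenario and baseline ensembles differ in size; odds compare raw counts")
  if (b == 0) {
    if (s == 0) return(1)
    warning("baseline has zero May-August deficit months; odds are infinite")
    return(Inf)
  }
  s / b
}
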