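# Daily workability probability curves, seasonal FWD comparisons, and
# goodness-of-fit of model predictions against the naive daily
# probabilities implied by weekly reports.

#' Daily workability probability curve
#'
#' Per-DOY probability of a workable day over an ensemble of years: each
#' day's indicator is aggregated soil -> station -> district (fractional
#' values), averaged across districts, then across years. With
#' `mode = "majority"` a district counts as workable on a day when its
#' aggregated indicator is at least 0.5; the default `"fraction"` keeps the
#' fractional values.
#'
#' @param data A [fwd_data()] table.
#' @param schedule A [threshold_schedule()].
#' @param doy_range Length-2 DOY range of the curve.
#' @param mode `"fraction"` (default) or `"majority"`.
#' @return A data.frame of class `workability_curve`: `doy`, `probability`,
#'   plus per-region columns in attribute `by_region`.
#' @export
workability_curve <- function(data, schedule, doy_range = c(85, 180),
                              mode = c("fraction", "majority")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "fwd_data"))
  keep <- data$doy >= doy_range[1] & data$doy <= doy_range[2]
  d <- data[keep, , drop = FALSE]
  if (nrow(d) == 0L) fail_field("data", "no days in the requested DOY range")
  th <- thresholds_at_doy(schedule, d$doy)
  d$ind <- classify_workday(d$sm, d$mt, th$ts, th$tt)
  so <- stats::aggregate(ind ~ district + station_id + year + doy, d, mean)
  di <- stats::aggregate(ind ~ district + year + doy, so, mean)
  if (mode == "majority") di$ind <- as.numeric(di$ind >= 0.5)
  by_region <- stats::aggregate(ind ~ district + doy, di, mean)
  names(by_region) <- c("region", "doy", "probability")
  reg <- stats::aggregate(ind ~ year + doy, di, mean) # region mean per year
  out <- stats::aggregate(ind ~ doy, reg, mean)
  names(out) <- c("doy", "probability")
  stopifnot(all(out$probability >= 0 & out$probability <= 1))
  attr(out, "by_region") <- by_region
  class(out) <- c("workability_curve", "data.frame")
  out
}

#' April-May change in field working days
#'
#' Mean total field working days over April-May (DOY 91-151 in the fixed
#' 365-day calendar) under a scenario minus under the baseline. Positive
#' values mean the scenario gains working days.
#'
#' @param scenario_curve,baseline_curve [workability_curve()]s (or any
#'   data.frames with `doy` and `probability`) covering DOY 91-151.
#' @return Signed change in days.
#' @export
april_may_fwd_change <- function(scenario_curve, baseline_curve) {
  window <- 91:151
  tot <- function(cv) {
    j <- match(window, cv$doy)
    if (anyNA(j)) fail_field("curve", "must cover DOY 91-151 (April-May)")
    sum(cv$probability[j])
  }
  tot(scenario_curve) - tot(baseline_curve)
}

#' Goodness of fit against weekly reports
#'
#' Compares the schedule's predicted weekly FWD counts, spread uniformly over
#' their 7-day windows exactly as the naive report probability is, with the
#' reports' naive daily probability, as a coefficient of determination per
#' DOY. Computed per region and for the region-mean ("statewide") curves.
#'
#' @param schedule A [threshold_schedule()] (or a `fwd_fit`, whose schedule
#'   is used).
#' @param data A [fwd_data()] table.
#' @param reports Weekly reports to validate against.
#' @return A list with `r2_overall` (region-mean curves) and `r2_by_region`.
#' @export
validate_against_reports <- function(schedule, data, reports) {
  if (inherits(schedule, "fwd_fit")) schedule <- schedule$schedule
  windows <- unique(reports[c("start_doy", "end_doy")])
  pred_weekly <- predict_weekly_fwd(data, schedule, windows)
  obs_daily <- naive_report_probability(reports)
  prd_daily <- naive_report_probability(pred_weekly)

  key_o <- paste(obs_daily$region, obs_daily$doy)
  key_p <- paste(prd_daily$region, prd_daily$doy)
  j <- match(key_o, key_p)
  ok <- !is.na(j)
  if (sum(ok) < 2L) fail_field("reports", "need at least 2 overlapping DOY points")
  obs <- obs_daily[ok, ]
  obs$pred <- prd_daily$probability[j[ok]]

  r2 <- function(o, p) 1 - sum((o - p)^2) / sum((o - mean(o))^2)
  by_reg <- vapply(split(obs, obs$region),
                   function(g) r2(g$probability, g$pred), numeric(1))
  state <- stats::aggregate(cbind(probability, pred) ~ doy, obs, mean)
  list(r2_overall = r2(state$probability, state$pred), r2_by_region = by_reg)
}
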