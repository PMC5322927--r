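# Day-of-year-trending workability thresholds and the workable-day
# indicator: a day is workable iff scaled soil moisture (fraction of the
# plastic limit) is at or below the moisture threshold AND the mid-range
# temperature is at or above the temperature threshold.

#' Workability threshold schedule
#'
#' Holds the two per-period threshold pairs and evaluates them as
#' day-of-year-trending thresholds: a straight line through
#' `(split_doy, period-1 value)` and `(trend_end_doy, period-2 value)` for
#' each threshold, extrapolated linearly outside that window. The evaluated
#' temperature threshold is clamped into `tt_clamp` (0-10 deg C by default)
#' and the moisture threshold into `ts_clamp` as a safety rail.
#'
#' @param ts1,tt1 Period-1 soil-moisture threshold (fraction of PL) and
#'   temperature threshold (deg C).
#' @param ts2,tt2 Period-2 thresholds.
#' @param split_doy DOY separating the two calibration periods (default 105).
#' @param trend_end_doy End of the trend window (default 150).
#' @param tt_clamp,ts_clamp Length-2 clamp bounds applied after evaluation.
#' @param mode `"trend"` (default) evaluates the connecting trend line;
#'   `"step"` evaluates piecewise-constant per-period thresholds (the form
#'   the calibration itself estimates).
#' @return An object of class `threshold_schedule`.
#' @export
threshold_schedule <- function(ts1, tt1, ts2, tt2, split_doy = 105L,
                               trend_end_doy = 150L, tt_clamp = c(0, 10),
                               ts_clamp = c(0.5, 1.2), mode = c("trend", "step")) {
  mode <- match.arg(mode)
  stopifnot(ts1 > 0, ts2 > 0, trend_end_doy > split_doy)
  s <- list(ts1 = ts1, tt1 = tt1, ts2 = ts2, tt2 = tt2,
            split_doy = as.integer(split_doy),
            trend_end_doy = as.integer(trend_end_doy),
            tt_clamp = tt_clamp, ts_clamp = ts_clamp, mode = mode,
            ts_slope = (ts2 - ts1) / (trend_end_doy - split_doy),
            tt_slope = (tt2 - tt1) / (trend_end_doy - split_doy))
  class(s) <- "threshold_schedule"
  s
}

#' Evaluate a threshold schedule at days of year
#'
#' Inside the trend window the thresholds follow the connecting line; outside
#' it the same line is extrapolated. The temperature threshold is clamped to
#' its stated bounds after evaluation (and the moisture threshold to its
#' safety bounds, with a warning when that clamp is active).
#'
#' @param schedule A [threshold_schedule()].
#' @param doy Integer vector, 1-365.
#' @return A data.frame with columns `doy`, `ts`, `tt`.
#' @export
thresholds_at_doy <- function(schedule, doy) {
  stopifnot(inherits(schedule, "threshold_schedule"), all(doy >= 1), all(doy <= 365))
  if (schedule$mode == "step") {
    # period 1 runs through the split day itself, so a report window ending
    # exactly on the split day lies wholly in period 1
    ts <- ifelse(doy <= schedule$split_doy, schedule$ts1, schedule$ts2)
    tt <- ifelse(doy <= schedule$split_doy, schedule$tt1, schedule$tt2)
  } else {
    ts <- schedule$ts1 + schedule$ts_slope * (doy - schedule$split_doy)
    tt <- schedule$tt1 + schedule$tt_slope * (doy - schedule$split_doy)
  }
  if (any(ts < schedule$ts_clamp[1] | ts > schedule$ts_clamp[2]))
    warning("moisture-threshold safety clamp active during extrapolation")
  ts <- pmin(pmax(ts, schedule$ts_clamp[1]), schedule$ts_clamp[2])
  tt <- pmin(pmax(tt, schedule$tt_clamp[1]), schedule$tt_clamp[2])
  data.frame(doy = doy, ts = ts, tt = tt)
}

#' @export
print.threshold_schedule <- function(x, ...) {
  cat("Workability threshold schedule (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  period 1 (DOY < %d):   Ts = %.3f x PL, Tt = %.2f degC\n",
              x$split_doy, x$ts1, x$tt1))
  cat(sprintf("  period 2 (DOY %d-%d): Ts = %.3f x PL, Tt = %.2f degC\n",
              x$split_doy, x$trend_end_doy, x$ts2, x$tt2))
  cat(sprintf("  trend slopes: Ts %+.5f /day, Tt %+.4f degC/day; Tt clamp [%g, %g]\n",
              x$ts_slope, x$tt_slope, x$tt_clamp[1], x$tt_clamp[2]))
  invisible(x)
}

#' Classify a day as workable
#'
#' The workable-day indicator: 1 iff scaled soil moisture is at or below the
#' moisture threshold and the mid-range temperature is at or above the
#' temperature threshold (both comparisons inclusive), else 0. Vectorized.
#'
#' @param scaled_moisture Soil moisture as a fraction of the plastic limit.
#' @param mean_temp Daily mid-range temperature (deg C).
#' @param ts Moisture threshold (fraction of PL).
#' @param tt Temperature threshold (deg C).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' classify_workday(0.8, 6, ts = 0.85, tt = 3) # workable
#' classify_workday(0.9, 6, ts = 0.85, tt = 3) # too wet
classify_workday <- function(scaled_moisture, mean_temp, ts, tt) {
  if (any(!is.finite(scaled_moisture)) || any(!is.finite(mean_temp)))
    fail_field("inputs", "must be finite")
  as.integer(scaled_moisture <= ts & mean_temp >= tt)
}

#' Serialize or restore a threshold schedule
#'
#' Small key-value text file so fitted schedules are reusable across runs.
#'
#' @param schedule A [threshold_schedule()].
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  flds <- schedule[c("ts1", "tt1", "ts2", "tt2", "split_doy", "trend_end_doy", "mode")]
  lines <- c(sprintf("%s: %s", names(flds), unlist(flds)),
             sprintf("tt_clamp: %g %g", schedule$tt_clamp[1], schedule$tt_clamp[2]),
             sprintf("ts_clamp: %g %g", schedule$ts_clamp[1], schedule$ts_clamp[2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  num2 <- function(s) as.numeric(strsplit(s, " ")[[1L]])
  threshold_schedule(as.numeric(vals$ts1), as.numeric(vals$tt1),
                     as.numeric(vals$ts2), as.numeric(vals$tt2),
                     split_doy = as.integer(vals$split_doy),
                     trend_end_doy = as.integer(vals$trend_end_doy),
                     tt_clamp = num2(vals$tt_clamp), ts_clamp = num2(vals$ts_clamp),
                     mode = vals$mode)
}
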