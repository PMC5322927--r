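# Grid-search calibration of the workability thresholds against weekly
# FWD reports: one (Ts, Tt) pair per calibration period minimizing the
# squared weekly prediction error under the full soil -> station ->
# district aggregation, the two optima then connected by a straight
# trend line over DOY to form the fitted schedule.

#' Grid specification for the threshold search
#'
#' @param ts_range,ts_step Moisture-threshold range (fraction of PL) and
#'   step.
#' @param tt_range,tt_step Temperature-threshold range (deg C) and step.
#' @return A list with the two grids.
#' @export
fwd_grid <- function(ts_range = c(0.6, 1.1), ts_step = 0.01,
                     tt_range = c(0, 10), tt_step = 0.25) {
  list(ts = seq(ts_range[1], ts_range[2], by = ts_step),
       tt = seq(tt_range[1], tt_range[2], by = tt_step),
       ts_step = ts_step, tt_step = tt_step)
}

# exhaustive SSE grid search over one period's report rows.
# rows: data.frame(sm, mt, rid, w); obs: observed fwd per rid.
# Ties broken toward the lowest Ts, then lowest Tt (loop order + strict
# improvement).
grid_search_period <- function(rows, obs, grid) {
  n_rep <- length(obs)
  best <- list(sse = Inf, ts = NA_real_, tt = NA_real_)
  sse_surface <- matrix(NA_real_, length(grid$ts), length(grid$tt),
                        dimnames = list(NULL, NULL))
  wet_ok <- outer(rows$sm, grid$ts, `<=`)        # n_rows x n_ts
  for (j in seq_along(grid$tt)) {
    warm <- rows$mt >= grid$tt[j]
    for (i in seq_along(grid$ts)) {
      ind <- wet_ok[, i] & warm
      pred <- rowsum(rows$w * ind, rows$rid, reorder = TRUE)[, 1L]
      sse <- sum((pred - obs)^2)
      sse_surface[i, j] <- sse
      if (sse < best$sse ||
          (sse == best$sse && (grid$ts[i] < best$ts ||
                               (grid$ts[i] == best$ts && grid$tt[j] < best$tt)))) {
        best <- list(sse = sse, ts = grid$ts[i], tt = grid$tt[j])
      }
    }
  }
  best$surface <- sse_surface
  best
}

# build the per-period row structure: every table day inside a report
# window, with its report index and aggregation weight. The weight makes
# the weighted row sum equal the district-aggregated weekly prediction:
# 1 / (number of stations in district x number of soils at station).
period_rows <- function(data, reports) {
  key_rep <- paste(reports$region, reports$year, reports$start_doy)
  widx <- rep(NA_integer_, nrow(data))
  rid <- rep(NA_integer_, nrow(data))
  for (i in seq_len(nrow(reports))) {
    sel <- data$district == reports$region[i] & data$year == reports$year[i] &
      data$doy >= reports$start_doy[i] & data$doy <= reports$end_doy[i]
    rid[sel] <- i
  }
  keep <- !is.na(rid)
  d <- data[keep, , drop = FALSE]
  rid <- rid[keep]
  # aggregation weights
  st_per_d <- tapply(data$station_id, data$district,
                     function(x) length(unique(x)))
  so_per_st <- tapply(data$soil_id, data$station_id,
                      function(x) length(unique(x)))
  w <- 1 / (st_per_d[d$district] * so_per_st[d$station_id])
  covered <- sort(unique(rid))
  data.frame(sm = d$sm, mt = d$mt,
             rid = match(rid, covered), w = as.numeric(w),
             stringsAsFactors = FALSE) -> rows
  list(rows = rows, obs_idx = covered)
}

#' Fit workability thresholds to weekly FWD reports
#'
#' The central estimator. Reports are split into two calibration periods by
#' window start DOY (period 1 before `split_doy`, period 2 from `split_doy`
#' to `trend_end_doy`; later reports are excluded). For each period an
#' exhaustive grid search over (moisture threshold, temperature threshold)
#' minimizes the summed squared error between district-aggregated predicted
#' weekly FWD counts and the reported counts. A straight line through
#' `(split_doy, period-1 optimum)` and `(trend_end_doy, period-2 optimum)`
#' for each threshold becomes the fitted DOY-trending schedule, whose
#' purpose is to remove day-of-year trends in the prediction error.
#'
#' @param reports Weekly report data.frame (`region, year, start_doy,
#'   end_doy, fwd`).
#' @param data A [fwd_data()] workability table covering the report days.
#' @param grid A [fwd_grid()].
#' @param split_doy,trend_end_doy Period boundaries (defaults 105 and 150).
#' @param tt_clamp,ts_clamp Clamp bounds passed to the fitted
#'   [threshold_schedule()].
#' @return An object of class `fwd_fit`: the fitted schedule plus per-period
#'   optima and SSEs, fitted weekly values, residuals and diagnostics.
#'   Supports `print`, `summary`, `coef`, `predict`, `residuals`, `plot`
#'   and `simulate`.
#' @export
fwd_fit <- function(reports, data, grid = fwd_grid(), split_doy = 105L,
                    trend_end_doy = 150L, tt_clamp = c(0, 10),
                    ts_clamp = c(0.5, 1.2)) {
  stopifnot(inherits(data, "fwd_data"))
  p1 <- reports[reports$start_doy < split_doy, , drop = FALSE]
  p2 <- reports[reports$start_doy >= split_doy & reports$start_doy <= trend_end_doy, ,
                drop = FALSE]
  if (nrow(p1) == 0L) fail_field("reports", "no reports before the split DOY (period 1 empty)")
  if (nrow(p2) == 0L) fail_field("reports", "no reports in the trend window (period 2 empty)")

  fit_period <- function(rep_p) {
    pr <- period_rows(data, rep_p)
    if (nrow(pr$rows) == 0L) fail_field("data", "workability table does not cover the reports")
    obs <- rep_p$fwd[pr$obs_idx]
    grid_search_period(pr$rows, obs, grid)
  }
  b1 <- fit_period(p1)
  b2 <- fit_period(p2)

  schedule <- threshold_schedule(b1$ts, b1$tt, b2$ts, b2$tt,
                                 split_doy = split_doy, trend_end_doy = trend_end_doy,
                                 tt_clamp = tt_clamp, ts_clamp = ts_clamp)

  used <- rbind(p1, p2)
  windows <- unique(used[c("start_doy", "end_doy")])
  fitted_tab <- predict_weekly_fwd(data, schedule, windows)
  key_f <- paste(fitted_tab$region, fitted_tab$year, fitted_tab$start_doy)
  key_u <- paste(used$region, used$year, used$start_doy)
  used$fitted <- fitted_tab$fwd[match(key_u, key_f)]
  used$residual <- used$fwd - used$fitted
  used$mid_doy <- (used$start_doy + used$end_doy) / 2

  # diagnostic: after trending thresholds the residuals should show no
  # DOY trend
  trend <- stats::lm(residual ~ mid_doy, data = used)
  sl <- summary(trend)$coefficients
  diag <- list(residual_doy_slope = unname(stats::coef(trend)[2L]),
               residual_doy_slope_p = if (nrow(sl) > 1L) sl[2L, 4L] else NA_real_)

  out <- list(schedule = schedule,
              period1 = list(ts = b1$ts, tt = b1$tt, sse = b1$sse, n = nrow(p1)),
              period2 = list(ts = b2$ts, tt = b2$tt, sse = b2$sse, n = nrow(p2)),
              grid = grid, reports = used, diagnostics = diag,
              data = data, call = match.call())
  class(out) <- "fwd_fit"
  out
}

#' @export
print.fwd_fit <- function(x, ...) {
  cat("Workability threshold calibration (grid search)\n")
  cat(sprintf("  period 1: Ts = %.3f x PL, Tt = %.2f degC  (SSE %.4g over %d reports)\n",
              x$period1$ts, x$period1$tt, x$period1$sse, x$period1$n))
  cat(sprintf("  period 2: Ts = %.3f x PL, Tt = %.2f degC  (SSE %.4g over %d reports)\n",
              x$period2$ts, x$period2$tt, x$period2$sse, x$period2$n))
  cat(sprintf("  trend window DOY %d-%d; residual DOY slope %+.4f d/d (p = %.3g)\n",
              x$schedule$split_doy, x$schedule$trend_end_doy,
              x$diagnostics$residual_doy_slope, x$diagnostics$residual_doy_slope_p))
  invisible(x)
}

#' @export
summary.fwd_fit <- function(object, ...) {
  r <- object$reports$residual
  structure(list(fit = object,
                 rmse = sqrt(mean(r^2)), mae = mean(abs(r)),
                 n_reports = nrow(object$reports),
                 diagnostics = object$diagnostics),
            class = "summary.fwd_fit")
}

#' @export
print.summary.fwd_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  weekly RMSE %.3f days, MAE %.3f days over %d reports\n",
              x$rmse, x$mae, x$n_reports))
  invisible(x)
}

#' @export
coef.fwd_fit <- function(object, ...) {
  s <- object$schedule
  c(ts1 = s$ts1, tt1 = s$tt1, ts2 = s$ts2, tt2 = s$tt2,
    ts_slope = s$ts_slope, tt_slope = s$tt_slope)
}

#' Predict weekly FWD counts from a fitted calibration
#'
#' @param object A `fwd_fit`.
#' @param newdata A [fwd_data()] table (defaults to the training table).
#' @param windows Report windows (defaults to the training windows).
#' @param ... Unused.
#' @return A data.frame `region, year, start_doy, end_doy, fwd`.
#' @export
predict.fwd_fit <- function(object, newdata = NULL, windows = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.null(windows))
    windows <- unique(object$reports[c("start_doy", "end_doy")])
  predict_weekly_fwd(newdata, object$schedule, windows)
}

#' @export
residuals.fwd_fit <- function(object, ...) object$reports$residual

#' @export
fitted.fwd_fit <- function(object, ...) object$reports$fitted

#' Simulate weekly reports from a fitted schedule
#'
#' @param object A `fwd_fit`.
#' @param nsim Number of replicate report sets.
#' @param seed Integer seed.
#' @param noise_sd Report noise s.d. (days).
#' @param ... Unused.
#' @return A list of `nsim` report data.frames.
#' @export
simulate.fwd_fit <- function(object, nsim = 1, seed = 1L, noise_sd = 0.5, ...) {
  windows <- unique(object$reports[c("start_doy", "end_doy")])
  lapply(seq_len(nsim), function(i)
    generate_fwd_reports(object$data, object$schedule, windows,
                         noise_sd = noise_sd, seed = derive_seed(seed, i)))
}

#' Plot a fitted threshold schedule
#'
#' Two panels: the DOY-trending moisture and temperature thresholds with the
#' period optima marked, base graphics.
#'
#' @param x A `fwd_fit`.
#' @param doy_range DOY range to draw.
#' @param ... Passed to `plot`.
#' @export
plot.fwd_fit <- function(x, doy_range = c(85, 180), ...) {
  doy <- doy_range[1]:doy_range[2]
  th <- suppressWarnings(thresholds_at_doy(x$schedule, doy))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(doy, th$ts, type = "l", xlab = "day of year",
                 ylab = "Ts (fraction of PL)", main = "Moisture threshold", ...)
  graphics::points(c(x$schedule$split_doy, x$schedule$trend_end_doy),
                   c(x$period1$ts, x$period2$ts), pch = 19)
  graphics::plot(doy, th$tt, type = "l", xlab = "day of year",
                 ylab = "Tt (degC)", main = "Temperature threshold", ...)
  graphics::points(c(x$schedule$split_doy, x$schedule$trend_end_doy),
                   c(x$period1$tt, x$period2$tt), pch = 19)
  invisible(x)
}
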