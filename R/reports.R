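# Weekly field-working-day reports: fixture generation from a known true
# threshold schedule (closed-loop testing of the calibration), the naive
# uniform daily probability derived from weekly counts, and delimited-text
# I/O. Region values are district averages, so non-integer counts are
# legal.

#' Generate weekly FWD reports from a known threshold schedule
#'
#' Emulates weekly crop-progress reporting: each report's FWD count is the
#' district-aggregated sum of workable-day indicators over its 7-day window
#' under `true_schedule`, optionally perturbed by integer-rounded Gaussian
#' noise truncated to `[0, 7]`. Used to close the loop on the threshold
#' calibration: the optimizer should recover the generating schedule.
#'
#' @param data A [fwd_data()] workability table.
#' @param true_schedule A [threshold_schedule()] (use `mode = "step"` when
#'   the calibration's piecewise-constant estimate is to be recovered
#'   exactly).
#' @param windows Report windows (see [weekly_windows()]); must lie within
#'   DOY 85-180.
#' @param noise_sd Report noise s.d. in days; 0 gives exact counts.
#' @param seed Seed for the noise draws.
#' @return A data.frame `region, year, start_doy, end_doy, fwd`.
#' @export
generate_fwd_reports <- function(data, true_schedule, windows, noise_sd = 0,
                                 seed = 1L) {
  if (any(windows$start_doy < 85 | windows$end_doy > 180))
    fail_field("windows", "report windows must lie within DOY 85-180")
  if (any(windows$end_doy - windows$start_doy != 6L))
    fail_field("windows", "windows must be 7 days long")
  rep <- predict_weekly_fwd(data, true_schedule, windows)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    rep$fwd <- pmin(7, pmax(0, round(rep$fwd + stats::rnorm(nrow(rep), 0, noise_sd))))
  }
  rep
}

#' Naive daily workability probability from weekly reports
#'
#' Assigns each reported weekly FWD count uniformly to the 7 days of its
#' window (`count / 7` per day) and averages across years per DOY and
#' region — the way weekly progress reports are conventionally turned into
#' a daily probability.
#'
#' @param reports A report data.frame (`region, year, start_doy, end_doy,
#'   fwd`); windows must not overlap within a region-year.
#' @return A data.frame `region, doy, probability`.
#' @export
naive_report_probability <- function(reports) {
  split_ry <- split(reports, paste(reports$region, reports$year))
  for (g in split_ry) {
    o <- g[order(g$start_doy), ]
    if (nrow(o) > 1L && any(o$start_doy[-1L] <= o$end_doy[-nrow(o)]))
      fail_field("reports", "windows overlap within a region-year")
  }
  day_rows <- do.call(rbind, lapply(seq_len(nrow(reports)), function(i)
    data.frame(region = reports$region[i],
               doy = reports$start_doy[i]:reports$end_doy[i],
               p = reports$fwd[i] / 7)))
  out <- stats::aggregate(p ~ region + doy, day_rows, mean)
  names(out)[names(out) == "p"] <- "probability"
  out[order(out$region, out$doy), ]
}

#' Read or write weekly FWD reports as delimited text
#'
#' Columns: `region, year, start_doy, end_doy, fwd` with `fwd` in `[0, 7]`.
#'
#' @param reports A report data.frame (for writing).
#' @param path File path.
#' @export
write_reports <- function(reports, path) {
  utils::write.table(reports, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  r <- utils::read.delim(path)
  if (any(r$fwd < 0 | r$fwd > 7)) fail_field("fwd", "counts must lie in [0, 7]")
  if (any(r$end_doy - r$start_doy != 6L)) fail_field("reports", "windows must be 7 days")
  r
}
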