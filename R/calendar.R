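#' @keywords internal
"_PACKAGE"

# Fixed 365-day calendar: all reasoning is in day-of-year (DOY 1-365),
# no leap days. Month lengths sum to 365.
MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_END_DOY <- cumsum(MONTH_DAYS)
MONTH_START_DOY <- MONTH_END_DOY - MONTH_DAYS + 1L

#' Month index for a day of year
#'
#' Maps DOY 1-365 (fixed 365-day calendar, no leap days) to month 1-12.
#'
#' @param doy Integer vector of days of year in 1..365.
#' @return Integer vector of months (1 = January).
#' @export
#' @examples
#' month_of_doy(c(1, 31, 32, 365))
month_of_doy <- function(doy) {
  stopifnot(all(doy >= 1), all(doy <= 365))
  findInterval(doy, MONTH_START_DOY)
}

#' Mid-month day of year
#'
#' @param month Integer vector of months 1-12.
#' @return DOY of the (rounded) middle day of each month.
#' @export
mid_month_doy <- function(month) {
  stopifnot(all(month >= 1), all(month <= 12))
  MONTH_START_DOY[month] + (MONTH_DAYS[month] - 1L) %/% 2L
}

# Derive a stage seed from a master seed; keeps the result a valid
# 32-bit R integer. Distinct tags give effectively independent streams.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}

# Stop with the offending field named, used by validators throughout.
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
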