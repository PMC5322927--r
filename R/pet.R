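# Thornthwaite monthly potential evapotranspiration: temperature- and
# latitude-only, the classical empirical formulation.

# Mean day length (hours) for each month at a latitude, evaluated at the
# mid-month day via the standard solar-declination approximation.
day_length_hours <- function(latitude, doy) {
  phi <- latitude * pi / 180
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(delta)
  x <- pmin(pmax(x, -1), 1) # polar day/night guard
  ws <- acos(x)
  24 / pi * ws
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical Thornthwaite PET from monthly mean temperature and latitude.
#' The annual heat index is `I = sum((T/5)^1.514)` over months with `T > 0`;
#' the exponent is `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`;
#' unadjusted PET is `16 (10 T / I)^a` mm for `0 < T <= 26.5` deg C, the
#' standard high-temperature polynomial `-415.85 + 32.24 T - 0.43 T^2` above
#' 26.5 deg C, and 0 for `T <= 0`. The result is adjusted by the day-length /
#' month-length factor `(L/12)(N/30)` with `L` the mid-month day length.
#'
#' @param monthly_mean_temp Numeric length-12, monthly mean temperatures
#'   (deg C).
#' @param latitude Latitude in decimal degrees, `|latitude| <= 66.5`.
#' @return Numeric length-12 of monthly PET (mm).
#' @export
#' @examples
#' thornthwaite_pet(c(-3, 0, 6, 12, 18, 23, 25, 24, 20, 13, 6, 0), 40)
thornthwaite_pet <- function(monthly_mean_temp, latitude) {
  Tm <- as.numeric(monthly_mean_temp)
  if (length(Tm) != 12L || any(!is.finite(Tm)))
    fail_field("monthly_mean_temp", "must be 12 finite values")
  if (abs(latitude) > 66.5) fail_field("latitude", "|latitude| must be <= 66.5")

  pos <- Tm > 0
  I <- sum((Tm[pos] / 5)^1.514)
  pet <- numeric(12L)
  if (I > 0) {
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    lo <- pos & Tm <= 26.5
    hi <- Tm > 26.5
    pet[lo] <- 16 * (10 * Tm[lo] / I)^a
    pet[hi] <- -415.85 + 32.24 * Tm[hi] - 0.43 * Tm[hi]^2
  }
  L <- day_length_hours(latitude, mid_month_doy(1:12))
  pet * (L / 12) * (MONTH_DAYS / 30)
}

# Daily PET proxy for the bucket model: the month's Thornthwaite PET
# divided evenly across its days, computed per simulated year from that
# year's monthly mean mid-range temperatures. One PET definition serves
# both the moisture and drought stages.
daily_pet_series <- function(weather, latitude) {
  mo <- month_of_doy(weather$doy)
  mid <- (weather$tmin_c + weather$tmax_c) / 2
  out <- numeric(nrow(weather))
  for (y in unique(weather$year)) {
    iy <- weather$year == y
    tm <- tapply(mid[iy], mo[iy], mean)
    tm12 <- numeric(12L); tm12[as.integer(names(tm))] <- tm
    pet_m <- thornthwaite_pet(tm12, latitude)
    out[iy] <- (pet_m / MONTH_DAYS)[mo[iy]]
  }
  out
}
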