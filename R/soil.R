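# Soil profiles and pedotransfer estimates of the parameters governing
# moisture scaling and workability: plastic limit (PL), field capacity
# (FC), wilting point (WP), porosity.

#' Estimate the soil plastic limit from clay and organic matter
#'
#' A simple linear pedotransfer of the gravimetric plastic limit,
#' `PL_g = 0.12 + 0.0030 * clay_pct + 0.010 * om_pct` (g water per g soil),
#' converted to a volumetric fraction by multiplying with the bulk density
#' (assuming water density 1 g cm-3). The coefficients give PL values typical
#' of temperate agricultural silt loams (about 0.20-0.30 g/g) and make PL
#' strictly increasing in both clay and organic matter, the behaviour that
#' workability thresholds expressed as fractions of PL rely on.
#'
#' @param clay Clay content, mass percent in `[0, 100]`.
#' @param organic_matter Organic matter content, mass percent in `[0, 30]`.
#' @param bulk_density Dry bulk density, g cm-3 in `(0.5, 2.0)`; default 1.3
#'   is typical of Illinois silt loams.
#' @return Volumetric plastic limit (m3 m-3).
#' @export
#' @examples
#' estimate_plastic_limit(clay = 25, organic_matter = 3)
estimate_plastic_limit <- function(clay, organic_matter, bulk_density = 1.3) {
  if (any(clay < 0 | clay > 100)) fail_field("clay", "must be in [0, 100] %")
  if (any(organic_matter < 0 | organic_matter > 30))
    fail_field("organic_matter", "must be in [0, 30] %")
  if (any(bulk_density <= 0.5 | bulk_density >= 2.0))
    fail_field("bulk_density", "must be in (0.5, 2.0) g cm-3")
  pl_grav <- 0.12 + 0.0030 * clay + 0.010 * organic_matter
  pl_grav * bulk_density
}

#' Estimate water retention parameters from texture
#'
#' Saxton & Rawls (2006)-type regression pedotransfer: wilting point
#' (1500 kPa water content), field capacity (33 kPa) and saturation
#' (porosity) from sand, clay and organic matter.
#'
#' @param sand,clay Sand / clay content, mass percent (silt is the
#'   remainder).
#' @param organic_matter Organic matter, mass percent.
#' @return A list with volumetric fractions `fc`, `wp`, `porosity`,
#'   satisfying `wp < fc < porosity`.
#' @export
#' @examples
#' estimate_water_retention(sand = 40, clay = 20, organic_matter = 2.5)
estimate_water_retention <- function(sand, clay, organic_matter) {
  if (any(sand < 0 | clay < 0 | sand + clay > 100))
    fail_field("texture", "sand and clay must be non-negative and sum to <= 100 %")
  S <- sand / 100; C <- clay / 100; OM <- organic_matter

  t1500 <- -0.024 * S + 0.487 * C + 0.006 * OM +
    0.005 * S * OM - 0.013 * C * OM + 0.068 * S * C + 0.031
  wp <- t1500 + (0.14 * t1500 - 0.02)

  t33 <- -0.251 * S + 0.195 * C + 0.011 * OM +
    0.006 * S * OM - 0.027 * C * OM + 0.452 * S * C + 0.299
  fc <- t33 + (1.283 * t33^2 - 0.374 * t33 - 0.015)

  ts33 <- 0.278 * S + 0.034 * C + 0.022 * OM -
    0.018 * S * OM - 0.027 * C * OM - 0.584 * S * C + 0.078
  sat_minus_fc <- ts33 + (0.636 * ts33 - 0.107)
  porosity <- fc + sat_minus_fc - 0.097 * S + 0.043

  wp <- pmax(wp, 0.01)
  fc <- pmax(fc, wp + 0.01)
  porosity <- pmin(pmax(porosity, fc + 0.01), 1)
  list(fc = fc, wp = wp, porosity = porosity)
}

#' Construct a soil profile
#'
#' Derives hydraulic and consistency parameters from texture and organic
#' matter via [estimate_water_retention()] and [estimate_plastic_limit()].
#'
#' @param soil_id Identifier.
#' @param sand,silt,clay Texture, mass percent; must sum to 100 +- 0.5.
#' @param organic_matter Organic matter, mass percent.
#' @param station_id,district Links into the station/district hierarchy.
#' @param bulk_density Dry bulk density, g cm-3.
#' @return An object of class `soil_profile` with fields `pl`, `fc`, `wp`,
#'   `porosity` (all volumetric fractions) alongside the inputs.
#' @export
soil_profile <- function(soil_id, sand, silt, clay, organic_matter,
                         station_id = NA_character_, district = NA_character_,
                         bulk_density = 1.3) {
  if (abs(sand + silt + clay - 100) > 0.5)
    fail_field("texture", "sand + silt + clay must equal 100 +- 0.5 %")
  ret <- estimate_water_retention(sand, clay, organic_matter)
  pl <- estimate_plastic_limit(clay, organic_matter, bulk_density)
  # PL must sit inside the physically meaningful moisture range
  pl <- min(pl, ret$porosity * 0.95)
  if (pl <= 0) fail_field("pl", "derived plastic limit must be positive")
  p <- list(soil_id = as.character(soil_id), station_id = as.character(station_id),
            district = as.character(district),
            sand = sand, silt = silt, clay = clay, organic_matter = organic_matter,
            bulk_density = bulk_density,
            pl = pl, fc = ret$fc, wp = ret$wp, porosity = ret$porosity)
  class(p) <- "soil_profile"
  stopifnot(p$wp > 0, p$wp < p$fc, p$fc < p$porosity, p$porosity <= 1)
  p
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("Soil '%s' (station %s, district %s)\n", x$soil_id, x$station_id, x$district))
  cat(sprintf("  texture: %g/%g/%g %% sand/silt/clay, OM %g %%\n",
              x$sand, x$silt, x$clay, x$organic_matter))
  cat(sprintf("  PL %.3f  FC %.3f  WP %.3f  porosity %.3f (m3 m-3)\n",
              x$pl, x$fc, x$wp, x$porosity))
  invisible(x)
}

#' Scale volumetric moisture by the plastic limit
#'
#' Workability thresholds are expressed as fractions of the soil-specific
#' plastic limit, so different soils share one threshold scale.
#'
#' @param vwc Volumetric water content (m3 m-3), in `[0, porosity]`.
#' @param profile A [soil_profile()].
#' @return `vwc / PL`, dimensionless.
#' @export
scale_moisture <- function(vwc, profile) {
  stopifnot(inherits(profile, "soil_profile"))
  if (profile$pl <= 0) fail_field("pl", "plastic limit must be > 0")
  if (any(vwc < 0 | vwc > profile$porosity + 1e-9))
    fail_field("vwc", "must lie in [0, porosity]")
  vwc / profile$pl
}

#' Read or write a soil table as delimited text
#'
#' Input columns: `soil_id, station_id, district, sand_pct, silt_pct,
#' clay_pct, om_pct` and optional `bulk_density`. `read_soils()` returns a
#' list of [soil_profile()] objects; `write_soils()` writes the table with
#' the derived `pl, fc, wp, porosity` columns appended.
#'
#' @param path File path.
#' @param soils A list of `soil_profile` objects (for writing).
#' @return `read_soils()`: a named list of `soil_profile`s.
#' @export
read_soils <- function(path) {
  tab <- utils::read.delim(path)
  bd <- if ("bulk_density" %in% names(tab)) tab$bulk_density else rep(1.3, nrow(tab))
  soils <- lapply(seq_len(nrow(tab)), function(i)
    soil_profile(tab$soil_id[i], tab$sand_pct[i], tab$silt_pct[i], tab$clay_pct[i],
                 tab$om_pct[i], station_id = tab$station_id[i],
                 district = tab$district[i], bulk_density = bd[i]))
  names(soils) <- tab$soil_id
  soils
}

#' @rdname read_soils
#' @export
write_soils <- function(soils, path) {
  tab <- do.call(rbind, lapply(soils, function(s)
    data.frame(soil_id = s$soil_id, station_id = s$station_id, district = s$district,
               sand_pct = s$sand, silt_pct = s$silt, clay_pct = s$clay,
               om_pct = s$organic_matter, bulk_density = s$bulk_density,
               pl = s$pl, fc = s$fc, wp = s$wp, porosity = s$porosity)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
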