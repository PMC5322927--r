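# End-to-end orchestration: build a synthetic multi-district study,
# calibrate the workability thresholds in a closed loop, and run
# baseline-vs-scenario comparisons (workability curves, April-May FWD
# deltas, May-August risk odds, GDD and frost deltas). Baseline and
# scenario share derived seeds per region so deltas are free of
# generator sampling noise from differing draws.

#' Default Illinois-like district set
#'
#' The nine crop-district identifiers whose unweighted mean defines the
#' state value.
#'
#' @return Character vector of nine district names.
#' @export
il_districts <- function() c("NW", "NE", "W", "C", "E", "WSW", "ESE", "SW", "SE")

#' Default soil set for a district list
#'
#' Two contrasting agricultural soils (a silt loam and a silty clay loam)
#' per district, attached to one representative station per district.
#'
#' @param districts Character vector of district names.
#' @return A list of [soil_profile()]s.
#' @export
default_soils <- function(districts = il_districts()) {
  out <- list()
  for (d in districts) {
    st <- paste0("st_", d)
    out[[paste0(d, "_siltloam")]] <-
      soil_profile(paste0(d, "_siltloam"), sand = 20, silt = 60, clay = 20,
                   organic_matter = 3, station_id = st, district = d)
    out[[paste0(d, "_sicl")]] <-
      soil_profile(paste0(d, "_sicl"), sand = 10, silt = 55, clay = 35,
                   organic_matter = 3.5, station_id = st, district = d)
  }
  out
}

#' Run configuration
#'
#' Collects everything an end-to-end run needs. Can be read from / written
#' to a YAML file.
#'
#' @param districts District names (one representative station each).
#' @param params Baseline [weather_params()].
#' @param soils List of [soil_profile()]s linked to the district stations.
#' @param scenarios Named list of [scenario_config()]s.
#' @param n_gen Years generated per region and scenario.
#' @param n_sub Years randomly subsampled for the soil-moisture runs.
#' @param windows Weekly report windows.
#' @param grid A [fwd_grid()].
#' @param bucket A [bucket_config()].
#' @param seed Master seed; all stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(districts = il_districts(), params = il_weather_params(),
                       soils = default_soils(districts),
                       scenarios = default_scenarios(),
                       n_gen = 1000L, n_sub = 100L,
                       windows = weekly_windows(), grid = fwd_grid(),
                       bucket = bucket_config(), seed = 20260101L) {
  stopifnot(n_sub <= n_gen)
  cfg <- list(districts = districts, params = params, soils = soils,
              scenarios = scenarios, n_gen = as.integer(n_gen),
              n_sub = as.integer(n_sub), windows = windows, grid = grid,
              bucket = bucket, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Stylized emissions scenarios
#'
#' Three delta-change scenarios of increasing intensity, emulating the
#' qualitative structure of low/intermediate/high emissions projections for
#' the US Midwest at mid-century: modest-to-strong warming, wetter winters
#' and springs, and drier or unchanged summers.
#'
#' @return A named list of [scenario_config()]s.
#' @export
default_scenarios <- function() {
  list(
    low = scenario_config(
      "low", temp_delta = rep(1.5, 12),
      precip_factor = c(1.05, 1.05, 1.1, 1.1, 1.05, 1, 0.95, 0.95, 1, 1, 1.05, 1.05),
      horizon = "mid-century"),
    mid = scenario_config(
      "mid", temp_delta = rep(2.5, 12),
      precip_factor = c(1.1, 1.1, 1.15, 1.15, 1.1, 0.95, 0.9, 0.9, 0.95, 1, 1.05, 1.1),
      horizon = "mid-century"),
    high = scenario_config(
      "high", temp_delta = c(3, 3, 3.5, 3.5, 3.5, 4, 4, 4, 3.5, 3.5, 3, 3),
      precip_factor = c(1.15, 1.15, 1.2, 1.15, 1.05, 0.9, 0.85, 0.85, 0.9, 1, 1.1, 1.15),
      horizon = "mid-century"))
}

#' Build a synthetic multi-district study
#'
#' Generates `n_gen` years of weather per district (one representative
#' station each, district-specific derived seeds), subsamples `n_sub` years,
#' runs the bucket model for every soil, and assembles the [fwd_data()]
#' workability table.
#'
#' @param config A [run_config()].
#' @param scenario Optional [scenario_config()] applied to the generator
#'   parameters before simulation (delta-change).
#' @return A list: `weather` (named by station, full `n_gen` years),
#'   `weather_sub` (subsampled years), `moisture` (named by soil),
#'   `data` (the `fwd_data` table).
#' @export
make_study <- function(config, scenario = NULL) {
  params <- config$params
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  weather <- list(); weather_sub <- list(); moisture <- list()
  for (d in config$districts) {
    st <- paste0("st_", d)
    w <- generate_daily_weather(params, config$n_gen,
                                seed = derive_seed(config$seed, paste0("wx_", d)))
    weather[[st]] <- w
    weather_sub[[st]] <- subsample_years(w, config$n_sub,
                                         seed = derive_seed(config$seed, paste0("sub_", d)))
  }
  for (s in config$soils) {
    st <- s$station_id
    moisture[[s$soil_id]] <- simulate_soil_moisture(weather_sub[[st]], s,
                                                    config = config$bucket,
                                                    latitude = params$latitude)
  }
  data <- fwd_data(weather_sub, moisture, config$soils)
  list(weather = weather, weather_sub = weather_sub, moisture = moisture, data = data)
}

#' Closed-loop calibration run
#'
#' Builds the baseline study, generates weekly reports from `true_schedule`
#' (step mode, optional noise), and calibrates the thresholds against them.
#'
#' @param config A [run_config()].
#' @param true_schedule The generating [threshold_schedule()]; defaults to a
#'   schedule in the range typical of the fitted thresholds (moisture
#'   thresholds between 0.7 and 1 times PL).
#' @param noise_sd Report noise s.d. (days).
#' @return A list: `fit` (the [fwd_fit()]), `reports`, `study`,
#'   `true_schedule`, and `validation` (closed-loop R^2 from
#'   [validate_against_reports()]).
#' @export
run_fit <- function(config, true_schedule = NULL, noise_sd = 0) {
  if (is.null(true_schedule))
    true_schedule <- threshold_schedule(0.80, 2.0, 0.95, 5.0, mode = "step")
  study <- make_study(config)
  reports <- generate_fwd_reports(study$data, true_schedule, config$windows,
                                  noise_sd = noise_sd,
                                  seed = derive_seed(config$seed, "reports"))
  fit <- fwd_fit(reports, study$data, grid = config$grid)
  val <- validate_against_reports(fit, study$data, reports)
  list(fit = fit, reports = reports, study = study,
       true_schedule = true_schedule, validation = val)
}

#' Baseline-vs-scenario comparison run
#'
#' For every scenario in the config: paired-seed generation (same derived
#' seeds as the baseline), then per-region and state workability curves,
#' April-May FWD deltas, May-August risk odds over the full `n_gen`-year
#' weather ensemble, and GDD / frost-free-season deltas.
#'
#' @param config A [run_config()].
#' @param schedule The fitted [threshold_schedule()] used for
#'   classification.
#' @param baseline_study Optional precomputed baseline [make_study()]
#'   result (reused to avoid regenerating it).
#' @return A list with `curves` (region x scenario daily probabilities,
#'   long format), `deltas` (one row per scenario: April-May FWD delta,
#'   risk odds, GDD delta, frost-free delta, all state-level), and
#'   `baseline_study`.
#' @export
run_scenarios <- function(config, schedule, baseline_study = NULL) {
  if (is.null(baseline_study)) baseline_study <- make_study(config)
  base_curve <- workability_curve(baseline_study$data, schedule)
  base_wb <- lapply(baseline_study$weather, function(w)
    cumulative_water_balance(w, config$params$latitude))
  base_season <- lapply(baseline_study$weather, frost_dates)
  pool_wb <- function(lst) { # state = pooled deficit counts across districts
    s <- list(may_aug_deficit_months = sum(vapply(lst, `[[`, 0, "may_aug_deficit_months")),
              n_years = sum(vapply(lst, `[[`, 0, "n_years")))
    class(s) <- "water_balance_summary"
    s
  }
  mean_season <- function(lst) {
    s <- list(summary = list(
      mean_gdd = mean(vapply(lst, function(x) x$summary$mean_gdd, 0)),
      mean_frost_free = mean(vapply(lst, function(x) x$summary$mean_frost_free, 0))),
      by_year = lst[[1L]]$by_year, percentile = lst[[1L]]$percentile)
    class(s) <- "season_metrics"
    s
  }
  curves <- data.frame(scenario = "baseline", doy = base_curve$doy,
                       probability = base_curve$probability)
  deltas <- NULL
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    st <- make_study(config, scenario = sc)
    cv <- workability_curve(st$data, schedule)
    wb <- lapply(st$weather, function(w)
      cumulative_water_balance(w, config$params$latitude))
    se <- lapply(st$weather, frost_dates)
    dd <- scenario_deltas(mean_season(se), mean_season(base_season))
    deltas <- rbind(deltas, data.frame(
      scenario = nm, horizon = sc$horizon,
      april_may_fwd_delta = april_may_fwd_change(cv, base_curve),
      risk_odds = risk_odds(pool_wb(wb), pool_wb(base_wb)),
      gdd_delta = unname(dd["gdd_delta"]),
      frost_free_delta = unname(dd["frost_free_delta"])))
    curves <- rbind(curves, data.frame(scenario = nm, doy = cv$doy,
                                       probability = cv$probability))
  }
  list(curves = curves, deltas = deltas, baseline_study = baseline_study)
}

#' Read or write a run configuration as YAML
#'
#' Serializes the scalar and monthly-vector parts of a [run_config()] (the
#' generator parameters, scenario blocks, ensemble sizes, windows, grid,
#' bucket settings and seed); soils are written as a texture table and
#' rebuilt through [soil_profile()] on read.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  soil_tab <- lapply(config$soils, function(s)
    list(soil_id = s$soil_id, station_id = s$station_id, district = s$district,
         sand = s$sand, silt = s$silt, clay = s$clay,
         organic_matter = s$organic_matter, bulk_density = s$bulk_density))
  obj <- list(districts = config$districts,
              params = unclass(config$params),
              soils = unname(soil_tab),
              scenarios = lapply(config$scenarios, unclass),
              n_gen = config$n_gen, n_sub = config$n_sub,
              windows = as.list(config$windows),
              grid = config$grid[c("ts_step", "tt_step")],
              grid_ts_range = range(config$grid$ts),
              grid_tt_range = range(config$grid$tt),
              bucket = config$bucket, seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  o <- yaml::read_yaml(path)
  params <- do.call(weather_params, o$params[c("tmax_mean", "tmin_mean", "temp_sd",
                                               "p_wet_wet", "p_wet_dry",
                                               "gamma_shape", "gamma_scale",
                                               "range_floor", "latitude")])
  soils <- lapply(o$soils, function(s)
    soil_profile(s$soil_id, s$sand, s$silt, s$clay, s$organic_matter,
                 station_id = s$station_id, district = s$district,
                 bulk_density = s$bulk_density))
  names(soils) <- vapply(soils, `[[`, "", "soil_id")
  scenarios <- lapply(o$scenarios, function(s)
    scenario_config(s$label, s$temp_delta, s$precip_factor, s$wet_prob_factor,
                    s$horizon))
  run_config(districts = o$districts, params = params, soils = soils,
             scenarios = scenarios, n_gen = o$n_gen, n_sub = o$n_sub,
             windows = data.frame(start_doy = o$windows$start_doy,
                                  end_doy = o$windows$end_doy),
             grid = fwd_grid(o$grid_ts_range, o$grid$ts_step,
                             o$grid_tt_range, o$grid$tt_step),
             bucket = do.call(bucket_config, o$bucket), seed = o$seed)
}
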