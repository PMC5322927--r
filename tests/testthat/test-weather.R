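test_that("generation is deterministic and satisfies the series invariants", {
  p <- il_weather_params()
  w1 <- generate_daily_weather(p, 4, seed = 99)
  w2 <- generate_daily_weather(p, 4, seed = 99)
  expect_identical(w1, w2)
  expect_silent(fieldwork:::validate_daily_weather(w1))
  expect_true(all(w1$tmax_c >= w1$tmin_c))
  expect_true(all(w1$precip_mm >= 0))
  expect_true(all(table(w1$year) == 365L))
  expect_true(all(w1$tmax_c - w1$tmin_c >= p$range_floor - 1e-12))
})

test_that("all-zero wet-day probabilities give an absorbing dry state", {
  p <- il_weather_params()
  p$p_wet_wet[] <- 0; p$p_wet_dry[] <- 0
  w <- generate_daily_weather(p, 3, seed = 1)
  expect_true(all(w$precip_mm == 0))
})

test_that("zero temperature noise reproduces the monthly mean curve", {
  p <- il_weather_params()
  p$temp_sd[] <- 0
  w <- generate_daily_weather(p, 1, seed = 1)
  mid <- (w$tmin_c + w$tmax_c) / 2
  # at mid-month anchor days the interpolated curve equals the monthly mean
  anchors <- mid_month_doy(1:12)
  expect_equal(mid[anchors], (p$tmax_mean + p$tmin_mean) / 2, tolerance = 1e-12)
})

test_that("July wet-day frequency and wet-day amounts match the generator", {
  p <- il_weather_params()
  p$p_wet_wet[7] <- 0.3; p$p_wet_dry[7] <- 0.3 # days independent in July
  w <- generate_daily_weather(p, 1000, seed = 123)
  jul <- w[month_of_doy(w$doy) == 7, ]
  n <- nrow(jul)
  freq <- mean(jul$precip_mm > 0)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(freq - 0.3), 3 * se)
  amt <- jul$precip_mm[jul$precip_mm > 0]
  mu <- p$gamma_shape[7] * p$gamma_scale[7]
  se_amt <- sqrt(p$gamma_shape[7]) * p$gamma_scale[7] / sqrt(length(amt))
  expect_lt(abs(mean(amt) - mu), 3 * se_amt)
})

test_that("parameter validation names the offending field", {
  p <- il_weather_params()
  p$gamma_scale[3] <- -1
  expect_error(generate_daily_weather(p, 1, 1), "gamma_scale")
  p <- il_weather_params(); p$p_wet_dry[1] <- 1.5
  expect_error(generate_daily_weather(p, 1, 1), "p_wet_dry")
  expect_error(weather_params(rep(0, 12), rep(5, 12), rep(1, 12), rep(.2, 12),
                              rep(.2, 12), rep(1, 12), rep(1, 12)),
               "tmax_mean")
})

test_that("scenario application shifts, scales, clips and preserves identity", {
  p <- il_weather_params()
  expect_equal(apply_scenario(p, scenario_config("null")), p)
  warm <- apply_scenario(p, scenario_config("w", temp_delta = rep(3, 12)))
  expect_equal(warm$tmax_mean, p$tmax_mean + 3)
  expect_equal(warm$tmin_mean, p$tmin_mean + 3)
  warns <- capture_warnings(
    clip <- apply_scenario(p, scenario_config("c", wet_prob_factor = rep(5, 12))))
  expect_match(warns, "clipped", all = TRUE)
  expect_length(warns, 2L) # both occurrence probabilities clipped
  expect_true(all(clip$p_wet_wet <= 1))
  expect_true(all(clip$p_wet_dry <= 1))
  dry <- apply_scenario(p, scenario_config("d", precip_factor = rep(0, 12)))
  w <- generate_daily_weather(dry, 2, seed = 3)
  expect_true(all(w$precip_mm == 0))
})

test_that("uniformly warmer scenarios raise the annual mean temperature", {
  p <- il_weather_params()
  for (delta in c(1, 3)) {
    sc <- apply_scenario(p, scenario_config("w", temp_delta = rep(delta, 12)))
    wb <- generate_daily_weather(p, 3, seed = 77)
    ws <- generate_daily_weather(sc, 3, seed = 77)
    expect_gt(mean((ws$tmin_c + ws$tmax_c) / 2), mean((wb$tmin_c + wb$tmax_c) / 2))
  }
})

test_that("year subsampling is reproducible, distinct and order-preserving", {
  w <- generate_daily_weather(il_weather_params(), 20, seed = 2)
  expect_identical(subsample_years(w, 20, seed = 1), w)
  s1 <- subsample_years(w, 5, seed = 9)
  s2 <- subsample_years(w, 5, seed = 9)
  expect_identical(s1, s2)
  expect_length(unique(s1$year), 5L)
  expect_error(subsample_years(w, 21, seed = 1), "more years")
})

test_that("weather round-trips through delimited text", {
  w <- generate_daily_weather(il_weather_params(), 2, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_weather(w, f)
  expect_equal(read_weather(f), w, tolerance = 1e-12)
})
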