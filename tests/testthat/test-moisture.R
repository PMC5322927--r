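test_that("mid-range temperature is the average and rejects inverted inputs", {
  expect_equal(daily_mean_temperature(10, 30), 20)
  expect_equal(daily_mean_temperature(0, 0), 0)
  expect_equal(daily_mean_temperature(-5, 5), 0)
  expect_error(daily_mean_temperature(10, 5), "tmax")
})

test_that("zero precipitation dries the profile monotonically down to wilting point", {
  s <- test_soil()
  w <- dry_weather(2)
  m <- simulate_soil_moisture(w, s, bucket_config(spinup_years = 0, snow_on = FALSE))
  expect_true(all(diff(m$vwc) <= 1e-12))
  expect_equal(m$vwc[nrow(m)], s$wp, tolerance = 1e-9)
})

test_that("saturating precipitation pins moisture at field capacity", {
  s <- test_soil()
  w <- dry_weather(1, tmin = -2, tmax = 2) # zero evaporative demand
  w$precip_mm <- 100 # far above daily pore space
  m <- simulate_soil_moisture(w, s, bucket_config(drainage_rate = 1,
                                                  spinup_years = 0, snow_on = FALSE))
  late <- m$vwc[200:365]
  expect_true(all(abs(late - s$fc) < 1e-9))
})

test_that("water is conserved: storage change equals summed fluxes", {
  s <- test_soil()
  w <- generate_daily_weather(il_weather_params(), 3, seed = 21)
  m <- simulate_soil_moisture(w, s, bucket_config(spinup_years = 0), latitude = 40)
  d <- attr(m, "depth_mm")
  storage <- m$vwc * d
  init <- s$fc * d
  for (i in c(1, 50, 400, nrow(m))) {
    lhs <- storage[i] - init
    rhs <- sum(m$infil_mm[1:i]) - sum(m$drain_mm[1:i]) - sum(m$evap_mm[1:i])
    expect_equal(lhs, rhs, tolerance = 1e-9 * max(1, abs(rhs)))
  }
})

test_that("moisture stays within [WP, porosity] and responds monotonically to precipitation", {
  s <- test_soil()
  for (seed in 1:3) {
    w <- generate_daily_weather(il_weather_params(), 2, seed = seed)
    m <- simulate_soil_moisture(w, s)
    expect_true(all(m$vwc >= s$wp - 1e-9))
    expect_true(all(m$vwc <= s$porosity + 1e-9))
    wetter <- w
    wetter$precip_mm <- wetter$precip_mm * 1.5
    m2 <- simulate_soil_moisture(wetter, s)
    expect_true(all(m2$vwc >= m$vwc - 1e-9))
  }
})

test_that("the bucket model is deterministic and converges under constant forcing", {
  s <- test_soil()
  w <- generate_daily_weather(il_weather_params(), 2, seed = 8)
  expect_identical(simulate_soil_moisture(w, s), simulate_soil_moisture(w, s))
  cw <- dry_weather(2, tmin = 12, tmax = 22)
  cw$precip_mm <- 2 # constant daily input; latitude 0 makes daily PET constant too
  m <- simulate_soil_moisture(cw, s, bucket_config(spinup_years = 0, snow_on = FALSE),
                              latitude = 0)
  tail_changes <- abs(diff(tail(m$vwc, 30)))
  expect_lt(max(tail_changes), 1e-4)
})

test_that("NA weather is rejected with the day named", {
  s <- test_soil()
  w <- dry_weather(1)
  w$tmin_c[40] <- NA
  expect_error(simulate_soil_moisture(w, s), "DOY 40")
})

test_that("snow delays infiltration until thaw", {
  s <- test_soil()
  w <- dry_weather(1, tmin = -10, tmax = -2) # frozen all year
  w$precip_mm[10] <- 20
  m_snow <- simulate_soil_moisture(w, s, bucket_config(spinup_years = 0, snow_on = TRUE))
  m_rain <- simulate_soil_moisture(w, s, bucket_config(spinup_years = 0, snow_on = FALSE))
  expect_equal(sum(m_snow$infil_mm), 0) # never thaws, never infiltrates
  expect_gt(sum(m_rain$infil_mm), 0)
})

test_that("moisture series round-trips through delimited text", {
  s <- test_soil()
  m <- simulate_soil_moisture(dry_weather(1), s, bucket_config(spinup_years = 0))
  f <- tempfile(fileext = ".tsv")
  write_moisture(m, f)
  back <- read_moisture(f)
  expect_equal(back$vwc, m$vwc, tolerance = 1e-9)
  expect_identical(attr(back, "soil_id"), "s1")
})
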