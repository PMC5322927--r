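test_that("the December cumulative balance telescopes to annual P minus PET", {
  w <- generate_daily_weather(il_weather_params(), 5, seed = 14)
  wb <- cumulative_water_balance(w, latitude = 40)
  for (y in unique(wb$monthly$year)) {
    g <- wb$monthly[wb$monthly$year == y, ]
    dec <- g$cum_balance_mm[g$month == 12]
    expect_equal(dec, sum(g$precip_mm) - sum(g$pet_mm),
                 tolerance = 1e-9 * max(1, abs(dec)))
  }
})

test_that("balanced months give zero accumulation and no deficits", {
  tm <- rep(20, 12)
  pet <- thornthwaite_pet(tm, 40)
  mc <- data.frame(year = 1, month = 1:12, precip_mm = pet, tmean_c = tm)
  wb <- cumulative_water_balance(mc, latitude = 40)
  expect_equal(wb$monthly$cum_balance_mm, rep(0, 12), tolerance = 1e-9)
  expect_false(any(wb$monthly$deficit))
  expect_equal(wb$may_aug_deficit_months, 0)
})

test_that("the first deficit month follows the running-sum arithmetic", {
  tm <- rep(20, 12)
  pet <- thornthwaite_pet(tm, 40) # all > 20 mm, so P stays non-negative
  mc <- data.frame(year = 1, month = 1:12,
                   precip_mm = pet + c(rep(10, 4), rep(-20, 8)), tmean_c = tm)
  wb <- cumulative_water_balance(mc, latitude = 40)
  expect_equal(wb$monthly$cum_balance_mm,
               cumsum(c(rep(10, 4), rep(-20, 8))), tolerance = 1e-9)
  expect_equal(which(wb$monthly$deficit), 7:12) # 40 - 60 < 0 first in month 7
})

test_that("deficit flags match a brute-force re-scan and quantiles are ordered", {
  w <- generate_daily_weather(il_weather_params(), 20, seed = 3)
  wb <- cumulative_water_balance(w, latitude = 40)
  # brute force: recompute the accumulation independently per year
  for (y in unique(wb$monthly$year)) {
    g <- wb$monthly[wb$monthly$year == y, ]
    run <- 0
    for (m in 1:12) {
      run <- run + g$precip_mm[m] - g$pet_mm[m]
      expect_identical(g$deficit[m], run < 0)
    }
  }
  bm <- wb$by_month
  expect_true(all(bm$q05 <= bm$mean + 1e-9))
  expect_true(all(bm$mean <= bm$q95 + 1e-9))
})

test_that("an ensemble of identical years collapses the quantiles onto the mean", {
  w1 <- generate_daily_weather(il_weather_params(), 1, seed = 6)
  w5 <- do.call(rbind, lapply(1:5, function(y) transform(w1, year = y)))
  class(w5) <- c("daily_weather", "data.frame")
  wb <- cumulative_water_balance(w5)
  expect_equal(wb$by_month$q05, wb$by_month$mean, tolerance = 1e-9)
  expect_equal(wb$by_month$q95, wb$by_month$mean, tolerance = 1e-9)
})

test_that("daily interpolation is linear between month ends and starts at zero", {
  w <- generate_daily_weather(il_weather_params(), 3, seed = 16)
  wb <- cumulative_water_balance(w)
  daily <- interpolate_balance_daily(wb)
  expect_equal(nrow(daily), 365L)
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  expect_equal(daily$cum_balance_mm[ends],
               wb$by_month$mean[order(wb$by_month$month)], tolerance = 1e-9)
  # linear within January: second differences vanish
  expect_lt(max(abs(diff(daily$cum_balance_mm[1:31], differences = 2))), 1e-9)
})

test_that("risk odds obey the self, ratio and guard identities", {
  w <- generate_daily_weather(il_weather_params(), 10, seed = 19)
  wb <- cumulative_water_balance(w)
  expect_identical(risk_odds(wb, wb), 1)
  mk <- function(count, n = 1000) structure(
    list(may_aug_deficit_months = count, n_years = n),
    class = "water_balance_summary")
  expect_equal(risk_odds(mk(40), mk(30)), 4 / 3)
  expect_equal(risk_odds(mk(0), mk(30)), 0)
  expect_warning(inf_odds <- risk_odds(mk(5), mk(0)), "infinite")
  expect_identical(inf_odds, Inf)
  expect_identical(suppressWarnings(risk_odds(mk(0), mk(0))), 1)
})
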