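make_tiny_instance <- function(seed = 11) {
  set.seed(seed)
  doys <- c(91:104, 106:119) # two windows per period
  d <- manual_fwd_data("D1", "st1", "a",
                       year = rep(1:3, each = length(doys)),
                       doy = rep(doys, 3),
                       sm = runif(3 * length(doys), 0.6, 1.2),
                       mt = runif(3 * length(doys), -2, 10))
  win <- data.frame(start_doy = c(91L, 98L, 106L, 113L),
                    end_doy = c(97L, 104L, 112L, 119L))
  reports <- do.call(rbind, lapply(1:3, function(y)
    data.frame(region = "D1", year = y, start_doy = win$start_doy,
               end_doy = win$end_doy, fwd = sample(0:7, 4, replace = TRUE))))
  list(data = d, windows = win, reports = reports)
}

# independent exhaustive enumeration (plain loops, no shared code with the
# fitter) for a single-soil single-station instance
enumerate_best <- function(d, reports, ts_grid, tt_grid) {
  best <- list(sse = Inf)
  for (ts in ts_grid) for (tt in tt_grid) {
    sse <- 0
    for (i in seq_len(nrow(reports))) {
      days <- d$year == reports$year[i] &
        d$doy >= reports$start_doy[i] & d$doy <= reports$end_doy[i]
      pred <- sum(d$sm[days] <= ts & d$mt[days] >= tt)
      sse <- sse + (pred - reports$fwd[i])^2
    }
    if (sse < best$sse) best <- list(sse = sse, ts = ts, tt = tt)
  }
  best
}

test_that("the grid search equals independent exhaustive enumeration", {
  inst <- make_tiny_instance()
  grid <- fwd_grid(c(0.7, 1.0), 0.1, c(0, 4), 2.0)
  fit <- fwd_fit(inst$reports, inst$data, grid = grid)
  p1 <- inst$reports[inst$reports$start_doy < 105, ]
  p2 <- inst$reports[inst$reports$start_doy >= 105, ]
  e1 <- enumerate_best(inst$data, p1, grid$ts, grid$tt)
  e2 <- enumerate_best(inst$data, p2, grid$ts, grid$tt)
  expect_equal(fit$period1$sse, e1$sse)
  expect_equal(fit$period2$sse, e2$sse)
  expect_equal(c(fit$period1$ts, fit$period1$tt), c(e1$ts, e1$tt))
  expect_equal(c(fit$period2$ts, fit$period2$tt), c(e2$ts, e2$tt))
})

test_that("noise-free closed-loop reports recover the generating thresholds", {
  cfg <- recovery_config(n_years = 8, districts = "C", seed = 31)
  study <- make_study(cfg)
  truth <- recovery_truth()
  reports <- generate_fwd_reports(study$data, truth, cfg$windows)
  fit <- fwd_fit(reports, study$data, grid = cfg$grid)
  expect_equal(fit$period1$ts, truth$ts1)
  expect_equal(fit$period1$tt, truth$tt1)
  expect_equal(fit$period2$ts, truth$ts2)
  expect_equal(fit$period2$tt, truth$tt2)
  expect_equal(fit$period1$sse + fit$period2$sse, 0)
  # recovered moisture thresholds sit in the plausible fraction-of-PL band
  expect_true(fit$period1$ts >= 0.7 && fit$period2$ts <= 1.1)
})

test_that("degenerate all-seven reports force the loosest grid point", {
  # one day per window sits just inside the loosest thresholds, so only
  # (max Ts, min Tt) reproduces the constant 7s
  doys <- c(91:97, 106:112)
  sm <- rep(0.7, 14); mt <- rep(8, 14)
  sm[c(3, 10)] <- 1.095 # between the last two Ts grid lines
  mt[c(5, 12)] <- 0.1   # between the first two Tt grid lines
  d <- manual_fwd_data("D1", "st1", "a", year = 1, doy = doys, sm = sm, mt = mt)
  reports <- data.frame(region = "D1", year = 1, start_doy = c(91L, 106L),
                        end_doy = c(97L, 112L), fwd = 7)
  fit <- fwd_fit(reports, d, grid = fwd_grid())
  expect_equal(fit$period1$ts, 1.1)
  expect_equal(fit$period1$tt, 0)
  expect_equal(fit$period2$ts, 1.1)
  expect_equal(fit$period2$tt, 0)
})

test_that("ties break toward the lowest moisture then temperature threshold", {
  # all days comfortably workable: every grid point with ts >= 0.8, tt <= 2
  # reproduces the reports, so the reported optimum must be the smallest
  d <- manual_fwd_data("D1", "st1", "a", year = 1, doy = c(91:97, 106:112),
                       sm = 0.75, mt = 5)
  reports <- data.frame(region = "D1", year = 1, start_doy = c(91L, 106L),
                        end_doy = c(97L, 112L), fwd = 7)
  fit <- fwd_fit(reports, d, grid = fwd_grid(c(0.8, 1.0), 0.1, c(0, 2), 1.0))
  expect_equal(c(fit$period1$ts, fit$period1$tt), c(0.8, 0))
})

test_that("empty calibration periods are rejected", {
  inst <- make_tiny_instance()
  early <- inst$reports[inst$reports$start_doy < 105, ]
  expect_error(fwd_fit(early, inst$data), "period 2")
  late <- inst$reports[inst$reports$start_doy >= 105, ]
  expect_error(fwd_fit(late, inst$data), "period 1")
})

test_that("the fitted object supports the standard modelling methods", {
  cfg <- recovery_config(n_years = 6, districts = "C", seed = 13)
  study <- make_study(cfg)
  reports <- generate_fwd_reports(study$data, recovery_truth(), cfg$windows)
  fit <- fwd_fit(reports, study$data, grid = cfg$grid)
  cf <- coef(fit)
  expect_named(cf, c("ts1", "tt1", "ts2", "tt2", "ts_slope", "tt_slope"))
  expect_equal(cf[["ts_slope"]], (cf[["ts2"]] - cf[["ts1"]]) / 45)
  expect_equal(residuals(fit), fit$reports$fwd - fitted(fit))
  expect_output(print(fit), "period 1")
  expect_output(print(summary(fit)), "RMSE")
  pred <- predict(fit)
  expect_true(all(pred$fwd >= 0 & pred$fwd <= 7))
  sims <- simulate(fit, nsim = 2, seed = 5, noise_sd = 0.5)
  expect_length(sims, 2L)
  expect_true(all(sims[[1]]$fwd >= 0 & sims[[1]]$fwd <= 7))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
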