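test_that("noise-free reports equal the aggregated indicator sums", {
  doys <- 91:97
  win <- data.frame(start_doy = 91L, end_doy = 97L)
  sch <- threshold_schedule(0.85, 3, 0.85, 3, mode = "step")
  all_work <- manual_fwd_data("D1", "st1", "a", 1, doys, sm = 0.7, mt = 10)
  expect_equal(generate_fwd_reports(all_work, sch, win)$fwd, 7)
  too_wet <- manual_fwd_data("D1", "st1", "a", 1, doys, sm = 1.2, mt = 10)
  expect_equal(generate_fwd_reports(too_wet, sch, win)$fwd, 0)
})

test_that("report noise is integer-rounded, truncated and reproducible", {
  doys <- 91:97
  win <- data.frame(start_doy = 91L, end_doy = 97L)
  sch <- threshold_schedule(0.85, 3, 0.85, 3, mode = "step")
  d <- manual_fwd_data("D1", "st1", "a", rep(1:30, each = 7), rep(doys, 30),
                       sm = 0.7, mt = 10)
  r1 <- generate_fwd_reports(d, sch, win, noise_sd = 1.5, seed = 4)
  r2 <- generate_fwd_reports(d, sch, win, noise_sd = 1.5, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$fwd >= 0 & r1$fwd <= 7))
  expect_true(all(r1$fwd == round(r1$fwd)))
  expect_true(any(r1$fwd < 7)) # noise actually perturbs
})

test_that("report windows are validated", {
  d <- manual_fwd_data("D1", "st1", "a", 1, 91:97, sm = 0.7, mt = 10)
  sch <- threshold_schedule(0.85, 3, 0.85, 3)
  expect_error(generate_fwd_reports(d, sch, data.frame(start_doy = 80L, end_doy = 86L)),
               "85-180")
  expect_error(generate_fwd_reports(d, sch, data.frame(start_doy = 91L, end_doy = 99L)),
               "7 days")
})

test_that("naive probability spreads weekly counts uniformly and averages years", {
  one <- data.frame(region = "st", year = 1, start_doy = 91L, end_doy = 97L, fwd = 7)
  p <- naive_report_probability(one)
  expect_equal(p$probability, rep(1, 7))
  expect_equal(p$doy, 91:97)
  half <- data.frame(region = "st", year = 1, start_doy = 91L, end_doy = 97L, fwd = 3.5)
  expect_equal(naive_report_probability(half)$probability, rep(0.5, 7))
  two_years <- data.frame(region = "st", year = 1:2, start_doy = 91L, end_doy = 97L,
                          fwd = c(7, 0))
  expect_equal(naive_report_probability(two_years)$probability, rep(0.5, 7))
})

test_that("overlapping windows within a region-year are rejected", {
  bad <- data.frame(region = "st", year = 1, start_doy = c(91L, 95L),
                    end_doy = c(97L, 101L), fwd = c(3, 4))
  expect_error(naive_report_probability(bad), "overlap")
})

test_that("reports round-trip through delimited text and are validated on read", {
  r <- data.frame(region = "D1", year = 1:2, start_doy = 91L, end_doy = 97L,
                  fwd = c(3.5, 6))
  f <- tempfile(fileext = ".tsv")
  write_reports(r, f)
  expect_equal(read_reports(f), r)
  bad <- r; bad$fwd[1] <- 9
  write_reports(bad, f)
  expect_error(read_reports(f), "fwd")
})
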