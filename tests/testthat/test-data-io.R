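write_toy_csv <- function(path, rows) {
  writeLines(c("analyte,value,age", rows), path)
}

test_that("age bounds 18-87 are inclusive on both ends", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(f, c("TSH,1.1,17", "TSH,1.2,18", "TSH,1.3,50",
                     "TSH,1.4,87", "TSH,1.5,88"))
  s <- suppressMessages(read_lis_csv(f, "TSH"))
  expect_equal(s$n, 3L)
  expect_equal(s$values, c(1.2, 1.3, 1.4))
  expect_equal(drop_log(s)$dropped_age_filter, 2L)
})

test_that("non-numeric and non-positive values are dropped and counted", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(f, c("TSH,-0.5,30", "TSH,abc,30", "TSH,2.0,30", "TSH,0,40"))
  s <- suppressMessages(read_lis_csv(f, "TSH"))
  expect_equal(s$n, 1L)
  log <- drop_log(s)
  expect_equal(log$dropped_non_positive, 2L)
  expect_equal(log$dropped_non_numeric, 1L)
})

test_that("missing columns and empty selections raise classed errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("analyte,result,age", "TSH,1.0,30"), f)
  expect_error(suppressMessages(read_lis_csv(f, "TSH")),
               class = "indirectRI_config_error")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(f2, "FT4,1.0,30")
  expect_error(suppressMessages(read_lis_csv(f2, "TSH")),
               class = "indirectRI_empty_input")
  # configurable header mapping recovers the renamed column
  s <- suppressMessages(read_lis_csv(
    f, "TSH", columns = c(analyte = "analyte", value = "result", age = "age")))
  expect_equal(s$n, 1L)
})

test_that("synthetic write -> read round-trips values, analyte and n", {
  spec <- tsh_like_preset(n = 1000, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  series <- write_synthetic_csv(spec, f)
  back <- suppressMessages(read_lis_csv(f, "TSH", unit = "mIU/L"))
  expect_equal(back$n, 1000L)
  expect_equal(back$analyte_name, series$analyte_name)
  expect_equal(sort(back$values), sort(series$values))
  expect_equal(back$decimals, series$decimals)
  # spec YAML round-trips the generative description
  spec2 <- read_synthetic_spec(sub("\\.csv$", ".yaml", f))
  expect_equal(spec2$healthy$lambda, spec$healthy$lambda)
  expect_equal(spec2$truth$lower, spec$truth$lower)
  expect_equal(generate_lab_data(spec2)$values, series$values)
})

test_that("filtering is idempotent: re-reading filtered output changes nothing", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- sprintf("TSH,%.1f,%d", seq(0.5, 10, by = 0.1), rep(c(10, 30, 90), length.out = 96))
  write_toy_csv(f, rows)
  s1 <- suppressMessages(read_lis_csv(f, "TSH"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_lis_csv(s1, f2, ages = 30)
  s2 <- suppressMessages(read_lis_csv(f2, "TSH"))
  expect_equal(s2$values, s1$values)
  expect_equal(drop_log(s2)$dropped_age_filter, 0L)
})

test_that("reporting resolution is inferred and validated", {
  expect_equal(measurement_series(c(1.2, 3.4), "x")$decimals, 1L)
  expect_equal(measurement_series(c(1, 17), "x")$decimals, 0L)
  expect_equal(measurement_series(c(0.123456789, 1), "x")$decimals, 6L)
  expect_error(measurement_series(c(1.23, 4.56), "x", decimals = 1),
               class = "indirectRI_domain_error")
  s <- measurement_series(c(1.2, 3.4), "x", decimals = 2)
  expect_equal(s$decimals, 2L)
})
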