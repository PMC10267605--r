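test_that("an IFU range must be a proper interval", {
  expect_error(ifu_range("TSH", 4.28, 0.38), class = "indirectRI_config_error")
  expect_error(ifu_range("TSH", -1, 2), class = "indirectRI_config_error")
})

test_that("all methods are comparable when the truth equals the IFU range", {
  s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 99, 10), n = 2e4,
                                        decimals = 1L, seed = 23))
  truth <- ground_truth_ri(s)
  ifu <- ifu_range("synthetic", truth$lower, truth$upper)
  rep <- suppressMessages(run_comparison(
    s, ifu, kosmic = kosmic_config(q_step = 0.05, lambda_grid = c(0.5, 1),
                                   tolerance = 1e-3)))
  expect_equal(nrow(rep), 3L)
  expect_setequal(rep$method, c("hoffman", "kosmic", "refiner"))
  expect_true(all(rep$verdict == "comparable"))
  expect_true(all(abs(rep$dev_lower_pct) <= 20))
})

test_that("per-limit deviations flip sign and keep magnitude when roles swap", {
  ifu_a <- ifu_range("x", 2, 8)
  ifu_b <- ifu_range("x", 4, 16)
  dev_ab <- 100 * (c(4, 16) - c(2, 8)) / c(2, 8)
  dev_ba <- 100 * (c(2, 8) - c(4, 16)) / c(4, 16)
  expect_equal(sign(dev_ab), -sign(dev_ba))
  expect_equal(abs(dev_ab) * c(2, 8), abs(dev_ba) * c(4, 16))
  expect_equal(dev_ab, c(100, 100))
})

test_that("a single failing method is reported without aborting the rest", {
  # 45 values: enough for Hoffman (n >= 40) but below the truncated-fit floor
  s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 99, 10), n = 45,
                                        decimals = 1L, seed = 24))
  rep <- suppressWarnings(suppressMessages(
    run_comparison(s, ifu_range("x", 80, 120))))
  expect_true("failed" %in% rep$verdict)
  expect_true(any(rep$verdict != "failed"))
  errs <- attr(rep, "errors")
  expect_false(is.na(errs$kosmic))
})

test_that("reports round-trip through JSON and CSV", {
  s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 99, 10), n = 5000,
                                        decimals = 1L, seed = 25))
  rep <- suppressMessages(run_comparison(
    s, ifu_range("synthetic", 80, 120),
    kosmic = kosmic_config(q_step = 0.05, lambda_grid = 1, tolerance = 1)))
  fj <- withr::local_tempfile(fileext = ".json")
  write_report(rep, fj)
  back <- read_report(fj)
  expect_equal(back$lower, rep$lower)
  expect_equal(back$verdict, rep$verdict)
  expect_equal(attr(back, "ifu")$upper, 120)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, fc)
  back_csv <- read_report(fc)
  expect_equal(back_csv$upper, rep$upper)
})

test_that("discordance verdicts flag the offending limit", {
  # estimated interval shifted high against a tight IFU
  ifu <- ifu_range("x", 1, 2)
  expect_equal(indirectRI:::verdict_for(1.05, 3.4, ifu, NULL, NULL, 0.2),
               "upper-discordant")
  expect_equal(indirectRI:::verdict_for(0.5, 2.1, ifu, NULL, NULL, 0.2),
               "lower-discordant")
  expect_equal(indirectRI:::verdict_for(0.5, 3.4, ifu, NULL, NULL, 0.2),
               "both-discordant")
  # CI containment rescues a limit whose point estimate deviates
  expect_equal(indirectRI:::verdict_for(0.5, 2.1, ifu, c(0.4, 1.2), NULL, 0.2),
               "comparable")
})
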