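test_that("peak and search region are located on unimodal data", {
  s <- gaussian_series(n = 2e4, mu = 100, sigma = 10, seed = 14, decimals = 1L)
  pk <- find_peak_region(s)
  expect_lt(abs(pk$peak - 101), 2 * pk$width)  # lambda=1 shifts mode to mu+1
  expect_true(pk$region[1] < 101 && pk$region[2] > 101)
  expect_error(find_peak_region(measurement_series(rep(5, 1000), "flat")),
               class = "indirectRI_fit_error")
})

test_that("the search region excludes the far pathological tail of TSH-like data", {
  s <- generate_lab_data(tsh_like_preset(n = 30000, seed = 15))
  pk <- find_peak_region(s)
  expect_lt(pk$region[2], quantile(s$values, 0.99))
})

test_that("clean-data recovery: P near 1 and limits near the closed form", {
  s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 99, 10), n = 2e4,
                                        decimals = 1L, seed = 16))
  fit <- fit_refiner(s)
  truth <- ground_truth_ri(s)
  expect_lt(abs(fit$p_scale - 1), 0.05)
  expect_lt(abs(rel_dev(fit$ri$lower, truth$lower)), 0.02)
  expect_lt(abs(rel_dev(fit$ri$upper, truth$upper)), 0.02)
  expect_equal(fit$ri$upper, model_ri(fit$model)$upper)
})

test_that("cost at the generating parameters beats clearly perturbed ones", {
  for (sd_seed in 1:10) {
    s <- generate_lab_data(synthetic_spec(tsh_model(), n = 2e4,
                                          decimals = 2L, seed = sd_seed))
    pk <- suppressWarnings(find_peak_region(s))
    breaks <- pk$breaks
    O <- tabulate(findInterval(s$values, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
    centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
    in_region <- centers >= pk$region[1] & centers <= pk$region[2]
    cost_at <- function(mu, sigma) {
      blk <- indirectRI:::refiner_cost_block(
        0.07, mu, sigma, 1.0, boxcox(breaks, 0.07), O, in_region, s$n)
      min(blk$cost)
    }
    c_true <- cost_at(0.734424, 0.688931)
    expect_lt(c_true, cost_at(0.734424, 2 * 0.688931))
    expect_lt(c_true, cost_at(0.734424 + 0.688931, 0.688931))
  }
})

test_that("duplicating every observation leaves the fitted model unchanged", {
  # integer reporting makes the bin width resolution-dominated, so both
  # series share the same histogram geometry and the cost scales uniformly
  s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 50, 5), n = 5000,
                                        decimals = 0L, seed = 17))
  s2 <- measurement_series(rep(s$values, 2), s$analyte_name, decimals = 0L)
  f1 <- fit_refiner(s)
  f2 <- fit_refiner(s2)
  expect_equal(f1$model$lambda, f2$model$lambda)
  expect_equal(f1$model$mu, f2$model$mu, tolerance = 1e-8)
  expect_equal(f1$model$sigma, f2$model$sigma, tolerance = 1e-8)
  expect_equal(f1$p_scale, f2$p_scale)
})

test_that("bootstrap CIs are seed-reproducible, ordered and bracket the estimate", {
  s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 99, 10), n = 4000,
                                        decimals = 1L, seed = 18))
  ci1 <- bootstrap_ci(s, n_boot = 20, seed = 123)
  ci2 <- bootstrap_ci(s, n_boot = 20, seed = 123)
  expect_identical(ci1$ci_lower, ci2$ci_lower)
  expect_identical(ci1$ci_upper, ci2$ci_upper)
  fit <- fit_refiner(s)
  expect_true(ci1$ci_lower[1] <= fit$ri$lower && fit$ri$lower <= ci1$ci_lower[2])
  expect_true(ci1$ci_upper[1] <= fit$ri$upper && fit$ri$upper <= ci1$ci_upper[2])
  # degenerate but valid at the minimum replicate count
  ci3 <- bootstrap_ci(s, n_boot = 2, seed = 5)
  expect_lte(ci3$ci_lower[1], ci3$ci_lower[2])
  expect_lte(ci3$ci_upper[1], ci3$ci_upper[2])
})

test_that("confidence intervals narrow as the sample grows", {
  widths <- sapply(c(2000, 20000), function(n) {
    s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 99, 10), n = n,
                                          decimals = 1L, seed = 19))
    ci <- bootstrap_ci(s, n_boot = 30, seed = 42)
    diff(ci$ci_upper)
  })
  expect_lt(widths[2], widths[1])
})

test_that("fit_refiner attaches CIs when bootstrapping is requested", {
  s <- generate_lab_data(synthetic_spec(box_cox_gaussian(1, 99, 10), n = 3000,
                                        decimals = 1L, seed = 20))
  fit <- fit_refiner(s, boot = 5, seed = 7)
  expect_false(is.null(fit$ri$ci_lower))
  expect_equal(fit$ri$ci_level, 0.95)
  td <- tidy(fit)
  expect_equal(td$term, c("lambda", "mu", "sigma", "p_scale"))
  expect_s3_class(autoplot(fit, s), "ggplot")
})
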