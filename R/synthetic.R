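#' Specification of a synthetic mixed laboratory population
#'
#' Describes a generative model for hospital-style laboratory data: a
#' healthy component that is Gaussian after Box-Cox transformation, plus
#' optional low-abnormal and high-abnormal pathological components mixed in
#' at configurable fractions. The ground-truth reference interval — the
#' 2.5th/97.5th percentile of the healthy component alone — is recorded in
#' the spec so estimator accuracy can be measured exactly. It depends only
#' on `healthy`, never on the pathological components or the seed.
#'
#' Pathological components are log-normal in original units
#' (`list(meanlog =, sdlog =)`); sensible presets place their medians beyond
#' the healthy 0.5th/99.5th percentiles so they overlap the healthy tails
#' the way disease results overlap in real mixed data.
#'
#' @param healthy A [box_cox_gaussian()] healthy-component model.
#' @param n Number of results to generate.
#' @param frac_patho_low,frac_patho_high Expected fractions of low/high
#'   pathological results; their sum must be < 1.
#' @param patho_low,patho_high Log-normal component parameters, each a list
#'   with `meanlog` and `sdlog`; required when the matching fraction is > 0.
#' @param decimals Reporting resolution applied after mixing, emulating how
#'   a laboratory information system rounds results.
#' @param seed Integer seed making generation reproducible.
#' @param analyte,unit Labels passed to the generated series.
#' @return An object of class `synthetic_spec`; `$truth` holds the
#'   ground-truth [reference_interval()].
#' @seealso [generate_lab_data()], [tsh_like_preset()]
#' @export
synthetic_spec <- function(healthy, n,
                           frac_patho_low = 0, frac_patho_high = 0,
                           patho_low = NULL, patho_high = NULL,
                           decimals = 1L, seed = 1L,
                           analyte = "synthetic", unit = "") {
  stopifnot(inherits(healthy, "box_cox_gaussian"), n >= 1)
  if (frac_patho_low < 0 || frac_patho_high < 0 ||
      frac_patho_low + frac_patho_high >= 1) {
    rlang::abort("pathological fractions must be >= 0 and sum to < 1.",
      class = "indirectRI_config_error")
  }
  check_comp <- function(comp, frac, what) {
    if (frac > 0 && (is.null(comp) || !all(c("meanlog", "sdlog") %in% names(comp)))) {
      rlang::abort(sprintf("`%s` must supply meanlog and sdlog when its fraction is > 0.", what),
        class = "indirectRI_config_error")
    }
  }
  check_comp(patho_low, frac_patho_low, "patho_low")
  check_comp(patho_high, frac_patho_high, "patho_high")
  structure(
    list(
      healthy = healthy, n = as.integer(n),
      frac_patho_low = frac_patho_low, frac_patho_high = frac_patho_high,
      patho_low = patho_low, patho_high = patho_high,
      decimals = as.integer(decimals), seed = as.integer(seed),
      analyte = analyte, unit = unit,
      truth = model_ri(healthy)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %s: n = %d, pathological %.0f%% low + %.0f%% high, decimals = %d, seed = %d\n",
    x$analyte, x$n, 100 * x$frac_patho_low, 100 * x$frac_patho_high,
    x$decimals, x$seed
  ))
  cat(sprintf("  ground-truth RI: %.4g - %.4g\n", x$truth$lower, x$truth$upper))
  invisible(x)
}

# draw k values, redrawing any that round to <= 0 at the reporting
# resolution or fall outside the inverse-transform support; bounded retries.
draw_positive <- function(k, rfun, decimals, max_tries = 100L) {
  if (k == 0L) return(numeric(0))
  x <- rfun(k)
  for (i in seq_len(max_tries)) {
    bad <- !is.finite(x) | round(x, decimals) <= 0
    if (!any(bad)) return(round(x, decimals))
    x[bad] <- rfun(sum(bad))
  }
  rlang::abort("could not generate positive rounded values within the retry budget; component mass sits too close to zero for this reporting resolution.",
    class = "indirectRI_generation_error")
}

#' Generate a synthetic mixed laboratory dataset
#'
#' Draws component sizes from a multinomial with the spec's expected
#' fractions, samples the healthy component as `inv_boxcox(N(mu, sigma))`,
#' the pathological components as log-normals, rounds everything to the
#' reporting resolution (redrawing the rare values that round to zero), and
#' shuffles the order. Deterministic given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed override; defaults to the spec's own seed.
#' @return A [measurement_series()]; the ground-truth interval is attached
#'   and retrievable with [ground_truth_ri()], the spec with
#'   `attr(x, "spec")`.
#' @export
generate_lab_data <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$healthy
  values <- withr::with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, spec$n, c(
      1 - spec$frac_patho_low - spec$frac_patho_high,
      spec$frac_patho_low, spec$frac_patho_high
    )))
    healthy_draw <- function(k) {
      y <- stats::rnorm(k, h$mu, h$sigma)
      if (abs(h$lambda) > bc_log_threshold) {
        # stay inside the inverse-transform support
        bad <- h$lambda * y + 1 <= 0
        while (any(bad)) {
          y[bad] <- stats::rnorm(sum(bad), h$mu, h$sigma)
          bad <- h$lambda * y + 1 <= 0
        }
      }
      inv_boxcox(y, h$lambda)
    }
    x <- c(
      draw_positive(counts[1], healthy_draw, spec$decimals),
      draw_positive(counts[2], function(k) {
        stats::rlnorm(k, spec$patho_low$meanlog, spec$patho_low$sdlog)
      }, spec$decimals),
      draw_positive(counts[3], function(k) {
        stats::rlnorm(k, spec$patho_high$meanlog, spec$patho_high$sdlog)
      }, spec$decimals)
    )
    sample(x)
  })
  out <- measurement_series(values, spec$analyte, unit = spec$unit,
                            decimals = spec$decimals)
  attr(out, "truth") <- spec$truth
  attr(out, "spec") <- spec
  out
}

#' Ground-truth reference interval of a synthetic series
#'
#' @param series A series produced by [generate_lab_data()].
#' @return The healthy-component [reference_interval()], or `NULL`.
#' @export
ground_truth_ri <- function(series) attr(series, "truth")

#' TSH-like synthetic population preset
#'
#' A realistic adult serum-TSH mixture: the healthy component is a strongly
#' right-skewed Box-Cox-Gaussian (`lambda = 0.07`, `mu = 0.734424`,
#' `sigma = 0.688931`, mIU/L) whose implied reference interval is about
#' 0.533-7.00 mIU/L; contamination defaults to 5% suppressed-TSH
#' (hyperthyroid-like, log-normal with median 0.06 mIU/L) plus 25%
#' elevated-TSH (hypothyroid-like, median 25 mIU/L), i.e. a 30% pathological
#' fraction overall. Both component medians sit beyond the healthy
#' 0.5th/99.5th percentiles (0.34 and 10.1 mIU/L) so the contamination
#' overlaps the healthy tails without being separable by eye.
#'
#' @param n Number of results.
#' @param frac_patho_low,frac_patho_high Pathological fractions.
#' @param decimals Reporting resolution.
#' @param seed Seed.
#' @return A [synthetic_spec()].
#' @export
tsh_like_preset <- function(n = 50000, frac_patho_low = 0.05,
                            frac_patho_high = 0.25, decimals = 1L,
                            seed = 1L) {
  synthetic_spec(
    healthy = box_cox_gaussian(lambda = 0.07, mu = 0.734424, sigma = 0.688931),
    n = n,
    frac_patho_low = frac_patho_low, frac_patho_high = frac_patho_high,
    patho_low = list(meanlog = log(0.06), sdlog = 1.0),
    patho_high = list(meanlog = log(25), sdlog = 0.8),
    decimals = decimals, seed = seed,
    analyte = "TSH", unit = "mIU/L"
  )
}

#' Write a synthetic dataset and its spec to disk
#'
#' Generates the data, writes it in the LIS CSV dialect ([write_lis_csv()]),
#' and serialises the generating spec as YAML next to it so every downstream
#' stage can be exercised from files alone.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output CSV path.
#' @param spec_path YAML path; defaults to `path` with a `.yaml` extension.
#' @return The generated [measurement_series()], invisibly.
#' @export
write_synthetic_csv <- function(spec, path, spec_path = NULL) {
  series <- generate_lab_data(spec)
  write_lis_csv(series, path)
  if (is.null(spec_path)) spec_path <- sub("\\.csv$", ".yaml", path)
  yaml::write_yaml(list(
    analyte = spec$analyte, unit = spec$unit, n = spec$n,
    healthy = spec$healthy[c("lambda", "mu", "sigma")],
    frac_patho_low = spec$frac_patho_low,
    frac_patho_high = spec$frac_patho_high,
    patho_low = spec$patho_low, patho_high = spec$patho_high,
    decimals = spec$decimals, seed = spec$seed,
    truth = list(lower = spec$truth$lower, upper = spec$truth$upper)
  ), spec_path)
  invisible(series)
}

#' Read a synthetic spec back from YAML
#'
#' @param path YAML file written by [write_synthetic_csv()].
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic_spec(
    healthy = box_cox_gaussian(y$healthy$lambda, y$healthy$mu, y$healthy$sigma),
    n = y$n, frac_patho_low = y$frac_patho_low,
    frac_patho_high = y$frac_patho_high,
    patho_low = y$patho_low, patho_high = y$patho_high,
    decimals = y$decimals, seed = y$seed,
    analyte = y$analyte, unit = y$unit
  )
}
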