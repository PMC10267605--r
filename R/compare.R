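#' Manufacturer (IFU) reference range
#'
#' The reference range published in a kit's instructions for use, the
#' comparator in a verification report.
#'
#' @param analyte Analyte name.
#' @param lower,upper Positive range limits, `lower < upper`.
#' @param source Free-text provenance, e.g. the kit name.
#' @return An object of class `ifu_range`.
#' @export
ifu_range <- function(analyte, lower, upper, source = "IFU") {
  stopifnot(is.character(analyte), is.numeric(lower), is.numeric(upper))
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || lower >= upper) {
    rlang::abort("an IFU range requires 0 < lower < upper.",
      class = "indirectRI_config_error")
  }
  structure(list(analyte = analyte, lower = lower, upper = upper, source = source),
            class = "ifu_range")
}

verdict_for <- function(lower, upper, ifu, ci_lower, ci_upper, threshold) {
  limit_ok <- function(est, ref, ci) {
    dev_ok <- is.finite(est) && abs(100 * (est - ref) / ref) <= 100 * threshold
    ci_ok <- !is.null(ci) && all(is.finite(ci)) && ref >= ci[1] && ref <= ci[2]
    dev_ok || ci_ok
  }
  lo_ok <- limit_ok(lower, ifu$lower, ci_lower)
  hi_ok <- limit_ok(upper, ifu$upper, ci_upper)
  if (lo_ok && hi_ok) "comparable"
  else if (!lo_ok && hi_ok) "lower-discordant"
  else if (lo_ok && !hi_ok) "upper-discordant"
  else "both-discordant"
}

#' Run all three estimators and verify against an IFU range
#'
#' Fits the Hoffman, truncated Box-Cox-Gaussian, and inverse-modelling
#' estimators on one series and tabulates each estimated reference interval
#' against the manufacturer range: per-limit relative deviations
#' `100 * (method - IFU) / IFU` and a verdict per method. A method is
#' `comparable` when both absolute deviations are within `threshold` *or*
#' the IFU limit lies inside the method's bootstrap confidence interval
#' (when one exists); otherwise it is flagged `lower-discordant`,
#' `upper-discordant` or `both-discordant`. The published literature leaves
#' "comparable" qualitative; the default 20% per limit is this package's
#' interpretation and is configurable.
#'
#' A single method's failure is recorded in the report without aborting the
#' others; the call errors only if all three fail.
#'
#' @param series A [measurement_series()].
#' @param ifu An [ifu_range()].
#' @param threshold Per-limit relative comparability threshold (fraction).
#' @param hoffman,kosmic Method configurations.
#' @param refiner_levels Grid depth for the inverse-modelling fit.
#' @param boot Bootstrap replicates for the inverse-modelling confidence
#'   intervals (0 disables).
#' @param ci_level Bootstrap confidence level.
#' @param seed Seed for the bootstrap.
#' @return A tibble of class `verification_report`, one row per method,
#'   with attributes `analyte`, `n`, `ifu`, `threshold`, `errors`.
#' @export
run_comparison <- function(series, ifu, threshold = 0.20,
                           hoffman = hoffman_config(),
                           kosmic = kosmic_config(),
                           refiner_levels = 3L, boot = 0L,
                           ci_level = 0.95, seed = NULL) {
  stopifnot(inherits(series, "measurement_series"), inherits(ifu, "ifu_range"))
  fits <- list(
    hoffman = tryCatch(suppressWarnings(fit_hoffman(series, hoffman)),
                       error = function(e) e),
    kosmic = tryCatch(suppressWarnings(fit_kosmic(series, kosmic)),
                      error = function(e) e),
    refiner = tryCatch(suppressWarnings(
      fit_refiner(series, levels = refiner_levels, boot = boot,
                  ci_level = ci_level, seed = seed)),
      error = function(e) e)
  )
  errors <- purrr::map(fits, function(f) {
    if (inherits(f, "error")) conditionMessage(f) else NA_character_
  })
  if (all(!is.na(unlist(errors)))) {
    rlang::abort(paste0("all three estimators failed:\n",
      paste0("  ", names(errors), ": ", unlist(errors), collapse = "\n")),
      class = "indirectRI_fit_error")
  }
  rows <- purrr::imap(fits, function(f, nm) {
    if (inherits(f, "error")) {
      return(tibble::tibble(
        method = nm, lower = NA_real_, upper = NA_real_,
        ci_lower_lo = NA_real_, ci_lower_hi = NA_real_,
        ci_upper_lo = NA_real_, ci_upper_hi = NA_real_,
        dev_lower_pct = NA_real_, dev_upper_pct = NA_real_,
        verdict = "failed"
      ))
    }
    ri <- f$ri
    tibble::tibble(
      method = nm, lower = ri$lower, upper = ri$upper,
      ci_lower_lo = if (is.null(ri$ci_lower)) NA_real_ else ri$ci_lower[1],
      ci_lower_hi = if (is.null(ri$ci_lower)) NA_real_ else ri$ci_lower[2],
      ci_upper_lo = if (is.null(ri$ci_upper)) NA_real_ else ri$ci_upper[1],
      ci_upper_hi = if (is.null(ri$ci_upper)) NA_real_ else ri$ci_upper[2],
      dev_lower_pct = 100 * (ri$lower - ifu$lower) / ifu$lower,
      dev_upper_pct = 100 * (ri$upper - ifu$upper) / ifu$upper,
      verdict = verdict_for(ri$lower, ri$upper, ifu,
                            ri$ci_lower, ri$ci_upper, threshold)
    )
  })
  report <- dplyr::bind_rows(rows)
  class(report) <- c("verification_report", class(report))
  attr(report, "analyte") <- series$analyte_name
  attr(report, "n") <- series$n
  attr(report, "ifu") <- ifu
  attr(report, "threshold") <- threshold
  attr(report, "errors") <- errors
  report
}

#' @export
print.verification_report <- function(x, ...) {
  ifu <- attr(x, "ifu")
  cat(sprintf("Verification report: %s (n = %d), IFU %.4g - %.4g [%s]\n",
              attr(x, "analyte"), attr(x, "n"), ifu$lower, ifu$upper, ifu$source))
  NextMethod()
  invisible(x)
}

#' Write / read a verification report
#'
#' CSV keeps the tabular body; JSON additionally keeps the analyte, sample
#' size, IFU range and threshold so a report round-trips completely.
#'
#' @param report A [run_comparison()] result.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  stopifnot(inherits(report, "verification_report"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(report), path)
  } else {
    ifu <- attr(report, "ifu")
    jsonlite::write_json(list(
      analyte = attr(report, "analyte"), n = attr(report, "n"),
      ifu = list(analyte = ifu$analyte, lower = ifu$lower,
                 upper = ifu$upper, source = ifu$source),
      threshold = attr(report, "threshold"),
      methods = tibble::as_tibble(report)
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    report <- tibble::as_tibble(j$methods)
    class(report) <- c("verification_report", class(report))
    attr(report, "analyte") <- j$analyte
    attr(report, "n") <- j$n
    attr(report, "ifu") <- ifu_range(j$ifu$analyte, j$ifu$lower, j$ifu$upper, j$ifu$source)
    attr(report, "threshold") <- j$threshold
    report
  } else {
    report <- readr::read_csv(path, show_col_types = FALSE)
    class(report) <- c("verification_report", class(report))
    report
  }
}
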