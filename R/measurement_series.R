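#' Measurement series
#'
#' One analyte's numeric results with unit and reporting resolution, the
#' common input container of every estimator in the package. All values must
#' be strictly positive (the Box-Cox transform used downstream requires
#' positivity) and consistent with the stated rounding resolution.
#'
#' @param values Positive numeric vector of results.
#' @param analyte Analyte name, e.g. `"TSH"`.
#' @param unit Reporting unit, e.g. `"mIU/L"`, `"pg/mL"`, `"ng/dL"`.
#' @param decimals Number of decimal places results are reported to. When
#'   `NULL`, inferred as the maximum number of decimal places observed
#'   (capped at 6).
#' @return An object of class `measurement_series` with fields
#'   `analyte_name`, `unit`, `values`, `decimals`, `n`.
#' @examples
#' s <- measurement_series(c(0.5, 2.1, 3.7), "TSH", "mIU/L")
#' s$decimals
#' @export
measurement_series <- function(values, analyte, unit = "", decimals = NULL) {
  stopifnot(is.numeric(values), is.character(analyte), length(analyte) == 1L)
  values <- as.numeric(values)
  if (length(values) == 0L) {
    rlang::abort("a measurement series needs at least one value.",
      class = "indirectRI_empty_input")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    rlang::abort("all values in a measurement series must be finite and > 0.",
      class = "indirectRI_domain_error")
  }
  if (is.null(decimals)) {
    decimals <- infer_decimals(values)
  } else {
    decimals <- as.integer(decimals)
    stopifnot(decimals >= 0L)
    scaled <- values * 10^decimals
    if (any(abs(scaled - round(scaled)) > 1e-6)) {
      rlang::abort(
        sprintf("values are not multiples of 10^-%d; pass the correct `decimals` or leave it NULL.", decimals),
        class = "indirectRI_domain_error"
      )
    }
  }
  structure(
    list(
      analyte_name = analyte, unit = unit,
      values = values, decimals = decimals, n = length(values)
    ),
    class = "measurement_series"
  )
}

# smallest d in 0..cap such that every value is a multiple of 10^-d;
# falls back to cap for values reported at higher resolution.
infer_decimals <- function(values, cap = 6L) {
  for (d in 0:cap) {
    scaled <- values * 10^d
    if (all(abs(scaled - round(scaled)) <= 1e-6)) return(d)
  }
  cap
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf(
    "<measurement_series> %s%s: n = %d, decimals = %d\n",
    x$analyte_name, if (nzchar(x$unit)) paste0(" [", x$unit, "]") else "",
    x$n, x$decimals
  ))
  q <- stats::quantile(x$values, c(0.025, 0.5, 0.975), names = FALSE)
  cat(sprintf("  sample quantiles 2.5/50/97.5%%: %.4g / %.4g / %.4g\n", q[1], q[2], q[3]))
  invisible(x)
}

#' @method as_tibble measurement_series
#' @export
as_tibble.measurement_series <- function(x, ...) {
  tibble::tibble(analyte = x$analyte_name, value = x$values)
}

#' Row filter for LIS exports
#'
#' Age bounds are inclusive on both ends, so the default keeps adult
#' patients aged 18 to 87 years. Optional value bounds drop implausible
#' results before analysis.
#'
#' @param age_min,age_max Inclusive age bounds in years.
#' @param value_min,value_max Optional positive result bounds.
#' @return An object of class `record_filter`.
#' @export
record_filter <- function(age_min = 18, age_max = 87,
                          value_min = NULL, value_max = NULL) {
  stopifnot(age_min <= age_max)
  if (!is.null(value_min) && !is.null(value_max) && value_min >= value_max) {
    rlang::abort("`value_min` must be smaller than `value_max`.",
      class = "indirectRI_config_error")
  }
  structure(
    list(age_min = age_min, age_max = age_max,
         value_min = value_min, value_max = value_max),
    class = "record_filter"
  )
}

#' Read a laboratory-information-system CSV export
#'
#' Reads a flat comma-separated export (UTF-8, header row required), keeps
#' the rows of one analyte that pass the [record_filter()], and returns a
#' [measurement_series()]. Non-numeric and non-positive results are dropped
#' and counted in a drop log attached to the result (`drop_log()`), which can
#' also be written to JSON. Each row is one result; no per-patient
#' deduplication is attempted, so repeat measurements of the same patient
#' remain correlated rows — a known property of retrospective LIS data.
#'
#' @param path CSV file path.
#' @param analyte Analyte name to select.
#' @param filter A [record_filter()]; defaults to adults aged 18-87.
#' @param columns Named character vector mapping the roles `analyte`,
#'   `value`, `age` to header names in the file.
#' @param unit Unit label to attach.
#' @param decimals Reporting resolution; inferred from the surviving values
#'   when `NULL`.
#' @param drop_log_path Optional path: the drop log is additionally written
#'   there as JSON.
#' @return A [measurement_series()] with the drop log as attribute.
#' @export
read_lis_csv <- function(path, analyte, filter = record_filter(),
                         columns = c(analyte = "analyte", value = "value", age = "age"),
                         unit = "", decimals = NULL, drop_log_path = NULL) {
  stopifnot(file.exists(path), inherits(filter, "record_filter"))
  need <- c("analyte", "value", "age")
  if (!all(need %in% names(columns))) {
    rlang::abort("`columns` must name the roles analyte, value and age.",
      class = "indirectRI_config_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      sprintf("required column(s) not found in %s: %s", path,
              paste(missing_cols, collapse = ", ")),
      class = "indirectRI_config_error"
    )
  }
  df <- df[df[[columns[["analyte"]]]] == analyte, , drop = FALSE]
  raw_value <- df[[columns[["value"]]]]
  value <- suppressWarnings(as.numeric(raw_value))
  age <- suppressWarnings(as.numeric(df[[columns[["age"]]]]))

  non_numeric <- is.na(value)
  non_positive <- !non_numeric & value <= 0
  ok <- !non_numeric & !non_positive
  age_out <- ok & (is.na(age) | age < filter$age_min | age > filter$age_max)
  ok <- ok & !age_out
  value_out <- rep(FALSE, length(value))
  if (!is.null(filter$value_min)) value_out <- value_out | value < filter$value_min
  if (!is.null(filter$value_max)) value_out <- value_out | value > filter$value_max
  value_out <- ok & value_out
  ok <- ok & !value_out

  log <- list(
    analyte = analyte, rows_matching_analyte = nrow(df),
    dropped_non_numeric = sum(non_numeric),
    dropped_non_positive = sum(non_positive),
    dropped_age_filter = sum(age_out),
    dropped_value_filter = sum(value_out),
    kept = sum(ok)
  )
  rlang::inform(sprintf(
    "%s: kept %d of %d rows (%d non-numeric, %d non-positive, %d outside age %g-%g, %d outside value bounds)",
    analyte, log$kept, log$rows_matching_analyte, log$dropped_non_numeric,
    log$dropped_non_positive, log$dropped_age_filter, filter$age_min,
    filter$age_max, log$dropped_value_filter
  ))
  if (!is.null(drop_log_path)) {
    jsonlite::write_json(log, drop_log_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (log$kept == 0L) {
    rlang::abort(sprintf("no rows for analyte '%s' survive the filter.", analyte),
      class = "indirectRI_empty_input")
  }
  out <- measurement_series(value[ok], analyte, unit = unit, decimals = decimals)
  attr(out, "drop_log") <- log
  attr(out, "filter") <- filter
  out
}

#' Drop log of a series read from CSV
#'
#' @param series A [measurement_series()] produced by [read_lis_csv()].
#' @return A named list of drop counts, or `NULL`.
#' @export
drop_log <- function(series) attr(series, "drop_log")

#' Write a measurement series in the LIS CSV dialect
#'
#' Writes `analyte,value,age` rows readable by [read_lis_csv()]. Values are
#' formatted at the series' reporting resolution. When `ages` is `NULL` a
#' deterministic cycle over 18-87 years is used so that the default adult
#' filter keeps every row on re-read.
#'
#' @param series A [measurement_series()].
#' @param path Output CSV path.
#' @param ages Optional integer vector of ages, recycled to `series$n`.
#' @return `path`, invisibly.
#' @export
write_lis_csv <- function(series, path, ages = NULL) {
  stopifnot(inherits(series, "measurement_series"))
  if (is.null(ages)) ages <- rep(18:87, length.out = series$n)
  df <- tibble::tibble(
    analyte = series$analyte_name,
    value = formatC(series$values, format = "f", digits = series$decimals),
    age = rep(ages, length.out = series$n)
  )
  readr::write_csv(df, path)
  invisible(path)
}
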