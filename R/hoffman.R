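#' Cumulative normal-probability plot coordinates
#'
#' Sorted values paired with standard-normal quantiles of their plotting
#' positions, the coordinates the Hoffman method regresses on. Plotting
#' position is Hazen's `(i - 0.5)/n`, which avoids the 0 and 1 quantiles;
#' tied values (common after rounding) share the mean of their positions so
#' a run of equal results maps to a single z.
#'
#' @param series A [measurement_series()] or numeric vector.
#' @return A tibble with columns `value`, `p`, `z`, one row per observation
#'   sorted ascending.
#' @export
cumulative_points <- function(series) {
  x <- if (inherits(series, "measurement_series")) series$values else as.numeric(series)
  n <- length(x)
  if (n < 40L) {
    rlang::warn(sprintf("only %d values: the Hoffman regression is unreliable below n = 40.", n))
  }
  x <- sort(x)
  p <- (seq_len(n) - 0.5) / n
  # average positions within tie groups; rounding makes equality exact
  p <- stats::ave(p, match(x, unique(x)), FUN = mean)
  tibble::tibble(value = x, p = p, z = stats::qnorm(p))
}

#' Settings for the Hoffman segment search
#'
#' The classic method asks a human to identify the linear (purely
#' physiological) central portion of the cumulative plot; this computerised
#' variant replaces the visual judgement with a reproducible rule: among
#' candidate windows `[q_lo, q_hi]` on a quantile grid, take the widest one
#' whose segment-restricted R-squared reaches `r2_threshold`, ties broken by
#' higher R-squared.
#'
#' @param q_range Quantile range the window must stay inside.
#' @param q_step Grid step for window endpoints.
#' @param min_mass Minimum quantile width of a window.
#' @param r2_threshold Linearity requirement; if no window reaches it the
#'   best-R-squared window is used with a warning.
#' @param log_scale Fit on `log(value)` instead of the original scale and
#'   exponentiate the limits. Off by default: classic Hoffman assumes
#'   physiological results are Gaussian in original units.
#' @return An object of class `hoffman_config`.
#' @export
hoffman_config <- function(q_range = c(0.05, 0.95), q_step = 0.01,
                           min_mass = 0.40, r2_threshold = 0.99,
                           log_scale = FALSE) {
  stopifnot(length(q_range) == 2L, q_range[1] < q_range[2],
            q_step > 0, min_mass > 0, min_mass < diff(q_range),
            r2_threshold > 0, r2_threshold <= 1)
  structure(
    list(q_range = q_range, q_step = q_step, min_mass = min_mass,
         r2_threshold = r2_threshold, log_scale = log_scale),
    class = "hoffman_config"
  )
}

#' Computerised Hoffman reference-interval fit
#'
#' Regresses value on normal quantile over the selected central segment of
#' the cumulative plot ([cumulative_points()]) and extrapolates the line to
#' the 2.5th/97.5th normal quantiles: `RI = intercept +/- 1.959964 * slope`.
#' Segment selection follows [hoffman_config()]. The regression is a
#' weighted ordinary-least-squares over distinct values (weights = tie
#' counts), computed from cumulative sums so the window search costs O(1)
#' per candidate window.
#'
#' If the extrapolated lower limit is non-positive — which happens on
#' strongly right-skewed analytes where the Gaussian assumption fails — it
#' is truncated to half the reporting resolution with a warning, since a
#' reference limit must be positive.
#'
#' @param series A [measurement_series()] with at least 40 values.
#' @param config A [hoffman_config()].
#' @return An object of class `hoffman_fit`: `slope`, `intercept`, `r2`,
#'   `segment` (quantile window used), `ri` ([reference_interval()]), plus
#'   the plot points for inspection.
#' @export
fit_hoffman <- function(series, config = hoffman_config()) {
  stopifnot(inherits(series, "measurement_series"), inherits(config, "hoffman_config"))
  if (series$n < 40L) {
    rlang::abort("the Hoffman fit needs at least 40 values.",
      class = "indirectRI_insufficient_data")
  }
  pts <- suppressWarnings(cumulative_points(series))
  if (config$log_scale) pts$value <- log(pts$value)

  d <- dplyr::summarise(dplyr::group_by(pts, .data$value),
                        z = .data$z[1], p = .data$p[1], w = dplyr::n(),
                        .groups = "drop")
  d <- dplyr::arrange(d, .data$value)
  if (nrow(d) < 3L) {
    rlang::abort("fewer than 3 distinct values: cumulative plot is degenerate.",
      class = "indirectRI_fit_error")
  }

  # cumulative weighted sums -> O(1) OLS per window
  cw  <- cumsum(d$w)
  cz  <- cumsum(d$w * d$z);  cz2 <- cumsum(d$w * d$z^2)
  cx  <- cumsum(d$w * d$value); cx2 <- cumsum(d$w * d$value^2)
  czx <- cumsum(d$w * d$z * d$value)
  seg_stats <- function(a, b) {
    lag <- function(v) if (a > 1L) v[a - 1L] else 0
    n <- cw[b] - lag(cw)
    sz <- cz[b] - lag(cz); sx <- cx[b] - lag(cx)
    szz <- cz2[b] - lag(cz2); sxx <- cx2[b] - lag(cx2)
    szx <- czx[b] - lag(czx)
    vz <- szz - sz^2 / n; vx <- sxx - sx^2 / n; cvzx <- szx - sz * sx / n
    if (vz <= 0 || vx <= 0) return(NULL)
    slope <- cvzx / vz
    list(n = n, slope = slope, intercept = (sx - slope * sz) / n,
         r2 = cvzx^2 / (vz * vx))
  }

  q_lo <- seq(config$q_range[1], config$q_range[2] - config$min_mass, by = config$q_step)
  best <- NULL; best_any <- NULL
  for (ql in q_lo) {
    qh_grid <- seq(ql + config$min_mass, config$q_range[2], by = config$q_step)
    a <- which(d$p >= ql - 1e-12)[1]
    if (is.na(a)) next
    for (qh in qh_grid) {
      b <- max(which(d$p <= qh + 1e-12))
      if (b - a < 2L) next
      st <- seg_stats(a, b)
      if (is.null(st)) next
      cand <- list(q_lo = ql, q_hi = qh, width = qh - ql,
                   slope = st$slope, intercept = st$intercept, r2 = st$r2)
      if (is.null(best_any) || cand$r2 > best_any$r2) best_any <- cand
      if (st$r2 >= config$r2_threshold) {
        if (is.null(best) || cand$width > best$width + 1e-12 ||
            (abs(cand$width - best$width) <= 1e-12 && cand$r2 > best$r2)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    if (is.null(best_any)) {
      rlang::abort("no candidate segment could be fitted.",
        class = "indirectRI_fit_error")
    }
    rlang::warn(sprintf(
      "no segment reached r2 >= %.3g; using the best available (r2 = %.4f, window %.2f-%.2f).",
      config$r2_threshold, best_any$r2, best_any$q_lo, best_any$q_hi))
    best <- best_any
  }
  if (best$slope <= 0) {
    rlang::abort("selected segment has non-positive slope: data are not monotone on the probability plot.",
      class = "indirectRI_fit_error")
  }

  z95 <- stats::qnorm(0.975)
  lims <- best$intercept + c(-z95, z95) * best$slope
  if (config$log_scale) lims <- exp(lims)
  if (lims[1] <= 0) {
    floor_val <- 10^(-series$decimals) / 2
    rlang::warn(sprintf(
      "extrapolated lower limit %.4g is non-positive (Gaussian assumption violated); truncated to %.4g.",
      lims[1], floor_val))
    lims[1] <- floor_val
  }
  structure(
    list(
      slope = best$slope, intercept = best$intercept, r2 = best$r2,
      segment = c(best$q_lo, best$q_hi),
      ri = reference_interval(lims[1], lims[2], method = "hoffman"),
      n = series$n, config = config, points = pts,
      analyte = series$analyte_name, unit = series$unit
    ),
    class = "hoffman_fit"
  )
}

#' @export
print.hoffman_fit <- function(x, ...) {
  cat(sprintf(
    "<hoffman_fit> %s: slope = %.4g, intercept = %.4g, r2 = %.5f on window [%.2f, %.2f]\n",
    x$analyte, x$slope, x$intercept, x$r2, x$segment[1], x$segment[2]))
  print(x$ri)
  invisible(x)
}

#' @method tidy hoffman_fit
#' @export
tidy.hoffman_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @method glance hoffman_fit
#' @export
glance.hoffman_fit <- function(x, ...) {
  tibble::tibble(
    method = "hoffman", analyte = x$analyte, n = x$n, r2 = x$r2,
    segment_lo = x$segment[1], segment_hi = x$segment[2],
    lower = x$ri$lower, upper = x$ri$upper
  )
}

#' Probability-plot figure for a Hoffman fit
#'
#' Points of the cumulative plot, the fitted segment line extrapolated to
#' the 2.5th/97.5th normal quantiles, and dashed horizontal markers at the
#' estimated reference limits.
#'
#' @param object A [hoffman_fit][fit_hoffman()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hoffman_fit
#' @export
autoplot.hoffman_fit <- function(object, ...) {
  z95 <- stats::qnorm(0.975)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$ri$lower, object$ri$upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(-z95, z95), linetype = "dotted") +
    ggplot2::labs(
      x = "standard-normal quantile",
      y = paste0(object$analyte, if (nzchar(object$unit)) paste0(" (", object$unit, ")") else ""),
      title = "Hoffman cumulative-probability fit"
    )
}
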