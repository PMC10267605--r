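#' Locate the principal peak and parameter search region
#'
#' First step of the inverse-modelling estimator: a histogram is built with
#' bin width at least the reporting resolution (widened by the
#' Freedman-Diaconis rule when that is finer, and capped at 800 bins for
#' very wide-ranged data), counts are smoothed with a 3-bin moving average,
#' the principal peak is the tallest smoothed bin (leftmost of the tallest
#' on a multimodal tie, with a warning), and the search region is the widest
#' contiguous interval around the peak where smoothed counts stay above 10%
#' of the peak height.
#'
#' @param series A [measurement_series()].
#' @return A list with `region` (length-2 bounds), `peak` (bin centre),
#'   `breaks`, `counts`, `smoothed`, `width`.
#' @export
find_peak_region <- function(series) {
  stopifnot(inherits(series, "measurement_series"))
  x <- series$values
  n <- length(x)
  if (n < 500L) rlang::warn("fewer than 500 values: peak/region detection will be noisy.")
  rng <- range(x)
  if (diff(rng) <= 0) {
    rlang::abort("all values identical: degenerate search region.",
      class = "indirectRI_fit_error")
  }
  res <- 10^(-series$decimals)
  fd <- 2 * stats::IQR(x) * n^(-1 / 3)
  width <- max(res, fd)
  if (diff(rng) / width > 800) width <- diff(rng) / 800
  lo <- max(rng[1] - width / 2, rng[1] / 2)
  breaks <- seq(lo, rng[2] + width, by = width)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(counts[1:2])
  sm[length(sm)] <- mean(counts[(length(sm) - 1):length(sm)])

  peak_h <- max(sm)
  tall <- which(sm >= 0.99 * peak_h)
  if (length(tall) > 1L && any(diff(tall) > 1L)) {
    rlang::warn("multiple non-adjacent bins tie for the principal peak; using the leftmost.")
  }
  ipk <- tall[1]
  keep <- sm >= 0.10 * peak_h
  a <- ipk; while (a > 1L && keep[a - 1L]) a <- a - 1L
  b <- ipk; while (b < length(sm) && keep[b + 1L]) b <- b + 1L

  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  list(
    region = c(breaks[a], breaks[b + 1L]),
    peak = centers[ipk],
    breaks = breaks, counts = counts, smoothed = sm, width = width
  )
}

# Vectorised cost over a (mu, sigma) x P block at one lambda.
# Pearson-chi-square discrepancy on bins inside the search region, plus a
# one-sided penalty where the scaled model overshoots observed counts
# outside it (pathological excess outside the region is free; healthy-model
# overshoot is not), plus the model mass falling outside the histogram.
refiner_cost_block <- function(lam, mu_g, sig_g, P_g, bcb, O, in_region, n) {
  pairs <- expand.grid(mu = mu_g, sigma = sig_g)
  # drop parameter pairs whose central 95% interval is undefined in
  # original units (outside the inverse-transform support)
  if (abs(lam) > bc_log_threshold) {
    z95 <- stats::qnorm(0.975)
    ok <- lam * (pairs$mu - z95 * pairs$sigma) + 1 > 0 &
          lam * (pairs$mu + z95 * pairs$sigma) + 1 > 0
    pairs <- pairs[ok, , drop = FALSE]
    if (nrow(pairs) == 0L) {
      return(list(cost = matrix(Inf, 1, length(P_g)),
                  pairs = data.frame(mu = NA_real_, sigma = NA_real_)))
    }
  }
  Fm <- stats::pnorm(outer(bcb, pairs$mu, "-") / rep(pairs$sigma, each = length(bcb)))
  Pb <- Fm[-1, , drop = FALSE] - Fm[-nrow(Fm), , drop = FALSE]
  eps <- 1e-9
  out <- matrix(Inf, nrow(pairs), length(P_g))
  tail_mass <- Fm[1, ] + (1 - Fm[nrow(Fm), ])
  for (ip in seq_along(P_g)) {
    E <- P_g[ip] * n * Pb
    Ein <- E[in_region, , drop = FALSE]
    chi_in <- colSums((O[in_region] - Ein)^2 / pmax(Ein, eps))
    Eout <- E[!in_region, , drop = FALSE]
    over <- pmax(Eout - O[!in_region], 0)
    chi_out <- colSums(over^2 / pmax(Eout, eps))
    out[, ip] <- chi_in + chi_out + P_g[ip] * n * tail_mass
  }
  list(cost = out, pairs = pairs)
}

#' Inverse-modelling reference-interval fit
#'
#' Three-step estimator for mixed hospital data: (1) locate the principal
#' peak and a search region around it ([find_peak_region()]); (2) a
#' multi-level grid search over the Box-Cox-Gaussian parameters
#' (lambda, mu, sigma) and a scaling factor P — the fraction of results
#' attributed to the non-pathological component — minimising a binned
#' one-sided chi-square cost: inside the search region the scaled model must
#' match the observed counts, outside it the model may not overshoot them
#' (pathological excess there is free); (3) the reference interval is the
#' closed-form 2.5th/97.5th percentile pair of the optimal model.
#'
#' Level 1 spans lambda in `{0, 0.1, ..., 1}`, mu and sigma around moment
#' estimates of the transformed in-region values (7 points each, spacing
#' sigma-hat/4), and P in `{0.3, ..., 1}`. Each further level re-grids one
#' coarse step around the incumbent at 5x resolution. Deterministic given
#' the series.
#'
#' @param series A [measurement_series()].
#' @param levels Grid-refinement depth (default 3).
#' @param boot Bootstrap replicate count for confidence intervals of the
#'   limits; 0 disables ([bootstrap_ci()] is used internally).
#' @param ci_level Confidence level for the bootstrap intervals.
#' @param seed Seed for the bootstrap.
#' @return An object of class `refiner_fit`: `model`, `p_scale`, `cost`,
#'   `ri` (with CIs when `boot > 0`), `search_region`, `peak`.
#' @export
fit_refiner <- function(series, levels = 3L, boot = 0L, ci_level = 0.95,
                        seed = NULL) {
  stopifnot(inherits(series, "measurement_series"), levels >= 1L)
  x <- series$values
  n <- length(x)
  pk <- suppressWarnings(find_peak_region(series))
  breaks <- pk$breaks
  O <- pk$counts
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  in_region <- centers >= pk$region[1] & centers <= pk$region[2]
  x_region <- x[x >= pk$region[1] & x <= pk$region[2]]

  lam_grid <- seq(0, 1, by = 0.1)
  P_grid <- seq(0.3, 1.0, by = 0.1)
  spacing <- list(lam = 0.1, P = 0.1, mu = NA, sigma = NA)

  best <- list(cost = Inf)
  eval_level <- function(lam_g, mu_g_of, sig_g_of, P_g) {
    lb <- list(cost = Inf)
    for (lam in lam_g) {
      bcb <- boxcox(breaks, lam)
      mg <- mu_g_of(lam); sg <- sig_g_of(lam)
      blk <- refiner_cost_block(lam, mg, sg, P_g, bcb, O, in_region, n)
      if (all(!is.finite(blk$cost))) next
      idx <- arrayInd(which.min(blk$cost), dim(blk$cost))
      cmin <- blk$cost[idx[1], idx[2]]
      if (cmin < lb$cost) {
        lb <- list(cost = cmin, lambda = lam,
                   mu = blk$pairs$mu[idx[1]], sigma = blk$pairs$sigma[idx[1]],
                   P = P_g[idx[2]])
      }
    }
    lb
  }

  # level 1: moment-anchored grids, per candidate power
  # population SD so that exact duplication of the data cannot move the
  # grid anchor (sample SD's n-1 denominator would)
  moment_grids <- function(lam) {
    y <- boxcox(x_region, lam)
    c(mean(y), sqrt(mean((y - mean(y))^2)))
  }
  mu_g1 <- function(lam) {
    ms <- moment_grids(lam); ms[1] + (-3:3) * ms[2] / 4
  }
  sig_g1 <- function(lam) {
    ms <- moment_grids(lam)
    g <- ms[2] + (-3:3) * ms[2] / 4
    g[g > ms[2] / 8]
  }
  best <- eval_level(lam_grid, mu_g1, sig_g1, P_grid)
  if (!is.finite(best$cost)) {
    rlang::abort("cost non-finite for every level-1 grid point.",
      class = "indirectRI_fit_error")
  }
  ms0 <- moment_grids(best$lambda)
  spacing$mu <- ms0[2] / 4
  spacing$sigma <- ms0[2] / 4

  if (levels > 1L) {
    for (lvl in seq(2L, levels)) {
      spacing <- lapply(spacing, function(s) s / 5)
      lam_g <- best$lambda + (-5:5) * spacing$lam
      lam_g <- lam_g[lam_g >= -0.5 & lam_g <= 1.5]
      mu_g <- best$mu + (-5:5) * spacing$mu
      sig_g <- best$sigma + (-5:5) * spacing$sigma
      sig_g <- sig_g[sig_g > 0]
      P_g <- best$P + (-5:5) * spacing$P
      P_g <- P_g[P_g > 0.05 & P_g <= 1]
      cand <- eval_level(lam_g, function(l) mu_g, function(l) sig_g, P_g)
      if (is.finite(cand$cost) && cand$cost < best$cost) best <- cand
    }
  }

  model <- box_cox_gaussian(best$lambda, best$mu, best$sigma)
  ri <- model_ri(model, method = "refiner")
  fit <- structure(
    list(
      model = model, p_scale = best$P, cost = best$cost,
      ri = ri, search_region = pk$region, peak = pk$peak,
      n = n, levels = levels,
      analyte = series$analyte_name, unit = series$unit
    ),
    class = "refiner_fit"
  )
  if (boot > 0L) {
    ci <- bootstrap_ci(series, n_boot = boot, level = ci_level,
                       levels = levels, seed = seed)
    fit$ri <- reference_interval(ri$lower, ri$upper, method = "refiner",
                                 ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
                                 ci_level = ci_level)
    fit$bootstrap <- ci
  }
  fit
}

#' @export
print.refiner_fit <- function(x, ...) {
  cat(sprintf(
    "<refiner_fit> %s: lambda = %.4g, mu = %.6g, sigma = %.6g, P = %.3g\n  search region %.4g - %.4g, cost = %.6g\n",
    x$analyte, x$model$lambda, x$model$mu, x$model$sigma, x$p_scale,
    x$search_region[1], x$search_region[2], x$cost))
  print(x$ri)
  invisible(x)
}

#' @method tidy refiner_fit
#' @export
tidy.refiner_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "mu", "sigma", "p_scale"),
                 estimate = c(x$model$lambda, x$model$mu, x$model$sigma, x$p_scale))
}

#' @method glance refiner_fit
#' @export
glance.refiner_fit <- function(x, ...) {
  tibble::tibble(
    method = "refiner", analyte = x$analyte, n = x$n,
    cost = x$cost, p_scale = x$p_scale,
    region_lo = x$search_region[1], region_hi = x$search_region[2],
    lower = x$ri$lower, upper = x$ri$upper
  )
}

#' Bootstrap confidence intervals for inverse-modelling reference limits
#'
#' Resamples the series with replacement (same size), refits
#' [fit_refiner()] on each replicate, and returns percentile confidence
#' intervals of the lower and upper limits. Failed replicate fits are
#' dropped and counted; more than 20% failures aborts. Reproducible given
#' the seed.
#'
#' @param series A [measurement_series()].
#' @param n_boot Number of replicates (>= 2; 200 is conventional).
#' @param level Confidence level of the percentile intervals.
#' @param levels Grid depth passed to [fit_refiner()].
#' @param seed Integer seed.
#' @return A list with `ci_lower`, `ci_upper` (each length 2), `level`,
#'   `n_failed`, and a tibble `replicates` of per-replicate limits.
#' @export
bootstrap_ci <- function(series, n_boot = 200L, level = 0.95, levels = 3L,
                         seed = NULL) {
  stopifnot(inherits(series, "measurement_series"), n_boot >= 2L,
            level > 0, level < 1)
  vals <- series$values
  n <- length(vals)
  lims <- withr::with_seed(seed %||% 1L, {
    purrr::map(seq_len(n_boot), function(i) {
      res <- tryCatch({
        s <- measurement_series(sample(vals, n, replace = TRUE),
                                series$analyte_name, unit = series$unit,
                                decimals = series$decimals)
        f <- suppressWarnings(fit_refiner(s, levels = levels, boot = 0L))
        c(f$ri$lower, f$ri$upper)
      }, error = function(e) c(NA_real_, NA_real_))
      res
    })
  })
  mat <- do.call(rbind, lims)
  failed <- rowSums(is.na(mat)) > 0
  if (mean(failed) > 0.20) {
    rlang::abort(sprintf("%d of %d bootstrap replicates failed to fit.",
      sum(failed), n_boot), class = "indirectRI_fit_error")
  }
  mat <- mat[!failed, , drop = FALSE]
  alpha <- (1 - level) / 2
  list(
    ci_lower = unname(stats::quantile(mat[, 1], c(alpha, 1 - alpha))),
    ci_upper = unname(stats::quantile(mat[, 2], c(alpha, 1 - alpha))),
    level = level, n_failed = sum(failed),
    replicates = tibble::tibble(lower = mat[, 1], upper = mat[, 2])
  )
}

#' Histogram-and-model figure for an inverse-modelling fit
#'
#' Input-data histogram, the estimated non-pathological model curve scaled
#' by P, and dashed vertical lines at the estimated reference limits.
#'
#' @param object A [refiner_fit][fit_refiner()].
#' @param series The fitted [measurement_series()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot refiner_fit
#' @export
autoplot.refiner_fit <- function(object, series, ...) {
  plot_fit_histogram(series, object$model, object$ri, scale = object$p_scale,
                     title = "Inverse-modelling fit")
}
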