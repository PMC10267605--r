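#' Settings for the truncated Box-Cox-Gaussian fit
#'
#' The estimator searches truncation intervals whose endpoints are sample
#' quantiles: the lower endpoint between `t1_min` and `t1_max`, the upper
#' between `t2_min` and `t2_max`, on a grid of step `q_step`. The Box-Cox
#' power is searched over `lambda_grid` and then refined locally by
#' golden-section search to `tolerance`.
#'
#' `sd_param` is carried for provenance with upstream truncated-fit tools
#' and logged with results; it does not enter this implementation's
#' computation.
#'
#' @param t1_min,t1_max Lower-truncation search bounds (sample quantiles).
#' @param t2_min,t2_max Upper-truncation search bounds.
#' @param q_step Truncation-grid step.
#' @param lambda_grid Base grid of Box-Cox powers.
#' @param tolerance Convergence tolerance of the lambda refinement; the
#'   inner likelihood optimiser uses the tighter of this and 1e-8. Setting
#'   a value larger than the lambda-grid spacing disables refinement.
#' @param decimals Reporting resolution of the inputs (informational; the
#'   series carries its own).
#' @param sd_param Opaque upstream setting, logged only.
#' @param penalize Divide the Kolmogorov-Smirnov distance by the square
#'   root of the data fraction inside the truncation window. Without this,
#'   the raw distance degenerately favours the narrowest window (fewer
#'   points fit anything well); see the package vignette.
#' @return An object of class `kosmic_config`.
#' @export
kosmic_config <- function(t1_min = 0.05, t1_max = 0.30,
                          t2_min = 0.70, t2_max = 0.95,
                          q_step = 0.01,
                          lambda_grid = seq(0, 1, by = 0.1),
                          tolerance = 1e-7, decimals = NULL,
                          sd_param = 0.8, penalize = TRUE) {
  if (!(0 < t1_min && t1_min <= t1_max && t1_max < t2_min &&
        t2_min <= t2_max && t2_max < 1)) {
    rlang::abort("truncation quantile bounds must satisfy 0 < t1_min <= t1_max < t2_min <= t2_max < 1.",
      class = "indirectRI_config_error")
  }
  stopifnot(tolerance > 0, q_step > 0, length(lambda_grid) >= 1L)
  structure(
    list(t1_min = t1_min, t1_max = t1_max, t2_min = t2_min, t2_max = t2_max,
         q_step = q_step, lambda_grid = sort(lambda_grid),
         tolerance = tolerance, decimals = decimals,
         sd_param = sd_param, penalize = penalize),
    class = "kosmic_config"
  )
}

# Negative log-likelihood of a Gaussian truncated to [t1y, t2y], expressed
# through sufficient statistics of the k inside-values (mean m, biased
# variance ss). O(1) per evaluation.
trunc_nll <- function(par, k, m, ss, t1y, t2y) {
  mu <- par[1]; sigma <- exp(par[2])
  a <- (t1y - mu) / sigma; b <- (t2y - mu) / sigma
  mass <- stats::pnorm(b) - stats::pnorm(a)
  if (!is.finite(mass) || mass < 1e-300) return(1e12)
  k * log(sigma) + k * (ss + (m - mu)^2) / (2 * sigma^2) + k * log(mass)
}

# analytic gradient of trunc_nll in (mu, log sigma)
trunc_nll_grad <- function(par, k, m, ss, t1y, t2y) {
  mu <- par[1]; sigma <- exp(par[2])
  a <- (t1y - mu) / sigma; b <- (t2y - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (!is.finite(Z) || Z < 1e-300) return(c(0, 0))
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  g_mu <- k * ((mu - m) / sigma^2 + (pa - pb) / (sigma * Z))
  g_ls <- k * (1 - (ss + (m - mu)^2) / sigma^2 + (a * pa - b * pb) / Z)
  c(g_mu, g_ls)
}

# Bounded quasi-Newton fit. The box constrains the two degenerate
# directions of truncated ML on contaminated data: as sigma grows the
# truncated Gaussian tends to a uniform on [t1y, t2y], and as mu wanders
# far outside the window the model becomes a near-exponential far-tail
# slice; both can out-score any proper fit. The truncation design places
# the window around the central mass of the healthy component, so mu is
# constrained to [t1y, t2y] and sigma to [width/100, 5*width].
trunc_ml_stats <- function(k, m, ss, t1y, t2y, init = NULL, reltol = 1e-10) {
  w <- t2y - t1y
  lo <- c(t1y, log(w / 100))
  hi <- c(t2y, log(5 * w))
  clamp <- function(p) pmin(pmax(p, lo + 1e-10), hi - 1e-10)
  if (is.null(init)) init <- c(m, log(max(sqrt(ss), w / 50)))
  opt <- stats::optim(clamp(init), trunc_nll, gr = trunc_nll_grad,
                      k = k, m = m, ss = ss, t1y = t1y, t2y = t2y,
                      method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(factr = max(reltol / 1e-15, 10),
                                     maxit = 200))
  if (!is.finite(opt$value) || opt$value >= 1e12) {
    opt <- stats::optim(clamp(init), trunc_nll, k = k, m = m, ss = ss,
                        t1y = t1y, t2y = t2y, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 500))
    opt$par <- clamp(opt$par)
  }
  list(mu = opt$par[1], sigma = exp(opt$par[2]),
       value = opt$value, convergence = opt$convergence, par = opt$par)
}

#' Maximum-likelihood fit of a truncated Gaussian
#'
#' Fits mean and standard deviation of a Gaussian restricted and
#' renormalised to `[t1y, t2y]`, using only the values inside the interval.
#' Unlike the plain mean/SD of the inside-values — which are biased towards
#' the interval centre — the truncated likelihood recovers the parameters of
#' the full underlying Gaussian.
#'
#' @param y Numeric vector (transformed-scale values).
#' @param t1y,t2y Truncation bounds, `t1y < t2y`.
#' @return A list with `mu`, `sigma`, `n_inside`, `loglik`.
#' @export
truncated_gauss_ml <- function(y, t1y, t2y) {
  stopifnot(is.numeric(y), t1y < t2y)
  inside <- y[y >= t1y & y <= t2y]
  k <- length(inside)
  if (k < 50L) {
    rlang::abort(sprintf("only %d values inside [t1y, t2y]; need at least 50.", k),
      class = "indirectRI_insufficient_data")
  }
  m <- mean(inside); ss <- mean((inside - m)^2)
  if (ss <= 0) {
    rlang::abort("inside-values have zero variance: degenerate truncated sample.",
      class = "indirectRI_fit_error")
  }
  fit <- trunc_ml_stats(k, m, ss, t1y, t2y)
  if (fit$convergence != 0) {
    rlang::abort(
      sprintf("truncated-likelihood optimiser did not converge (last iterate mu = %.6g, sigma = %.6g).",
        fit$mu, fit$sigma),
      class = "indirectRI_convergence_error"
    )
  }
  list(mu = fit$mu, sigma = fit$sigma, n_inside = k, loglik = -fit$value)
}

# KS distance between the empirical CDF of inside-values (built on distinct
# rounded values, step heights = tie counts) and the truncated-Gaussian CDF,
# evaluated at both sides of each step.
ks_trunc_stats <- function(v_inside, counts_inside, mu, sigma, t1y, t2y) {
  k <- sum(counts_inside)
  A <- stats::pnorm((t1y - mu) / sigma)
  B <- stats::pnorm((t2y - mu) / sigma)
  if (B - A < 1e-300) return(1)
  Fm <- (stats::pnorm((v_inside - mu) / sigma) - A) / (B - A)
  Fe_hi <- cumsum(counts_inside) / k
  Fe_lo <- c(0, Fe_hi[-length(Fe_hi)])
  min(max(abs(Fe_hi - Fm), abs(Fe_lo - Fm)), 1)
}

#' Kolmogorov-Smirnov distance on a truncation interval
#'
#' Sup-distance between the renormalised empirical CDF of the values inside
#' `[t1y, t2y]` and the Gaussian `(mu, sigma)` truncated to the same
#' interval. Ties from rounded reporting are handled by evaluating the
#' empirical CDF at both sides of each step.
#'
#' @param y Numeric vector (transformed scale).
#' @param mu,sigma Gaussian parameters.
#' @param t1y,t2y Truncation bounds.
#' @return Distance in `[0, 1]`.
#' @export
ks_truncated <- function(y, mu, sigma, t1y, t2y) {
  stopifnot(is.numeric(y), t1y < t2y, sigma > 0)
  inside <- y[y >= t1y & y <= t2y]
  if (length(inside) == 0L) {
    rlang::abort("no values inside the truncation interval.",
      class = "indirectRI_domain_error")
  }
  tab <- table(inside)
  v <- as.numeric(names(tab))
  ks_trunc_stats(v, as.integer(tab), mu, sigma, t1y, t2y)
}

#' Truncated Box-Cox-Gaussian reference-interval fit
#'
#' For each candidate Box-Cox power and each truncation window (a pair of
#' sample quantiles from [kosmic_config()]), the transformed values inside
#' the window are fitted as a truncated Gaussian by maximum likelihood and
#' scored by the Kolmogorov-Smirnov distance between the truncated model
#' and the renormalised empirical CDF — penalised by the inside fraction
#' when `penalize` is on. The window and power with the smallest score
#' define the healthy-component model; the reference interval is its
#' closed-form 2.5th/97.5th percentile pair, [model_ri()].
#'
#' The power search evaluates the base grid and then refines around the
#' best grid point by golden-section search. The whole fit is deterministic.
#'
#' @param series A [measurement_series()]; at least 50 values (hard floor),
#'   500 recommended.
#' @param config A [kosmic_config()].
#' @return An object of class `kosmic_fit`: `model`
#'   ([box_cox_gaussian()]), truncation limits `t1`, `t2` in analyte units,
#'   raw `ks` distance, penalised `score`, `frac_inside`, and `ri`.
#' @export
fit_kosmic <- function(series, config = kosmic_config()) {
  stopifnot(inherits(series, "measurement_series"), inherits(config, "kosmic_config"))
  x <- series$values
  n <- length(x)
  if (n < 50L) {
    rlang::abort("the truncated fit needs at least 50 values.",
      class = "indirectRI_insufficient_data")
  }
  if (n < 500L) rlang::warn("fewer than 500 values: truncated-fit estimates will be unstable.")

  tab <- table(x)
  v <- as.numeric(names(tab))          # distinct sorted values
  cnt <- as.integer(tab)
  ccnt <- cumsum(cnt)

  q1s <- seq(config$t1_min, config$t1_max, by = config$q_step)
  q2s <- seq(config$t2_min, config$t2_max, by = config$q_step)
  t1x <- stats::quantile(x, q1s, type = 1, names = FALSE)
  t2x <- stats::quantile(x, q2s, type = 1, names = FALSE)

  # candidate windows; membership is power-invariant because the transform
  # is strictly increasing, so index ranges are precomputed once
  pairs <- expand.grid(i = seq_along(q1s), j = seq_along(q2s))
  pairs$i1 <- findInterval(t1x[pairs$i] - 1e-12, v) + 1L
  pairs$i2 <- findInterval(t2x[pairs$j] + 1e-12, v)
  pairs$k <- ccnt[pairs$i2] - ifelse(pairs$i1 > 1L, ccnt[pairs$i1 - 1L], 0L)
  pairs <- pairs[pairs$k >= 50L & pairs$i2 - pairs$i1 >= 2L, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    rlang::abort("no truncation window contains at least 50 values.",
      class = "indirectRI_fit_error")
  }

  eval_lambda <- function(lam) {
    yv <- boxcox(v, lam)
    cy <- cumsum(cnt * yv); cy2 <- cumsum(cnt * yv^2)
    t1y <- boxcox(t1x, lam); t2y <- boxcox(t2x, lam)
    best <- list(score = Inf)
    warm <- NULL
    failures <- 0L
    for (r in seq_len(nrow(pairs))) {
      i1 <- pairs$i1[r]; i2 <- pairs$i2[r]; k <- pairs$k[r]
      lag <- if (i1 > 1L) c(ccnt[i1 - 1L], cy[i1 - 1L], cy2[i1 - 1L]) else c(0, 0, 0)
      m <- (cy[i2] - lag[2]) / k
      ss <- (cy2[i2] - lag[3]) / k - m^2
      if (!is.finite(ss) || ss <= 0) { failures <- failures + 1L; next }
      a <- t1y[pairs$i[r]]; b <- t2y[pairs$j[r]]
      fit <- trunc_ml_stats(k, m, ss, a, b, init = warm,
                            reltol = min(config$tolerance, 1e-8))
      if (!is.finite(fit$value) || fit$sigma <= 0) { failures <- failures + 1L; next }
      warm <- fit$par
      # a candidate healthy model must have a defined central 95% interval
      z95 <- stats::qnorm(0.975)
      if (abs(lam) > bc_log_threshold &&
          (lam * (fit$mu - z95 * fit$sigma) + 1 <= 0 ||
           lam * (fit$mu + z95 * fit$sigma) + 1 <= 0)) {
        failures <- failures + 1L; next
      }
      ks <- ks_trunc_stats(yv[i1:i2], cnt[i1:i2], fit$mu, fit$sigma, a, b)
      frac <- k / n
      score <- if (config$penalize) ks / sqrt(frac) else ks
      if (score < best$score) {
        best <- list(score = score, ks = ks, mu = fit$mu, sigma = fit$sigma,
                     t1 = t1x[pairs$i[r]], t2 = t2x[pairs$j[r]], frac = frac)
      }
    }
    if (!is.finite(best$score)) {
      rlang::abort(sprintf("all %d truncation candidates failed at lambda = %.4g.",
        nrow(pairs), lam), class = "indirectRI_fit_error")
    }
    best$lambda <- lam
    best
  }

  grid_fits <- lapply(config$lambda_grid, function(l) {
    tryCatch(eval_lambda(l), error = function(e) list(score = Inf, lambda = l, error = conditionMessage(e)))
  })
  scores <- vapply(grid_fits, function(f) f$score, numeric(1))
  if (all(!is.finite(scores))) {
    rlang::abort(paste0("every candidate power failed:\n",
      paste(vapply(grid_fits, function(f) paste0("  lambda=", f$lambda, ": ", f$error %||% "non-finite score"),
                   character(1)), collapse = "\n")),
      class = "indirectRI_fit_error")
  }
  ibest <- which.min(scores)
  best <- grid_fits[[ibest]]

  # golden-section refinement of the power between the neighbouring grid points
  lg <- config$lambda_grid
  lo <- if (ibest > 1L) lg[ibest - 1L] else lg[ibest]
  hi <- if (ibest < length(lg)) lg[ibest + 1L] else lg[ibest]
  if (hi - lo > config$tolerance) {
    safe_eval <- function(l) {
      tryCatch(eval_lambda(l), error = function(e) list(score = Inf, lambda = l))
    }
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
    f1 <- safe_eval(c1); f2 <- safe_eval(c2)
    while (b - a > max(config$tolerance, 1e-9)) {
      if (f1$score < f2$score) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - phi * (b - a); f1 <- safe_eval(c1)
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + phi * (b - a); f2 <- safe_eval(c2)
      }
    }
    cand <- if (f1$score < f2$score) f1 else f2
    if (is.finite(cand$score) && cand$score < best$score) best <- cand
  }

  model <- box_cox_gaussian(best$lambda, best$mu, best$sigma)
  structure(
    list(
      model = model, t1 = best$t1, t2 = best$t2,
      ks = best$ks, score = best$score, frac_inside = best$frac,
      ri = model_ri(model, method = "kosmic"),
      n = n, config = config,
      analyte = series$analyte_name, unit = series$unit
    ),
    class = "kosmic_fit"
  )
}

#' @export
print.kosmic_fit <- function(x, ...) {
  cat(sprintf(
    "<kosmic_fit> %s: lambda = %.4g, mu = %.6g, sigma = %.6g\n  truncation %.4g - %.4g (%.0f%% of data inside), KS = %.4g\n",
    x$analyte, x$model$lambda, x$model$mu, x$model$sigma,
    x$t1, x$t2, 100 * x$frac_inside, x$ks))
  print(x$ri)
  invisible(x)
}

#' @method tidy kosmic_fit
#' @export
tidy.kosmic_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "mu", "sigma"),
                 estimate = c(x$model$lambda, x$model$mu, x$model$sigma))
}

#' @method glance kosmic_fit
#' @export
glance.kosmic_fit <- function(x, ...) {
  tibble::tibble(
    method = "kosmic", analyte = x$analyte, n = x$n,
    ks = x$ks, score = x$score, t1 = x$t1, t2 = x$t2,
    frac_inside = x$frac_inside,
    lower = x$ri$lower, upper = x$ri$upper
  )
}

#' Histogram-and-model figure for a truncated Box-Cox-Gaussian fit
#'
#' Input-data histogram with the estimated healthy-component density
#' overlaid and dashed vertical lines at the reference limits.
#'
#' @param object A [kosmic_fit][fit_kosmic()].
#' @param series The fitted [measurement_series()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot kosmic_fit
#' @export
autoplot.kosmic_fit <- function(object, series, ...) {
  plot_fit_histogram(series, object$model, object$ri, scale = 1,
                     title = "Truncated Box-Cox-Gaussian fit")
}

# shared histogram + scaled model curve + dashed RI lines
plot_fit_histogram <- function(series, model, ri, scale = 1, title = "") {
  x <- series$values
  bw <- max(10^(-series$decimals), 2 * stats::IQR(x) * length(x)^(-1 / 3))
  xmax <- stats::quantile(x, 0.995, names = FALSE)
  grid <- seq(max(min(x), 1e-6), xmax, length.out = 400)
  curve <- tibble::tibble(
    x = grid,
    y = scale * length(x) * bw * model_density(model, grid)
  )
  ggplot2::ggplot(tibble::tibble(x = x[x <= xmax]), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(binwidth = bw, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = c(ri$lower, ri$upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = paste0(series$analyte_name,
                 if (nzchar(series$unit)) paste0(" (", series$unit, ")") else ""),
      y = "count", title = title
    )
}
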