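# switchover below which the Box-Cox power branch is replaced by its
# log limit: cancellation in (x^l - 1)/l dominates before l reaches this
bc_log_threshold <- 1e-6

#' Box-Cox power transform
#'
#' The one-parameter Box-Cox transform \eqn{y = (x^\lambda - 1)/\lambda}
#' (\eqn{\lambda \neq 0}), \eqn{y = \log x} (\eqn{\lambda = 0}), used
#' throughout the package to Gaussianise right-skewed analyte distributions
#' such as TSH before fitting a normal model.
#'
#' The log branch is taken whenever `abs(lambda) < 1e-6`; below that the
#' power branch suffers cancellation, while the two branches agree to
#' better than 1e-8 at the switchover.
#'
#' @param x Positive numeric vector of results in original units.
#' @param lambda Power parameter (scalar).
#' @return Numeric vector of transformed values.
#' @seealso [inv_boxcox()], [box_cox_gaussian()]
#' @examples
#' boxcox(2, 1)      # 1
#' boxcox(1, 0.37)   # 0 for every lambda
#' @export
boxcox <- function(x, lambda) {
  stopifnot(is.numeric(x), is.numeric(lambda), length(lambda) == 1L)
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort("`x` must be finite and > 0: the Box-Cox transform is undefined otherwise.",
      class = "indirectRI_domain_error")
  }
  if (abs(lambda) <= bc_log_threshold) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#'
#' Exact inverse of [boxcox()]: maps a value on the transformed (Gaussian)
#' scale back to original analyte units. Defined only where
#' \eqn{\lambda y + 1 > 0} (\eqn{\lambda \neq 0}).
#'
#' @param y Numeric vector on the transformed scale.
#' @param lambda Power parameter (scalar).
#' @return Positive numeric vector in original units.
#' @examples
#' inv_boxcox(0, 0.5)  # 1
#' inv_boxcox(1, 1)    # 2
#' @export
inv_boxcox <- function(y, lambda) {
  stopifnot(is.numeric(y), is.numeric(lambda), length(lambda) == 1L)
  if (abs(lambda) <= bc_log_threshold) return(exp(y))
  arg <- lambda * y + 1
  if (any(!is.finite(arg)) || any(arg <= 0)) {
    rlang::abort("`lambda * y + 1` must be > 0: outside the support of the inverse Box-Cox transform.",
      class = "indirectRI_domain_error")
  }
  arg^(1 / lambda)
}

#' Box-Cox-Gaussian model of a healthy analyte distribution
#'
#' The shared healthy-component model of all estimators in this package: a
#' variable whose Box-Cox transform (power `lambda`) is Gaussian with mean
#' `mu` and standard deviation `sigma`. Reference limits are closed-form
#' percentiles of this model ([model_percentile()], [model_ri()]).
#'
#' @param lambda Box-Cox power parameter.
#' @param mu Mean of the transformed values.
#' @param sigma Standard deviation of the transformed values (> 0).
#' @return An object of class `box_cox_gaussian`.
#' @examples
#' m <- box_cox_gaussian(lambda = 0.07, mu = 0.734, sigma = 0.689)
#' model_ri(m)
#' @export
box_cox_gaussian <- function(lambda, mu, sigma) {
  stopifnot(is.numeric(lambda), is.numeric(mu), is.numeric(sigma))
  if (!is.finite(sigma) || sigma <= 0) {
    rlang::abort("`sigma` must be a positive finite number.",
      class = "indirectRI_domain_error")
  }
  structure(
    list(lambda = as.numeric(lambda), mu = as.numeric(mu), sigma = as.numeric(sigma)),
    class = "box_cox_gaussian"
  )
}

#' @export
print.box_cox_gaussian <- function(x, ...) {
  cat(sprintf(
    "<box_cox_gaussian>  lambda = %.4g, mu = %.6g, sigma = %.6g\n",
    x$lambda, x$mu, x$sigma
  ))
  ri <- tryCatch(model_ri(x), error = function(e) NULL)
  if (!is.null(ri)) {
    cat(sprintf("  implied 95%% reference interval: %.6g - %.6g\n", ri$lower, ri$upper))
  }
  invisible(x)
}

#' Percentile of a Box-Cox-Gaussian model in original units
#'
#' Evaluates `inv_boxcox(mu + z_p * sigma, lambda)` where `z_p` is the exact
#' standard-normal quantile; strictly increasing in `p`.
#'
#' @param model A [box_cox_gaussian()] object.
#' @param p Probability (vector allowed), each in (0, 1).
#' @return Percentile(s) in original analyte units.
#' @export
model_percentile <- function(model, p) {
  stopifnot(inherits(model, "box_cox_gaussian"), is.numeric(p))
  if (any(p <= 0 | p >= 1)) {
    rlang::abort("`p` must lie strictly between 0 and 1.",
      class = "indirectRI_domain_error")
  }
  y <- model$mu + stats::qnorm(p) * model$sigma
  if (abs(model$lambda) > bc_log_threshold && any(model$lambda * y + 1 <= 0)) {
    bad <- p[model$lambda * y + 1 <= 0]
    rlang::abort(
      sprintf("percentile map undefined at p = %s for this model (lambda * (mu + z*sigma) + 1 <= 0).",
        paste(signif(bad, 4), collapse = ", ")),
      class = "indirectRI_domain_error"
    )
  }
  inv_boxcox(y, model$lambda)
}

#' Cumulative distribution function of a Box-Cox-Gaussian model
#'
#' @param model A [box_cox_gaussian()] object.
#' @param x Positive numeric vector in original units.
#' @return P(X <= x) under the model.
#' @export
model_cdf <- function(model, x) {
  stopifnot(inherits(model, "box_cox_gaussian"))
  stats::pnorm((boxcox(x, model$lambda) - model$mu) / model$sigma)
}

#' Density of a Box-Cox-Gaussian model in original units
#'
#' Change-of-variables density: \eqn{f(x) = \phi((bc(x) - \mu)/\sigma)
#' \cdot x^{\lambda - 1} / \sigma}.
#'
#' @inheritParams model_cdf
#' @return Density values.
#' @export
model_density <- function(model, x) {
  stopifnot(inherits(model, "box_cox_gaussian"))
  stats::dnorm((boxcox(x, model$lambda) - model$mu) / model$sigma) *
    x^(model$lambda - 1) / model$sigma
}

#' Reference interval implied by a Box-Cox-Gaussian model
#'
#' The central `level` interval: lower limit at percentile `(1 - level)/2`,
#' upper at `(1 + level)/2`. With the default `level = 0.95` these are the
#' conventional 2.5th and 97.5th reference percentiles.
#'
#' @param model A [box_cox_gaussian()] object.
#' @param level Central coverage of the interval (default 0.95).
#' @param method Optional method label propagated to the result.
#' @return A [reference_interval()] object.
#' @export
model_ri <- function(model, level = 0.95, method = NA_character_) {
  lims <- model_percentile(model, c((1 - level) / 2, (1 + level) / 2))
  reference_interval(lims[1], lims[2], method = method)
}

#' Reference interval
#'
#' Lower and upper reference limits in analyte units, optionally with
#' bootstrap confidence intervals around each limit.
#'
#' @param lower,upper Positive reference limits, `lower < upper`.
#' @param method Label of the producing method (`"hoffman"`, `"kosmic"`,
#'   `"refiner"`, or `NA`).
#' @param ci_lower,ci_upper Optional length-2 ordered confidence bounds for
#'   the lower / upper limit.
#' @param ci_level Confidence level of the bounds (e.g. 0.95).
#' @return An object of class `reference_interval`.
#' @export
reference_interval <- function(lower, upper, method = NA_character_,
                               ci_lower = NULL, ci_upper = NULL,
                               ci_level = NULL) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L, length(upper) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || lower >= upper) {
    rlang::abort("reference interval requires 0 < lower < upper.",
      class = "indirectRI_domain_error")
  }
  check_ci <- function(ci, what) {
    if (is.null(ci)) return(NULL)
    stopifnot(is.numeric(ci), length(ci) == 2L)
    if (ci[1] > ci[2]) {
      rlang::abort(sprintf("%s confidence bounds must be ordered.", what),
        class = "indirectRI_domain_error")
    }
    as.numeric(ci)
  }
  structure(
    list(
      lower = as.numeric(lower), upper = as.numeric(upper),
      ci_lower = check_ci(ci_lower, "lower-limit"),
      ci_upper = check_ci(ci_upper, "upper-limit"),
      ci_level = ci_level,
      method = method
    ),
    class = "reference_interval"
  )
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("<reference_interval%s>  %.4g - %.4g\n",
    if (is.na(x$method)) "" else paste0(": ", x$method), x$lower, x$upper))
  if (!is.null(x$ci_lower)) {
    cat(sprintf("  %d%% CI lower limit: %.4g - %.4g\n",
      round(100 * x$ci_level), x$ci_lower[1], x$ci_lower[2]))
  }
  if (!is.null(x$ci_upper)) {
    cat(sprintf("  %d%% CI upper limit: %.4g - %.4g\n",
      round(100 * x$ci_level), x$ci_upper[1], x$ci_upper[2]))
  }
  invisible(x)
}

#' @method tidy reference_interval
#' @export
tidy.reference_interval <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    lower = x$lower,
    upper = x$upper,
    ci_lower_lo = if (is.null(x$ci_lower)) NA_real_ else x$ci_lower[1],
    ci_lower_hi = if (is.null(x$ci_lower)) NA_real_ else x$ci_lower[2],
    ci_upper_lo = if (is.null(x$ci_upper)) NA_real_ else x$ci_upper[1],
    ci_upper_hi = if (is.null(x$ci_upper)) NA_real_ else x$ci_upper[2],
    ci_level = if (is.null(x$ci_level)) NA_real_ else x$ci_level
  )
}
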