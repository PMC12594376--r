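#' Construct a relaxation time series
#'
#' @param t times (s, positive, strictly increasing after sorting).
#' @param s normalized stress values (positive; usually in (0, 1]).
#' @param label curve identifier.
#' @return An object of class `relaxation_series`.
#' @export
relaxation_series <- function(t, s, label = "") {
  t <- as.numeric(t); s <- as.numeric(s)
  if (length(t) != length(s) || length(t) < 3L) {
    stop_bonevpd("a relaxation series needs at least 3 (t, s) pairs",
                 "bonevpd_series_error")
  }
  if (any(!is.finite(t)) || any(t <= 0) || any(!is.finite(s)) || any(s <= 0)) {
    stop_bonevpd("times and normalized stresses must be finite and positive",
                 "bonevpd_series_error")
  }
  o <- order(t)
  t <- t[o]; s <- s[o]
  if (any(diff(t) <= 0)) {
    stop_bonevpd("times must be distinct", "bonevpd_series_error")
  }
  if (any(diff(s) > 0)) {
    warning("relaxation series is not monotonically decreasing (noise?)")
  }
  x <- list(t = t, s = s, label = as.character(label))
  class(x) <- "relaxation_series"
  x
}

#' Fit a power law to a relaxation curve
#'
#' Least-squares fit of `s(t) = a * t^(-b)` in log-log space (ordinary
#' linear regression of `log(s)` on `log(t)`). The residual sum of squares
#' is reported on the original stress scale.
#'
#' @param series a [relaxation_series()] object.
#' @return An object of class `power_law_fit` with elements `a`, `b`, `rss`.
#' @export
fit_power_law <- function(series) {
  stopifnot(inherits(series, "relaxation_series"))
  fit <- stats::lm(log(s) ~ log(t), data = list(t = series$t, s = series$s))
  a <- exp(unname(stats::coef(fit)[1]))
  b <- -unname(stats::coef(fit)[2])
  out <- list(a = a, b = b,
              rss = sum((series$s - a * series$t^(-b))^2),
              label = series$label)
  class(out) <- "power_law_fit"
  out
}

#' Extrapolated percentage stress reduction
#'
#' Evaluates the fitted power law at a long-time horizon relative to a
#' reference time: `100 * (1 - s(horizon)/s(t_ref))`, clipped to [0, 100].
#' The prefactor cancels in the ratio, so the reduction depends only on the
#' exponent and the time ratio. A pure power law has no finite nonzero
#' asymptote; the value at the conventional 1e6 s horizon stands in for the
#' asymptotic reduction.
#'
#' @param fit a [fit_power_law()] object.
#' @param t_ref reference time (s, > 0), typically the first sample time.
#' @param horizon extrapolation horizon (s, > t_ref); default 1e6.
#' @return Reduction percentage in [0, 100].
#' @export
stress_reduction <- function(fit, t_ref, horizon = 1e6) {
  stopifnot(inherits(fit, "power_law_fit"))
  check_scalar(t_ref, "t_ref", positive = TRUE)
  check_scalar(horizon, "horizon", positive = TRUE)
  if (horizon <= t_ref) {
    stop_bonevpd("'horizon' must exceed 't_ref'", "bonevpd_parameter_error")
  }
  red <- 100 * (1 - (horizon / t_ref)^(-fit$b))
  min(max(red, 0), 100)
}

#' Mean stress-reduction fraction
#'
#' Averages per-curve reduction percentages, rounds to the nearest integer
#' percent and converts to a fraction. Rounding to whole percent matches
#' the conventional reporting of the calibration procedure (the nine
#' reference curves average to 24.33%, used as 24%).
#'
#' @param reductions non-empty numeric vector of percentages.
#' @return Mean reduction as a fraction in [0, 1].
#' @export
#' @examples
#' mean_reduction(c(27, 23, 24, 9, 3, 39, 62, 25, 7))  # 0.24
mean_reduction <- function(reductions) {
  if (length(reductions) == 0L || any(!is.finite(reductions))) {
    stop_bonevpd("'reductions' must be a non-empty finite numeric vector",
                 "bonevpd_parameter_error")
  }
  round(mean(reductions)) / 100
}

#' Scale yield strains to their long-time equilibrium values
#'
#' Multiplies the tensile and compressive yield strains by the
#' mean-reduction fraction, leaving every other field untouched. The scaled
#' set approximates the equilibrium (infinitely slow loading) yield surface
#' used for viscoplastic simulations.
#'
#' @param yp a [yield_parameters()] object.
#' @param fraction scaling fraction in (0, 1].
#' @return A new `yield_parameters` object with scaled `eps0p`, `eps0m`.
#' @export
scale_yield_parameters <- function(yp, fraction) {
  stopifnot(inherits(yp, "yield_parameters"))
  check_scalar(fraction, "fraction", positive = TRUE)
  if (fraction > 1) {
    stop_bonevpd("'fraction' must be in (0, 1]", "bonevpd_parameter_error")
  }
  yield_parameters(eps0p = yp$eps0p * fraction,
                   eps0m = yp$eps0m * fraction,
                   xi0 = yp$xi0, m1 = yp$m1, m2 = yp$m2, m3 = yp$m3)
}
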