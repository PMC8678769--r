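#' Evaluate a polynomial trajectory shape
#'
#' A trajectory group's mean blood pressure over time is modelled as a
#' polynomial in hours since the start of thrombolysis, with coefficients
#' stored intercept-first: \code{value(t) = b0 + b1 t + b2 t^2 + ...}.
#'
#' @param coefficients numeric vector, intercept first; length is polynomial
#'   degree + 1. Degrees 0 through 4 are used by the trajectory model.
#' @param t numeric vector of times (hours).
#' @return numeric vector of trajectory values (mmHg), same length as `t`.
#' @examples
#' # a flat 120 mmHg trajectory
#' trajectory_value(120, c(0, 12, 24))
#' # a declining quadratic
#' trajectory_value(c(150, -2, 0.05), 0:4)
#' @export
trajectory_value <- function(coefficients, t) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || anyNA(coefficients) || any(!is.finite(coefficients)))
    stop("'coefficients' must be a non-empty finite numeric vector")
  if (any(!is.finite(t))) stop("'t' must be finite")
  # Horner evaluation, highest degree first
  out <- rep(coefficients[length(coefficients)], length(t))
  if (length(coefficients) > 1L) {
    for (m in (length(coefficients) - 1L):1L) out <- out * t + coefficients[m]
  }
  out
}

#' Censored-normal log-density
#'
#' Density of the censored normal (CNORM) outcome distribution used by the
#' trajectory likelihood: normal in the interior of `(lower, upper)`, with the
#' tail mass accumulated at the scale bounds. Observations at or below `lower`
#' contribute `log P(Y <= lower)`; observations at or above `upper` contribute
#' `log P(Y >= upper)`. With infinite bounds this is the ordinary normal
#' log-density.
#'
#' @param x observed values.
#' @param mean,sd normal location and scale; `sd` must be positive.
#' @param lower,upper censoring bounds, `lower < upper`; default uncensored.
#' @param log logical; return log density (default TRUE, the use in the
#'   mixture likelihood).
#' @return numeric vector of (log-)densities.
#' @export
dcnorm <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf, log = TRUE) {
  if (any(sd <= 0)) stop("'sd' must be positive")
  if (any(lower >= upper)) stop("'lower' must be less than 'upper'")
  n <- max(length(x), length(mean))
  x <- rep_len(x, n); mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  lo <- rep_len(lower, n); up <- rep_len(upper, n)
  ll <- stats::dnorm(x, mean, sd, log = TRUE)
  at_lo <- x <= lo
  at_up <- x >= up
  if (any(at_lo))
    ll[at_lo] <- stats::pnorm(lo[at_lo], mean[at_lo], sd[at_lo], log.p = TRUE)
  if (any(at_up))
    ll[at_up] <- stats::pnorm(up[at_up], mean[at_up], sd[at_up],
                              lower.tail = FALSE, log.p = TRUE)
  if (log) ll else exp(ll)
}

#' Log-likelihood of one series under one trajectory group
#'
#' Sums the censored-normal log-density of each observation around the group's
#' polynomial mean at the observation time.
#'
#' @param values observed pressures (mmHg).
#' @param times observation times (hours), same length as `values`.
#' @param coefficients polynomial coefficients, intercept first.
#' @param sd residual standard deviation (mmHg), positive.
#' @param lower,upper censoring bounds.
#' @return scalar log-likelihood.
#' @export
series_loglik <- function(values, times, coefficients, sd,
                          lower = -Inf, upper = Inf) {
  if (length(values) == 0L) stop("empty series")
  if (length(values) != length(times)) stop("'values' and 'times' lengths differ")
  mu <- trajectory_value(coefficients, times)
  sum(dcnorm(values, mu, sd, lower, upper, log = TRUE))
}
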