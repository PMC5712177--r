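# Closed-form identities for the log-normal distribution parameterised by
# its untransformed median m and untransformed SD phi, and the exponential-
# distribution facts used by the sensitivity analysis.
#
# If T ~ logN(mu, sigma^2) then median(T) = exp(mu), so mu = log(m), and the
# raw variance phi^2 = m^2 * x * (x - 1) with x = exp(sigma^2).  Solving the
# quadratic in x gives sigma^2 = log(1/2 + sqrt(1/4 + phi^2 / m^2)).

as_group <- function(group, sd = NULL, label = NULL) {
  if (inherits(group, "group_spec")) return(group)
  group_spec(group, if (is.null(sd)) 0 else sd, label = label)
}

#' Log-scale mean implied by an untransformed median
#'
#' For a log-normal outcome the population median equals the geometric mean
#' `exp(mu)`, so the log-scale mean is simply the natural log of the median.
#'
#' @param group A [group_spec()], or a positive numeric median.
#' @return The log-scale mean `mu = log(median)`.
#' @examples
#' log_scale_mean(20)                 # log(20)
#' log_scale_mean(group_spec(20, 5))  # identical
#' @export
log_scale_mean <- function(group) {
  g <- as_group(group)
  log(g$median)
}

#' Log-scale variance implied by an untransformed median and SD
#'
#' Converts the untransformed standard deviation `phi` of a log-normal
#' outcome with median `m` to the variance of the log-transformed outcome:
#' `sigma^2 = log(1/2 + sqrt(1/4 + phi^2 / m^2))`.  The conversion depends
#' on `m` and `phi` only through the coefficient of variation `phi / m`, and
#' is zero exactly when `phi = 0`.
#'
#' @param group A [group_spec()], or a positive numeric median.
#' @param sd Untransformed standard deviation, ignored when `group` is a
#'   `group_spec`.
#' @return The non-negative log-scale variance `sigma^2`.
#' @examples
#' log_scale_variance(20, 5)
#' log_scale_variance(1, 1 / log(2))  # ~0.7065, the exponential-matched value
#' @export
log_scale_variance <- function(group, sd = NULL) {
  g <- as_group(group, sd)
  log(0.5 + sqrt(0.25 + g$sd^2 / g$median^2))
}

#' Untransformed variance of a log-normal distribution
#'
#' Inverse of [log_scale_variance()]: given log-scale mean `mu` and variance
#' `sigma_sq`, returns the variance on the original scale,
#' `m^2 * x * (x - 1)` with `m = exp(mu)` and `x = exp(sigma_sq)`.  Used as
#' the round-trip check on the median/SD conversion.
#'
#' @param mu Log-scale mean.
#' @param sigma_sq Non-negative log-scale variance.
#' @return The untransformed variance.
#' @examples
#' raw_variance_from_log(log(20), log_scale_variance(20, 5))  # 25
#' @export
raw_variance_from_log <- function(mu, sigma_sq) {
  check_scalar(mu, "mu")
  check_scalar(sigma_sq, "sigma_sq", nonneg = TRUE)
  x <- exp(sigma_sq)
  exp(mu)^2 * x * (x - 1)
}

#' Untransformed mean of a log-normal distribution
#'
#' The population mean on the original scale is `median * exp(sigma^2 / 2)`,
#' always at least the median (equality only for a degenerate distribution).
#' This is why a raw-scale t-test compares a different location functional
#' than the log-scale t-test: two groups with equal medians but unequal raw
#' SDs have unequal raw means.
#'
#' @inheritParams log_scale_variance
#' @return The untransformed mean, `>= median`.
#' @examples
#' lognormal_mean(20, 5)
#' @export
lognormal_mean <- function(group, sd = NULL) {
  g <- as_group(group, sd)
  g$median * exp(log_scale_variance(g) / 2)
}

#' Exponential distribution matching a given median
#'
#' For X ~ Exp(rate) the median is `log(2) / rate` and the standard
#' deviation is `1 / rate`, so a pre-specified median determines the rate as
#' `rate = log(2) / median`.  Used by the sensitivity analysis to generate
#' skewed-but-not-log-normal data with the same medians as a log-normal
#' scenario.
#'
#' @param median Positive target median.
#' @return An object of class `exponential_spec` with elements `rate`,
#'   `median`, `sd` (`= 1 / rate`).
#' @examples
#' exponential_from_median(0.1)  # rate ~6.93
#' @export
exponential_from_median <- function(median) {
  check_scalar(median, "median", positive = TRUE)
  rate <- log(2) / median
  structure(list(rate = rate, median = median, sd = 1 / rate),
            class = "exponential_spec")
}

#' @export
print.exponential_spec <- function(x, ...) {
  cat(sprintf("Exponential(rate = %g): median %g, SD %g\n",
              x$rate, x$median, x$sd))
  invisible(x)
}

#' Variance of the log of an exponential random variable
#'
#' If X ~ Exp(rate) then Var(log X) = pi^2 / 6 ~ 1.645, independent of the
#' rate (log X is a shifted negative Gumbel variable).  This is the correct
#' log-scale variance to use in the sample size formula when outcomes are
#' exponential rather than log-normal, and is more than twice the value
#' (~0.7065) that the log-normal conversion would assign to an
#' exponential-matched median/SD pair.
#'
#' @return `pi^2 / 6`.
#' @examples
#' log_exponential_variance()
#' @export
log_exponential_variance <- function() {
  pi^2 / 6
}
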