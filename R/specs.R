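# S3 constructors for the design inputs.  All validation lives here so the
# arithmetic in the other files can assume well-formed inputs.

ln_stop <- function(msg, class = "lognsize_domain_error") {
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(class, "lognsize_error", "error", "condition")
  ))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ln_stop(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    ln_stop(sprintf("`%s` must be positive (got %g)", name, x))
  if (nonneg && x < 0)
    ln_stop(sprintf("`%s` must be non-negative (got %g)", name, x))
  x
}

#' Specify one arm by its untransformed median and standard deviation
#'
#' A `group_spec` summarises the outcome distribution of one study arm on the
#' original measurement scale (e.g. minutes): the population median and the
#' untransformed (raw-scale) standard deviation.  These are the quantities a
#' clinical team can usually pre-specify for a positively skewed outcome;
#' the log-scale parameters needed by the sample size formula are derived
#' from them by [log_scale_mean()] and [log_scale_variance()] under a
#' log-normal assumption.
#'
#' @param median Positive number; the group median on the untransformed scale.
#' @param sd Non-negative number; the untransformed standard deviation.
#'   `sd = 0` describes a degenerate (point-mass) distribution and is allowed
#'   in the conversions.
#' @param label Optional group label used in error messages and reports.
#'
#' @return An object of class `group_spec` with elements `median`, `sd`,
#'   `label`.
#' @examples
#' group_spec(20, 5, label = "manual placement")
#' @export
group_spec <- function(median, sd, label = NULL) {
  if (is.numeric(median) && length(median) == 1L && is.finite(median) &&
      median <= 0)
    ln_stop(sprintf("median must be positive (got %g)%s", median,
                    if (is.null(label)) "" else paste0(" for group ", label)))
  check_scalar(median, "median", positive = TRUE)
  check_scalar(sd, "sd", nonneg = TRUE)
  structure(list(median = median, sd = sd, label = label),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("Group%s: median %g, raw SD %g (untransformed scale)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$median, x$sd))
  invisible(x)
}

#' Specify the test size and target power
#'
#' Holds the two-sided significance level and target power, and optionally
#' explicit values for the standard-normal quantiles used by the sample size
#' formula.  By default the quantiles are computed in full double precision
#' with [stats::qnorm()]; the overrides exist for reproducing calculations
#' done with rounded quantile values (e.g. 1.96 and 1.28).
#'
#' @param alpha Two-sided significance level, in (0, 1).  Default 0.05.
#' @param power Target power, in (0, 1).  Default 0.9.
#' @param z_alpha Optional positive override for the upper alpha/2 quantile.
#' @param z_beta Optional positive override for the upper beta quantile.
#'
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(alpha = 0.05, power = 0.9)
#' design_spec(z_alpha = 1.96, z_beta = 1.28)  # rounded-quantile variant
#' @export
design_spec <- function(alpha = 0.05, power = 0.9,
                        z_alpha = NULL, z_beta = NULL) {
  check_scalar(alpha, "alpha")
  check_scalar(power, "power")
  if (alpha <= 0 || alpha >= 1) ln_stop("alpha must lie strictly in (0, 1)")
  if (power <= 0 || power >= 1) ln_stop("power must lie strictly in (0, 1)")
  if (!is.null(z_alpha)) check_scalar(z_alpha, "z_alpha", positive = TRUE)
  if (!is.null(z_beta)) check_scalar(z_beta, "z_beta", positive = TRUE)
  structure(list(alpha = alpha, power = power,
                 z_alpha = z_alpha, z_beta = z_beta),
            class = "design_spec")
}

# Quantiles actually used by the sizing formulas: exact qnorm unless
# overridden.
z_alpha_half <- function(design) {
  if (!is.null(design$z_alpha)) design$z_alpha
  else stats::qnorm(1 - design$alpha / 2)
}

z_beta <- function(design) {
  if (!is.null(design$z_beta)) design$z_beta
  else stats::qnorm(design$power)
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Design: two-sided alpha = %g, power = %g\n", x$alpha, x$power))
  if (!is.null(x$z_alpha) || !is.null(x$z_beta))
    cat(sprintf("  quantile overrides: z_alpha/2 = %s, z_beta = %s\n",
                if (is.null(x$z_alpha)) "(exact)" else format(x$z_alpha),
                if (is.null(x$z_beta)) "(exact)" else format(x$z_beta)))
  invisible(x)
}

#' Specify within-cluster correlation for a clustered design
#'
#' Describes clustering of observations within sampling units (e.g.
#' electrodes within patients) through the intra-class correlation
#' coefficient (ICC) and the average cluster size.  The implied variance
#' inflation factor is `1 + icc * (cluster_size - 1)`; see
#' [design_effect()].
#'
#' @param icc Intra-class correlation coefficient, in \[0, 1).
#' @param cluster_size Average cluster size, at least 1.
#'
#' @return An object of class `cluster_spec`.
#' @examples
#' cluster_spec(icc = 0.2, cluster_size = 10)
#' @export
cluster_spec <- function(icc, cluster_size) {
  check_scalar(icc, "icc")
  check_scalar(cluster_size, "cluster_size")
  if (icc < 0 || icc >= 1) ln_stop("icc must lie in [0, 1)")
  if (cluster_size < 1) ln_stop("cluster_size must be at least 1")
  structure(list(icc = icc, cluster_size = cluster_size),
            class = "cluster_spec")
}

#' @export
print.cluster_spec <- function(x, ...) {
  cat(sprintf("Clustering: ICC = %g, average cluster size = %g (def = %g)\n",
              x$icc, x$cluster_size, design_effect(x)))
  invisible(x)
}
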