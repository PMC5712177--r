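# Per-group sample sizes for the two-sample t-test on log-transformed
# outcomes, with the effect specified as a difference in untransformed
# medians.  All sizing funnels through n_from_log_variances(); the public
# entry points differ only in how the log-scale variances are obtained.

new_sample_size_result <- function(n_continuous, pad, sigma_sq_1, sigma_sq_2,
                                   tau, method, design, note = NULL) {
  # round up to whole subjects; never fewer than 2 per arm (a two-sample
  # t-test needs at least 2 observations per group)
  n_per_group <- max(2L, as.integer(ceiling(n_continuous)) + as.integer(pad))
  structure(list(
    n_continuous = n_continuous,
    n_per_group = n_per_group,
    sigma_sq_1 = sigma_sq_1,
    sigma_sq_2 = sigma_sq_2,
    tau = tau,
    small_sample_pad = as.integer(pad),
    method = method,
    design = design,
    note = note
  ), class = "sample_size_result")
}

#' Per-group sample size from explicit log-scale variances
#'
#' The normal-approximation sample size for a two-sided two-sample
#' comparison of log-scale means:
#' `n = (sigma_sq_1 + sigma_sq_2) * (z_{alpha/2} + z_beta)^2 / tau^2`,
#' where `tau` is the log-scale mean difference.  The continuous value is
#' rounded up to the next integer; `pad` adds further subjects per group to
#' compensate for the normal (rather than t) quantiles at small n.
#'
#' @param sigma_sq_1,sigma_sq_2 Non-negative log-scale variances, not both
#'   zero.
#' @param tau Non-zero log-scale mean difference,
#'   `log(median1) - log(median2)`.
#' @param design A [design_spec()].
#' @param pad Non-negative integer added to the rounded per-group n.
#' @param method Internal tag recording which formula produced the result.
#'
#' @return An object of class `sample_size_result` with elements
#'   `n_continuous`, `n_per_group`, `sigma_sq_1`, `sigma_sq_2`, `tau`,
#'   `small_sample_pad`, `method`, `design`.
#' @examples
#' n_from_log_variances(pi^2 / 6, pi^2 / 6, log(80) - log(70),
#'                      design_spec(power = 0.9))
#' @export
n_from_log_variances <- function(sigma_sq_1, sigma_sq_2, tau, design,
                                 pad = 0L, method = "explicit_log_variances") {
  check_scalar(sigma_sq_1, "sigma_sq_1", nonneg = TRUE)
  check_scalar(sigma_sq_2, "sigma_sq_2", nonneg = TRUE)
  check_scalar(tau, "tau")
  check_scalar(pad, "pad", nonneg = TRUE)
  stopifnot(inherits(design, "design_spec"))
  if (tau == 0)
    ln_stop("no detectable difference: tau is zero (medians must differ)")
  if (sigma_sq_1 == 0 && sigma_sq_2 == 0)
    ln_stop("degenerate design: both log-scale variances are zero")
  zsum <- z_alpha_half(design) + z_beta(design)
  n_cont <- (sigma_sq_1 + sigma_sq_2) * zsum^2 / tau^2
  new_sample_size_result(n_cont, pad, sigma_sq_1, sigma_sq_2, tau,
                         method, design)
}

#' Per-group sample size for log-normal outcomes specified by medians
#'
#' Converts each arm's untransformed median and SD to log-scale parameters
#' (see [log_scale_mean()], [log_scale_variance()]) and applies the
#' two-sample normal-approximation formula.  The result is symmetric in the
#' two groups.
#'
#' @param group1,group2 [group_spec()] objects (medians must differ).
#' @param design A [design_spec()].
#' @param pad Extra subjects per group added after rounding up; useful at
#'   small n where normal quantiles slightly under-size a t-test.
#'
#' @return A `sample_size_result` (method `"lognormal_eq4"`).
#' @examples
#' n_lognormal(group_spec(20, 5), group_spec(16, 5),
#'             design_spec(alpha = 0.05, power = 0.9))
#' @export
n_lognormal <- function(group1, group2, design, pad = 0L) {
  g1 <- as_group(group1, label = "1")
  g2 <- as_group(group2, label = "2")
  if (g1$median == g2$median)
    ln_stop("no detectable difference: medians must differ")
  tau <- log_scale_mean(g1) - log_scale_mean(g2)
  n_from_log_variances(log_scale_variance(g1), log_scale_variance(g2),
                       tau, design, pad = pad, method = "lognormal_eq4")
}

#' Per-group sample size for exponential outcomes (corrected variance)
#'
#' For exponentially distributed outcomes the variance of the
#' log-transformed outcome is `pi^2 / 6` regardless of the rate, so the
#' sizing formula uses that value in both groups together with
#' `tau = log(median1) - log(median2)`.
#'
#' @param median1,median2 Positive, distinct group medians.
#' @inheritParams n_lognormal
#'
#' @return A `sample_size_result` (method `"exponential_corrected"`).
#' @examples
#' n_exponential(80, 70, design_spec(power = 0.9))  # n = 1939 per group
#' @export
n_exponential <- function(median1, median2, design, pad = 0L) {
  check_scalar(median1, "median1", positive = TRUE)
  check_scalar(median2, "median2", positive = TRUE)
  if (median1 == median2)
    ln_stop("no detectable difference: medians must differ")
  v <- log_exponential_variance()
  n_from_log_variances(v, v, log(median1) - log(median2), design,
                       pad = pad, method = "exponential_corrected")
}

#' Mis-specified log-normal sizing for exponential outcomes
#'
#' Applies the log-normal formula of [n_lognormal()] to medians and SDs that
#' actually come from exponential distributions (`sd = median / log(2)`).
#' The implied log-scale variance is then ~0.7065 in every group — less than
#' half the true value `pi^2 / 6` — so the resulting n under-sizes the study
#' badly.  Provided to quantify the cost of the distributional
#' mis-specification; use [n_exponential()] for exponential data.
#'
#' @inheritParams n_exponential
#' @return A `sample_size_result` (method `"lognormal_eq4"`, with a `note`
#'   flagging the mis-specification).
#' @examples
#' n_exponential_naive(80, 70, design_spec(power = 0.9))  # n = 833, too small
#' @export
n_exponential_naive <- function(median1, median2, design, pad = 0L) {
  check_scalar(median1, "median1", positive = TRUE)
  check_scalar(median2, "median2", positive = TRUE)
  res <- n_lognormal(group_spec(median1, median1 / log(2)),
                     group_spec(median2, median2 / log(2)),
                     design, pad = pad)
  res$note <- paste("log-normal sizing applied to exponential-matched",
                    "median/SD values; under-sizes for exponential data",
                    "(true log-scale variance is pi^2/6)")
  res
}

#' Unequal-allocation sample sizes
#'
#' Standard allocation-ratio generalisation of the two-sample formula:
#' with `n2 = ratio * n1`,
#' `n1 = (sigma_sq_1 + sigma_sq_2 / ratio) * (z_{alpha/2} + z_beta)^2 / tau^2`.
#' With `ratio = 1` both groups reproduce [n_lognormal()]'s continuous n.
#' This is a conventional extension of the equal-allocation method.
#'
#' @inheritParams n_lognormal
#' @param ratio Positive allocation ratio `n2 / n1`.
#'
#' @return A list with `n1_continuous`, `n2_continuous`, `n1`, `n2`
#'   (rounded up, clamped at 2), `ratio`, and the log-scale intermediates.
#' @examples
#' n_unequal_allocation(group_spec(1, 0.5), group_spec(1.5, 0.5),
#'                      design_spec(power = 0.8), ratio = 2)
#' @export
n_unequal_allocation <- function(group1, group2, design, ratio = 1) {
  check_scalar(ratio, "ratio", positive = TRUE)
  g1 <- as_group(group1, label = "1")
  g2 <- as_group(group2, label = "2")
  if (g1$median == g2$median)
    ln_stop("no detectable difference: medians must differ")
  s1 <- log_scale_variance(g1)
  s2 <- log_scale_variance(g2)
  if (s1 == 0 && s2 == 0)
    ln_stop("degenerate design: both log-scale variances are zero")
  tau <- log_scale_mean(g1) - log_scale_mean(g2)
  zsum <- z_alpha_half(design) + z_beta(design)
  n1 <- (s1 + s2 / ratio) * zsum^2 / tau^2
  n2 <- ratio * n1
  round_up <- function(x) {
    x <- max(2, ceiling(x))
    if (x <= .Machine$integer.max) as.integer(x) else x
  }
  list(n1_continuous = n1, n2_continuous = n2,
       n1 = round_up(n1), n2 = round_up(n2),
       ratio = ratio, sigma_sq_1 = s1, sigma_sq_2 = s2, tau = tau)
}

#' Variance inflation factor for a clustered design
#'
#' `def = 1 + icc * (cluster_size - 1)`: the factor by which the sample size
#' must grow when observations are correlated within clusters of the given
#' average size.
#'
#' @param cluster A [cluster_spec()].
#' @return The design effect, at least 1.
#' @examples
#' design_effect(cluster_spec(0.2, 10))  # 2.8
#' @export
design_effect <- function(cluster) {
  stopifnot(inherits(cluster, "cluster_spec"))
  1 + cluster$icc * (cluster$cluster_size - 1)
}

#' Inflate a per-group sample size for clustering
#'
#' Multiplies the (already rounded, and padded) per-group number of
#' observations by the design effect and rounds up, then converts to a
#' number of clusters per group by dividing by the average cluster size and
#' rounding up.  E.g. 32 observations at ICC 0.2 with clusters of 10 become
#' `ceil(2.8 * 32) = 90` observations in `ceil(90 / 10) = 9` clusters.
#'
#' @param n_per_group Positive integer per-group sample size, or a
#'   `sample_size_result` (its `n_per_group` is used).
#' @param cluster A [cluster_spec()].
#'
#' @return A list of class `cluster_inflation`: `design_effect`, `n_units`
#'   (observations per group), `n_clusters` (clusters per group).
#' @examples
#' inflate_for_clustering(32, cluster_spec(0.2, 10))
#' @export
inflate_for_clustering <- function(n_per_group, cluster) {
  if (inherits(n_per_group, "sample_size_result"))
    n_per_group <- n_per_group$n_per_group
  check_scalar(n_per_group, "n_per_group", positive = TRUE)
  if (n_per_group < 1) ln_stop("n_per_group must be at least 1")
  def <- design_effect(cluster)
  n_units <- as.integer(ceiling(n_per_group * def))
  n_clusters <- as.integer(ceiling(n_units / cluster$cluster_size))
  structure(list(design_effect = def, n_units = n_units,
                 n_clusters = n_clusters),
            class = "cluster_inflation")
}

#' @export
print.cluster_inflation <- function(x, ...) {
  cat(sprintf("Design effect %g: %d observations in %d clusters per group\n",
              x$design_effect, x$n_units, x$n_clusters))
  invisible(x)
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("Two-group sample size (t-test on log-transformed outcomes)\n")
  cat(sprintf("  method:               %s\n", x$method))
  cat(sprintf("  alpha (two-sided):    %g\n", x$design$alpha))
  cat(sprintf("  target power:         %g\n", x$design$power))
  cat(sprintf("  z_alpha/2 + z_beta:   %.6g + %.6g\n",
              z_alpha_half(x$design), z_beta(x$design)))
  cat(sprintf("  log-scale variances:  sigma1^2 = %.6g, sigma2^2 = %.6g\n",
              x$sigma_sq_1, x$sigma_sq_2))
  cat(sprintf("  log-median difference (tau): %.6g\n", x$tau))
  cat(sprintf("  n per group (continuous):    %.4f\n", x$n_continuous))
  if (x$small_sample_pad > 0)
    cat(sprintf("  small-sample pad:            +%d\n", x$small_sample_pad))
  cat(sprintf("  n per group (rounded up):    %d\n", x$n_per_group))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.sample_size_result <- function(x, ...) {
  data.frame(method = x$method,
             sigma_sq_1 = x$sigma_sq_1,
             sigma_sq_2 = x$sigma_sq_2,
             tau = x$tau,
             n_continuous = x$n_continuous,
             small_sample_pad = x$small_sample_pad,
             n_per_group = x$n_per_group,
             n_total = 2L * x$n_per_group,
             stringsAsFactors = FALSE)
}
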