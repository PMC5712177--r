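# Monte-Carlo power engine: draw two-group samples (log-normal or
# exponential), apply three two-sided tests, report rejection proportions.

#' Define a two-group Monte-Carlo power scenario
#'
#' @param group1,group2 [group_spec()] objects.  For `family =
#'   "exponential"` the raw SDs are ignored: each group's rate is
#'   `log(2) / median` so the medians match the log-normal scenario.
#' @param n_per_group Per-group sample size, at least 2.
#' @param family `"lognormal"` or `"exponential"`.
#' @param n_reps Number of Monte-Carlo replicates, at least 1.
#' @param alpha Two-sided significance level for all three tests.
#' @param seed Integer seed; together with the replicate index and group it
#'   determines every draw, so results are fully reproducible.
#'
#' @return An object of class `simulation_scenario`.
#' @examples
#' simulation_scenario(group_spec(1, 0.5), group_spec(1.5, 0.5),
#'                     n_per_group = 14, n_reps = 1000, seed = 1)
#' @export
simulation_scenario <- function(group1, group2, n_per_group,
                                family = c("lognormal", "exponential"),
                                n_reps = 100000, alpha = 0.05, seed = 1) {
  family <- match.arg(family)
  g1 <- as_group(group1, label = "1")
  g2 <- as_group(group2, label = "2")
  check_scalar(n_per_group, "n_per_group", positive = TRUE)
  check_scalar(n_reps, "n_reps", positive = TRUE)
  check_scalar(alpha, "alpha")
  check_scalar(seed, "seed")
  if (n_per_group < 2) ln_stop("n_per_group must be at least 2")
  if (n_reps < 1) ln_stop("n_reps must be at least 1")
  if (alpha <= 0 || alpha >= 1) ln_stop("alpha must lie strictly in (0, 1)")
  structure(list(group1 = g1, group2 = g2,
                 n_per_group = as.integer(n_per_group),
                 family = family, n_reps = as.integer(n_reps),
                 alpha = alpha, seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Deterministic per-(seed, replicate, group) stream seed.  A small integer
# hash keeps replicates independent and order-insensitive, so a replicate
# can be redrawn in isolation.  All operands stay below 2^53 and the result
# below 2^31.
stream_seed <- function(seed, replicate, group) {
  h <- (abs(as.double(seed)) %% 2147483647) * 48271 +
    as.double(replicate) * 2654435761 +
    as.double(group) * 40503 + 11
  as.integer(h %% 2147483647)
}

draw_group <- function(g, n, family, seed) {
  set.seed(seed)
  if (family == "lognormal") {
    stats::rlnorm(n, meanlog = log_scale_mean(g),
                  sdlog = sqrt(log_scale_variance(g)))
  } else {
    stats::rexp(n, rate = exponential_from_median(g$median)$rate)
  }
}

#' Draw one replicate's two-group sample
#'
#' For the log-normal family, group j's values are draws from
#' `logN(log(median_j), sigma_j^2)` with `sigma_j^2` from
#' [log_scale_variance()]; for the exponential family, from
#' `Exp(log(2) / median_j)`.  The same `(seed, replicate_index)` pair always
#' produces the same sample, and the caller's RNG state is left untouched.
#'
#' @param scenario A [simulation_scenario()].
#' @param replicate_index Positive integer replicate number.
#' @return A list with numeric vectors `sample1` and `sample2`, all values
#'   strictly positive.
#' @examples
#' sc <- simulation_scenario(group_spec(1, 0.5), group_spec(1.5, 0.5),
#'                           n_per_group = 5, n_reps = 10, seed = 42)
#' draw_two_group_sample(sc, 1)
#' @export
draw_two_group_sample <- function(scenario, replicate_index) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  check_scalar(replicate_index, "replicate_index", positive = TRUE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  list(
    sample1 = draw_group(scenario$group1, scenario$n_per_group,
                         scenario$family,
                         stream_seed(scenario$seed, replicate_index, 1)),
    sample2 = draw_group(scenario$group2, scenario$n_per_group,
                         scenario$family,
                         stream_seed(scenario$seed, replicate_index, 2))
  )
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Apply the three comparison tests to one two-group sample
#'
#' Runs, at level `alpha`, (i) a two-sided two-sample t-test on the
#' log-transformed values, (ii) a Mann-Whitney U test on the untransformed
#' values, and (iii) a two-sample t-test on the untransformed values.
#' The t-tests pool the group variances by default (`t_variant = "pooled"`);
#' `"welch"` drops the equal-variance assumption.  The Mann-Whitney p-value
#' follows standard practice by default (`mw_exact = NULL`): exact
#' enumeration when both groups have fewer than 50 observations and there
#' are no ties, otherwise the normal approximation with continuity
#' correction.  At small n the approximation is conservative enough to
#' depress power visibly, so the exact default matters there.  Set
#' `mw_exact` to `TRUE`/`FALSE` to force a method.
#'
#' Two identical constant samples retain the null under all three tests
#' (zero-variance guard); two distinct constant samples reject.
#'
#' @param sample1,sample2 Numeric vectors of at least 2 strictly positive
#'   values each.
#' @param alpha Two-sided significance level.
#' @param t_variant `"pooled"` or `"welch"`.
#' @param mw_exact `NULL` (auto), `TRUE` (exact) or `FALSE` (normal
#'   approximation with continuity correction) for the Mann-Whitney
#'   p-value.
#'
#' @return A list with logical elements `reject_log_t`, `reject_mw`,
#'   `reject_raw_t` (`TRUE` = reject the null) and numeric `p_log_t`,
#'   `p_mw`, `p_raw_t`.
#' @examples
#' run_three_tests(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' @export
run_three_tests <- function(sample1, sample2, alpha = 0.05,
                            t_variant = c("pooled", "welch"),
                            mw_exact = NULL) {
  t_variant <- match.arg(t_variant)
  if (length(sample1) < 2 || length(sample2) < 2)
    ln_stop("each sample needs at least 2 observations")
  if (any(sample1 <= 0) || any(sample2 <= 0))
    ln_stop("samples must be strictly positive (log transform required)")
  check_scalar(alpha, "alpha")

  if (stats::var(sample1) == 0 && stats::var(sample2) == 0) {
    # degenerate draws: equal constants retain, distinct constants separate
    sep <- sample1[1] != sample2[1]
    p <- if (sep) 0 else 1
    return(list(reject_log_t = sep, reject_mw = sep, reject_raw_t = sep,
                p_log_t = p, p_mw = p, p_raw_t = p))
  }

  pooled <- t_variant == "pooled"
  p_log <- stats::t.test(log(sample1), log(sample2),
                         var.equal = pooled)$p.value
  p_raw <- stats::t.test(sample1, sample2, var.equal = pooled)$p.value
  p_mw <- suppressWarnings(
    stats::wilcox.test(sample1, sample2, exact = mw_exact,
                       correct = TRUE)$p.value)
  list(reject_log_t = p_log < alpha,
       reject_mw = p_mw < alpha,
       reject_raw_t = p_raw < alpha,
       p_log_t = p_log, p_mw = p_mw, p_raw_t = p_raw)
}

#' Estimate power of the three tests by Monte-Carlo simulation
#'
#' Repeats draw-and-test over `scenario$n_reps` replicates and reports each
#' test's rejection proportion with its Monte-Carlo standard error
#' `sqrt(p * (1 - p) / n_reps)`.  Identical scenarios (including the seed)
#' give bit-identical results.
#'
#' @param scenario A [simulation_scenario()].
#' @inheritParams run_three_tests
#' @return An object of class `power_estimates`: `power_log_t`,
#'   `power_mann_whitney`, `power_raw_t`, their `mc_se_*`, `n_reps`, and
#'   the scenario.
#' @examples
#' sc <- simulation_scenario(group_spec(1, 0.5), group_spec(1.5, 0.5),
#'                           n_per_group = 14, n_reps = 500, seed = 7)
#' estimate_power(sc)
#' @export
estimate_power <- function(scenario, t_variant = c("pooled", "welch"),
                           mw_exact = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  t_variant <- match.arg(t_variant)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))

  hits <- c(log_t = 0L, mw = 0L, raw_t = 0L)
  for (r in seq_len(scenario$n_reps)) {
    s <- list(
      sample1 = draw_group(scenario$group1, scenario$n_per_group,
                           scenario$family,
                           stream_seed(scenario$seed, r, 1)),
      sample2 = draw_group(scenario$group2, scenario$n_per_group,
                           scenario$family,
                           stream_seed(scenario$seed, r, 2))
    )
    res <- tryCatch(
      run_three_tests(s$sample1, s$sample2, alpha = scenario$alpha,
                      t_variant = t_variant, mw_exact = mw_exact),
      error = function(e) {
        ln_stop(sprintf("replicate %d: %s", r, conditionMessage(e)),
                class = "lognsize_runtime_error")
      })
    hits <- hits + c(res$reject_log_t, res$reject_mw, res$reject_raw_t)
  }
  p <- hits / scenario$n_reps
  se <- sqrt(p * (1 - p) / scenario$n_reps)
  structure(list(power_log_t = unname(p["log_t"]),
                 power_mann_whitney = unname(p["mw"]),
                 power_raw_t = unname(p["raw_t"]),
                 mc_se_log_t = unname(se["log_t"]),
                 mc_se_mw = unname(se["mw"]),
                 mc_se_raw_t = unname(se["raw_t"]),
                 n_reps = scenario$n_reps,
                 scenario = scenario),
            class = "power_estimates")
}

#' @export
print.power_estimates <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Monte-Carlo power (%s data, n = %d per group, %d replicates, alpha = %g)\n",
              sc$family, sc$n_per_group, x$n_reps, sc$alpha))
  cat(sprintf("  medians %g vs %g; raw SDs %g, %g%s\n",
              sc$group1$median, sc$group2$median,
              sc$group1$sd, sc$group2$sd,
              if (sc$family == "exponential") " (SDs ignored: rates from medians)" else ""))
  fmt <- function(p, se) sprintf("%.4f (mc se %.4f)", p, se)
  cat("  log-scale t-test:  ", fmt(x$power_log_t, x$mc_se_log_t), "\n")
  cat("  Mann-Whitney U:    ", fmt(x$power_mann_whitney, x$mc_se_mw), "\n")
  cat("  raw-scale t-test:  ", fmt(x$power_raw_t, x$mc_se_raw_t), "\n")
  invisible(x)
}

#' @export
as.data.frame.power_estimates <- function(x, ...) {
  sc <- x$scenario
  data.frame(family = sc$family, m1 = sc$group1$median, m2 = sc$group2$median,
             sd1 = sc$group1$sd, sd2 = sc$group2$sd,
             n_per_group = sc$n_per_group, alpha = sc$alpha,
             n_reps = x$n_reps, seed = sc$seed,
             power_log_t = x$power_log_t,
             power_mann_whitney = x$power_mann_whitney,
             power_raw_t = x$power_raw_t,
             mc_se_log_t = x$mc_se_log_t, mc_se_mw = x$mc_se_mw,
             mc_se_raw_t = x$mc_se_raw_t,
             stringsAsFactors = FALSE)
}
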