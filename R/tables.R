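# Built-in simulation study: three scenario sets covering the log-normal
# sizing method, its failure under exponential data, and the corrected
# exponential sizing.

# Set 1: log-normal outcomes sized by the median/raw-SD formula, a
# power-0.8 block and a power-0.9 block.  Sets 2 and 3 share one grid of
# exponential medians (SDs are median/log(2) by construction); set 2 sizes
# with the mis-specified log-normal formula, set 3 with pi^2/6.
lognormal_grid <- function() {
  g8 <- data.frame(
    m1 = 1,
    m2 = c(1.5, 1.25, 1.1, 0.5, 0.7, 0.9, 0.6, 0.7, 0.8, 0.75, 0.88, 0.94),
    sd1 = c(rep(0.5, 3), rep(0.4, 3), rep(0.3, 3), rep(0.25, 3)),
    sd2 = c(rep(0.5, 3), rep(0.4, 3), rep(0.3, 3), rep(0.25, 3)),
    power = 0.8)
  g9 <- data.frame(
    m1 = 1,
    m2 = c(1.5, 1.25, 1.1, 0.5, 0.7, 0.9, 0.6, 0.7, 0.8, 0.75, 0.88, 0.94),
    sd1 = c(rep(0.5, 3), rep(0.6, 3), rep(0.5, 3), rep(0.4, 3)),
    sd2 = c(rep(0.7, 3), rep(0.4, 3), rep(0.3, 3), rep(0.25, 3)),
    power = 0.9)
  rbind(g8, g9)
}

exponential_grid <- function() {
  data.frame(
    m1 = c(0.1, 1, 10, 20, 60, 80),
    m2 = c(0.3, 1.5, 7, 15, 48, 70),
    power = 0.9)
}

#' Scenario definitions of the built-in simulation study
#'
#' Returns the parameter grid of one of the three bundled scenario sets:
#' \describe{
#'   \item{1}{24 log-normal scenarios (medians and raw SDs; target power
#'     0.8 for the first 12 rows, 0.9 for the rest), sized with
#'     [n_lognormal()].}
#'   \item{2}{6 exponential scenarios (`sd = median / log(2)`), deliberately
#'     sized with the mis-specified log-normal formula
#'     ([n_exponential_naive()]) to expose its under-sizing.}
#'   \item{3}{the same 6 exponential scenarios sized with the corrected
#'     formula ([n_exponential()]).}
#' }
#' The `n` column is computed from the sizing formula, not stored.
#'
#' @param table_id 1, 2 or 3.
#' @param alpha Two-sided significance level used for sizing.
#' @return A data frame with columns `table`, `scenario`, `family`, `m1`,
#'   `m2`, `sd1`, `sd2`, `power_target`, `alpha`, `n`.
#' @examples
#' scenario_table(3)
#' @export
scenario_table <- function(table_id, alpha = 0.05) {
  if (!is.numeric(table_id) || length(table_id) != 1L ||
      !table_id %in% 1:3)
    ln_stop("table_id must be 1, 2 or 3", class = "lognsize_usage_error")
  if (table_id == 1) {
    g <- lognormal_grid()
    g$family <- "lognormal"
  } else {
    g <- exponential_grid()
    g$sd1 <- g$m1 / log(2)
    g$sd2 <- g$m2 / log(2)
    g$family <- "exponential"
  }
  g$n <- vapply(seq_len(nrow(g)), function(i) {
    design <- design_spec(alpha = alpha, power = g$power[i])
    res <- switch(as.character(table_id),
      "1" = n_lognormal(group_spec(g$m1[i], g$sd1[i]),
                        group_spec(g$m2[i], g$sd2[i]), design),
      "2" = n_exponential_naive(g$m1[i], g$m2[i], design),
      "3" = n_exponential(g$m1[i], g$m2[i], design))
    res$n_per_group
  }, integer(1))
  data.frame(table = as.integer(table_id), scenario = seq_len(nrow(g)),
             family = g$family, m1 = g$m1, m2 = g$m2,
             sd1 = g$sd1, sd2 = g$sd2, power_target = g$power,
             alpha = alpha, n = g$n, stringsAsFactors = FALSE)
}

#' Replicate one scenario set of the simulation study
#'
#' For each row of [scenario_table()] computes the analytic per-group n and
#' estimates the power of the three tests by Monte-Carlo simulation at that
#' n.  Each row gets its own deterministic seed derived from `seed`, so the
#' whole table is reproducible and rows can be recomputed independently.
#'
#' At the default `n_reps = 100000` a full set takes minutes; a few
#' thousand replicates already locate each power to about one percentage
#' point (Monte-Carlo se `sqrt(p(1-p)/n_reps)`).
#'
#' @inheritParams scenario_table
#' @param n_reps Monte-Carlo replicates per scenario.
#' @param seed Integer master seed.
#' @inheritParams run_three_tests
#' @return The scenario data frame with columns `power_log_t`,
#'   `power_mann_whitney`, `power_raw_t`, their Monte-Carlo standard
#'   errors, `n_reps` and `seed` appended.
#' @examples
#' replicate_table(3, n_reps = 200, seed = 1)[, c("m1", "m2", "n", "power_log_t")]
#' @export
replicate_table <- function(table_id, n_reps = 100000, seed = 1,
                            alpha = 0.05,
                            t_variant = c("pooled", "welch"),
                            mw_exact = NULL) {
  t_variant <- match.arg(t_variant)
  check_scalar(n_reps, "n_reps", positive = TRUE)
  if (n_reps < 1) ln_stop("n_reps must be at least 1")
  tab <- scenario_table(table_id, alpha = alpha)
  est <- lapply(seq_len(nrow(tab)), function(i) {
    sc <- simulation_scenario(
      group_spec(tab$m1[i], tab$sd1[i]), group_spec(tab$m2[i], tab$sd2[i]),
      n_per_group = tab$n[i], family = tab$family[i],
      n_reps = n_reps, alpha = alpha,
      seed = stream_seed(seed, 7919L * as.integer(table_id), i))
    e <- estimate_power(sc, t_variant = t_variant, mw_exact = mw_exact)
    c(e$power_log_t, e$power_mann_whitney, e$power_raw_t,
      e$mc_se_log_t, e$mc_se_mw, e$mc_se_raw_t)
  })
  est <- do.call(rbind, est)
  tab$power_log_t <- est[, 1]
  tab$power_mann_whitney <- est[, 2]
  tab$power_raw_t <- est[, 3]
  tab$mc_se_log_t <- est[, 4]
  tab$mc_se_mw <- est[, 5]
  tab$mc_se_raw_t <- est[, 6]
  tab$n_reps <- as.integer(n_reps)
  tab$seed <- as.integer(seed)
  tab
}
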