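# Monte-Carlo engine: reproducible draws, correct test verdicts, calibrated
# rejection rates.

test_that("draws are reproducible, positive, and match the target distributions", {
  sc <- simulation_scenario(group_spec(20, 5), group_spec(16, 5),
                            n_per_group = 50, n_reps = 10, seed = 99)
  a <- draw_two_group_sample(sc, 3)
  b <- draw_two_group_sample(sc, 3)
  expect_identical(a, b)
  expect_false(identical(a, draw_two_group_sample(sc, 4)))
  expect_true(all(a$sample1 > 0) && all(a$sample2 > 0))

  # degenerate spec: all draws equal the median
  scd <- simulation_scenario(group_spec(3, 0), group_spec(4, 0),
                             n_per_group = 5, n_reps = 1, seed = 1)
  expect_equal(draw_two_group_sample(scd, 1)$sample1, rep(3, 5))

  # pooled draws recover median and SD (log-normal) and median (exponential)
  big <- simulation_scenario(group_spec(20, 5), group_spec(0.1, 1),
                             n_per_group = 1000, n_reps = 1000, seed = 42)
  x1 <- unlist(lapply(1:1000, function(r) draw_two_group_sample(big, r)$sample1))
  f20 <- stats::dlnorm(20, log(20), sqrt(log_scale_variance(20, 5)))
  expect_lt(abs(stats::median(x1) - 20), 3 / (2 * f20 * sqrt(1e6)))
  s2 <- stats::var(x1)
  expect_lt(abs(s2 - 25),
            3 * sqrt((mean((x1 - mean(x1))^4) - s2^2) / 1e6))

  bige <- simulation_scenario(group_spec(0.1, 0), group_spec(0.3, 0),
                              n_per_group = 1000, n_reps = 1000,
                              family = "exponential", seed = 42)
  e1 <- unlist(lapply(1:1000, function(r) draw_two_group_sample(bige, r)$sample1))
  fe <- stats::dexp(0.1, log(2) / 0.1)
  expect_lt(abs(stats::median(e1) - 0.1), 3 / (2 * fe * sqrt(1e6)))
})

test_that("drawing does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- stats::runif(1)
  set.seed(123)
  sc <- simulation_scenario(group_spec(1, 0.5), group_spec(2, 0.5),
                            n_per_group = 10, n_reps = 5, seed = 7)
  invisible(draw_two_group_sample(sc, 1))
  invisible(estimate_power(simulation_scenario(group_spec(1, 0.5),
                                               group_spec(2, 0.5), 5,
                                               n_reps = 3, seed = 7)))
  expect_identical(stats::runif(1), r1)
})

test_that("test verdicts agree with independently computed statistics", {
  # fixed 5 + 5 toy samples; t and U statistics computed from first
  # principles, independent of the implementation's calls
  x <- c(1.8, 2.6, 3.1, 4.9, 5.4)
  y <- c(3.9, 5.2, 6.8, 8.1, 11.0)
  res <- run_three_tests(x, y, alpha = 0.05, mw_exact = TRUE)

  pooled_t_p <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    2 * stats::pt(-abs(tt), n1 + n2 - 2)
  }
  expect_equal(res$p_raw_t, pooled_t_p(x, y), tolerance = 1e-10)
  expect_equal(res$p_log_t, pooled_t_p(log(x), log(y)), tolerance = 1e-10)

  # exact Mann-Whitney: enumerate all choose(10, 5) group assignments
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(x, y)
  combos <- utils::combn(10, 5)
  u_obs <- u_stat(x, y)
  u_null <- apply(combos, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  # two-sided exact p as twice the smaller tail (no ties here)
  p_exact <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
  expect_equal(res$p_mw, min(1, p_exact), tolerance = 1e-10)
})

test_that("trivial verdicts: identical samples retain, separated samples reject", {
  s <- c(1.2, 3.4, 2.2, 5.1)
  same <- run_three_tests(s, s)
  expect_false(same$reject_log_t || same$reject_mw || same$reject_raw_t)
  far <- run_three_tests(s, s + 1e6)
  expect_true(far$reject_log_t && far$reject_mw && far$reject_raw_t)
  # degenerate constant samples
  eq <- run_three_tests(rep(2, 5), rep(2, 5))
  expect_false(eq$reject_log_t || eq$reject_mw || eq$reject_raw_t)
  ne <- run_three_tests(rep(2, 5), rep(3, 5))
  expect_true(ne$reject_log_t && ne$reject_mw && ne$reject_raw_t)
  expect_error(run_three_tests(c(-1, 2, 3), s), "positive")
  expect_error(run_three_tests(1, s), "at least 2")
})

test_that("power estimation is deterministic given the scenario", {
  sc <- simulation_scenario(group_spec(1, 0.5), group_spec(1.5, 0.5),
                            n_per_group = 14, n_reps = 300, seed = 17)
  e1 <- estimate_power(sc)
  e2 <- estimate_power(sc)
  expect_identical(e1, e2)
  expect_equal(e1$mc_se_log_t,
               sqrt(e1$power_log_t * (1 - e1$power_log_t) / 300))
  e3 <- estimate_power(simulation_scenario(group_spec(1, 0.5),
                                           group_spec(1.5, 0.5),
                                           14, n_reps = 300, seed = 18))
  expect_false(identical(e1$power_log_t, e3$power_log_t))
})

test_that("type-I error is calibrated at the null", {
  sc <- simulation_scenario(group_spec(1, 0.5), group_spec(1, 0.5),
                            n_per_group = 30, n_reps = 4000, alpha = 0.05,
                            seed = 2718)
  e <- estimate_power(sc)
  tol <- 3 * sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(e$power_log_t - 0.05), tol)
  expect_lt(abs(e$power_mann_whitney - 0.05), tol)
  expect_lt(abs(e$power_raw_t - 0.05), tol)
})

test_that("raw-scale t-test over-rejects when medians agree but SDs differ", {
  # equal medians with unequal raw SDs imply unequal raw means
  # m exp(sigma^2/2), so the raw-scale null is false while the log-scale
  # null is true
  expect_equal(lognormal_mean(1, 0.2) == lognormal_mean(1, 2), FALSE)
  sc <- simulation_scenario(group_spec(1, 0.2), group_spec(1, 2),
                            n_per_group = 100, n_reps = 2000, alpha = 0.05,
                            seed = 314)
  e <- estimate_power(sc)
  expect_gt(e$power_raw_t, 0.05 + 3 * e$mc_se_raw_t)
  expect_lt(abs(e$power_log_t - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("scenario tables compute analytic n and validate their inputs", {
  t1 <- scenario_table(1)
  expect_identical(nrow(t1), 24L)
  expect_identical(t1$n, as.integer(ref_table1()$n))
  t2 <- scenario_table(2)
  t3 <- scenario_table(3)
  expect_identical(t2$n, as.integer(ref_exponential()$n_naive))
  expect_identical(t3$n, as.integer(ref_exponential()$n_corrected))
  expect_equal(t2$sd1, t2$m1 / log(2))
  expect_error(scenario_table(9), "table_id")
  expect_error(replicate_table(1, n_reps = 0), "n_reps")
})

test_that("replicated scenario rows attain published power within Monte-Carlo error", {
  reps <- 1500
  t3 <- replicate_table(3, n_reps = reps, seed = 5)
  ref <- ref_exponential()
  expect_identical(t3$n, as.integer(ref$n_corrected))
  for (i in seq_len(nrow(t3))) {
    expect_power_match(t3$power_log_t[i], ref$log_t_corr[i], reps)
    # Mann-Whitney beats the log-scale t-test on log-exponential data
    expect_gt(t3$power_mann_whitney[i], t3$power_log_t[i])
  }
})
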