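test_that("the deterministic TP estimate evaluates the baseline-offset formula", {
  expect_equal(tp_point(7.6, 7.6), 1)
  expect_equal(tp_point(7.6 + 4.3, 7.6), 2)
  expect_equal(tp_point(7.6 + 8.6, 7.6), 3)
  expect_equal(tp_point(10, 7, tdf_d15N = 2, lambda = 2), 3.5)
  expect_error(tp_point(10, 7, tdf_d15N = 0), "non-zero")
})

test_that("population one-baseline model recovers a known trophic position", {
  set.seed(31)
  b <- baseline_from(rnorm(20, 7.6, 0.8))
  sim <- simulate_consumers_known_tp(2.3, b, n_consumers = 8,
                                     sigma_consumer = 0.5, seed = 31)
  fit <- fit_tp(sim$consumers$d15N, b, "oneBaseline", cfg = light_cfg(seed = 31))
  expect_lt(abs(coef(fit)[["TP"]] - 2.3), 0.25)
  expect_true(fit$converged)
  expect_equal(fit$n_draws, 4000 / 2 * 3)
})

test_that("two-baselines full model recovers mixture proportion and TP", {
  set.seed(32)
  s1 <- baseline_from(rnorm(15, 6.2, 1.0), d13C = rnorm(15, -26, 1))
  s2 <- baseline_from(rnorm(15, 6.2, 1.0), d13C = rnorm(15, -13, 1))
  src <- list(source1 = s1, source2 = s2)
  sim <- simulate_consumers_known_tp(1.9, src, n_consumers = 10,
                                     sigma_consumer = 0.4, alpha_true = 0.5,
                                     seed = 32)
  fit <- fit_tp(sim$consumers, src, "twoBaselinesFull",
                cfg = light_cfg(seed = 32))
  expect_lt(abs(coef(fit)[["TP"]] - 1.9), 0.3)
  expect_lt(abs(coef(fit)[["alpha"]] - 0.5), 0.15)

  # consumers sitting exactly on source1 pull alpha to 1 and TP to 2
  tdf <- tdf_liver()
  at1 <- data.frame(d15N = rnorm(10, s1$d15N_mean + tdf$d15N_mean, 0.2),
                    d13C = rnorm(10, s1$d13C_mean + tdf$d13C_mean, 0.2))
  fit1 <- fit_tp(at1, src, "twoBaselinesFull", cfg = light_cfg(seed = 33))
  expect_gt(fit1$summary["alpha", "mean"], 0.8)
  expect_lt(abs(coef(fit1)[["TP"]] - 2), 0.35)
})

test_that("the individual model handles exactly one consumer and tracks the formula", {
  b <- baseline_from(rnorm(20, 2.0, 0.01))
  fit <- fit_tp(b$d15N_mean + 4.3, b, "individualOneBaseline",
                cfg = light_ind_cfg(seed = 34))
  expect_lt(abs(coef(fit)[["TP"]] - 2.0), 0.15)
  expect_error(fit_tp(c(7, 8), b, "individualOneBaseline"), "exactly one")
})

test_that("all Bayesian models collapse to the point formula in the zero-variance limit", {
  set.seed(35)
  tdf <- tdf_liver()
  eps <- 1e-3
  bvals <- rnorm(20, 7.6, eps)
  b <- baseline_from(bvals)
  tp_true <- 2.4
  # epsilon jitter keeps the residual-SD posterior proper at sigma -> 0
  consumers <- mean(bvals) + tdf$d15N_mean * (tp_true - 1) + rnorm(8, 0, eps)
  tight <- light_cfg(seed = 35, sigma_prior_scale = eps)
  tight_tdf <- tdf; tight_tdf$d15N_sd <- eps; tight_tdf$d13C_sd <- eps
  ref <- tp_point(mean(consumers), mean(bvals))

  f1 <- fit_tp(consumers, b, "oneBaseline", tdf = tight_tdf, cfg = tight)
  expect_lt(abs(coef(f1)[["TP"]] - ref), 0.02)

  # two sources with equal d15N means: TP identified by nitrogen alone
  s1 <- baseline_from(rnorm(10, 7.6, eps), d13C = rnorm(10, -26, eps))
  s2 <- baseline_from(rnorm(10, 7.6, eps), d13C = rnorm(10, -13, eps))
  cons2 <- data.frame(d15N = consumers,
                      d13C = 0.5 * s1$d13C_mean + 0.5 * s2$d13C_mean +
                        tight_tdf$d13C_mean * (tp_true - 1) + rnorm(8, 0, eps))
  f2 <- fit_tp(cons2, list(source1 = s1, source2 = s2), "twoBaselinesFull",
               tdf = tight_tdf, cfg = tight)
  expect_lt(abs(coef(f2)[["TP"]] - ref), 0.02)

  f3 <- fit_tp(consumers[1], b, "individualOneBaseline", tdf = tight_tdf,
               cfg = light_ind_cfg(seed = 35, sigma_prior_scale = eps))
  expect_lt(abs(coef(f3)[["TP"]] - ref), 0.02)
})

test_that("posterior mean TP is monotone in consumer d15N and draws respect the prior", {
  set.seed(36)
  b <- baseline_from(rnorm(20, 7.6, 0.8))
  base_consumers <- rnorm(8, 12, 0.5)
  means <- vapply(c(0, 2, 4), function(shift) {
    f <- fit_tp(base_consumers + shift, b, "oneBaseline",
                cfg = light_cfg(seed = 36))
    expect_true(all(f$draws$TP >= f$cfg$tp_prior[1] - 1e-12))
    expect_true(all(f$draws$TP <= f$cfg$tp_prior[2] + 1e-12))
    expect_true(all(f$draws$sigma_c >= 0))
    f$summary["TP", "mean"]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("identical configuration and seed give identical draws", {
  b <- baseline_from(rnorm(20, 7.6, 0.8))
  f1 <- fit_tp(c(11, 12, 12.5), b, "oneBaseline", cfg = light_cfg(seed = 77))
  f2 <- fit_tp(c(11, 12, 12.5), b, "oneBaseline", cfg = light_cfg(seed = 77))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_tp(c(11, 12, 12.5), b, "oneBaseline", cfg = light_cfg(seed = 78))
  expect_false(identical(f1$draws$TP, f3$draws$TP))
})

test_that("a high-plateau-like configuration yields herbivore-to-omnivore TP", {
  # plants ~1.8 permil at high elevation, consumers ~7.1: one trophic step up
  set.seed(38)
  b <- baseline_from(rnorm(25, 1.8, 1.5))
  consumers <- rnorm(5, 7.1, 0.1)
  fit <- fit_tp(consumers, b, "oneBaseline", cfg = light_cfg(seed = 38))
  expect_lt(abs(coef(fit)[["TP"]] - 2.2), 0.35)
})

test_that("empty consumer input and bad configs are rejected", {
  b <- baseline_from(rnorm(10, 7, 1))
  expect_error(fit_tp(numeric(0), b, "oneBaseline"), "no consumer")
  expect_error(tp_config(lambda = 0.5), "lambda")
  expect_error(tp_config(n_chains = 1), "n_chains")
})
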