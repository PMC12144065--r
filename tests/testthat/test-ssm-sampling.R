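# Sampling tests use reduced chain settings to stay fast; the full-size
# parameter-recovery and calibration runs live in test-acceptance.R.

test_that("sampling is reproducible under a fixed seed", {
  tr <- ssm_truth(mu = ncc_decay_path(15), delta = rep(-0.08, 15),
                  kappa = 40, seed = 2)
  d <- ssm_data(ncc_sim_to_table(simulate_ncc_series(tr)),
                "control", "experimental")
  p1 <- suppressWarnings(sample_posterior(d, chains = 2, warmup = 300,
                                          draws = 200, seed = 5))
  p2 <- suppressWarnings(sample_posterior(d, chains = 2, warmup = 300,
                                          draws = 200, seed = 5))
  expect_identical(p1$draws, p2$draws)
  expect_identical(summarize_posterior(p1), summarize_posterior(p2))
  p3 <- suppressWarnings(sample_posterior(d, chains = 2, warmup = 300,
                                          draws = 200, seed = 6))
  expect_false(identical(p1$draws, p3$draws))
  # every draw satisfies the support constraints
  T <- d$T
  mu <- p1$draws[, sprintf("mu[%d]", 1:T)]
  delta <- p1$draws[, sprintf("delta[%d]", 1:T)]
  expect_true(all(mu > 0 & mu < 1))
  expect_true(all(mu + delta > 0 & mu + delta < 1))
  expect_true(all(p1$draws[, c("sigma_mu", "sigma_delta", "kappa")] > 0))
})

test_that("summaries have the stated quantile semantics", {
  # degenerate posterior: identical draws -> zero-width intervals
  draws <- matrix(rep(c(0.7, -0.1), each = 50), 50, 2)
  colnames(draws) <- c("mu[1]", "delta[1]")
  sm <- summarize_posterior(draws)
  expect_equal(sm$mu_med, 0.7)
  expect_equal(sm$mu_lo, sm$mu_hi)
  expect_true(sm$excludes_zero)
  # large-sample quantile oracle: standard normal draws
  set.seed(40)
  dn <- cbind(rnorm(1e5), rnorm(1e5))
  colnames(dn) <- c("mu[1]", "delta[1]")
  smn <- summarize_posterior(dn)
  expect_equal(smn$delta_lo, -1.96, tolerance = 0.02)
  expect_equal(smn$delta_hi, 1.96, tolerance = 0.02)
  expect_false(smn$excludes_zero)
  expect_error(summarize_posterior(dn[0, , drop = FALSE]), "empty")
})

test_that("moderate-size recovery: posterior tracks the latent path", {
  tr <- ssm_truth(mu = ncc_decay_path(30), delta = rep(-0.1, 30), kappa = 50,
                  n_cells_control = 5, n_cells_experimental = 5, seed = 13)
  d <- ssm_data(ncc_sim_to_table(simulate_ncc_series(tr)),
                "control", "experimental")
  post <- suppressWarnings(sample_posterior(d, chains = 2, warmup = 600,
                                            draws = 600, seed = 3))
  sm <- summarize_posterior(post)
  expect_lt(sqrt(mean((sm$mu_med - tr$mu)^2)), 0.05)
  expect_gt(mean(sm$excludes_zero), 0.8)
  expect_lt(median(sm$delta_med), 0)
})

test_that("label swap negates the fitted difference curve", {
  tr <- ssm_truth(mu = ncc_decay_path(20), delta = rep(-0.1, 20), kappa = 50,
                  seed = 23)
  tab <- ncc_sim_to_table(simulate_ncc_series(tr))
  d <- ssm_data(tab, "control", "experimental")
  dsw <- ssm_data(tab, control = "experimental", experimental = "control")
  a <- summarize_posterior(suppressWarnings(
    sample_posterior(d, chains = 2, warmup = 500, draws = 500, seed = 7)))
  b <- summarize_posterior(suppressWarnings(
    sample_posterior(dsw, chains = 2, warmup = 500, draws = 500, seed = 7)))
  # antisymmetry within Monte-Carlo error
  expect_lt(max(abs(a$delta_med + b$delta_med)), 0.02)
})

test_that("an upward experimental shift gives a positive late difference", {
  tr <- ssm_truth(mu = ncc_decay_path(25, start = 0.9, floor = 0.65),
                  delta = c(rep(0.02, 10), rep(0.12, 15)), kappa = 60,
                  seed = 31)
  d <- ssm_data(ncc_sim_to_table(simulate_ncc_series(tr)),
                "control", "experimental")
  sm <- summarize_posterior(suppressWarnings(
    sample_posterior(d, chains = 2, warmup = 500, draws = 500, seed = 2)))
  expect_true(all(sm$delta_med[20:25] > 0))
})

test_that("diagnostics report Rhat and ESS per parameter", {
  tr <- ssm_truth(mu = ncc_decay_path(10), kappa = 40, seed = 5)
  d <- ssm_data(ncc_sim_to_table(simulate_ncc_series(tr)),
                "control", "experimental")
  post <- suppressWarnings(sample_posterior(d, chains = 2, warmup = 300,
                                            draws = 200, seed = 1))
  expect_equal(nrow(post$diagnostics), 2 * d$T + 3)
  expect_true(all(is.finite(post$diagnostics$rhat)))
  expect_true(all(post$diagnostics$ess > 0))
  expect_type(post$converged, "logical")
})
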