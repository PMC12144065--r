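test_that("beta proportion density matches an independent Beta oracle", {
  # mu = 0.5, kappa = 2 is Beta(1, 1): log density 0 everywhere in (0,1)
  for (th in c(0.01, 0.3, 0.5, 0.9, 0.99))
    expect_equal(beta_proportion_logpdf(th, 0.5, 2), 0)
  # closed-form case Beta(7, 3) via the log-gamma representation
  th <- 0.3; a <- 7; b <- 3
  oracle <- (a - 1) * log(th) + (b - 1) * log(1 - th) -
    (lgamma(a) + lgamma(b) - lgamma(a + b))
  expect_equal(beta_proportion_logpdf(0.3, 0.7, 10), oracle, tolerance = 1e-10)
  # 100 random triples against stats::dbeta
  set.seed(21)
  for (i in 1:100) {
    th <- runif(1, 0.01, 0.99); mu <- runif(1, 0.05, 0.95)
    ka <- exp(runif(1, log(0.5), log(500)))
    expect_equal(beta_proportion_logpdf(th, mu, ka),
                 dbeta(th, mu * ka, (1 - mu) * ka, log = TRUE),
                 tolerance = 1e-10)
  }
  # support handling
  expect_identical(beta_proportion_logpdf(c(0, 1, -2), 0.5, 5),
                   rep(-Inf, 3))
  expect_error(beta_proportion_logpdf(0.5, 1.2, 5), "0, 1")
  expect_error(beta_proportion_logpdf(0.5, 0.5, -1), "positive")
})

test_that("beta proportion density integrates to 1 over a (mu, kappa) grid", {
  for (mu in c(0.2, 0.5, 0.8)) for (ka in c(2, 20, 120)) {
    val <- integrate(function(x) exp(beta_proportion_logpdf(x, mu, ka)),
                     0, 1, rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("cauchy density has the quoted form and integrates to 1", {
  expect_equal(cauchy_logpdf(2, 2, 0.5), log(1 / (pi * 0.5)))
  # half maximum one scale away from the mode
  expect_equal(cauchy_logpdf(2.5, 2, 0.5), cauchy_logpdf(2, 2, 0.5) - log(2))
  expect_equal(cauchy_logpdf(1.3, 0.2, 0.7),
               dcauchy(1.3, 0.2, 0.7, log = TRUE), tolerance = 1e-12)
  val <- integrate(function(x) exp(cauchy_logpdf(x, 0, 1)),
                   -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(val, 1, tolerance = 1e-4)
  expect_error(cauchy_logpdf(0, 0, -1), "positive")
})

# a tiny T = 2 dataset with one observation per group and time
tiny_data <- function(yc = c(0.8, 0.7), ye = c(0.6, 0.5)) {
  tab <- data.frame(
    cell_id = "c1", condition = rep(c("ctl", "exp"), each = 2),
    time_s = c(10, 20, 10, 20), ncc = c(yc, ye))
  ssm_data(tab, control = "ctl", experimental = "exp")
}

test_that("log_posterior is the sum of its stated terms (T = 2 oracle)", {
  d <- tiny_data()
  pars <- list(mu = c(0.75, 0.72), delta = c(-0.12, -0.2),
               sigma_mu = 0.05, sigma_delta = 0.03, kappa = 25)
  # term-by-term, assembled independently of the implementation
  oracle <- dnorm(0.72, 0.75, 0.05, log = TRUE) +
    dcauchy(-0.2, -0.12, 0.03, log = TRUE) +
    dbeta(0.8, 0.75 * 25, 0.25 * 25, log = TRUE) +
    dbeta(0.7, 0.72 * 25, 0.28 * 25, log = TRUE) +
    dbeta(0.6, 0.63 * 25, 0.37 * 25, log = TRUE) +
    dbeta(0.5, 0.52 * 25, 0.48 * 25, log = TRUE)
  expect_equal(log_posterior(pars, d, jacobian = FALSE), oracle,
               tolerance = 1e-10)
  # support violations yield -Inf, not errors
  bad <- pars; bad$mu <- c(0.75, 1.2)
  expect_identical(log_posterior(bad, d), -Inf)
  bad2 <- pars; bad2$delta <- c(0.3, 0.4)   # mu + delta > 1
  expect_identical(log_posterior(bad2, d), -Inf)
})

test_that("log_posterior is symmetric under label swap when delta = 0", {
  d <- tiny_data(yc = c(0.8, 0.7), ye = c(0.8, 0.7))
  dsw <- tiny_data(yc = c(0.8, 0.7), ye = c(0.8, 0.7))  # identical data
  pars <- list(mu = c(0.75, 0.7), delta = c(0, 0),
               sigma_mu = 0.05, sigma_delta = 0.02, kappa = 30)
  expect_equal(log_posterior(pars, d), log_posterior(pars, dsw))
})

test_that("duplicating the replicates adds exactly the observation terms", {
  tab1 <- data.frame(cell_id = "c1", condition = rep(c("ctl", "exp"), each = 2),
                     time_s = c(10, 20, 10, 20), ncc = c(0.8, 0.7, 0.6, 0.5))
  tab2 <- rbind(tab1, transform(tab1, cell_id = "c2"))
  d1 <- ssm_data(tab1, "ctl", "exp")
  d2 <- ssm_data(tab2, "ctl", "exp")
  pars <- list(mu = c(0.7, 0.68), delta = c(-0.1, -0.12),
               sigma_mu = 0.04, sigma_delta = 0.05, kappa = 40)
  obs <- sum(beta_proportion_logpdf(c(0.8, 0.7), pars$mu, 40)) +
    sum(beta_proportion_logpdf(c(0.6, 0.5), pars$mu + pars$delta, 40))
  expect_equal(log_posterior(pars, d2) - log_posterior(pars, d1), obs,
               tolerance = 1e-10)
})

test_that("compiled evaluators agree with the R reference and each other", {
  set.seed(31)
  tr <- ssm_truth(mu = ncc_decay_path(10), delta = seq(-0.02, -0.1, length.out = 10),
                  kappa = 35, seed = 8)
  d <- ssm_data(ncc_sim_to_table(simulate_ncc_series(tr)), "control", "experimental")
  st <- vacmorph:::.ssm_stats(d)
  T <- d$T
  for (rep_ in 1:5) {
    q <- c(rnorm(T, 0, 0.6), rnorm(T, 0, 0.6), log(0.1), log(0.04), log(20))
    mu <- plogis(q[1:T]); eta <- plogis(q[T + 1:T])
    pars <- list(mu = mu, delta = eta - mu, sigma_mu = exp(q[2 * T + 1]),
                 sigma_delta = exp(q[2 * T + 2]), kappa = exp(q[2 * T + 3]))
    expect_equal(vacmorph:::.ssm_lp_cpp(q, st), log_posterior(pars, d),
                 tolerance = 1e-8)
  }
  # non-centered target equals the centered one after change of variables
  qn <- c(rnorm(T, 0, 0.5), rnorm(1, 0, 0.5), rnorm(T - 1, 0, 0.5),
          log(0.08), log(0.03), log(25))
  mu <- plogis(qn[1:T]); eta1 <- plogis(qn[T + 1]); sd_ <- exp(qn[2 * T + 2])
  u <- plogis(qn[T + 1 + seq_len(T - 1)]); e <- tan(pi * (u - 0.5))
  eta <- mu + (eta1 - mu[1]) + c(0, sd_ * cumsum(e))
  qc <- c(qlogis(mu), qlogis(eta), qn[2 * T + 1:3])
  jac <- sum(log(sd_) + log(pi * (1 + e^2)) + log(u * (1 - u)) -
               log(eta[-1] * (1 - eta[-1])))
  expect_equal(vacmorph:::.ssm_lp_ncp_cpp(qn, st),
               vacmorph:::.ssm_lp_cpp(qc, st) + jac, tolerance = 1e-8)
  # analytic gradient of the sampling target vs numeric differentiation
  g <- vacmorph:::.ssm_grad_ncp_cpp(qn, st)
  h <- 1e-6
  gn <- vapply(seq_along(qn), function(i) {
    qp <- qn; qm <- qn; qp[i] <- qn[i] + h; qm[i] <- qn[i] - h
    (vacmorph:::.ssm_lp_ncp_cpp(qp, st) - vacmorph:::.ssm_lp_ncp_cpp(qm, st)) / (2 * h)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-4)
})

test_that("ssm_data excludes t = 0, drops NA, and clips out-of-support", {
  tab <- data.frame(cell_id = "c1",
                    condition = rep(c("ctl", "exp"), each = 3),
                    time_s = rep(c(0, 10, 20), 2),
                    ncc = c(1, 0.8, NA, 1, 0.7, 1.4))
  expect_warning(d <- ssm_data(tab, "ctl", "exp"), "clipped")
  expect_equal(d$T, 2)
  expect_equal(d$times_s, c(10, 20))
  expect_equal(lengths(d$y_control), c(1L, 0L))      # NA dropped
  expect_true(all(unlist(d$y_experimental) < 1))     # 1.4 clipped
  expect_error(ssm_data(tab, "nope", "exp"), "not present")
})
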