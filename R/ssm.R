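# Bayesian state-space comparison of NCC time series.
#
# Control-group mean mu[t] follows a Normal random walk (scale sigma_mu),
# the group difference delta[t] a Cauchy random walk (scale sigma_delta,
# heavy tails allow abrupt divergence between conditions), and observed
# NCC values are Beta-proportion distributed around mu[t] (control) or
# mu[t] + delta[t] (experimental) with shared concentration kappa.

#' Beta-proportion log density
#'
#' Beta distribution parameterized by its mean `mu` and concentration
#' `kappa`, i.e. `Beta(mu * kappa, (1 - mu) * kappa)`:
#' \deqn{f(\theta \mid \mu, \kappa) = \frac{\theta^{\mu\kappa - 1}
#'   (1-\theta)^{(1-\mu)\kappa - 1}}{B(\mu\kappa, (1-\mu)\kappa)}.}
#'
#' @param theta value(s) in (0, 1); values outside get `-Inf`.
#' @param mu mean in (0, 1).
#' @param kappa concentration (> 0).
#' @return log density (vectorized over `theta`).
#' @export
beta_proportion_logpdf <- function(theta, mu, kappa) {
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must lie in (0, 1)")
  if (any(kappa <= 0)) stop("`kappa` must be positive")
  out <- rep(-Inf, length(theta))
  ok <- theta > 0 & theta < 1
  a <- mu * kappa; b <- (1 - mu) * kappa
  out[ok] <- (a - 1) * log(theta[ok]) + (b - 1) * log1p(-theta[ok]) -
    lbeta(a, b)
  out
}

#' Cauchy log density
#'
#' \deqn{f(\theta \mid \mu, \sigma) = \frac{1}{\pi\sigma}
#'   \frac{1}{1 + ((\theta - \mu)/\sigma)^2}.}
#'
#' @param theta value(s).
#' @param mu location.
#' @param sigma scale (> 0).
#' @return log density.
#' @export
cauchy_logpdf <- function(theta, mu, sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  -log(pi * sigma) - log1p(((theta - mu) / sigma)^2)
}

#' Assemble NCC observations for the state-space model
#'
#' Takes a long NCC table (as produced by [ncc_series()] or
#' [ncc_sim_to_table()]), keeps the `control` and `experimental`
#' conditions, drops the t = 0 reference point (its NCC of exactly 1 lies
#' outside the Beta-proportion support) and any missing values, and clips
#' residual values outside (0, 1) to `[clip, 1 - clip]` with a warning.
#'
#' @param ncc_table data frame with `cell_id`, `condition`, `time_s`, `ncc`.
#' @param control,experimental condition labels to compare.
#' @param clip clipping margin for out-of-support values.
#' @return object of class `ssm_data`: list with `T`, `times_s`, and
#'   per-time-point observation lists `y_control`, `y_experimental`.
#' @export
ssm_data <- function(ncc_table, control, experimental, clip = 1e-6) {
  need <- c("cell_id", "condition", "time_s", "ncc")
  if (!all(need %in% names(ncc_table)))
    stop("`ncc_table` needs columns ", paste(need, collapse = ", "))
  if (!control %in% ncc_table$condition)
    stop("control condition '", control, "' not present")
  if (!experimental %in% ncc_table$condition)
    stop("experimental condition '", experimental, "' not present")
  d <- ncc_table[ncc_table$condition %in% c(control, experimental), ]
  d <- d[d$time_s > 0 & is.finite(d$ncc), ]
  n_out <- sum(d$ncc <= 0 | d$ncc >= 1)
  if (n_out > 0) {
    warning(n_out, " NCC value(s) outside (0, 1) clipped to the support")
    d$ncc <- pmin(pmax(d$ncc, clip), 1 - clip)
  }
  times <- sort(unique(d$time_s))
  if (length(times) < 2) stop("need at least 2 modeled time points")
  split_by_t <- function(cond) {
    lapply(times, function(tt) d$ncc[d$condition == cond & d$time_s == tt])
  }
  structure(list(T = length(times), times_s = times,
                 control = control, experimental = experimental,
                 y_control = split_by_t(control),
                 y_experimental = split_by_t(experimental)),
            class = "ssm_data")
}

# sufficient statistics consumed by the compiled log posterior
.ssm_stats <- function(data) {
  s <- function(ys, f) vapply(ys, function(y) if (length(y)) sum(f(y)) else 0,
                              numeric(1))
  list(T = data$T,
       Sc1 = s(data$y_control, log), Sc2 = s(data$y_control, log1p_neg),
       nc = vapply(data$y_control, length, integer(1)) * 1.0,
       Se1 = s(data$y_experimental, log), Se2 = s(data$y_experimental, log1p_neg),
       ne = vapply(data$y_experimental, length, integer(1)) * 1.0)
}

log1p_neg <- function(y) log1p(-y)

#' State-space model log posterior (reference implementation)
#'
#' Pure-R evaluation of the joint log posterior: Normal random-walk
#' transitions for `mu`, Cauchy transitions for `delta`, Beta-proportion
#' observation terms for both groups, and (optionally) the log-Jacobian
#' terms corresponding to flat priors on the unconstrained scale (logit
#' for each `mu[t]` and `mu[t] + delta[t]`, log for the three scale
#' parameters). With `jacobian = TRUE` this equals the target density the
#' compiled HMC sampler explores; the compiled evaluator is independently
#' tested against this function.
#'
#' @param params list with `mu`, `delta` (length `T`), `sigma_mu`,
#'   `sigma_delta`, `kappa`.
#' @param data an [ssm_data()].
#' @param jacobian include the unconstrained-scale Jacobian terms.
#' @return log posterior value; `-Inf` outside the support.
#' @export
log_posterior <- function(params, data, jacobian = TRUE) {
  stopifnot(inherits(data, "ssm_data"))
  mu <- params$mu; delta <- params$delta
  eta <- mu + delta
  T <- data$T
  if (length(mu) != T || length(delta) != T) stop("parameter length != T")
  if (any(!is.finite(c(mu, delta, params$sigma_mu, params$sigma_delta,
                       params$kappa)))) return(-Inf)
  if (any(mu <= 0 | mu >= 1) || any(eta <= 0 | eta >= 1) ||
      params$sigma_mu <= 0 || params$sigma_delta <= 0 || params$kappa <= 0)
    return(-Inf)
  lp <- 0
  for (t in 2:T) {
    lp <- lp + stats::dnorm(mu[t], mu[t - 1], params$sigma_mu, log = TRUE)
    lp <- lp + cauchy_logpdf(delta[t], delta[t - 1], params$sigma_delta)
  }
  for (t in seq_len(T)) {
    yc <- data$y_control[[t]]; ye <- data$y_experimental[[t]]
    if (length(yc))
      lp <- lp + sum(beta_proportion_logpdf(yc, mu[t], params$kappa))
    if (length(ye))
      lp <- lp + sum(beta_proportion_logpdf(ye, eta[t], params$kappa))
  }
  if (jacobian) {
    lp <- lp + sum(log(mu) + log1p(-mu)) + sum(log(eta) + log1p(-eta)) +
      log(params$sigma_mu) + log(params$sigma_delta) + log(params$kappa)
  }
  lp
}

# moment-matched initial values on the (non-centered) sampling scale,
# jittered; innovations start at zero (delta initially constant)
.ssm_init <- function(stats_, jitter_sd = 0.05, shrink = 1) {
  T <- stats_$T
  mu0 <- ifelse(stats_$nc > 0, exp(stats_$Sc1 / pmax(stats_$nc, 1)), 0.5)
  eta0 <- ifelse(stats_$ne > 0, exp(stats_$Se1 / pmax(stats_$ne, 1)), 0.5)
  mu0 <- 0.5 + (mu0 - 0.5) * shrink
  eta0 <- 0.5 + (eta0 - 0.5) * shrink
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  c(stats::qlogis(clamp(mu0)) + stats::rnorm(T, 0, jitter_sd),
    stats::qlogis(clamp(eta0[1])) + stats::rnorm(1, 0, jitter_sd),
    stats::rnorm(T - 1, 0, jitter_sd),
    log(0.05) + stats::rnorm(1, 0, jitter_sd),
    log(0.02) + stats::rnorm(1, 0, jitter_sd),
    log(30) + stats::rnorm(1, 0, jitter_sd))
}

# map non-centered draws (rows) to the constrained parameter scale
.ssm_constrain <- function(q, T) {
  D <- 2 * T + 3
  mu <- stats::plogis(q[, seq_len(T), drop = FALSE])
  eta1 <- stats::plogis(q[, T + 1])
  sd_ <- exp(q[, D - 1])
  e <- tan(pi * (stats::plogis(q[, T + 1 + seq_len(T - 1), drop = FALSE]) - 0.5))
  csum <- t(apply(e, 1, cumsum))
  delta <- cbind(eta1 - mu[, 1],
                 (eta1 - mu[, 1]) + sd_ * csum)
  out <- cbind(mu, delta, exp(q[, D - 2]), sd_, exp(q[, D]))
  colnames(out) <- c(sprintf("mu[%d]", seq_len(T)),
                     sprintf("delta[%d]", seq_len(T)),
                     "sigma_mu", "sigma_delta", "kappa")
  out
}

#' Sample the state-space model posterior
#'
#' Fits the model by Hamiltonian Monte Carlo (compiled leapfrog integrator
#' with dual-averaging step-size adaptation and a diagonal metric learned
#' during warmup) over the exact joint log posterior. Chains are seeded
#' deterministically from `seed`, so repeated calls reproduce identical
#' draws. Convergence is summarized by split-Rhat and effective sample
#' size; if any monitored parameter has Rhat > 1.01 or ESS < 100, the
#' returned object carries `converged = FALSE` and a warning is emitted.
#'
#' @param data an [ssm_data()].
#' @param chains number of chains (default 4).
#' @param warmup,draws warmup and retained iterations per chain.
#' @param seed integer seed.
#' @param max_steps maximum leapfrog steps per iteration.
#' @param target_accept dual-averaging acceptance target.
#' @return object of class `ssm_posterior`: list with `draws` (matrix,
#'   `chains * draws` rows; columns `mu[1..T]`, `delta[1..T]`, `sigma_mu`,
#'   `sigma_delta`, `kappa` on the constrained scale), `chain` index,
#'   `data`, `diagnostics` (per-parameter Rhat and ESS), `converged`, and
#'   sampler info.
#' @export
sample_posterior <- function(data, chains = 4L, warmup = 1000L, draws = 1000L,
                             seed = 1L, max_steps = 32L, target_accept = 0.8) {
  stopifnot(inherits(data, "ssm_data"))
  if (chains < 1 || warmup < 50 || draws < 10) stop("sampler settings too small")
  stats_ <- .ssm_stats(data)
  T <- stats_$T
  D <- 2 * T + 3
  all_draws <- matrix(0, chains * draws, D)
  chain_id <- rep(seq_len(chains), each = draws)
  info <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    # retry initialization with shrinking jitter and paths pulled towards
    # 0.5 until the log posterior is finite
    q0 <- NULL
    for (try_ in 0:29) {
      cand <- .ssm_init(stats_, jitter_sd = 0.05 * 0.7^try_,
                        shrink = 0.97^try_)
      if (is.finite(.ssm_lp_ncp_cpp(cand, stats_))) { q0 <- cand; break }
    }
    if (is.null(q0))
      stop("non-finite log posterior at initialization after retries")
    res <- .ssm_hmc_chain_cpp(stats_, q0, as.integer(warmup), as.integer(draws),
                              target_accept, as.integer(max_steps), 0.05)
    all_draws[chain_id == ch, ] <- res$draws
    info[[ch]] <- res[c("accept_rate", "step_size", "n_divergent")]
  }
  # transform to the constrained scale
  out <- .ssm_constrain(all_draws, T)
  diag_ <- .ssm_diagnostics(out, chain_id, chains, draws)
  converged <- all(diag_$rhat < 1.01, na.rm = TRUE) &&
    all(diag_$ess >= 100, na.rm = TRUE)
  if (!converged)
    warning("sampler convergence flags: max Rhat = ",
            round(max(diag_$rhat, na.rm = TRUE), 3), ", min ESS = ",
            round(min(diag_$ess, na.rm = TRUE), 1))
  structure(list(draws = out, chain = chain_id, data = data,
                 diagnostics = diag_, converged = converged,
                 sampler_info = info,
                 settings = list(chains = chains, warmup = warmup,
                                 draws = draws, seed = seed)),
            class = "ssm_posterior")
}

# split-Rhat (Gelman et al.) and coda effective sample size per parameter
.ssm_diagnostics <- function(draws, chain_id, chains, n_draw) {
  half <- floor(n_draw / 2)
  rhat <- apply(draws, 2, function(v) {
    segs <- lapply(seq_len(chains), function(ch) {
      vc <- v[chain_id == ch]
      list(vc[seq_len(half)], vc[(n_draw - half + 1):n_draw])
    })
    segs <- unlist(segs, recursive = FALSE)
    m <- length(segs); n <- half
    means <- vapply(segs, mean, numeric(1))
    vars <- vapply(segs, stats::var, numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  ess <- apply(draws, 2, function(v) {
    sum(vapply(seq_len(chains), function(ch) {
      as.numeric(coda::effectiveSize(v[chain_id == ch]))
    }, numeric(1)))
  })
  data.frame(parameter = colnames(draws), rhat = rhat, ess = ess,
             row.names = NULL)
}

#' @export
print.ssm_posterior <- function(x, ...) {
  T <- x$data$T
  cat(sprintf(paste0("ssm_posterior: T = %d, %d chains x %d draws, ",
                     "converged = %s\n  max Rhat = %.3f, min ESS = %.0f\n"),
              T, x$settings$chains, x$settings$draws, x$converged,
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summaries per time point
#'
#' Median and central 95% credible interval of `mu[t]` and `delta[t]` for
#' every modeled time point, plus a flag marking intervals for the group
#' difference that exclude 0 (the visual criterion for a difference
#' between conditions).
#'
#' @param posterior an [sample_posterior()] result, or a plain draws
#'   matrix with the same column naming.
#' @param probs quantiles for the band (default `c(0.025, 0.5, 0.975)`).
#' @return data frame with `time_s`, `mu_med`, `mu_lo`, `mu_hi`,
#'   `delta_med`, `delta_lo`, `delta_hi`, `excludes_zero`.
#' @export
summarize_posterior <- function(posterior, probs = c(0.025, 0.5, 0.975)) {
  draws <- if (inherits(posterior, "ssm_posterior")) posterior$draws else posterior
  if (!nrow(draws)) stop("empty posterior draws")
  T <- sum(grepl("^mu\\[", colnames(draws)))
  times <- if (inherits(posterior, "ssm_posterior"))
    posterior$data$times_s else seq_len(T)
  q <- function(name) {
    m <- draws[, sprintf("%s[%d]", name, seq_len(T)), drop = FALSE]
    t(apply(m, 2, stats::quantile, probs = probs, names = FALSE))
  }
  qm <- q("mu"); qd <- q("delta")
  data.frame(time_s = times,
             mu_med = qm[, 2], mu_lo = qm[, 1], mu_hi = qm[, 3],
             delta_med = qd[, 2], delta_lo = qd[, 1], delta_hi = qd[, 3],
             excludes_zero = qd[, 1] > 0 | qd[, 3] < 0,
             row.names = NULL)
}
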