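#' Ground truth for the NCC state-space model
#'
#' Bundles a known latent path for direct simulation from the observation
#' model: the control-group mean `mu[t]`, the group difference `delta[t]`
#' (experimental mean is `mu[t] + delta[t]`), the shared Beta-proportion
#' concentration `kappa`, and the number of cells per group.
#'
#' @param mu numeric vector, each value in (0, 1).
#' @param delta numeric vector, same length, with `mu + delta` in (0, 1).
#' @param kappa positive concentration of the Beta-proportion observation
#'   distribution `Beta(mu * kappa, (1 - mu) * kappa)`.
#' @param n_cells_control,n_cells_experimental cells per group.
#' @param seed RNG seed.
#' @return an object of class `ssm_truth`.
#' @export
ssm_truth <- function(mu, delta = rep(0, length(mu)), kappa = 50,
                      n_cells_control = 5L, n_cells_experimental = 5L,
                      seed = 1L) {
  if (length(delta) != length(mu)) stop("`mu` and `delta` lengths differ")
  if (any(mu <= 0 | mu >= 1)) stop("all mu[t] must lie in (0, 1)")
  if (any(mu + delta <= 0 | mu + delta >= 1))
    stop("all mu[t] + delta[t] must lie in (0, 1)")
  if (kappa <= 0) stop("`kappa` must be positive")
  structure(list(mu = mu, delta = delta, kappa = kappa,
                 n_cells_control = as.integer(n_cells_control),
                 n_cells_experimental = as.integer(n_cells_experimental),
                 seed = as.integer(seed)),
            class = "ssm_truth")
}

#' A smooth declining latent NCC path
#'
#' Convenience latent path resembling measured NCC series: starts near 1
#' (morphology identical to the reference frame) and decays exponentially
#' towards a floor as the morphology drifts.
#'
#' @param T number of time points.
#' @param start,floor initial and asymptotic mean NCC.
#' @param tau decay constant in time points.
#' @return numeric vector of length `T` in (0, 1).
#' @export
ncc_decay_path <- function(T = 60L, start = 0.95, floor = 0.6, tau = 20) {
  floor + (start - floor) * exp(-(seq_len(T) - 1) / tau)
}

#' Draw NCC series directly from the observation model
#'
#' For each time point `t`, control cells are drawn i.i.d. from
#' `BetaProportion(mu[t], kappa)` and experimental cells from
#' `BetaProportion(mu[t] + delta[t], kappa)`. This is the generative
#' counterpart of the state-space model fitted by [sample_posterior()],
#' enabling exact parameter-recovery checks.
#'
#' @param truth an [ssm_truth()].
#' @return list with `control` and `experimental` matrices (`T x n_cells`),
#'   plus attribute `truth`.
#' @export
simulate_ncc_series <- function(truth) {
  stopifnot(inherits(truth, "ssm_truth"))
  set.seed(truth$seed)
  T <- length(truth$mu)
  k <- truth$kappa
  draw <- function(m, n) {
    out <- matrix(0, T, n)
    for (t in seq_len(T)) out[t, ] <- stats::rbeta(n, m[t] * k, (1 - m[t]) * k)
    out
  }
  ctl <- draw(truth$mu, truth$n_cells_control)
  exp_ <- draw(truth$mu + truth$delta, truth$n_cells_experimental)
  # rbeta can return exact 0/1 only by floating underflow; keep the open
  # interval promised by the observation model
  eps <- 1e-12
  ctl <- pmin(pmax(ctl, eps), 1 - eps)
  exp_ <- pmin(pmax(exp_, eps), 1 - eps)
  structure(list(control = ctl, experimental = exp_), truth = truth)
}

#' Convert simulated NCC matrices to the long NCC table
#'
#' @param sim output of [simulate_ncc_series()].
#' @param frame_interval_s cadence used to assign `time_s` (the first
#'   modeled time point is one interval after the reference frame).
#' @param control,experimental condition labels.
#' @return data frame with `cell_id`, `condition`, `time_s`, `ncc`.
#' @export
ncc_sim_to_table <- function(sim, frame_interval_s = 10,
                             control = "control", experimental = "experimental") {
  stack_one <- function(m, cond, prefix) {
    do.call(rbind, lapply(seq_len(ncol(m)), function(i) {
      data.frame(cell_id = sprintf("%s%d", prefix, i), condition = cond,
                 time_s = seq_len(nrow(m)) * frame_interval_s, ncc = m[, i],
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(stack_one(sim$control, control, "c"),
        stack_one(sim$experimental, experimental, "e"))
}
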