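#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bayesian state-space model for NCC time series.
//
// Latent states: mu[1..T] (control mean, Normal random walk, scale sigma_mu)
// and delta[1..T] (group difference, Cauchy random walk, scale sigma_delta).
// Observations: NCC_control[t] ~ BetaProportion(mu[t], kappa),
// NCC_experimental[t] ~ BetaProportion(mu[t] + delta[t], kappa), kappa shared.
//
// Sampling is done on an unconstrained vector q of length 2T + 3:
//   q[0..T)     z_mu   : mu[t]  = inv_logit(z_mu[t])
//   q[T..2T)    z_eta  : eta[t] = inv_logit(z_eta[t]),  delta = eta - mu
//   q[2T]       log sigma_mu
//   q[2T+1]     log sigma_delta
//   q[2T+2]     log kappa
// Flat priors on this unconstrained scale (log-Jacobian terms included),
// mirroring the default behaviour of constrained flat priors in HMC software.
//
// Beta-proportion observation terms enter through per-timepoint sufficient
// statistics: S1[t] = sum log y_i, S2[t] = sum log(1 - y_i), n[t] = count.

static inline double inv_logit(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// log(sigmoid(x)), stable for large |x|
static inline double log_sigmoid(double x) {
  if (x >= 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

struct SSMStats {
  int T;
  std::vector<double> Sc1, Sc2, nc, Se1, Se2, ne;
};

static SSMStats as_stats(const List& stats) {
  SSMStats s;
  s.T = as<int>(stats["T"]);
  s.Sc1 = as<std::vector<double> >(stats["Sc1"]);
  s.Sc2 = as<std::vector<double> >(stats["Sc2"]);
  s.nc  = as<std::vector<double> >(stats["nc"]);
  s.Se1 = as<std::vector<double> >(stats["Se1"]);
  s.Se2 = as<std::vector<double> >(stats["Se2"]);
  s.ne  = as<std::vector<double> >(stats["ne"]);
  return s;
}

// Log posterior density in q-space and its gradient (if grad != NULL).
static double lp_grad(const double* q, const SSMStats& S, double* grad) {
  const int T = S.T;
  const double lsm = q[2 * T], lsd = q[2 * T + 1], lk = q[2 * T + 2];
  const double sm = std::exp(lsm), sd = std::exp(lsd), kappa = std::exp(lk);

  std::vector<double> mu(T), eta(T), gmu(T, 0.0), geta(T, 0.0);
  for (int t = 0; t < T; ++t) {
    mu[t]  = inv_logit(q[t]);
    eta[t] = inv_logit(q[T + t]);
  }

  double lp = 0.0, gsm = 0.0, gsd = 0.0, gk = 0.0;

  // observation terms (Beta proportion via sufficient statistics)
  for (int t = 0; t < T; ++t) {
    if (S.nc[t] > 0) {
      const double a = mu[t] * kappa, b = (1.0 - mu[t]) * kappa;
      lp += (a - 1.0) * S.Sc1[t] + (b - 1.0) * S.Sc2[t]
            - S.nc[t] * (R::lgammafn(a) + R::lgammafn(b) - R::lgammafn(kappa));
      if (grad) {
        const double da = R::digamma(a), db = R::digamma(b);
        gmu[t] += kappa * (S.Sc1[t] - S.Sc2[t]) - S.nc[t] * kappa * (da - db);
        gk += mu[t] * S.Sc1[t] + (1.0 - mu[t]) * S.Sc2[t]
              - S.nc[t] * (mu[t] * da + (1.0 - mu[t]) * db - R::digamma(kappa));
      }
    }
    if (S.ne[t] > 0) {
      const double a = eta[t] * kappa, b = (1.0 - eta[t]) * kappa;
      lp += (a - 1.0) * S.Se1[t] + (b - 1.0) * S.Se2[t]
            - S.ne[t] * (R::lgammafn(a) + R::lgammafn(b) - R::lgammafn(kappa));
      if (grad) {
        const double da = R::digamma(a), db = R::digamma(b);
        geta[t] += kappa * (S.Se1[t] - S.Se2[t]) - S.ne[t] * kappa * (da - db);
        gk += eta[t] * S.Se1[t] + (1.0 - eta[t]) * S.Se2[t]
              - S.ne[t] * (eta[t] * da + (1.0 - eta[t]) * db - R::digamma(kappa));
      }
    }
  }

  // transition terms, t = 2..T
  const double HALF_LOG_2PI = 0.9189385332046727;
  for (int t = 1; t < T; ++t) {
    // Normal random walk on mu
    const double d = mu[t] - mu[t - 1];
    lp += -lsm - HALF_LOG_2PI - d * d / (2.0 * sm * sm);
    if (grad) {
      gmu[t]     += -d / (sm * sm);
      gmu[t - 1] +=  d / (sm * sm);
      gsm += -1.0 / sm + d * d / (sm * sm * sm);
    }
    // Cauchy random walk on delta = eta - mu
    const double e = (eta[t] - mu[t]) - (eta[t - 1] - mu[t - 1]);
    const double r = e / sd, opr2 = 1.0 + r * r;
    lp += -std::log(M_PI * sd) - std::log(opr2);
    if (grad) {
      const double w = 2.0 * r / (sd * opr2);
      geta[t]     += -w; gmu[t]     +=  w;
      geta[t - 1] +=  w; gmu[t - 1] += -w;
      gsd += -1.0 / sd + 2.0 * r * r / (sd * opr2);
    }
  }

  // log-Jacobian of the transforms (flat prior on the unconstrained scale)
  for (int t = 0; t < T; ++t) {
    lp += log_sigmoid(q[t]) + log_sigmoid(-q[t]);
    lp += log_sigmoid(q[T + t]) + log_sigmoid(-q[T + t]);
  }
  lp += lsm + lsd + lk;

  if (grad) {
    for (int t = 0; t < T; ++t) {
      grad[t]     = gmu[t]  * mu[t]  * (1.0 - mu[t])  + (1.0 - 2.0 * mu[t]);
      grad[T + t] = geta[t] * eta[t] * (1.0 - eta[t]) + (1.0 - 2.0 * eta[t]);
    }
    grad[2 * T]     = gsm * sm + 1.0;
    grad[2 * T + 1] = gsd * sd + 1.0;
    grad[2 * T + 2] = gk * kappa + 1.0;
  }
  return lp;
}

// [[Rcpp::export(name = ".ssm_lp_cpp")]]
double ssm_lp_cpp(NumericVector q, List stats) {
  SSMStats S = as_stats(stats);
  if ((int)q.size() != 2 * S.T + 3) stop("q has wrong length");
  return lp_grad(q.begin(), S, NULL);
}

// ---------------------------------------------------------------------------
// Non-centered coordinates for sampling. The Cauchy random walk on delta
// creates a funnel (sigma_delta -> 0 ties all deltas together) that defeats
// diagonal-metric HMC in the centered coordinates above. We therefore sample
// in coordinates where the innovations are a-priori independent of their
// scale, targeting the SAME posterior over (mu, delta, scales):
//   q[0..T)    z_mu    : mu[t] = inv_logit(z_mu[t])           (centered)
//   q[T]       z_eta1  : eta[1] = inv_logit(z_eta1), delta[1] = eta[1]-mu[1]
//   q[T+1..2T) z_e[t]  : u = inv_logit(z_e), e[t] = tan(pi*(u - 1/2)),
//                        delta[t] = delta[t-1] + sigma_delta * e[t], t=2..T
//   q[2T..2T+3) log sigma_mu, log sigma_delta, log kappa
// e[t] is standard-Cauchy when u is uniform, so the Cauchy transition
// density is absorbed into the flat prior on u (plus its logit Jacobian);
// the change of variables cancels the eta[t]-interval Jacobians for t >= 2,
// making this target exactly equivalent to the centered one.
static double lp_grad_ncp(const double* q, const SSMStats& S, double* grad) {
  const int T = S.T;
  const double lsm = q[2 * T], lsd = q[2 * T + 1], lk = q[2 * T + 2];
  const double sm = std::exp(lsm), sd = std::exp(lsd), kappa = std::exp(lk);
  if (!R_finite(sm) || !R_finite(sd) || !R_finite(kappa)) return R_NegInf;

  std::vector<double> mu(T), eta(T), u(T, 0.0), e(T, 0.0), c(T, 0.0);
  for (int t = 0; t < T; ++t) mu[t] = inv_logit(q[t]);
  eta[0] = inv_logit(q[T]);
  double csum = 0.0;
  for (int t = 1; t < T; ++t) {
    u[t] = inv_logit(q[T + t]);
    e[t] = std::tan(M_PI * (u[t] - 0.5));
    csum += e[t];
    c[t] = csum;
    eta[t] = mu[t] + (eta[0] - mu[0]) + sd * csum;
    if (!(eta[t] > 0.0 && eta[t] < 1.0)) return R_NegInf;
  }

  std::vector<double> gmu(T, 0.0), geta(T, 0.0);
  double lp = 0.0, gsm = 0.0, gk = 0.0;

  for (int t = 0; t < T; ++t) {
    if (S.nc[t] > 0) {
      const double a = mu[t] * kappa, b = (1.0 - mu[t]) * kappa;
      lp += (a - 1.0) * S.Sc1[t] + (b - 1.0) * S.Sc2[t]
            - S.nc[t] * (R::lgammafn(a) + R::lgammafn(b) - R::lgammafn(kappa));
      if (grad) {
        const double da = R::digamma(a), db = R::digamma(b);
        gmu[t] += kappa * (S.Sc1[t] - S.Sc2[t]) - S.nc[t] * kappa * (da - db);
        gk += mu[t] * S.Sc1[t] + (1.0 - mu[t]) * S.Sc2[t]
              - S.nc[t] * (mu[t] * da + (1.0 - mu[t]) * db - R::digamma(kappa));
      }
    }
    if (S.ne[t] > 0) {
      const double a = eta[t] * kappa, b = (1.0 - eta[t]) * kappa;
      lp += (a - 1.0) * S.Se1[t] + (b - 1.0) * S.Se2[t]
            - S.ne[t] * (R::lgammafn(a) + R::lgammafn(b) - R::lgammafn(kappa));
      if (grad) {
        const double da = R::digamma(a), db = R::digamma(b);
        geta[t] += kappa * (S.Se1[t] - S.Se2[t]) - S.ne[t] * kappa * (da - db);
        gk += eta[t] * S.Se1[t] + (1.0 - eta[t]) * S.Se2[t]
              - S.ne[t] * (eta[t] * da + (1.0 - eta[t]) * db - R::digamma(kappa));
      }
    }
  }

  const double HALF_LOG_2PI = 0.9189385332046727;
  for (int t = 1; t < T; ++t) {
    const double d = mu[t] - mu[t - 1];
    lp += -lsm - HALF_LOG_2PI - d * d / (2.0 * sm * sm);
    if (grad) {
      gmu[t]     += -d / (sm * sm);
      gmu[t - 1] +=  d / (sm * sm);
      gsm += -1.0 / sm + d * d / (sm * sm * sm);
    }
  }

  // Jacobians / flat priors on the sampling scale
  for (int t = 0; t < T; ++t)
    lp += log_sigmoid(q[t]) + log_sigmoid(-q[t]);      // z_mu
  lp += log_sigmoid(q[T]) + log_sigmoid(-q[T]);        // z_eta1
  for (int t = 1; t < T; ++t)
    lp += log_sigmoid(q[T + t]) + log_sigmoid(-q[T + t]); // z_e (uniform u)
  lp += lsm + lsd + lk;
  if (!R_finite(lp)) return R_NegInf;

  if (grad) {
    // suffix sums of d lp / d eta over t = 2..T
    std::vector<double> suf(T + 1, 0.0);
    for (int t = T - 1; t >= 1; --t) suf[t] = suf[t + 1] + geta[t];
    double gsd = 0.0;
    for (int t = 1; t < T; ++t) gsd += geta[t] * c[t] * sd; // d lp/d lsd part

    for (int t = 0; t < T; ++t) {
      double g = gmu[t];
      if (t == 0) g -= suf[1];     // mu[1] enters delta[1] with sign -1
      else g += geta[t];           // eta[t] = mu[t] + ...
      grad[t] = g * mu[t] * (1.0 - mu[t]) + (1.0 - 2.0 * mu[t]);
    }
    const double geta1 = geta[0] + suf[1];
    grad[T] = geta1 * eta[0] * (1.0 - eta[0]) + (1.0 - 2.0 * eta[0]);
    for (int t = 1; t < T; ++t) {
      const double de_du = M_PI * (1.0 + e[t] * e[t]);
      const double du_dz = u[t] * (1.0 - u[t]);
      grad[T + t] = suf[t] * sd * de_du * du_dz + (1.0 - 2.0 * u[t]);
    }
    grad[2 * T]     = gsm * sm + 1.0;
    grad[2 * T + 1] = gsd + 1.0;
    grad[2 * T + 2] = gk * kappa + 1.0;
  }
  return lp;
}

// [[Rcpp::export(name = ".ssm_lp_ncp_cpp")]]
double ssm_lp_ncp_cpp(NumericVector q, List stats) {
  SSMStats S = as_stats(stats);
  if ((int)q.size() != 2 * S.T + 3) stop("q has wrong length");
  return lp_grad_ncp(q.begin(), S, NULL);
}

// [[Rcpp::export(name = ".ssm_grad_ncp_cpp")]]
NumericVector ssm_grad_ncp_cpp(NumericVector q, List stats) {
  SSMStats S = as_stats(stats);
  if ((int)q.size() != 2 * S.T + 3) stop("q has wrong length");
  NumericVector g(q.size());
  lp_grad_ncp(q.begin(), S, g.begin());
  return g;
}

// One HMC chain with dual-averaging step-size adaptation and a diagonal
// metric estimated during warmup. Momentum p ~ N(0, M), M_i = 1 / var(q_i).
// The number of leapfrog steps is jittered uniformly on 1..max_steps.
// Uses the R RNG: seed the chain with set.seed() before the call.
// [[Rcpp::export(name = ".ssm_hmc_chain_cpp")]]
List ssm_hmc_chain_cpp(List stats, NumericVector q_init,
                       int iter_warmup, int iter_sample,
                       double target_accept, int max_steps,
                       double init_eps) {
  RNGScope scope;
  SSMStats S = as_stats(stats);
  const int D = 2 * S.T + 3;
  if ((int)q_init.size() != D) stop("q_init has wrong length");

  std::vector<double> q(q_init.begin(), q_init.end());
  std::vector<double> grad(D), qn(D), gn(D), p(D), minv(D, 1.0);
  double lp = lp_grad_ncp(q.data(), S, grad.data());
  if (!R_finite(lp)) stop("log posterior not finite at initial values");

  // dual averaging state (Hoffman & Gelman 2014 defaults)
  double eps = init_eps, log_eps_bar = std::log(eps), h_bar = 0.0;
  double da_mu = std::log(10.0 * init_eps);
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int da_count = 0;

  // Welford accumulators for the metric, refreshed per adaptation window
  std::vector<double> wm(D, 0.0), ws(D, 0.0);
  long wn = 0;

  // expanding slow-adaptation windows (Stan-style): an initial fast
  // interval adapts only the step size, then doubling windows each end
  // with a metric update and a step-size restart, then a terminal fast
  // interval re-tunes the step size under the final metric
  std::vector<int> window_end;
  {
    int init_buf = 75, term_buf = 50, base_win = 25;
    if (iter_warmup >= init_buf + term_buf + base_win) {
      int pos = init_buf, w = base_win;
      while (pos + w < iter_warmup - term_buf) {
        // widen the last window to absorb the remainder
        if (pos + 3 * w >= iter_warmup - term_buf) w = iter_warmup - term_buf - pos;
        window_end.push_back(pos + w);
        pos += w;
        w *= 2;
      }
    } else if (iter_warmup >= 60) {
      window_end.push_back((3 * iter_warmup) / 4);
    }
  }
  size_t win_idx = 0;

  NumericMatrix draws(iter_sample, D);
  double accept_sum = 0.0;
  int n_div = 0;

  const int total = iter_warmup + iter_sample;
  for (int it = 0; it < total; ++it) {
    const bool warm = it < iter_warmup;

    for (int i = 0; i < D; ++i) p[i] = norm_rand() / std::sqrt(minv[i]);
    double kin0 = 0.0;
    for (int i = 0; i < D; ++i) kin0 += 0.5 * p[i] * p[i] * minv[i];
    const double H0 = lp - kin0;

    std::copy(q.begin(), q.end(), qn.begin());
    std::copy(grad.begin(), grad.end(), gn.begin());
    int L = 1 + (int)std::floor(unif_rand() * max_steps);
    if (L > max_steps) L = max_steps;

    bool diverged = false;
    double lpn = lp;
    for (int s = 0; s < L; ++s) {
      for (int i = 0; i < D; ++i) p[i] += 0.5 * eps * gn[i];
      for (int i = 0; i < D; ++i) qn[i] += eps * minv[i] * p[i];
      lpn = lp_grad_ncp(qn.data(), S, gn.data());
      if (!R_finite(lpn)) { diverged = true; break; }
      for (int i = 0; i < D; ++i) p[i] += 0.5 * eps * gn[i];
    }

    double alpha = 0.0;
    if (!diverged) {
      double kin1 = 0.0;
      for (int i = 0; i < D; ++i) kin1 += 0.5 * p[i] * p[i] * minv[i];
      const double dH = (lpn - kin1) - H0;
      alpha = dH > 0 ? 1.0 : std::exp(dH);
      if (!R_finite(alpha)) { alpha = 0.0; diverged = true; }
    }
    if (diverged && !warm) ++n_div;

    if (!diverged && unif_rand() < alpha) {
      std::swap(q, qn);
      std::swap(grad, gn);
      lp = lpn;
    }

    if (warm) {
      // step-size adaptation
      ++da_count;
      const double eta1 = 1.0 / (da_count + da_t0);
      h_bar = (1.0 - eta1) * h_bar + eta1 * (target_accept - alpha);
      double log_eps = da_mu - std::sqrt((double)da_count) / da_gamma * h_bar;
      eps = std::exp(log_eps);
      const double eta2 = std::pow((double)da_count, -da_kappa);
      log_eps_bar = (1.0 - eta2) * log_eps_bar + eta2 * log_eps;
      // metric accumulation within the current slow window
      if (win_idx < window_end.size() && it >= 75) {
        ++wn;
        for (int i = 0; i < D; ++i) {
          const double d = q[i] - wm[i];
          wm[i] += d / wn;
          ws[i] += d * (q[i] - wm[i]);
        }
      }
      if (win_idx < window_end.size() && it + 1 == window_end[win_idx]) {
        if (wn > 10) {
          for (int i = 0; i < D; ++i) {
            double v = ws[i] / (wn - 1);
            if (v < 1e-8) v = 1e-8;
            // regularize towards unity as Stan does for small samples
            minv[i] = (wn / (wn + 5.0)) * v + 1e-3 * (5.0 / (wn + 5.0));
          }
        }
        std::fill(wm.begin(), wm.end(), 0.0);
        std::fill(ws.begin(), ws.end(), 0.0);
        wn = 0;
        // restart step-size adaptation under the new metric
        eps = std::exp(log_eps_bar);
        da_mu = std::log(10.0 * eps);
        da_count = 0; h_bar = 0.0; log_eps_bar = std::log(eps);
        ++win_idx;
      }
      if (it == iter_warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      accept_sum += alpha;
      for (int i = 0; i < D; ++i) draws(it - iter_warmup, i) = q[i];
    }
  }

  return List::create(_["draws"] = draws,
                      _["accept_rate"] = accept_sum / iter_sample,
                      _["step_size"] = eps,
                      _["n_divergent"] = n_div);
}
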