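// Tokens-task kernels: reward-rate-optimal backward induction over the
// reachable token states, and forward simulation of the three observer
// models on token sequences.  R's RNG is used throughout so that set.seed()
// in R makes every simulation reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static const int NTOK = 15;

// One backward pass at fixed rho.  pmat(n, U) = Pr(top | n moved, U up).
// iti[n] is the commitment penalty time after n movements.  Returns the
// start-state value; optionally fills the action matrix (1 plus, 2 minus,
// 3 wait).
static double tokens_pass(const NumericMatrix& pmat, const NumericVector& iti,
                          double Rc, double cost, double Ri, double dt,
                          double rho, IntegerMatrix* act) {
  double V[NTOK + 1][NTOK + 1];
  for (int n = NTOK; n >= 0; --n) {
    for (int U = 0; U <= n; ++U) {
      const double p = pmat(n, U);
      const double vp = Rc * p + Ri * (1.0 - p) - iti[n] * rho;
      const double vm = Rc * (1.0 - p) + Ri * p - iti[n] * rho;
      const bool plus = (p >= 0.5) ? (vp >= vm) : (vp > vm);
      const double vc = plus ? vp : vm;
      if (n == NTOK) {
        V[n][U] = vc;
        if (act) (*act)(n, U) = plus ? 1 : 2;
      } else {
        const double vw = 0.5 * (V[n + 1][U] + V[n + 1][U + 1]) -
          cost * dt - rho * dt;
        if (vc >= vw) {
          V[n][U] = vc;
          if (act) (*act)(n, U) = plus ? 1 : 2;
        } else {
          V[n][U] = vw;
          if (act) (*act)(n, U) = 3;
        }
      }
    }
  }
  return V[0][0];
}

// [[Rcpp::export]]
List cpp_tokens_solve(const NumericMatrix& pmat, const NumericVector& iti,
                      double Rc, double cost, double Ri, double dt,
                      double rho_init, double tol) {
  // bracket the decreasing start-value function g(rho)
  double iti_min = iti[0];
  for (int n = 0; n <= NTOK; ++n) iti_min = std::min(iti_min, iti[n]);
  iti_min = std::max(iti_min, 1e-9);
  double lo = (std::min(0.0, Ri) - cost * NTOK * dt) / iti_min - 1e-3;
  double hi = std::max(std::fabs(Rc), std::fabs(Ri)) / iti_min + 1e-3;
  auto g = [&](double rho) {
    return tokens_pass(pmat, iti, Rc, cost, Ri, dt, rho, nullptr);
  };
  double glo = g(lo), ghi = g(hi);
  for (int i = 0; i < 10 && glo < 0; ++i) { hi = lo; ghi = glo; lo -= std::max(1.0, std::fabs(lo)) * 2; glo = g(lo); }
  for (int i = 0; i < 10 && ghi > 0; ++i) { lo = hi; glo = ghi; hi += std::max(1.0, std::fabs(hi)) * 2; ghi = g(hi); }
  if (glo < 0 || ghi > 0) stop("tokens reward-rate root: no sign change in bracket");
  double x0 = lo, g0 = glo, x1 = hi, g1 = ghi, x = 0.5 * (lo + hi), gx;
  if (R_finite(rho_init) && rho_init > lo && rho_init < hi) {
    gx = g(rho_init);
    if (gx > 0) { x0 = rho_init; g0 = gx; } else { x1 = rho_init; g1 = gx; }
  }
  int side = 0;
  for (int iter = 0; iter < 100; ++iter) {
    x = x1 - g1 * (x1 - x0) / (g1 - g0);
    if (!R_finite(x) || x <= x0 || x >= x1) x = 0.5 * (x0 + x1);
    gx = g(x);
    if (std::fabs(gx) <= tol || (x1 - x0) < 1e-14) break;
    if (gx > 0) { x0 = x; g0 = gx; if (side == 1) g1 *= 0.5; side = 1; }
    else        { x1 = x; g1 = gx; if (side == -1) g0 *= 0.5; side = -1; }
  }
  IntegerMatrix act(NTOK + 1, NTOK + 1);
  const double v0 = tokens_pass(pmat, iti, Rc, cost, Ri, dt, x, &act);
  // upper threshold per step: smallest state likelihood with a plus commit
  NumericVector thr_p(NTOK + 1), thr_llr(NTOK + 1);
  for (int n = 0; n <= NTOK; ++n) {
    double th = R_PosInf;
    for (int U = 0; U <= n; ++U) {
      if (act(n, U) == 1) { th = pmat(n, U); break; }
    }
    thr_p[n] = th;
    if (R_finite(th)) {
      const double pc = std::min(std::max(th, 1e-9), 1.0 - 1e-9);
      thr_llr[n] = std::log(pc / (1.0 - pc));
    } else {
      thr_llr[n] = R_PosInf;
    }
  }
  return List::create(_["rho"] = x, _["v0"] = v0, _["thr_p"] = thr_p,
                      _["thr_llr"] = thr_llr, _["action"] = act);
}

// Simulate tokens-task trials.  model: 1 noisy Bayesian (uses thr_llr),
// 2 constant threshold, 3 urgency gating.  seqs holds +1 (up) / -1 (down)
// moves, one row per trial.  Beliefs are the exact token-state LLRs plus
// accumulated sensory noise; the urgency model low-pass filters the state
// likelihood.  Response times pass through a Gaussian motor filter with
// rejection resampling into [0, 3] s, then snap to the 0..15 bin grid.
// [[Rcpp::export]]
List cpp_sim_tokens(int model, const IntegerMatrix& seqs,
                    const NumericMatrix& pmat,
                    const NumericVector& thr_llr,
                    double theta0, double gain, double tau,
                    double sigma_y, double sigma_mn, int ugm_alt) {
  const int n_trials = seqs.nrow();
  const double dt = 0.2;
  IntegerVector rt_bin(n_trials), choice(n_trials), state(n_trials);
  NumericVector rt_raw(n_trials);
  RNGScope scope;
  for (int tr = 0; tr < n_trials; ++tr) {
    int U = 0;
    double noise = 0.0, E = 0.0;
    int ch = 0;
    double t_resp = -1.0;
    for (int n = 0; n <= NTOK; ++n) {
      if (n > 0) {
        if (seqs(tr, n - 1) > 0) ++U;
        if (model != 3) noise += sigma_y * std::sqrt(dt) * norm_rand();
      }
      const double p = pmat(n, U);
      const double pc = std::min(std::max(p, 1e-9), 1.0 - 1e-9);
      const double y = std::log(pc / (1.0 - pc)) + noise;
      double up;  // upper bound in the model's belief coordinates
      double bel;
      if (model == 1) { up = thr_llr[n]; bel = y; }
      else if (model == 2) { up = theta0; bel = y; }
      else {
        if (n > 0) {
          const double pn = 1.0 / (1.0 + std::exp(-y));
          E += dt / tau * (-E + pn - 0.5) +
            sigma_y * std::sqrt(dt) * norm_rand();
        }
        const double t = n * dt;
        up = (t <= 0) ? R_PosInf
                      : (ugm_alt ? theta0 / (1.0 + gain * t)
                                 : theta0 / (gain * t));
        bel = E;
      }
      if (n == NTOK) {
        ch = (bel > 0) ? 1 : (bel < 0 ? -1 : (unif_rand() < 0.5 ? 1 : -1));
        t_resp = NTOK * dt;
        break;
      }
      if (R_finite(up) && bel >= up) { ch = 1; t_resp = n * dt; break; }
      if (R_finite(up) && bel <= -up) { ch = -1; t_resp = n * dt; break; }
    }
    // final majority decides correctness
    int Ufin = 0;
    for (int n = 0; n < NTOK; ++n) if (seqs(tr, n) > 0) ++Ufin;
    state[tr] = (2 * Ufin > NTOK) ? 1 : -1;
    choice[tr] = ch;
    rt_raw[tr] = t_resp;
    double t_obs = t_resp;
    if (sigma_mn > 0) {
      const double t_max = NTOK * dt;
      do {
        t_obs = t_resp + sigma_mn * norm_rand();
      } while (t_obs < 0.0 || t_obs > t_max);
    }
    int b = (int)std::lround(t_obs / dt);
    if (b < 0) b = 0;
    if (b > NTOK) b = NTOK;
    rt_bin[tr] = b;
  }
  return List::create(_["rt_bin"] = rt_bin, _["choice"] = choice,
                      _["state"] = state, _["rt_raw"] = rt_raw);
}
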