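// Bellman backward-induction kernels.
//
// The belief grid is fixed over time; one likelihood transfer matrix applies
// per schedule piece.  Commit values arrive precomputed (reward-rate penalty
// included), so a single pass is a sequence of matrix-vector products plus
// elementwise maxima.  Tie rule: at exact equality commitment beats waiting,
// and between the two commitments the one whose half of belief space
// contains p wins.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_backward_pass(List mats, IntegerVector piece,
                       const arma::mat& vplus, const arma::mat& vminus,
                       const arma::vec& wait_sub, const arma::vec& p,
                       bool full) {
  const int n = vplus.n_rows;
  const int nT = piece.size();  // vplus has nT + 1 columns
  std::vector<arma::mat> M;
  M.reserve(mats.size());
  for (int i = 0; i < mats.size(); ++i) M.push_back(as<arma::mat>(mats[i]));

  arma::vec V(n);
  arma::mat Vall;
  arma::imat A;
  if (full) { Vall.set_size(n, nT + 1); A.set_size(n, nT + 1); }

  for (int i = 0; i < n; ++i) {
    const double vp = vplus(i, nT), vm = vminus(i, nT);
    const bool plus = (p[i] >= 0.5) ? (vp >= vm) : (vp > vm);
    V[i] = plus ? vp : vm;
    if (full) { Vall(i, nT) = V[i]; A(i, nT) = plus ? 1 : 2; }
  }

  for (int k = nT - 1; k >= 0; --k) {
    const arma::mat& Mk = M[piece[k] - 1];
    arma::vec Vw = Mk * V;
    Vw -= wait_sub[k];
    for (int i = 0; i < n; ++i) {
      const double vp = vplus(i, k), vm = vminus(i, k);
      const bool plus = (p[i] >= 0.5) ? (vp >= vm) : (vp > vm);
      const double vc = plus ? vp : vm;
      if (vc >= Vw[i]) {
        V[i] = vc;
        if (full) A(i, k) = plus ? 1 : 2;
      } else {
        V[i] = Vw[i];
        if (full) A(i, k) = 3;
      }
    }
    if (!V.is_finite())
      stop("non-finite values in backward induction at step %d", k);
    if (full) Vall.col(k) = V;
  }

  const int mid = (n - 1) / 2;
  if (full) {
    return List::create(_["v0"] = V[mid], _["V"] = Vall,
                        _["action"] = wrap(A));
  }
  return List::create(_["v0"] = V[mid]);
}

// Two-dimensional backward pass for the inferred reward-change task: the
// state is (p, q) where q is the belief that reward is currently high.
// Commit values use the expected reward RH*q + RL*(1-q); both transfer
// matrices are time-homogeneous, so V_w = Mp * V * Mq^T - (c + rho) dt.
// Returns the start value at (p = 0.5, q = 0.5) and the per-timestep upper
// threshold in p for every q column (NaN when waiting is optimal at all p).
// [[Rcpp::export]]
List cpp_backward_pass_2d(const arma::mat& Mp, const arma::mat& Mq,
                          const arma::vec& p, const arma::vec& q,
                          double RH, double RL, double Ri,
                          double iti_rho, double wait_sub, int nT,
                          bool full) {
  const int np = p.n_elem, nq = q.n_elem;
  arma::mat vplus(np, nq), vminus(np, nq);
  for (int j = 0; j < nq; ++j) {
    const double rbar = RH * q[j] + RL * (1.0 - q[j]);
    for (int i = 0; i < np; ++i) {
      vplus(i, j) = rbar * p[i] + Ri * (1.0 - p[i]) - iti_rho;
      vminus(i, j) = rbar * (1.0 - p[i]) + Ri * p[i] - iti_rho;
    }
  }
  arma::mat V = arma::max(vplus, vminus);
  arma::mat thr;
  if (full) thr.set_size(nT + 1, nq);

  if (full) {
    // terminal step: waiting impossible, plus-commit region is the upper
    // tail in p
    for (int j = 0; j < nq; ++j) {
      double th = arma::datum::nan;
      for (int i = 0; i < np; ++i) {
        const double vp = vplus(i, j), vm = vminus(i, j);
        if ((p[i] >= 0.5) ? (vp >= vm) : (vp > vm)) { th = p[i]; break; }
      }
      thr(nT, j) = th;
    }
  }

  for (int k = nT - 1; k >= 0; --k) {
    arma::mat Vw = Mp * V * Mq.t();
    Vw -= wait_sub;
    V = arma::max(arma::max(vplus, vminus), Vw);
    if (!V.is_finite())
      stop("non-finite values in 2-D backward induction at step %d", k);
    if (full) {
      for (int j = 0; j < nq; ++j) {
        double th = arma::datum::nan;
        for (int i = 0; i < np; ++i) {
          const double vp = vplus(i, j), vm = vminus(i, j);
          const bool plus = (p[i] >= 0.5) ? (vp >= vm) : (vp > vm);
          if (plus && (plus ? vp : vm) >= Vw(i, j)) { th = p[i]; break; }
        }
        thr(k, j) = th;
      }
    }
  }

  const int midp = (np - 1) / 2, midq = (nq - 1) / 2;
  if (full) {
    return List::create(_["v0"] = V(midp, midq), _["thr_upper_p"] = thr,
                        _["V0"] = V);
  }
  return List::create(_["v0"] = V(midp, midq));
}
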