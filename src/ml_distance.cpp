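#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pairwise maximum-likelihood amino acid distance under a reversible
// empirical model, given the cached spectral decomposition
//   P(t) = E1 * diag(exp(lambda * t)) * E2.
//
// The per-pair log-likelihood over shared-residue columns is
//   L(t) = sum_{ab} N_ab * log(pi_a * P_ab(t)).
// By detailed balance pi_a * P_ab(t) = pi_b * P_ba(t), so the (a,b) and
// (b,a) cells contribute identical log terms and are folded together.
// For each occupied unordered cell we precompute the 20-vectors
//   W_c[k]   = E1(a,k) * E2(k,b)
//   W1_c[k]  = W_c[k] * lambda[k]
//   W2_c[k]  = W_c[k] * lambda[k]^2
// so P_ab(t), dP/dt and d2P/dt2 are three dot products against
// exp(lambda * t). The optimum of L(t) on [0, t_max] is found by a
// bracketed Newton iteration on dL/dt, started from the equal-rates
// closed-form transform of the observed mismatch proportion; Newton steps
// that leave the bracket fall back to bisection.

namespace {

struct PairLik {
  std::vector<double> w;      // cells x 60 (W, W1, W2 interleaved blocks)
  std::vector<double> logpi;  // log(pi_a) per cell
  std::vector<double> n;      // folded counts per cell
  const double *lambda;
  int ncell = 0;

  void reset() {
    w.clear();
    logpi.clear();
    n.clear();
    ncell = 0;
  }

  // negative log-likelihood (for final reporting)
  double negloglik(double t) const {
    double ev[20];
    for (int k = 0; k < 20; ++k) ev[k] = std::exp(lambda[k] * t);
    double ll = 0.0;
    for (int c = 0; c < ncell; ++c) {
      const double *wc = &w[60 * c];
      double p = 0.0;
      for (int k = 0; k < 20; ++k) p += wc[k] * ev[k];
      if (p < 1e-300) p = 1e-300;
      ll += n[c] * (logpi[c] + std::log(p));
    }
    return -ll;
  }

  // first and second derivative of the negative log-likelihood
  void derivs(double t, double &g, double &h) const {
    double ev[20];
    for (int k = 0; k < 20; ++k) ev[k] = std::exp(lambda[k] * t);
    g = 0.0;
    h = 0.0;
    for (int c = 0; c < ncell; ++c) {
      const double *wc = &w[60 * c];
      double p = 0.0, p1 = 0.0, p2 = 0.0;
      for (int k = 0; k < 20; ++k) {
        p += wc[k] * ev[k];
        p1 += wc[20 + k] * ev[k];
        p2 += wc[40 + k] * ev[k];
      }
      if (p < 1e-300) p = 1e-300;
      double r = p1 / p;
      g -= n[c] * r;
      h -= n[c] * (p2 / p - r * r);
    }
  }
};

void ml_optimize(PairLik &pl, double ndiff, double ntot, double tmax,
                 double tol, double &dist, double &loglik) {
  if (ndiff == 0) {  // identical on shared columns: MLE at t = 0
    dist = 0.0;
    double ll = 0.0;
    for (int c = 0; c < pl.ncell; ++c) ll += pl.n[c] * pl.logpi[c];
    loglik = ll;
    return;
  }
  // boundary: likelihood still rising at the saturation cap
  double g, h;
  pl.derivs(tmax, g, h);
  if (g <= 0) {
    dist = tmax;
    loglik = -pl.negloglik(tmax);
    return;
  }
  // start from the equal-rates closed form of the mismatch proportion;
  // dL/dt -> +inf as t -> 0 when mismatches exist, so [0, tmax] brackets
  // the root of the derivative
  double phat = ndiff / ntot;
  double t = (phat < 0.94) ? -(19.0 / 20.0) * std::log1p(-(20.0 / 19.0) * phat)
                           : 3.0;
  if (t < 1e-8) t = 1e-8;
  if (t > tmax - 1e-8) t = tmax - 1e-8;
  double lo = 0.0, hi = tmax;
  for (int iter = 0; iter < 100; ++iter) {
    pl.derivs(t, g, h);
    if (g > 0) hi = t; else lo = t;
    double step;
    if (h > 0) {
      step = -g / h;
      double tn = t + step;
      if (tn <= lo || tn >= hi) {  // Newton left the bracket: bisect
        tn = 0.5 * (lo + hi);
        step = tn - t;
      }
      t = tn;
    } else {
      double tn = 0.5 * (lo + hi);
      step = tn - t;
      t = tn;
    }
    if (std::fabs(step) < tol * (1.0 + t)) break;
  }
  dist = t;
  loglik = -pl.negloglik(t);
}

// Build the folded cell representation from a 20x20 count matrix.
void build_cells(PairLik &pl, const double *counts, const NumericMatrix &E1,
                 const NumericMatrix &E2, const NumericVector &lambda,
                 const NumericVector &pi, double &ndiff, double &ntot) {
  pl.reset();
  pl.lambda = lambda.begin();
  ndiff = 0.0;
  ntot = 0.0;
  for (int a = 0; a < 20; ++a) {
    for (int b = a; b < 20; ++b) {
      double nab = counts[a + 20 * b] + ((a == b) ? 0.0 : counts[b + 20 * a]);
      if (nab <= 0) continue;
      ntot += nab;
      if (a != b) ndiff += nab;
      size_t base = pl.w.size();
      pl.w.resize(base + 60);
      for (int k = 0; k < 20; ++k) {
        double wk = E1(a, k) * E2(k, b);
        pl.w[base + k] = wk;
        pl.w[base + 20 + k] = wk * lambda[k];
        pl.w[base + 40 + k] = wk * lambda[k] * lambda[k];
      }
      pl.logpi.push_back(std::log(pi[a]));
      pl.n.push_back(nab);
    }
  }
  pl.ncell = (int)pl.n.size();
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_ml_from_counts(NumericMatrix counts, NumericMatrix E1,
                                 NumericMatrix E2, NumericVector lambda,
                                 NumericVector pi, double tmax, double tol) {
  PairLik pl;
  double ndiff, ntot;
  build_cells(pl, counts.begin(), E1, E2, lambda, pi, ndiff, ntot);
  if (ntot <= 0) return NumericVector::create(NA_REAL, NA_REAL, 0.0);
  double d, ll;
  ml_optimize(pl, ndiff, ntot, tmax, tol, d, ll);
  return NumericVector::create(d, ll, ntot);
}

// codes: n_taxa x n_sites integer matrix, 1..20 or NA for gap/ambiguity.
// [[Rcpp::export]]
List cpp_ml_distmat(IntegerMatrix codes, NumericMatrix E1, NumericMatrix E2,
                    NumericVector lambda, NumericVector pi, double tmax,
                    double tol) {
  int n = codes.nrow(), L = codes.ncol();
  NumericMatrix D(n, n), LL(n, n), NS(n, n);
  std::vector<double> counts(400);
  std::vector<int> ci(n * L);  // row-contiguous copy for the pair loop
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) ci[i * L + s] = codes(i, s);
  PairLik pl;
  pl.w.reserve(400 * 60);
  pl.logpi.reserve(400);
  pl.n.reserve(400);
  for (int i = 0; i < n; ++i) {
    LL(i, i) = 0.0;
    NS(i, i) = 0.0;
    const int *ri = &ci[i * L];
    for (int j = i + 1; j < n; ++j) {
      const int *rj = &ci[j * L];
      std::fill(counts.begin(), counts.end(), 0.0);
      for (int s = 0; s < L; ++s) {
        int a = ri[s], b = rj[s];
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        counts[(a - 1) + 20 * (b - 1)] += 1.0;
      }
      double ndiff, ntot;
      build_cells(pl, counts.data(), E1, E2, lambda, pi, ndiff, ntot);
      double d = NA_REAL, ll = NA_REAL;
      if (ntot > 0) ml_optimize(pl, ndiff, ntot, tmax, tol, d, ll);
      D(i, j) = D(j, i) = d;
      LL(i, j) = LL(j, i) = ll;
      NS(i, j) = NS(j, i) = ntot;
    }
  }
  return List::create(_["D"] = D, _["loglik"] = LL, _["n_shared"] = NS);
}
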