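#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// ZOOPS (zero-or-one-occurrence-per-sequence) EM for a single motif width.
//
// X:      n x L matrix of letter codes 0..3 (A,C,G,T)
// avail:  n x L availability in [0,1]; positions already claimed by earlier
//         motifs have availability < 1 (probabilistic erasure)
// pwm0:   4 x width initial position weight matrix (column-stochastic)
// bg:     length-4 0-order background probabilities
// lambda0: initial occupancy prior (probability a sequence holds a site)
// pseudo: Dirichlet pseudocount added per pwm cell in the M-step
//
// The maximized objective is the ZOOPS log-likelihood plus the Dirichlet
// log-prior implied by the pseudocounts (a MAP EM); that penalized objective
// is non-decreasing by the EM guarantee and is what the trace records.
// [[Rcpp::export(name = ".em_zoops_core")]]
List em_zoops_core(const IntegerMatrix X, const NumericMatrix avail,
                   const NumericMatrix pwm0, const NumericVector bg,
                   const double lambda0, const int max_iter,
                   const double tol, const double pseudo) {
  const int n = X.nrow(), L = X.ncol(), w = pwm0.ncol();
  const int m = L - w + 1;
  if (m < 1) stop("motif width exceeds window length");

  NumericMatrix pwm = clone(pwm0);
  double lambda = lambda0;

  // per-sequence background log-likelihood (constant across iterations)
  NumericVector logp0(n);
  NumericVector logbg(4);
  for (int a = 0; a < 4; ++a) logbg[a] = std::log(bg[a]);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < L; ++t) s += logbg[X(i, t)];
    logp0[i] = s;
  }

  // availability weight of a site starting at offset j
  NumericMatrix aw(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double p = 1.0;
      for (int k = 0; k < w; ++k) p *= avail(i, j + k);
      aw(i, j) = p;
    }

  NumericMatrix z(n, m);
  NumericVector z0(n);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double obj_prev = R_NegInf, obj = R_NegInf;
  int iter = 0;

  NumericMatrix logratio(4, w); // log(pwm/bg)
  for (iter = 0; iter < max_iter; ++iter) {
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < w; ++k)
        logratio(a, k) = std::log(pwm(a, k)) - logbg[a];

    // E-step + objective
    double loglik = 0.0;
    for (int i = 0; i < n; ++i) {
      double denom = 1.0 - lambda;
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int k = 0; k < w; ++k) s += logratio(X(i, j + k), k);
        double wgt = (lambda / m) * aw(i, j) * std::exp(s);
        z(i, j) = wgt;
        denom += wgt;
      }
      if (denom <= 0.0) denom = DBL_MIN;
      for (int j = 0; j < m; ++j) z(i, j) /= denom;
      z0[i] = (1.0 - lambda) / denom;
      loglik += logp0[i] + std::log(denom);
    }
    double logprior = 0.0;
    for (int a = 0; a < 4; ++a)
      for (int k = 0; k < w; ++k) logprior += pseudo * std::log(pwm(a, k));
    obj = loglik + logprior;
    trace.push_back(obj);
    if (iter > 0 && std::fabs(obj - obj_prev) <
        tol * (std::fabs(obj_prev) + 1e-12)) { ++iter; break; }
    obj_prev = obj;

    // M-step
    double zsum = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j) zsum += z(i, j);
    lambda = zsum / n;
    if (lambda < 0.0) lambda = 0.0;
    if (lambda > 1.0) lambda = 1.0;
    if (zsum > 0.0) {
      NumericMatrix cnt(4, w);
      std::fill(cnt.begin(), cnt.end(), pseudo);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
          const double zij = z(i, j);
          if (zij > 0.0)
            for (int k = 0; k < w; ++k) cnt(X(i, j + k), k) += zij;
        }
      for (int k = 0; k < w; ++k) {
        double tot = 0.0;
        for (int a = 0; a < 4; ++a) tot += cnt(a, k);
        for (int a = 0; a < 4; ++a) pwm(a, k) = cnt(a, k) / tot;
      }
    } // zsum == 0 (e.g. lambda 0): no site evidence, pwm kept as-is
  }

  // final data log-likelihood under the returned parameters
  double loglik_final = 0.0;
  for (int a = 0; a < 4; ++a)
    for (int k = 0; k < w; ++k)
      logratio(a, k) = std::log(pwm(a, k)) - logbg[a];
  for (int i = 0; i < n; ++i) {
    double denom = 1.0 - lambda;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < w; ++k) s += logratio(X(i, j + k), k);
      denom += (lambda / m) * aw(i, j) * std::exp(s);
    }
    if (denom <= 0.0) denom = DBL_MIN;
    loglik_final += logp0[i] + std::log(denom);
  }

  double logp0_sum = 0.0;
  for (int i = 0; i < n; ++i) logp0_sum += logp0[i];
  return List::create(
    _["pwm"] = pwm, _["lambda"] = lambda,
    _["loglik"] = loglik_final,
    _["logp0_sum"] = logp0_sum,
    _["objective_trace"] = NumericVector(trace.begin(), trace.end()),
    _["z"] = z, _["z0"] = z0, _["n_iter"] = iter);
}
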