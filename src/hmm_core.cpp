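#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over one chain.
// emis: n x K likelihoods (not logs), trans: K x K, init: K.
// Returns gamma (n x K posteriors) and the chain log-likelihood.
// [[Rcpp::export(name = ".fb_chain")]]
List fb_chain(NumericMatrix emis, NumericMatrix trans, NumericVector init) {
  int n = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector scale(n);
  double ll = 0.0;

  for (int k = 0; k < K; ++k) alpha(0, k) = init[k] * emis(0, k);
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += alpha(0, k);
  if (s <= 0) stop("zero forward mass at position 1");
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  ll += std::log(s);

  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      a *= emis(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) stop("zero forward mass at position %d", t + 1);
    scale[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    ll += std::log(s);
  }

  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k)
        b += trans(j, k) * emis(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / scale[t + 1];
    }
  }

  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = ll);
}

// Viterbi over one chain in log space. Ties (within tol) break toward the
// state with the smaller neutral-distance penalty `ndist` (|CN - 2|), so
// near-flat data does not acquire spurious aberrations.
// [[Rcpp::export(name = ".viterbi_chain")]]
IntegerVector viterbi_chain(NumericMatrix logemis, NumericMatrix logtrans,
                            NumericVector loginit, NumericVector ndist) {
  int n = logemis.nrow(), K = logemis.ncol();
  const double tol = 1e-9;
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);

  for (int k = 0; k < K; ++k) delta(0, k) = loginit[k] + logemis(0, k);

  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      int best = 0;
      double bestv = delta(t - 1, 0) + logtrans(0, k);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logtrans(j, k);
        if (v > bestv + tol ||
            (std::abs(v - bestv) <= tol && ndist[j] < ndist[best])) {
          bestv = v;
          best = j;
        }
      }
      delta(t, k) = bestv + logemis(t, k);
      psi(t, k) = best;
    }
  }

  IntegerVector path(n);
  int best = 0;
  double bestv = delta(n - 1, 0);
  for (int k = 1; k < K; ++k) {
    double v = delta(n - 1, k);
    if (v > bestv + tol ||
        (std::abs(v - bestv) <= tol && ndist[k] < ndist[best])) {
      bestv = v;
      best = k;
    }
  }
  path[n - 1] = best + 1;
  for (int t = n - 1; t > 0; --t) {
    best = psi(t, best);
    path[t - 1] = best + 1;
  }
  return path;
}
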