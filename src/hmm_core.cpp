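#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a small-state HMM.
//
// E:    T x S emission probability matrix (row t = P(x_t | state)).
// P:    S x S transition matrix (row = from-state).
// init: initial state distribution.
//
// Returns the observed-data log likelihood, the T x S posterior matrix
// (gamma), and the S x S matrix of expected transition counts
// (sum over t of the normalized two-slice posteriors xi_t), which is all the
// M-step of a tied-parameter model needs.
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix E, NumericMatrix P, NumericVector init) {
  const int T = E.nrow(), S = E.ncol();
  NumericMatrix alpha(T, S), beta(T, S), gamma(T, S), xi(S, S);
  NumericVector scale(T);

  // forward pass with per-step scaling (no underflow at T = 10,000)
  double c0 = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha(0, s) = init[s] * E(0, s);
    c0 += alpha(0, s);
  }
  if (c0 <= 0.0) stop("zero-probability observation sequence at trial 1");
  for (int s = 0; s < S; ++s) alpha(0, s) /= c0;
  scale[0] = c0;

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < S; ++j) {
      double a = 0.0;
      for (int i = 0; i < S; ++i) a += alpha(t - 1, i) * P(i, j);
      a *= E(t, j);
      alpha(t, j) = a;
      ct += a;
    }
    if (ct <= 0.0) stop("zero-probability observation sequence at trial %d", t + 1);
    for (int j = 0; j < S; ++j) alpha(t, j) /= ct;
    scale[t] = ct;
  }

  // backward pass, same scaling constants
  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < S; ++i) {
      double b = 0.0;
      for (int j = 0; j < S; ++j) b += P(i, j) * E(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / scale[t + 1];
    }
  }

  // posteriors and pooled two-slice counts
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int s = 0; s < S; ++s) {
      gamma(t, s) = alpha(t, s) * beta(t, s);
      g += gamma(t, s);
    }
    for (int s = 0; s < S; ++s) gamma(t, s) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < S; ++i) {
      double ai = alpha(t, i);
      if (ai == 0.0) continue;
      for (int j = 0; j < S; ++j) {
        double v = ai * P(i, j) * E(t + 1, j) * beta(t + 1, j) / scale[t + 1];
        xi(i, j) += v;
      }
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

  return List::create(_["log_likelihood"] = ll,
                      _["gamma"] = gamma,
                      _["xi_sum"] = xi);
}

// Viterbi decoding in log space. logE/logP carry structural zeros as large
// negative sentinels (never NaN). Ties broken toward the lowest state index
// by strict-greater comparison while scanning states in increasing order.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logE, NumericMatrix logP, NumericVector logInit) {
  const int T = logE.nrow(), S = logE.ncol();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);

  for (int s = 0; s < S; ++s) delta(0, s) = logInit[s] + logE(0, s);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        double v = delta(t - 1, i) + logP(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logE(t, j);
      psi(t, j) = arg;
    }
  }

  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < S; ++s) {
    if (delta(T - 1, s) > best) { best = delta(T - 1, s); arg = s; }
  }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices for R
}
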