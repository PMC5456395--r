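#include <Rcpp.h>
using namespace Rcpp;

// Two-state Gaussian HMM internals. Observations are concatenated
// per-chromosome sequences; seqlen gives the length of each sequence so
// that no transition is counted across a chromosome boundary.

static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.91893853320467274178;
}

// Scaled forward-backward pass. Returns the sufficient statistics of the
// Baum-Welch M-step plus the total log-likelihood:
//   gamma_first : sum over sequences of gamma_1(k)
//   trans_num   : sum over t of xi_t(j,k) (numerator of A update)
//   gamma_sum   : sum over all t of gamma_t(k)
//   gamma_x     : sum gamma_t(k) * x_t
//   gamma_xx    : sum gamma_t(k) * x_t^2
// [[Rcpp::export(name = ".hmm_estep2")]]
List hmm_estep2(NumericVector obs, IntegerVector seqlen,
                NumericVector pi0, NumericMatrix A,
                NumericVector mu, NumericVector sd) {
  const int S = 2;
  NumericVector gamma_first(S), gamma_sum(S), gamma_x(S), gamma_xx(S);
  NumericMatrix trans_num(S, S);
  double loglik = 0.0;

  int offset = 0;
  for (int s = 0; s < seqlen.size(); ++s) {
    const int T = seqlen[s];
    if (T <= 0) continue;
    NumericMatrix alpha(T, S), beta(T, S), b(T, S);
    NumericVector cscale(T);

    // emission densities (linear scale via per-row max shift is not needed
    // with alpha scaling; compute densities directly, guarding underflow)
    for (int t = 0; t < T; ++t) {
      double x = obs[offset + t];
      for (int k = 0; k < S; ++k) {
        double lp = ldnorm(x, mu[k], sd[k]);
        b(t, k) = std::exp(std::max(lp, -700.0));
      }
    }

    // forward with scaling
    double c0 = 0.0;
    for (int k = 0; k < S; ++k) { alpha(0, k) = pi0[k] * b(0, k); c0 += alpha(0, k); }
    if (c0 <= 0) c0 = 1e-300;
    for (int k = 0; k < S; ++k) alpha(0, k) /= c0;
    cscale[0] = c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int k = 0; k < S; ++k) {
        double acc = 0.0;
        for (int j = 0; j < S; ++j) acc += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = acc * b(t, k);
        ct += alpha(t, k);
      }
      if (ct <= 0) ct = 1e-300;
      for (int k = 0; k < S; ++k) alpha(t, k) /= ct;
      cscale[t] = ct;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(cscale[t]);

    // backward with the same scaling
    for (int k = 0; k < S; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int j = 0; j < S; ++j) {
        double acc = 0.0;
        for (int k = 0; k < S; ++k) acc += A(j, k) * b(t + 1, k) * beta(t + 1, k);
        beta(t, j) = acc / cscale[t + 1];
      }
    }

    // accumulate statistics
    for (int t = 0; t < T; ++t) {
      double x = obs[offset + t];
      double norm = 0.0;
      double g[2];
      for (int k = 0; k < S; ++k) { g[k] = alpha(t, k) * beta(t, k); norm += g[k]; }
      if (norm <= 0) norm = 1e-300;
      for (int k = 0; k < S; ++k) {
        double gk = g[k] / norm;
        gamma_sum[k] += gk;
        gamma_x[k] += gk * x;
        gamma_xx[k] += gk * x * x;
        if (t == 0) gamma_first[k] += gk;
      }
      if (t < T - 1) {
        double xin = 0.0;
        double xi[2][2];
        for (int j = 0; j < S; ++j)
          for (int k = 0; k < S; ++k) {
            xi[j][k] = alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k);
            xin += xi[j][k];
          }
        if (xin <= 0) xin = 1e-300;
        for (int j = 0; j < S; ++j)
          for (int k = 0; k < S; ++k) trans_num(j, k) += xi[j][k] / xin;
      }
    }
    offset += T;
  }

  return List::create(_["loglik"] = loglik,
                      _["gamma_first"] = gamma_first,
                      _["trans_num"] = trans_num,
                      _["gamma_sum"] = gamma_sum,
                      _["gamma_x"] = gamma_x,
                      _["gamma_xx"] = gamma_xx);
}

// Viterbi decoding per sequence; returns 1-based state indices.
// [[Rcpp::export(name = ".hmm_viterbi2")]]
IntegerVector hmm_viterbi2(NumericVector obs, IntegerVector seqlen,
                           NumericVector pi0, NumericMatrix A,
                           NumericVector mu, NumericVector sd) {
  const int S = 2;
  IntegerVector path(obs.size());
  NumericVector lpi(S);
  NumericMatrix lA(S, S);
  for (int k = 0; k < S; ++k) lpi[k] = std::log(std::max(pi0[k], 1e-300));
  for (int j = 0; j < S; ++j)
    for (int k = 0; k < S; ++k) lA(j, k) = std::log(std::max(A(j, k), 1e-300));

  int offset = 0;
  for (int s = 0; s < seqlen.size(); ++s) {
    const int T = seqlen[s];
    if (T <= 0) continue;
    NumericMatrix delta(T, S);
    IntegerMatrix psi(T, S);
    for (int k = 0; k < S; ++k)
      delta(0, k) = lpi[k] + ldnorm(obs[offset], mu[k], sd[k]);
    for (int t = 1; t < T; ++t) {
      double x = obs[offset + t];
      for (int k = 0; k < S; ++k) {
        double best = delta(t - 1, 0) + lA(0, k);
        int arg = 0;
        double alt = delta(t - 1, 1) + lA(1, k);
        if (alt > best) { best = alt; arg = 1; }
        delta(t, k) = best + ldnorm(x, mu[k], sd[k]);
        psi(t, k) = arg;
      }
    }
    int last = delta(T - 1, 1) > delta(T - 1, 0) ? 1 : 0;
    path[offset + T - 1] = last + 1;
    for (int t = T - 2; t >= 0; --t) {
      last = psi(t + 1, last);
      path[offset + t] = last + 1;
    }
    offset += T;
  }
  return path;
}
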