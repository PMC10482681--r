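#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass. obs is 0-based. Returns the log-likelihood, or
// -Inf if some step has zero probability under every state.
// [[Rcpp::export]]
double cpp_forward_loglik(NumericVector pi, NumericMatrix A,
                          NumericMatrix B, IntegerVector obs) {
  const int K = pi.size(), T = obs.size();
  std::vector<double> alpha(K), alpha_new(K);
  double ll = 0.0;
  double c = 0.0;
  for (int i = 0; i < K; ++i) {
    alpha[i] = pi[i] * B(i, obs[0]);
    c += alpha[i];
  }
  if (c <= 0.0) return R_NegInf;
  for (int i = 0; i < K; ++i) alpha[i] /= c;
  ll += std::log(c);
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha[i] * A(i, j);
      alpha_new[j] = s * B(j, obs[t]);
      c += alpha_new[j];
    }
    if (c <= 0.0) return R_NegInf;
    for (int j = 0; j < K; ++j) alpha[j] = alpha_new[j] / c;
    ll += std::log(c);
  }
  return ll;
}

// Scaled forward-backward. Returns per-time posteriors gamma (T x K),
// expected transition counts xi_sum (K x K), expected emission counts
// emis_num (K x V), gamma at t=1, and the log-likelihood.
// [[Rcpp::export]]
List cpp_forward_backward(NumericVector pi, NumericMatrix A,
                          NumericMatrix B, IntegerVector obs) {
  const int K = pi.size(), T = obs.size(), V = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector cs(T);
  double ll = 0.0;

  double c = 0.0;
  for (int i = 0; i < K; ++i) {
    alpha(0, i) = pi[i] * B(i, obs[0]);
    c += alpha(0, i);
  }
  if (c <= 0.0) stop("zero-probability observation at step 1");
  for (int i = 0; i < K; ++i) alpha(0, i) /= c;
  cs[0] = c; ll = std::log(c);

  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, j);
      alpha(t, j) = s * B(j, obs[t]);
      c += alpha(t, j);
    }
    if (c <= 0.0) stop("zero-probability observation at step %d", t + 1);
    for (int j = 0; j < K; ++j) alpha(t, j) /= c;
    cs[t] = c; ll += std::log(c);
  }

  for (int i = 0; i < K; ++i) beta(T - 1, i) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += A(i, j) * B(j, obs[t + 1]) * beta(t + 1, j);
      beta(t, i) = s / cs[t + 1];
    }
  }

  NumericMatrix gamma(T, K), xi_sum(K, K), emis_num(K, V);
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    for (int i = 0; i < K; ++i) {
      gamma(t, i) = alpha(t, i) * beta(t, i);
      tot += gamma(t, i);
    }
    for (int i = 0; i < K; ++i) {
      gamma(t, i) /= tot;
      emis_num(i, obs[t]) += gamma(t, i);
    }
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i) {
      double ab = alpha(t, i);
      if (ab == 0.0) continue;
      for (int j = 0; j < K; ++j)
        xi_sum(i, j) += ab * A(i, j) * B(j, obs[t + 1]) *
                        beta(t + 1, j) / cs[t + 1];
    }
  }

  NumericVector gamma1(K);
  for (int i = 0; i < K; ++i) gamma1[i] = gamma(0, i);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum, _["emis_num"] = emis_num,
                      _["gamma1"] = gamma1);
}

// Log-space Viterbi; ties broken toward the lowest state index.
// Returns 0-based path and its log joint probability.
// [[Rcpp::export]]
List cpp_viterbi(NumericVector log_pi, NumericMatrix log_A,
                 NumericMatrix log_B, IntegerVector obs) {
  const int K = log_pi.size(), T = obs.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int i = 0; i < K; ++i) delta(0, i) = log_pi[i] + log_B(i, obs[0]);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + log_A(i, j);
        if (v > best) { best = v; arg = i; }  // strict >: lowest index wins ties
      }
      delta(t, j) = best + log_B(j, obs[t]);
      psi(t, j) = arg;
    }
  }
  double best = R_NegInf; int last = 0;
  for (int i = 0; i < K; ++i)
    if (delta(T - 1, i) > best) { best = delta(T - 1, i); last = i; }
  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return List::create(_["path"] = path, _["logprob"] = best);
}
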