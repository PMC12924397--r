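#include <Rcpp.h>
using namespace Rcpp;

// State-dependent log-densities for every (step, state) pair.
// step lengths: gamma(shape, rate) with optional point mass zeta at exactly 0;
// turn angles: von Mises(theta, kappa), marginalized out when missing (NA).
// log_norm_vm[i] = log(2 * pi * I0(kappa_i)) is precomputed in R (besselI).
// [[Rcpp::export(name = ".emissionLogdensCpp")]]
NumericMatrix emission_logdens_cpp(NumericVector step, NumericVector angle,
                                   NumericVector shape, NumericVector rate,
                                   NumericVector zeta, NumericVector kappa,
                                   NumericVector theta, NumericVector log_norm_vm) {
  const int T = step.size();
  const int N = shape.size();
  NumericMatrix out(T, N);
  std::vector<double> lgam(N), lograte(N);
  for (int i = 0; i < N; ++i) {
    lgam[i] = R::lgammafn(shape[i]);
    lograte[i] = std::log(rate[i]);
  }
  for (int t = 0; t < T; ++t) {
    const double x = step[t];
    const bool zero = (x <= 0.0);
    const double lx = zero ? 0.0 : std::log(x);
    const bool amiss = NumericVector::is_na(angle[t]);
    const double a = amiss ? 0.0 : angle[t];
    for (int i = 0; i < N; ++i) {
      double ld;
      if (zero) {
        ld = (zeta[i] > 0.0) ? std::log(zeta[i]) : R_NegInf;
      } else {
        ld = shape[i] * lograte[i] - lgam[i] + (shape[i] - 1.0) * lx - rate[i] * x;
        if (zeta[i] > 0.0) ld += std::log1p(-zeta[i]);
      }
      if (!amiss)
        ld += kappa[i] * std::cos(a - theta[i]) - log_norm_vm[i];
      out(t, i) = ld;
    }
  }
  return out;
}

// Scaled forward recursion. burst_len gives the number of steps per burst;
// the initial law delta restarts at each burst. Returns the total loglik.
// [[Rcpp::export(name = ".forwardLoglikCpp")]]
double forward_loglik_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                          NumericVector delta, IntegerVector burst_len) {
  const int N = logdens.ncol();
  double ll = 0.0;
  int t0 = 0;
  std::vector<double> alpha(N), anew(N), b(N);
  for (int k = 0; k < burst_len.size(); ++k) {
    const int T = burst_len[k];
    for (int t = 0; t < T; ++t) {
      const int row = t0 + t;
      double m = R_NegInf;
      for (int i = 0; i < N; ++i) if (logdens(row, i) > m) m = logdens(row, i);
      if (!R_finite(m)) return R_NegInf;  // zero density in every state
      for (int i = 0; i < N; ++i) b[i] = std::exp(logdens(row, i) - m);
      double c = 0.0;
      if (t == 0) {
        for (int i = 0; i < N; ++i) { anew[i] = delta[i] * b[i]; c += anew[i]; }
      } else {
        for (int j = 0; j < N; ++j) {
          double s = 0.0;
          for (int i = 0; i < N; ++i) s += alpha[i] * Gamma(i, j);
          anew[j] = s * b[j];
          c += anew[j];
        }
      }
      if (c <= 0.0) return R_NegInf;
      for (int i = 0; i < N; ++i) alpha[i] = anew[i] / c;
      ll += std::log(c) + m;
    }
    t0 += T;
  }
  return ll;
}

// Forward-backward smoothing. Returns the loglik, the posterior state
// probabilities gamma (T x N), the expected transition counts
// xi_sum(i,j) = sum_t P(S_t = i, S_{t+1} = j | data) aggregated over bursts,
// and d loglik / d delta = sum over bursts of gamma_1(i) / delta_i.
// These are the sufficient pieces for the Fisher-identity score.
// [[Rcpp::export(name = ".forwardBackwardCpp")]]
List forward_backward_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                          NumericVector delta, IntegerVector burst_len) {
  const int Ttot = logdens.nrow();
  const int N = logdens.ncol();
  NumericMatrix post(Ttot, N);
  NumericMatrix xi_sum(N, N);
  NumericVector dldelta(N);
  double ll = 0.0;

  NumericMatrix ahat(Ttot, N);   // scaled forward
  NumericMatrix bmat(Ttot, N);   // emission probs scaled by row max
  NumericVector cvec(Ttot);      // normalizers
  int t0 = 0;
  std::vector<double> b(N);
  for (int k = 0; k < burst_len.size(); ++k) {
    const int T = burst_len[k];
    for (int t = 0; t < T; ++t) {
      const int row = t0 + t;
      double m = R_NegInf;
      for (int i = 0; i < N; ++i) if (logdens(row, i) > m) m = logdens(row, i);
      for (int i = 0; i < N; ++i) bmat(row, i) = std::exp(logdens(row, i) - m);
      double c = 0.0;
      if (t == 0) {
        for (int i = 0; i < N; ++i) { b[i] = delta[i] * bmat(row, i); c += b[i]; }
      } else {
        for (int j = 0; j < N; ++j) {
          double s = 0.0;
          for (int i = 0; i < N; ++i) s += ahat(row - 1, i) * Gamma(i, j);
          b[j] = s * bmat(row, j);
          c += b[j];
        }
      }
      if (c <= 0.0 || !R_finite(m)) stop("zero likelihood encountered in forward pass");
      for (int i = 0; i < N; ++i) ahat(row, i) = b[i] / c;
      cvec[row] = c;
      ll += std::log(c) + m;
    }
    // backward pass for this burst
    std::vector<double> beta(N, 1.0), bnew(N);
    for (int i = 0; i < N; ++i) post(t0 + T - 1, i) = ahat(t0 + T - 1, i);
    for (int t = T - 2; t >= 0; --t) {
      const int row = t0 + t;
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int j = 0; j < N; ++j)
          s += Gamma(i, j) * bmat(row + 1, j) * beta[j];
        bnew[i] = s / cvec[row + 1];
      }
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < N; ++j)
          xi_sum(i, j) += ahat(row, i) * Gamma(i, j) * bmat(row + 1, j) * beta[j] / cvec[row + 1];
      for (int i = 0; i < N; ++i) {
        beta[i] = bnew[i];
        post(row, i) = ahat(row, i) * beta[i];
      }
    }
    for (int i = 0; i < N; ++i)
      if (delta[i] > 0.0) dldelta[i] += post(t0, i) / delta[i];
    t0 += T;
  }
  return List::create(_["loglik"] = ll, _["gamma"] = post,
                      _["xi_sum"] = xi_sum, _["dldelta"] = dldelta);
}

// Viterbi decoding per burst, ties broken toward the lower state index.
// Returns 1-based states, one per step.
// [[Rcpp::export(name = ".viterbiCpp")]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                          NumericVector delta, IntegerVector burst_len) {
  const int Ttot = logdens.nrow();
  const int N = logdens.ncol();
  IntegerVector path(Ttot);
  NumericMatrix lG(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      lG(i, j) = Gamma(i, j) > 0.0 ? std::log(Gamma(i, j)) : R_NegInf;

  int t0 = 0;
  for (int k = 0; k < burst_len.size(); ++k) {
    const int T = burst_len[k];
    NumericMatrix v(T, N);
    IntegerMatrix back(T, N);
    for (int i = 0; i < N; ++i)
      v(0, i) = (delta[i] > 0.0 ? std::log(delta[i]) : R_NegInf) + logdens(t0, i);
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < N; ++j) {
        double best = R_NegInf;
        int arg = 0;
        for (int i = 0; i < N; ++i) {
          const double cand = v(t - 1, i) + lG(i, j);
          if (cand > best) { best = cand; arg = i; }  // strict: lowest index wins ties
        }
        v(t, j) = best + logdens(t0 + t, j);
        back(t, j) = arg;
      }
    }
    double best = R_NegInf;
    int arg = 0;
    for (int i = 0; i < N; ++i)
      if (v(T - 1, i) > best) { best = v(T - 1, i); arg = i; }
    path[t0 + T - 1] = arg + 1;
    for (int t = T - 1; t >= 1; --t) {
      arg = back(t, arg);
      path[t0 + t - 1] = arg + 1;
    }
    t0 += T;
  }
  return path;
}

// First-order Markov chain sampler on R's RNG stream (so set.seed applies).
// [[Rcpp::export(name = ".markovSimCpp")]]
IntegerVector markov_sim_cpp(NumericMatrix P, NumericVector init, int n) {
  const int N = P.ncol();
  IntegerVector out(n);
  RNGScope scope;
  double u = unif_rand();
  int s = N - 1;
  double acc = 0.0;
  for (int i = 0; i < N; ++i) { acc += init[i]; if (u <= acc) { s = i; break; } }
  out[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    u = unif_rand();
    acc = 0.0;
    int nxt = N - 1;
    for (int j = 0; j < N; ++j) { acc += P(s, j); if (u <= acc) { nxt = j; break; } }
    s = nxt;
    out[t] = s + 1;
  }
  return out;
}
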