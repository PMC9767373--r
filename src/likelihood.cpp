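#include <Rcpp.h>
using namespace Rcpp;

// Forward pass shared by the likelihood and the simulator.
//
// Per-trial dynamics:
//   p(go) = 1 / (1 + exp(-(Q[s] + b_k) / tau_k))   (k = block type)
//   reinforced + go : Q[s] += alpha * (r - Q[s]),  r = +1 (go stim) / -1 (no-go stim)
//   probe + go      : Q[s] unchanged
//   any + no-go     : Q[s] *= theta   (passive forgetting of displayed option)
//
// Block coding: 0 = reinforced, 1 = probe. Response coding: 1 = go, 0 = no-go.

static inline double go_prob(double q, double bias, double tau) {
  return 1.0 / (1.0 + std::exp(-(q + bias) / tau));
}

// [[Rcpp::export]]
double cpp_session_nll(const IntegerVector& stim,     // 0-based stimulus ids
                       const IntegerVector& block,    // 0 reinforced, 1 probe
                       const IntegerVector& resp,     // 1 go, 0 nogo
                       const NumericVector& outcome,  // +1 / -1 / 0 (ignored unless reinforced go)
                       int n_stimuli,
                       double alpha, double tau_R, double tau_P,
                       double b_R, double b_P, double Q0, double theta,
                       double lik_floor) {
  const int n = stim.size();
  std::vector<double> q(n_stimuli, Q0);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int s = stim[t];
    const bool probe = block[t] == 1;
    const double tau = probe ? tau_P : tau_R;
    const double b   = probe ? b_P : b_R;
    const double p   = go_prob(q[s], b, tau);
    double lik = resp[t] == 1 ? p : 1.0 - p;
    if (lik < lik_floor) lik = lik_floor;
    nll -= std::log(lik);
    if (resp[t] == 1) {
      if (!probe) q[s] += alpha * (outcome[t] - q[s]);
    } else {
      q[s] *= theta;
    }
  }
  return nll;
}

// [[Rcpp::export]]
List cpp_simulate_session(const IntegerVector& stim,
                          const IntegerVector& cls,   // 1 go stimulus, 0 no-go stimulus
                          const IntegerVector& block,
                          int n_stimuli,
                          double alpha, double tau_R, double tau_P,
                          double b_R, double b_P, double Q0, double theta,
                          bool keep_trace) {
  const int n = stim.size();
  std::vector<double> q(n_stimuli, Q0);
  IntegerVector resp(n);
  NumericVector outcome(n);
  NumericVector pgo(n);
  NumericMatrix trace = keep_trace ? NumericMatrix(n, n_stimuli) : NumericMatrix(0, 0);
  RNGScope scope;  // draws come from R's RNG so set.seed() governs reproducibility
  for (int t = 0; t < n; ++t) {
    const int s = stim[t];
    const bool probe = block[t] == 1;
    if (keep_trace)
      for (int j = 0; j < n_stimuli; ++j) trace(t, j) = q[j];
    const double p = go_prob(q[s], probe ? b_P : b_R, probe ? tau_P : tau_R);
    pgo[t] = p;
    const int r = unif_rand() < p ? 1 : 0;
    resp[t] = r;
    if (r == 1) {
      if (!probe) {
        outcome[t] = cls[t] == 1 ? 1.0 : -1.0;
        q[s] += alpha * (outcome[t] - q[s]);
      } else {
        outcome[t] = 0.0;
      }
    } else {
      outcome[t] = 0.0;
      q[s] *= theta;
    }
  }
  List out = List::create(_["response"] = resp,
                          _["outcome"] = outcome,
                          _["p_go"] = pgo);
  if (keep_trace) out["q_trace"] = trace;
  return out;
}
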