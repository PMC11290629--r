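#include <Rcpp.h>
using namespace Rcpp;

// Independence Metropolis-Hastings over policies with an online Dirichlet
// estimate of the posterior and an entropy stopping rule.
//
// Draw discipline (kept identical to the pure-R reference in R/sampler.R):
//   step 1:   one uniform (proposal; accepted unconditionally)
//   step n>1: two uniforms (proposal, then acceptance -- drawn even when
//             rho == 1 so the R and C++ paths consume the same stream)
//
// The Dirichlet differential entropy
//   H(eta) = ln B(eta) + (eta0 - K) psi(eta0) - sum_j (eta_j - 1) psi(eta_j)
// is maintained incrementally: when eta_j -> eta_j + 1,
//   ln B   += log(eta_j) - log(eta0)
//   sumterm += eta_j * psi(eta_j + 1) - (eta_j - 1) * psi(eta_j)
// so each step costs O(log K) (proposal lookup) + O(1) entropy update.

// [[Rcpp::export(name = ".cpp_run_sampler")]]
List cpp_run_sampler(NumericVector prior, NumericVector likelihood,
                     double s, int max_samples, bool record_trace) {
  const int K = prior.size();
  if (K < 1) stop("empty prior");
  if (likelihood.size() != K) stop("prior and likelihood lengths differ");
  double tot = 0.0;
  for (int j = 0; j < K; ++j) {
    if (prior[j] < 0) stop("negative prior mass");
    if (likelihood[j] < 0) stop("negative likelihood");
    tot += prior[j];
  }
  if (tot <= 0) stop("prior has zero mass everywhere");

  const double h_init = -R::lgammafn((double) K);
  const double h_thr = h_init + (h_init - 1.0) * s;

  if (K == 1) {
    return List::create(_["chosen"] = 1, _["n_samples"] = 1,
                        _["capped"] = false, _["h_init"] = h_init,
                        _["h_thr"] = h_thr, _["entropy"] = h_thr,
                        _["counts"] = NumericVector::create(1.0),
                        _["trace"] = R_NilValue);
  }

  std::vector<double> cum(K);
  double acc = 0.0;
  for (int j = 0; j < K; ++j) { acc += prior[j] / tot; cum[j] = acc; }
  cum[K - 1] = 1.0;

  std::vector<double> eta(K, 1.0);
  double eta0 = (double) K;
  double lnB = -R::lgammafn((double) K);  // sum lgamma(1) - lgamma(K)
  double sumterm = 0.0;
  double H = h_init;

  int chain = -1, n = 0;
  bool stopped = false;

  NumericMatrix trace;
  if (record_trace) trace = NumericMatrix(max_samples, 6);

  while (n < max_samples) {
    double u = unif_rand();
    int prop = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (prop >= K) prop = K - 1;
    double rho = 1.0;
    bool accepted = true;
    if (n == 0) {
      chain = prop;  // first draw starts the chain unconditionally
    } else {
      double lprev = likelihood[chain];
      rho = (lprev <= 0.0) ? 1.0 : std::min(likelihood[prop] / lprev, 1.0);
      double u2 = unif_rand();
      accepted = (u2 < rho);
      if (accepted) chain = prop;
    }
    // increment the Dirichlet pseudo count of the current chain entry
    lnB += std::log(eta[chain]) - std::log(eta0);
    sumterm += eta[chain] * R::digamma(eta[chain] + 1.0) -
               (eta[chain] - 1.0) * R::digamma(eta[chain]);
    eta[chain] += 1.0;
    eta0 += 1.0;
    H = lnB + (eta0 - K) * R::digamma(eta0) - sumterm;
    ++n;
    if (record_trace) {
      trace(n - 1, 0) = n;
      trace(n - 1, 1) = prop + 1;
      trace(n - 1, 2) = rho;
      trace(n - 1, 3) = accepted ? 1.0 : 0.0;
      trace(n - 1, 4) = chain + 1;
      trace(n - 1, 5) = H;
    }
    if (H <= h_thr) { stopped = true; break; }
  }

  NumericVector counts(K);
  for (int j = 0; j < K; ++j) counts[j] = eta[j] - 1.0;

  SEXP tr = R_NilValue;
  if (record_trace) {
    NumericMatrix out(n, 6);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 6; ++j) out(i, j) = trace(i, j);
    colnames(out) = CharacterVector::create("step", "proposal", "rho",
                                            "accepted", "chain", "entropy");
    tr = out;
  }

  return List::create(_["chosen"] = chain + 1, _["n_samples"] = n,
                      _["capped"] = !stopped, _["h_init"] = h_init,
                      _["h_thr"] = h_thr, _["entropy"] = H,
                      _["counts"] = counts, _["trace"] = tr);
}
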