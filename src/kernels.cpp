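// Monte Carlo kernels for primacy-coding simulations.
//
// All randomness goes through R's RNG so that set.seed() in R controls
// every draw.  Receptor sensitivities are redrawn for every trial
// (ensemble averages over sensitivity matrices); ligand identities are
// exchangeable under that ensemble, so only the number of present
// ligands and their concentrations matter for pattern statistics.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

namespace {

inline double rlognorm(double meanlog, double sdlog) {
  return std::exp(R::rnorm(meanlog, sdlog));
}

// Indices of the k largest entries of e, ties broken by lower index.
inline void top_k(const std::vector<double>& e, int k, std::vector<int>& idx) {
  const int n = static_cast<int>(e.size());
  idx.resize(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                    [&e](int a, int b) {
                      if (e[a] != e[b]) return e[a] > e[b];
                      return a < b;
                    });
}

}  // namespace

// Sample primacy-set bit patterns under the odor environment.
// Returns one integer code per sample: bit n (0-based) is set iff
// receptor n belongs to the primacy set.  Requires n_receptors <= 30.
// xi holds the fixed per-receptor sensitivity factors of the array.
// Samples with zero present ligands are redrawn; the count of redraws
// is attached as attribute "n_resampled".
// [[Rcpp::export]]
IntegerVector cpp_primacy_pattern_codes(int n_samples, int n_receptors,
                                        int n_primacy, int n_ligands,
                                        double presence_prob,
                                        double conc_meanlog, double conc_sdlog,
                                        NumericVector xi,
                                        double sens_meanlog,
                                        double sens_sdlog) {
  if (n_receptors > 30) stop("pattern codes support at most 30 receptor types");
  if (n_primacy < 1 || n_primacy > n_receptors) stop("invalid primacy dimension");
  if (presence_prob <= 0.0) stop("presence probability must be positive");

  IntegerVector codes(n_samples);
  std::vector<double> e(n_receptors);
  std::vector<int> idx;
  double n_resampled = 0.0;

  for (int t = 0; t < n_samples; ++t) {
    int k = 0;
    while ((k = static_cast<int>(R::rbinom(n_ligands, presence_prob))) == 0)
      n_resampled += 1.0;
    std::fill(e.begin(), e.end(), 0.0);
    for (int j = 0; j < k; ++j) {
      const double c = rlognorm(conc_meanlog, conc_sdlog);
      for (int n = 0; n < n_receptors; ++n)
        e[n] += c * rlognorm(sens_meanlog, sens_sdlog);
    }
    for (int n = 0; n < n_receptors; ++n) e[n] *= xi[n];
    top_k(e, n_primacy, idx);
    int code = 0;
    for (int r = 0; r < n_primacy; ++r) code |= (1 << idx[r]);
    codes[t] = code;
    if (t % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  codes.attr("n_resampled") = n_resampled;
  return codes;
}

// Hamming distances between the primacy sets of two odors sharing one
// ligand index space.  conc_a / conc_b give the (fixed) concentration of
// each ligand in the two odors; a fresh sensitivity column is drawn per
// ligand and trial.  family: 0 = log-normal(sens_meanlog, sens_sdlog),
// 1 = log-uniform on [sens_log_lo, sens_log_hi].  If jitter is true,
// every ligand concentration is multiplied by a per-trial log-normal
// factor (shared between the two odors, since it is the same ligand).
// [[Rcpp::export]]
IntegerVector cpp_discrimination_distances(int n_trials, int n_receptors,
                                           int n_primacy,
                                           NumericVector conc_a,
                                           NumericVector conc_b,
                                           int family,
                                           double sens_meanlog,
                                           double sens_sdlog,
                                           double sens_log_lo,
                                           double sens_log_hi,
                                           double jitter_meanlog,
                                           double jitter_sdlog,
                                           bool jitter) {
  const int n_lig = conc_a.size();
  if (conc_b.size() != n_lig) stop("concentration vectors differ in length");
  if (n_primacy < 1 || n_primacy > n_receptors) stop("invalid primacy dimension");

  IntegerVector dist(n_trials);
  std::vector<double> e1(n_receptors), e2(n_receptors);
  std::vector<int> idx;
  std::vector<char> in1(n_receptors);

  for (int t = 0; t < n_trials; ++t) {
    std::fill(e1.begin(), e1.end(), 0.0);
    std::fill(e2.begin(), e2.end(), 0.0);
    for (int i = 0; i < n_lig; ++i) {
      double ca = conc_a[i], cb = conc_b[i];
      if (ca == 0.0 && cb == 0.0) continue;
      if (jitter) {
        const double f = rlognorm(jitter_meanlog, jitter_sdlog);
        ca *= f;
        cb *= f;
      }
      for (int n = 0; n < n_receptors; ++n) {
        const double s = (family == 0)
                             ? rlognorm(sens_meanlog, sens_sdlog)
                             : std::exp(R::runif(sens_log_lo, sens_log_hi));
        e1[n] += s * ca;
        e2[n] += s * cb;
      }
    }
    top_k(e1, n_primacy, idx);
    std::fill(in1.begin(), in1.end(), 0);
    for (int r = 0; r < n_primacy; ++r) in1[idx[r]] = 1;
    top_k(e2, n_primacy, idx);
    int shared = 0;
    for (int r = 0; r < n_primacy; ++r) shared += in1[idx[r]];
    dist[t] = 2 * (n_primacy - shared);
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return dist;
}

// Trials for the coding-scheme comparison: a background mixture of
// mixture_size ligands, all at concentration 1, plus one added ligand at
// concentration 1 (sigma = 0).  For each trial the activity pattern of
// the background and the perturbed odor is computed under primacy,
// binary (fixed threshold gamma_bin) and normalized (threshold
// alpha_norm * mean excitation) coding.  Columns of the result:
// primacy_changed, binary_changed, normalized_changed, primacy_active,
// binary_active, normalized_active (active counts for the background).
// [[Rcpp::export]]
NumericMatrix cpp_scheme_trials(int n_trials, int n_receptors, int n_primacy,
                                int mixture_size, double gamma_bin,
                                double alpha_norm, double sens_meanlog,
                                double sens_sdlog) {
  NumericMatrix out(n_trials, 6);
  std::vector<double> eb(n_receptors), e2(n_receptors);
  std::vector<int> idx;
  std::vector<char> in1(n_receptors);

  for (int t = 0; t < n_trials; ++t) {
    std::fill(eb.begin(), eb.end(), 0.0);
    for (int i = 0; i < mixture_size; ++i)
      for (int n = 0; n < n_receptors; ++n)
        eb[n] += rlognorm(sens_meanlog, sens_sdlog);
    double mb = 0.0, m2 = 0.0;
    for (int n = 0; n < n_receptors; ++n) {
      e2[n] = eb[n] + rlognorm(sens_meanlog, sens_sdlog);
      mb += eb[n];
      m2 += e2[n];
    }
    mb /= n_receptors;
    m2 /= n_receptors;

    // primacy
    top_k(eb, n_primacy, idx);
    std::fill(in1.begin(), in1.end(), 0);
    for (int r = 0; r < n_primacy; ++r) in1[idx[r]] = 1;
    top_k(e2, n_primacy, idx);
    int shared = 0;
    for (int r = 0; r < n_primacy; ++r) shared += in1[idx[r]];
    out(t, 0) = (shared < n_primacy) ? 1.0 : 0.0;
    out(t, 3) = n_primacy;

    // binary and normalized
    int bin_b = 0, nrm_b = 0;
    bool bin_chg = false, nrm_chg = false;
    const double thr_b = alpha_norm * mb, thr_2 = alpha_norm * m2;
    for (int n = 0; n < n_receptors; ++n) {
      const bool b1 = eb[n] > gamma_bin, b2 = e2[n] > gamma_bin;
      const bool v1 = eb[n] > thr_b, v2 = e2[n] > thr_2;
      bin_b += b1;
      nrm_b += v1;
      if (b1 != b2) bin_chg = true;
      if (v1 != v2) nrm_chg = true;
    }
    out(t, 1) = bin_chg ? 1.0 : 0.0;
    out(t, 2) = nrm_chg ? 1.0 : 0.0;
    out(t, 4) = bin_b;
    out(t, 5) = nrm_b;
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
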