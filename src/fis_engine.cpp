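#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shannon entropy (natural log) of an unnormalized non-negative vector is NOT
// computed here; all entropies below act on already-normalized probabilities.
static inline double entropy_of(const std::vector<double>& p) {
  double h = 0.0;
  for (double v : p) if (v > 0.0) h -= v * std::log(v);
  return h;
}

// Workspace for one feature index set: control-side summaries reused by every case.
struct SetSummary {
  std::vector<double> mbar;   // uniform mixture of control distributions
  double mean_h;              // mean control entropy
  double i_controls;          // I-index of the control set alone
};

// Restrict the control matrix to `idx`, add the pseudocount, renormalize rows,
// and compute the control-only generalized Jensen-Shannon overlap.
static void summarize_controls(const NumericMatrix& ctrl,
                               const std::vector<int>& idx,
                               double pc, SetSummary& out) {
  const int n0 = ctrl.nrow();
  const int m = (int) idx.size();
  out.mbar.assign(m, 0.0);
  double mean_h = 0.0;
  std::vector<double> row(m);
  for (int i = 0; i < n0; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) {
      double x = ctrl(i, idx[k]) + pc;
      row[k] = x;
      s += x;
    }
    double hi = 0.0;
    for (int k = 0; k < m; ++k) {
      double p = row[k] / s;
      out.mbar[k] += p;
      if (p > 0.0) hi -= p * std::log(p);
    }
    mean_h += hi;
  }
  const double inv_n0 = 1.0 / n0;
  for (int k = 0; k < m; ++k) out.mbar[k] *= inv_n0;
  out.mean_h = mean_h * inv_n0;
  double h_mix = entropy_of(out.mbar);
  out.i_controls = 1.0 - (h_mix - out.mean_h) / std::log((double) n0);
}

// d(case; controls) = I(controls) - I(controls + case), all restricted to idx,
// for every case row at once.
static void set_distances(const NumericMatrix& cases,
                          const std::vector<int>& idx,
                          double pc, int n0, const SetSummary& cs,
                          std::vector<double>& out) {
  const int nc = cases.nrow();
  const int m = (int) idx.size();
  const double log_n1 = std::log((double) (n0 + 1));
  std::vector<double> p(m), mix(m);
  for (int c = 0; c < nc; ++c) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) {
      double x = cases(c, idx[k]) + pc;
      p[k] = x;
      s += x;
    }
    double hc = 0.0;
    for (int k = 0; k < m; ++k) {
      double v = p[k] / s;
      p[k] = v;
      if (v > 0.0) hc -= v * std::log(v);
      mix[k] = (n0 * cs.mbar[k] + v) / (n0 + 1);
    }
    double h_mix = entropy_of(mix);
    double mean_h = (n0 * cs.mean_h + hc) / (n0 + 1);
    double i_all = 1.0 - (h_mix - mean_h) / log_n1;
    out[c] = cs.i_controls - i_all;
  }
}

//' Batch FIS evaluation over sampled feature subsets (internal engine).
//'
//' For every subset J and every feature j in J, the FIS of j for each case is
//' d(case; controls | J) - d(case; controls | J \ j). Values are pooled per
//' (case, feature) and summarized as medians.
//'
//' @noRd
// [[Rcpp::export(name = ".fis_engine_medians")]]
List fis_engine_medians(NumericMatrix ctrl, NumericMatrix cases,
                        IntegerMatrix subsets, double pseudocount) {
  const int n0 = ctrl.nrow();
  const int nc = cases.nrow();
  const int K = ctrl.ncol();
  const int M = subsets.nrow();
  const int m = subsets.ncol();
  if (cases.ncol() != K) stop("case and control matrices must share columns");
  if (m < 2) stop("subset size must be at least 2");
  if (n0 < 2) stop("need at least 2 controls");

  // per (case, feature) pooled FIS values
  std::vector< std::vector<double> > pool((size_t) nc * K);
  std::vector<int> n_evals(K, 0);

  std::vector<int> idx(m), sub_idx(m - 1);
  std::vector<double> d_full(nc), d_sub(nc);
  SetSummary cs_full, cs_sub;

  for (int s = 0; s < M; ++s) {
    for (int k = 0; k < m; ++k) {
      int f = subsets(s, k);
      if (f < 0 || f >= K) stop("subset feature index out of range");
      idx[k] = f;
    }
    summarize_controls(ctrl, idx, pseudocount, cs_full);
    set_distances(cases, idx, pseudocount, n0, cs_full, d_full);
    for (int k = 0; k < m; ++k) {
      int j = idx[k];
      int t = 0;
      for (int q = 0; q < m; ++q) if (q != k) sub_idx[t++] = idx[q];
      summarize_controls(ctrl, sub_idx, pseudocount, cs_sub);
      set_distances(cases, sub_idx, pseudocount, n0, cs_sub, d_sub);
      for (int c = 0; c < nc; ++c)
        pool[(size_t) c * K + j].push_back(d_full[c] - d_sub[c]);
      n_evals[j] += 1;
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix med(nc, K);
  for (int c = 0; c < nc; ++c) {
    for (int j = 0; j < K; ++j) {
      std::vector<double>& v = pool[(size_t) c * K + j];
      if (v.empty()) {
        med(c, j) = NA_REAL;
      } else {
        size_t n = v.size();
        size_t h = n / 2;
        std::nth_element(v.begin(), v.begin() + h, v.end());
        double hi = v[h];
        if (n % 2 == 1) {
          med(c, j) = hi;
        } else {
          double lo = *std::max_element(v.begin(), v.begin() + h);
          med(c, j) = 0.5 * (lo + hi);
        }
      }
    }
  }
  return List::create(_["medians"] = med,
                      _["n_evals"] = IntegerVector(n_evals.begin(), n_evals.end()));
}
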