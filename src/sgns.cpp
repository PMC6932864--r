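// Skip-gram negative-sampling epoch for Gene2Vec.
//
// Embeddings are passed transposed (d x n, one contiguous column per gene).
// Mini-batch SGD: per-pair gradients are computed against the parameters
// frozen at the start of the batch, accumulated, and applied as one step.
// Negatives are drawn through R's RNG so a set.seed() in R makes the whole
// sweep deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export(name = ".sgns_epoch")]]
double sgns_epoch(NumericMatrix Win_t, NumericMatrix Wout_t,
                  IntegerVector center, IntegerVector context,
                  NumericVector neg_cdf, int n_negative, double lr,
                  int batch_size) {
  const int d = Win_t.nrow();
  const int n = Win_t.ncol();
  const R_xlen_t np = center.size();
  double *win = REAL(Win_t);
  double *wout = REAL(Wout_t);
  const double *cdf = REAL(neg_cdf);

  std::vector<double> dwin((size_t)d * n, 0.0), dwout((size_t)d * n, 0.0);
  std::vector<int> touched_in, touched_out;
  std::vector<char> flag_in(n, 0), flag_out(n, 0);
  touched_in.reserve(2 * batch_size);
  touched_out.reserve(2 * batch_size * (1 + n_negative));

  double loss = 0.0;

  auto accumulate = [&](int c, int t, double label) {
    const double *wc = win + (size_t)c * d;
    const double *wt = wout + (size_t)t * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += wc[j] * wt[j];
    double p = sigmoid(s);
    double g = p - label;
    loss -= std::log(std::max(label == 1.0 ? p : 1.0 - p, 1e-12));
    double *gc = dwin.data() + (size_t)c * d;
    double *gt = dwout.data() + (size_t)t * d;
    for (int j = 0; j < d; ++j) {
      gc[j] += g * wt[j];
      gt[j] += g * wc[j];
    }
    if (!flag_in[c]) { flag_in[c] = 1; touched_in.push_back(c); }
    if (!flag_out[t]) { flag_out[t] = 1; touched_out.push_back(t); }
  };

  auto apply = [&]() {
    for (int c : touched_in) {
      double *w = win + (size_t)c * d;
      double *g = dwin.data() + (size_t)c * d;
      for (int j = 0; j < d; ++j) { w[j] -= lr * g[j]; g[j] = 0.0; }
      flag_in[c] = 0;
    }
    for (int t : touched_out) {
      double *w = wout + (size_t)t * d;
      double *g = dwout.data() + (size_t)t * d;
      for (int j = 0; j < d; ++j) { w[j] -= lr * g[j]; g[j] = 0.0; }
      flag_out[t] = 0;
    }
    touched_in.clear();
    touched_out.clear();
  };

  for (R_xlen_t i = 0; i < np; ++i) {
    int c = center[i] - 1;
    int o = context[i] - 1;
    accumulate(c, o, 1.0);
    for (int k = 0; k < n_negative; ++k) {
      double u = unif_rand();
      int t = (int)(std::upper_bound(cdf, cdf + n, u) - cdf);
      if (t >= n) t = n - 1;
      accumulate(c, t, 0.0);
    }
    if ((i + 1) % batch_size == 0 || i == np - 1) apply();
  }
  return loss / (double)np;
}
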