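#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// adjacency is CSR over sorted 0-based neighbor ids
static inline bool has_edge(const IntegerVector& nb, const IntegerVector& ptr,
                            int u, int v) {
  const int* beg = nb.begin() + ptr[u];
  const int* end = nb.begin() + ptr[u + 1];
  return std::binary_search(beg, end, v);
}

// Second-order biased random walks (return parameter p, in-out parameter q).
// Returns a matrix with one walk per row, 0-based node ids.
// [[Rcpp::export]]
IntegerMatrix node2vec_walks_cpp(IntegerVector nb, IntegerVector ptr,
                                 double p, double q, int walk_length,
                                 int walks_per_node, int seed) {
  const int m = ptr.size() - 1;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  IntegerMatrix walks(m * walks_per_node, walk_length);
  std::vector<double> w;
  int row = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < m; ++start, ++row) {
      int prev = -1, cur = start;
      walks(row, 0) = cur;
      for (int step = 1; step < walk_length; ++step) {
        int deg = ptr[cur + 1] - ptr[cur];
        if (deg == 0) { // isolated node: stay (connected graphs never hit this)
          walks(row, step) = cur;
          continue;
        }
        int nxt;
        if (prev < 0 || (p == 1.0 && q == 1.0)) {
          nxt = nb[ptr[cur] + static_cast<int>(unif(rng) * deg) % deg];
        } else {
          w.resize(deg);
          double tot = 0.0;
          for (int j = 0; j < deg; ++j) {
            int x = nb[ptr[cur] + j];
            double wt = (x == prev) ? 1.0 / p
                       : (has_edge(nb, ptr, prev, x) ? 1.0 : 1.0 / q);
            w[j] = wt;
            tot += wt;
          }
          double r = unif(rng) * tot, acc = 0.0;
          nxt = nb[ptr[cur]];
          for (int j = 0; j < deg; ++j) {
            acc += w[j];
            if (r <= acc) { nxt = nb[ptr[cur] + j]; break; }
          }
        }
        walks(row, step) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

// Skip-gram with negative sampling over a walk corpus (0-based node ids).
// Linear learning-rate decay, dynamic window as in word2vec, unigram^0.75
// negative-sampling table. Returns the input-vector matrix (m x dim).
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(IntegerMatrix walks, int m, int dim, int window,
                             int negative, int epochs, double alpha0,
                             int seed) {
  const int n_walks = walks.nrow(), wl = walks.ncol();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // unigram^(3/4) cumulative table for negative sampling
  std::vector<double> cnt(m, 0.0);
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < wl; ++j) cnt[walks(i, j)] += 1.0;
  std::vector<double> cum(m);
  double tot = 0.0;
  for (int v = 0; v < m; ++v) { tot += std::pow(cnt[v], 0.75); cum[v] = tot; }
  auto draw_neg = [&]() {
    double r = unif(rng) * tot;
    return static_cast<int>(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
  };

  std::vector<double> in(static_cast<size_t>(m) * dim), out(static_cast<size_t>(m) * dim, 0.0);
  for (auto& v : in) v = (unif(rng) - 0.5) / dim;

  const double total_steps = static_cast<double>(epochs) * n_walks * wl;
  double done = 0.0;
  std::vector<double> grad(dim);
  std::vector<int> walk(wl);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walks; ++i) {
      for (int j = 0; j < wl; ++j) walk[j] = walks(i, j);
      for (int j = 0; j < wl; ++j, done += 1.0) {
        double alpha = alpha0 * std::max(1.0 - done / total_steps, 1e-4);
        int center = walk[j];
        int b = 1 + static_cast<int>(unif(rng) * window) % window; // dynamic window
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int jj = j + off;
          if (jj < 0 || jj >= wl) continue;
          int ctx = walk[jj];
          double* vin = &in[static_cast<size_t>(ctx) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = center; label = 1.0; }
            else {
              target = draw_neg();
              if (target == center) continue;
              label = 0.0;
            }
            double* vout = &out[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int t = 0; t < dim; ++t) dot += vin[t] * vout[t];
            double g = (label - 1.0 / (1.0 + std::exp(-dot))) * alpha;
            for (int t = 0; t < dim; ++t) {
              grad[t] += g * vout[t];
              vout[t] += g * vin[t];
            }
          }
          for (int t = 0; t < dim; ++t) vin[t] += grad[t];
        }
      }
    }
  }
  NumericMatrix res(m, dim);
  for (int v = 0; v < m; ++v)
    for (int t = 0; t < dim; ++t) res(v, t) = in[static_cast<size_t>(v) * dim + t];
  return res;
}
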