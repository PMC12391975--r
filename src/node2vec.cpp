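// Hot loops for biased random walks and skip-gram training.
// All randomness comes from a local xorshift64* stream seeded explicitly,
// so results are bit-reproducible and independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    // splitmix64 scramble so small seeds give well-mixed streams
    s = seed + 0x9E3779B97F4A7C15ULL;
    s = (s ^ (s >> 30)) * 0xBF58476D1CE4E5B9ULL;
    s = (s ^ (s >> 27)) * 0x94D049BB133111EBULL;
    s = s ^ (s >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint64_t below(uint64_t n) { return next() % n; }
};

bool contains_sorted(const std::vector<int>& v, int x) {
  int lo = 0, hi = (int)v.size() - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (v[mid] == x) return true;
    if (v[mid] < x) lo = mid + 1; else hi = mid - 1;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_generate_walks(List neighbors, List weights,
                                 double p, double q,
                                 int walks_per_node, int walk_length,
                                 int seed) {
  int n = neighbors.size();
  std::vector<std::vector<int>> nbr(n);
  std::vector<std::vector<double>> wts(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ni = neighbors[i];
    NumericVector wi = weights[i];
    nbr[i].assign(ni.begin(), ni.end());   // 1-based, sorted
    for (auto& v : nbr[i]) v -= 1;         // to 0-based
    wts[i].assign(wi.begin(), wi.end());
  }
  Rng rng((uint64_t)(uint32_t)seed);
  IntegerMatrix walks(n * walks_per_node, walk_length);
  std::fill(walks.begin(), walks.end(), -1);
  std::vector<double> cum;

  int row = 0;
  for (int start = 0; start < n; ++start) {
    for (int w = 0; w < walks_per_node; ++w, ++row) {
      int curr = start, prev = -1;
      walks(row, 0) = curr;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int>& nb = nbr[curr];
        if (nb.empty()) break;  // stranded: truncate
        size_t m = nb.size();
        cum.resize(m);
        double tot = 0.0;
        if (prev < 0) {
          for (size_t k = 0; k < m; ++k) { tot += wts[curr][k]; cum[k] = tot; }
        } else {
          const std::vector<int>& tn = nbr[prev];
          for (size_t k = 0; k < m; ++k) {
            int x = nb[k];
            double a;
            if (x == prev) a = 1.0 / p;
            else if (contains_sorted(tn, x)) a = 1.0;
            else a = 1.0 / q;
            tot += a * wts[curr][k];
            cum[k] = tot;
          }
        }
        double u = rng.unif() * tot;
        size_t k = 0;
        while (k + 1 < m && cum[k] <= u) ++k;
        prev = curr;
        curr = nb[k];
        walks(row, step) = curr;
      }
    }
  }
  return walks;
}

// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(IntegerMatrix walks, int n_nodes, int dim,
                             int window, int negative, int epochs,
                             double alpha0, int seed) {
  const int TABLE_SIZE = 1 << 17;
  const int SIG_SIZE = 2048;
  const double SIG_MAX = 6.0;
  Rng rng((uint64_t)(uint32_t)seed);

  // precomputed logistic table on [-SIG_MAX, SIG_MAX]
  std::vector<double> sig(SIG_SIZE);
  for (int t = 0; t < SIG_SIZE; ++t) {
    double x = (2.0 * t / (SIG_SIZE - 1) - 1.0) * SIG_MAX;
    sig[t] = 1.0 / (1.0 + std::exp(-x));
  }

  // copy walks into contiguous row-major storage
  const int nw = walks.nrow(), wl = walks.ncol();
  std::vector<int> W((size_t)nw * wl);
  for (int i = 0; i < nw; ++i)
    for (int j = 0; j < wl; ++j) W[(size_t)i * wl + j] = walks(i, j);

  // unigram^0.75 negative-sampling table from corpus frequencies
  std::vector<double> counts(n_nodes, 0.0);
  long long total_tokens = 0;
  for (size_t k = 0; k < W.size(); ++k)
    if (W[k] >= 0) { counts[W[k]] += 1.0; ++total_tokens; }
  std::vector<int> table(TABLE_SIZE);
  {
    double z = 0.0;
    for (int v = 0; v < n_nodes; ++v) z += std::pow(counts[v], 0.75);
    if (z <= 0) z = 1.0;
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / z;
    for (int t = 0; t < TABLE_SIZE; ++t) {
      table[t] = v;
      if ((t + 1.0) / TABLE_SIZE > cum && v < n_nodes - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / z;
      }
    }
  }

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (auto& x : syn0) x = (rng.unif() - 0.5) / dim;

  std::vector<double> grad(dim);
  long long processed = 0;
  const long long plan = (long long)epochs * total_tokens;
  const double min_alpha = alpha0 * 1e-4;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < nw; ++i) {
      const int* row = &W[(size_t)i * wl];
      for (int j = 0; j < wl; ++j) {
        int center = row[j];
        if (center < 0) break;
        double alpha = alpha0 * (1.0 - (double)processed / (plan + 1));
        if (alpha < min_alpha) alpha = min_alpha;
        ++processed;
        int b = (int)rng.below((uint64_t)window);  // shrunk window
        int lo = j - (window - b); if (lo < 0) lo = 0;
        int hi = j + (window - b); if (hi >= wl) hi = wl - 1;
        for (int cj = lo; cj <= hi; ++cj) {
          if (cj == j) continue;
          int ctx = row[cj];
          if (ctx < 0) continue;
          double* v0 = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target; double label;
            if (d == 0) { target = center; label = 1.0; }
            else {
              target = table[rng.below(TABLE_SIZE)];
              if (target == center) continue;
              label = 0.0;
            }
            double* v1 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v0[k] * v1[k];
            double g;
            if (f > SIG_MAX) g = (label - 1.0) * alpha;
            else if (f < -SIG_MAX) g = label * alpha;
            else g = (label - sig[(int)((f + SIG_MAX) *
                         ((SIG_SIZE - 1) / (2.0 * SIG_MAX)))]) * alpha;
            for (int k = 0; k < dim; ++k) grad[k] += g * v1[k];
            for (int k = 0; k < dim; ++k) v1[k] += g * v0[k];
          }
          for (int k = 0; k < dim; ++k) v0[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
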