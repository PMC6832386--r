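// Random-walk samplers.  Transition kernels are defined (and unit-tested)
// in R; this file only samples from them, with one deterministic random
// stream per walk derived from (seed, subnetwork, start node, walk index)
// so corpora are reproducible and independent of generation order.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct WalkRng {
  uint64_t state;
  WalkRng(uint64_t seed, uint64_t subnet, uint64_t start, uint64_t widx) {
    uint64_t x = seed;
    state = splitmix64(x);
    x = state ^ (subnet * 0x9E3779B97F4A7C15ULL);
    state = splitmix64(x);
    x = state ^ (start * 0xC2B2AE3D27D4EB4FULL);
    state = splitmix64(x);
    x = state ^ (widx * 0x165667B19E3779F9ULL);
    state = splitmix64(x);
  }
  double unif() {
    return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Sample index proportional to score[0..n); returns -1 when total mass is 0.
static inline int sampleProp(const double *score, int n, double total,
                             WalkRng &rng) {
  if (total <= 0.0) return -1;
  double u = rng.unif() * total, cum = 0.0;
  int last = -1;
  for (int i = 0; i < n; ++i) {
    if (score[i] <= 0.0) continue;
    cum += score[i];
    last = i;
    if (u < cum) return i;
  }
  return last;  // guard against rounding at the top end
}

// First-order walks from a precomputed n x n kernel (rows sum to 1 or 0).
// [[Rcpp::export]]
List cpp_walk_first_order(NumericMatrix K, IntegerVector starts, int len,
                          int seed, int subnet, IntegerVector widx) {
  const int n = K.ncol(), nw = starts.size();
  List out(nw);
  std::vector<double> row(n);
  for (int w = 0; w < nw; ++w) {
    WalkRng rng((uint64_t)(uint32_t)seed, (uint64_t)subnet,
                (uint64_t)(starts[w] + 1), (uint64_t)widx[w]);
    std::vector<int> path;
    path.reserve(len);
    int cur = starts[w];
    path.push_back(cur + 1);
    while ((int)path.size() < len) {
      double tot = 0.0;
      for (int h = 0; h < n; ++h) { row[h] = K(cur, h); tot += row[h]; }
      int nxt = sampleProp(row.data(), n, tot, rng);
      if (nxt < 0) break;  // dead end terminates the walk early
      cur = nxt;
      path.push_back(cur + 1);
    }
    out[w] = IntegerVector(path.begin(), path.end());
  }
  return out;
}

// Second-order BFS/DFS-biased walks on a dense nonnegative weight matrix:
// neighbor h of current node s scores alpha*w(s,h) when h is adjacent to
// the previous node t or equals t, beta*w(s,h) otherwise; first step is
// weight-proportional.
// [[Rcpp::export]]
List cpp_walk_second_order(NumericMatrix W, IntegerVector starts, int len,
                           double alpha, double beta, int seed, int subnet,
                           IntegerVector widx) {
  const int n = W.ncol(), nw = starts.size();
  List out(nw);
  std::vector<double> score(n);
  for (int w = 0; w < nw; ++w) {
    WalkRng rng((uint64_t)(uint32_t)seed, (uint64_t)subnet,
                (uint64_t)(starts[w] + 1), (uint64_t)widx[w]);
    std::vector<int> path;
    path.reserve(len);
    int prev = -1, cur = starts[w];
    path.push_back(cur + 1);
    while ((int)path.size() < len) {
      double tot = 0.0;
      for (int h = 0; h < n; ++h) {
        double wsh = W(cur, h);
        if (wsh <= 0.0) { score[h] = 0.0; continue; }
        double b = 1.0;
        if (prev >= 0) b = (W(prev, h) != 0.0 || h == prev) ? alpha : beta;
        score[h] = b * wsh;
        tot += score[h];
      }
      int nxt = sampleProp(score.data(), n, tot, rng);
      if (nxt < 0) break;
      prev = cur;
      cur = nxt;
      path.push_back(cur + 1);
    }
    out[w] = IntegerVector(path.begin(), path.end());
  }
  return out;
}

// Exact second-order kernel row as the sampler sees it (renormalized);
// exposed for cross-checking against the R reference kernel.
// [[Rcpp::export]]
NumericVector cpp_unsigned_kernel_row(NumericMatrix W, int prev, int cur,
                                      double alpha, double beta) {
  const int n = W.ncol();
  NumericVector score(n);
  double tot = 0.0;
  for (int h = 0; h < n; ++h) {
    double wsh = W(cur, h);
    if (wsh <= 0.0) continue;
    double b = 1.0;
    if (prev >= 0) b = (W(prev, h) != 0.0 || h == prev) ? alpha : beta;
    score[h] = b * wsh;
    tot += score[h];
  }
  if (tot > 0) for (int h = 0; h < n; ++h) score[h] /= tot;
  return score;
}
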