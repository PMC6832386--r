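// Skip-gram with negative sampling, single-threaded SGD over an
// integer-coded walk corpus.  Deliberately minimal: fixed symmetric
// window that never crosses walk boundaries, unigram^0.75 noise
// distribution, linearly decaying learning rate, and one private RNG so
// training is bitwise reproducible for a fixed seed.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double rngUnif(uint64_t &s) {
  return (splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// Precomputed sigmoid and log-sigmoid over [-MAX_EXP, MAX_EXP], the
// standard word2vec device; outside the range the gradient is clipped to
// the saturated value.
#define EXP_TABLE_SIZE 4096
#define MAX_EXP 8.0
struct SigTables {
  double sig[EXP_TABLE_SIZE], logsig[EXP_TABLE_SIZE];
  SigTables() {
    for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
      double x = (2.0 * i / (EXP_TABLE_SIZE - 1) - 1.0) * MAX_EXP;
      sig[i] = 1.0 / (1.0 + std::exp(-x));
      logsig[i] = std::log(sig[i]);
    }
  }
};
static const SigTables tables;

static inline int sigIndex(double x) {
  if (x >= MAX_EXP) return EXP_TABLE_SIZE - 1;
  if (x <= -MAX_EXP) return 0;
  return (int)((x / MAX_EXP + 1.0) * 0.5 * (EXP_TABLE_SIZE - 1));
}

// [[Rcpp::export]]
List cpp_train_skipgram(List corpus, int vocab, int dim, int window,
                        int epochs, int negative, double lr, int seed) {
  const int V = vocab, D = dim;
  std::vector<std::vector<int>> walks;
  walks.reserve(corpus.size());
  std::vector<double> counts(V, 0.0);
  long long totalCenters = 0;
  for (int i = 0; i < corpus.size(); ++i) {
    IntegerVector w = corpus[i];
    std::vector<int> wk(w.begin(), w.end());
    for (int t : wk) counts[t] += 1.0;
    if ((int)wk.size() >= 2) totalCenters += wk.size();
    walks.push_back(std::move(wk));
  }

  // unigram^0.75 noise table
  const int TBL = 1 << 17;
  std::vector<int> noise(TBL);
  {
    std::vector<double> pw(V);
    double z = 0.0;
    for (int v = 0; v < V; ++v) { pw[v] = std::pow(counts[v], 0.75); z += pw[v]; }
    if (z <= 0.0) z = 1.0;
    double cum = pw[0] / z;
    int v = 0;
    for (int i = 0; i < TBL; ++i) {
      noise[i] = v;
      if ((i + 1.0) / TBL > cum && v < V - 1) { ++v; cum += pw[v] / z; }
    }
  }

  uint64_t rs = (uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL;
  std::vector<double> syn0((size_t)V * D), syn1((size_t)V * D, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rngUnif(rs) - 0.5) / D;

  std::vector<double> grad(D);
  NumericVector lossByEpoch(epochs);
  const long long budget = std::max(1LL, totalCenters * epochs);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    long long pairs = 0;
    for (const auto &wk : walks) {
      const int L = (int)wk.size();
      if (L < 2) continue;
      for (int i = 0; i < L; ++i) {
        double eta = lr * std::max(1.0 - (double)processed / budget, 1e-4);
        ++processed;
        const int center = wk[i];
        double *v0 = &syn0[(size_t)center * D];
        for (int c = std::max(0, i - window);
             c <= std::min(L - 1, i + window); ++c) {
          if (c == i) continue;
          const int ctx = wk[c];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = ctx; label = 1.0; }
            else {
              target = noise[(int)(rngUnif(rs) * TBL)];
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v1 = &syn1[(size_t)target * D];
            double f = 0.0;
            for (int d = 0; d < D; ++d) f += v0[d] * v1[d];
            const int si = sigIndex(f);
            double s = tables.sig[si];
            // -log sigma(f) for the positive, -log sigma(-f) for noise
            loss -= (label > 0.5) ? tables.logsig[si]
                                  : tables.logsig[EXP_TABLE_SIZE - 1 - si];
            double g = (label - s) * eta;
            for (int d = 0; d < D; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < D; ++d) v0[d] += grad[d];
          ++pairs;
        }
      }
    }
    lossByEpoch[ep] = pairs > 0 ? loss / pairs : NA_REAL;
  }

  NumericMatrix emb(V, D);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < D; ++d)
      emb(v, d) = syn0[(size_t)v * D + d];
  return List::create(_["vectors"] = emb, _["lossByEpoch"] = lossByEpoch);
}
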