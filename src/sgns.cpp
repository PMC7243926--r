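#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// deterministic xorshift64* generator so training is reproducible and
// independent of R's RNG state
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// Skip-gram with negative sampling, single-threaded SGD.
// tokens: 0-based vocabulary ids of the merged training stream.
// counts: per-id corpus frequencies (for the unigram^0.75 noise distribution).
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(IntegerVector tokens, IntegerVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha0, double min_alpha, int seed) {
  const int64_t n = tokens.size();
  const int vocab = counts.size();
  if (n < 2 || vocab < 1) stop("training stream too small");

  uint64_t rng = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(seed * 2654435761U + 1U);
  for (int i = 0; i < 8; ++i) xorshift64(rng);

  std::vector<float> syn0((size_t)vocab * dim);
  std::vector<float> syn1((size_t)vocab * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((runif01(rng) - 0.5) / dim);

  // precomputed sigmoid table, word2vec-style
  const int EXP_TABLE_SIZE = 1000;
  const float MAX_EXP = 6.0f;
  std::vector<float> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    float e = std::exp((i / (float)EXP_TABLE_SIZE * 2.0f - 1.0f) * MAX_EXP);
    expTable[i] = e / (e + 1.0f);
  }

  // unigram^0.75 sampling table (O(1) draws)
  const int TABLE_SIZE = 1 << 20;
  std::vector<int> negTable(TABLE_SIZE);
  {
    double tot = 0.0;
    for (int v = 0; v < vocab; ++v) tot += std::pow((double)counts[v], 0.75);
    int v = 0;
    double acc = std::pow((double)counts[0], 0.75) / tot;
    for (int i = 0; i < TABLE_SIZE; ++i) {
      negTable[i] = v;
      if ((double)(i + 1) / TABLE_SIZE > acc && v < vocab - 1) {
        ++v;
        acc += std::pow((double)counts[v], 0.75) / tot;
      }
    }
  }

  const int64_t total_pairs = (int64_t)epochs * n;
  int64_t processed = 0;
  std::vector<float> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int64_t i = 0; i < n; ++i, ++processed) {
      double alpha = alpha0 * (1.0 - (double)processed / (double)(total_pairs + 1));
      if (alpha < min_alpha) alpha = min_alpha;
      int w = tokens[i];
      int b = (int)(xorshift64(rng) % (uint64_t)window);  // dynamic window
      for (int64_t j = i - window + b; j <= i + window - b; ++j) {
        if (j == i || j < 0 || j >= n) continue;
        int c = tokens[j];
        float * __restrict vw = &syn0[(size_t)w * dim];
        for (int d = 0; d < dim; ++d) grad[d] = 0.0f;
        for (int s = 0; s <= negative; ++s) {
          int target;
          float label;
          if (s == 0) {
            target = c;
            label = 1.0f;
          } else {
            target = negTable[xorshift64(rng) >> 44];  // top 20 bits
            if (target == c) continue;
            label = 0.0f;
          }
          float * __restrict vc = &syn1[(size_t)target * dim];
          float dot = 0.0f;
          for (int d = 0; d < dim; ++d) dot += vw[d] * vc[d];
          float sig;
          if (dot > MAX_EXP) sig = 1.0f;
          else if (dot < -MAX_EXP) sig = 0.0f;
          else sig = expTable[(int)((dot + MAX_EXP) *
                                    (EXP_TABLE_SIZE / MAX_EXP / 2.0f))];
          float g = (float)alpha * (label - sig);
          for (int d = 0; d < dim; ++d) {
            grad[d] += g * vc[d];
            vc[d] += g * vw[d];
          }
        }
        for (int d = 0; d < dim; ++d) vw[d] += grad[d];
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
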