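// Skip-gram with negative sampling (SGNS), single-threaded and seeded so
// that training is bit-reproducible. The inner loop mirrors the classic
// word2vec formulation: for each (center, context) token pair within the
// window, the context vector is pulled toward the center's output vector
// and pushed away from `negative` noise words drawn from the unigram
// distribution raised to the 3/4 power.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShiftRNG {
  uint64_t s;
  explicit XorShiftRNG(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int r = static_cast<int>(unif() * n);
    return r >= n ? n - 1 : r;
  }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// sentences: list of integer vectors of 0-based vocabulary ids.
// counts: vocabulary frequencies (for the negative-sampling table).
// Returns a (vocab_size x dim) matrix of input vectors.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab_size,
                             NumericVector counts, int dim, int window,
                             int epochs, int negative, double alpha,
                             int seed) {
  XorShiftRNG rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // unigram^{3/4} negative-sampling table
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int i = 0; i < vocab_size; ++i) z += std::pow(counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / z;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if (static_cast<double>(t) / table_size > cum && i < vocab_size - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / z;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  long long total_tokens = 0;
  const int n_sent = sentences.size();
  std::vector<IntegerVector> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    sents[s] = sentences[s];
    total_tokens += sents[s].size();
  }
  const double total_steps =
      static_cast<double>(total_tokens) * std::max(epochs, 1);
  long long processed = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const IntegerVector& sent = sents[s];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        const double lr =
            alpha * std::max(1.0 - processed / total_steps, 1e-4);
        ++processed;
        const int center = sent[pos];
        const int lo = pos - window < 0 ? 0 : pos - window;
        const int hi = pos + window >= len ? len - 1 : pos + window;
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          const int context = sent[cpos];
          double* v_in = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = context;
              label = 1.0;
            } else {
              target = table[rng.below(table_size)];
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            const double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i) {
    for (int k = 0; k < dim; ++k) {
      out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
    }
  }
  return out;
}
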