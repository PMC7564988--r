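#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// word2vec-style 64-bit LCG, kept for exact reproducibility of draws
static inline uint64_t lcg(uint64_t &state) {
  state = state * 25214903917ULL + 11ULL;
  return state;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling. Inputs are 0-based token ids.
// When `input_map` is non-empty, it gives, per vocabulary word, the 0-based
// rows of the input matrix that jointly represent the word (its character
// n-grams); the word's input vector is the SUM of those rows. With an empty
// map the input matrix has one row per vocabulary word.
// [[Rcpp::export(name = ".sg_train_cpp")]]
List sg_train_cpp(List sentences, int vocab_size, NumericVector counts,
                  List input_map, int n_inputs, int dim, int window,
                  int negative, int epochs, double alpha0, double downsample,
                  int seed) {
  const bool subword = input_map.size() > 0;
  uint64_t rng = static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL;

  std::vector<double> syn0((size_t)n_inputs * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = ((double)(lcg(rng) >> 16 & 0xFFFF) / 65536.0 - 0.5) / dim;
  }

  // unigram table for negative sampling, 0.75 power
  const int table_size = 1000000;
  std::vector<int> table(table_size);
  double train_words = 0.0, acc = 0.0;
  for (int w = 0; w < vocab_size; ++w) acc += std::pow(counts[w], 0.75);
  {
    int w = 0;
    double cum = std::pow(counts[0], 0.75) / acc;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((double)(i + 1) / table_size > cum && w < vocab_size - 1) {
        ++w;
        cum += std::pow(counts[w], 0.75) / acc;
      }
    }
  }
  for (int w = 0; w < vocab_size; ++w) train_words += counts[w];

  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector iv = sentences[s];
    sents.emplace_back(iv.begin(), iv.end());
  }
  std::vector<std::vector<int>> imap;
  if (subword) {
    imap.reserve(input_map.size());
    for (int w = 0; w < input_map.size(); ++w) {
      IntegerVector iv = input_map[w];
      imap.emplace_back(iv.begin(), iv.end());
    }
  }

  std::vector<double> hidden(dim), grad(dim);
  const double total = train_words * epochs;
  double processed = 0.0;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    for (size_t s = 0; s < sents.size(); ++s) {
      // frequent-word downsampling
      std::vector<int> sen;
      sen.reserve(sents[s].size());
      for (int w : sents[s]) {
        processed += 1.0;
        if (downsample > 0) {
          double f = counts[w] / train_words;
          double keep = (std::sqrt(f / downsample) + 1.0) * downsample / f;
          if (keep < 1.0 &&
              keep < (double)(lcg(rng) >> 16 & 0xFFFF) / 65536.0) {
            continue;
          }
        }
        sen.push_back(w);
      }
      double alpha = alpha0 * (1.0 - processed / (total + 1.0));
      if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;

      for (size_t pos = 0; pos < sen.size(); ++pos) {
        int center = sen[pos];
        int b = (int)(lcg(rng) >> 16) % window;  // reduced window
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = (int)pos + off;
          if (cpos < 0 || cpos >= (int)sen.size()) continue;
          int context = sen[cpos];

          // compose the input vector for the center word
          const std::vector<int> *rows = nullptr;
          if (subword) {
            rows = &imap[center];
            std::fill(hidden.begin(), hidden.end(), 0.0);
            for (int r : *rows) {
              const double *v = &syn0[(size_t)r * dim];
              for (int d = 0; d < dim; ++d) hidden[d] += v[d];
            }
          } else {
            const double *v = &syn0[(size_t)center * dim];
            std::copy(v, v + dim, hidden.begin());
          }
          std::fill(grad.begin(), grad.end(), 0.0);

          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = context;
              label = 1.0;
            } else {
              target = table[(lcg(rng) >> 16) % table_size];
              if (target == context) continue;
              label = 0.0;
            }
            double *out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += hidden[d] * out[d];
            double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * out[d];
              out[d] += g * hidden[d];
            }
          }
          if (subword) {
            for (int r : *rows) {
              double *v = &syn0[(size_t)r * dim];
              for (int d = 0; d < dim; ++d) v[d] += grad[d];
            }
          } else {
            double *v = &syn0[(size_t)center * dim];
            for (int d = 0; d < dim; ++d) v[d] += grad[d];
          }
        }
      }
    }
  }

  NumericMatrix out(n_inputs, dim);
  for (int i = 0; i < n_inputs; ++i) {
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  }
  return List::create(_["input_vectors"] = out);
}
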