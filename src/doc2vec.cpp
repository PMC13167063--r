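// Paragraph-vector document embeddings with hierarchical softmax.
//
// Two training modes share one update kernel:
//  * distributed memory (DM): the document vector plus the averaged context
//    word vectors predict the centre word;
//  * distributed bag of words (DBOW): the document vector alone predicts
//    each word in the document.
// Output probabilities use hierarchical softmax over a Huffman tree built
// from corpus word frequencies (codes/points are supplied from R).
// Training is single-threaded with one seeded mt19937, so vectors are
// bit-reproducible for a fixed seed; inference freezes word and inner-node
// weights and fits only the new document vector.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

struct HsTree {
  std::vector<std::vector<int>> codes;   // per word: 0/1 branch labels
  std::vector<std::vector<int>> points;  // per word: inner-node ids
};

HsTree unpack_tree(const List& codes, const List& points) {
  HsTree t;
  t.codes.reserve(codes.size());
  t.points.reserve(points.size());
  for (int i = 0; i < codes.size(); ++i) {
    t.codes.push_back(as<std::vector<int>>(codes[i]));
    t.points.push_back(as<std::vector<int>>(points[i]));
  }
  return t;
}

// one hierarchical-softmax step for target word w against hidden vector h;
// returns the backpropagated error in err (length dim); updates syn1 when
// train_syn1 is true
inline void hs_update(int w, const double* h, double* err, double* syn1,
                      const HsTree& tree, int dim, double lr, bool train_syn1) {
  const std::vector<int>& code = tree.codes[w];
  const std::vector<int>& point = tree.points[w];
  for (size_t b = 0; b < code.size(); ++b) {
    double* row = syn1 + (size_t)point[b] * dim;
    double z = 0;
    for (int d = 0; d < dim; ++d) z += h[d] * row[d];
    double g = (1.0 - code[b] - sigmoid(z)) * lr;
    for (int d = 0; d < dim; ++d) err[d] += g * row[d];
    if (train_syn1)
      for (int d = 0; d < dim; ++d) row[d] += g * h[d];
  }
}

void init_uniform(std::vector<double>& v, int dim, std::mt19937& rng) {
  std::uniform_real_distribution<double> u(-0.5 / dim, 0.5 / dim);
  for (double& x : v) x = u(rng);
}

}  // namespace

// docs: list of integer vectors of 0-based word ids (OOV already removed).
// Returns syn0 (V x dim word vectors; unused columns of zeros for DBOW),
// syn1 (inner-node weights) and docvecs (one row per document).
// [[Rcpp::export]]
List cpp_pv_train(List docs, List codes, List points, int vocab_size, int dim,
                  int window, int epochs, double alpha, double min_alpha,
                  bool dm, int seed) {
  HsTree tree = unpack_tree(codes, points);
  const int D = docs.size();
  std::mt19937 rng((unsigned)seed);

  std::vector<std::vector<int>> dv(D);
  long long total_pos = 0;
  for (int i = 0; i < D; ++i) {
    dv[i] = as<std::vector<int>>(docs[i]);
    total_pos += dv[i].size();
  }
  std::vector<double> syn0((size_t)vocab_size * dim, 0.0);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  std::vector<double> docvec((size_t)D * dim, 0.0);
  if (dm) init_uniform(syn0, dim, rng);
  init_uniform(docvec, dim, rng);

  std::vector<double> h(dim), err(dim);
  long long done = 0;
  const long long total = (long long)epochs * std::max(total_pos, 1LL);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int di = 0; di < D; ++di) {
      const std::vector<int>& doc = dv[di];
      double* dvp = docvec.data() + (size_t)di * dim;
      const int L = (int)doc.size();
      for (int t = 0; t < L; ++t, ++done) {
        double lr = alpha - (alpha - min_alpha) * ((double)done / total);
        int w = doc[t];
        std::fill(err.begin(), err.end(), 0.0);
        if (dm) {
          int lo = std::max(0, t - window), hi = std::min(L - 1, t + window);
          int cw = 1;  // the document vector always contributes
          for (int d = 0; d < dim; ++d) h[d] = dvp[d];
          for (int c = lo; c <= hi; ++c) {
            if (c == t) continue;
            const double* wv = syn0.data() + (size_t)doc[c] * dim;
            for (int d = 0; d < dim; ++d) h[d] += wv[d];
            ++cw;
          }
          for (int d = 0; d < dim; ++d) h[d] /= cw;
          hs_update(w, h.data(), err.data(), syn1.data(), tree, dim, lr, true);
          for (int d = 0; d < dim; ++d) dvp[d] += err[d];
          for (int c = lo; c <= hi; ++c) {
            if (c == t) continue;
            double* wv = syn0.data() + (size_t)doc[c] * dim;
            for (int d = 0; d < dim; ++d) wv[d] += err[d];
          }
        } else {
          hs_update(w, dvp, err.data(), syn1.data(), tree, dim, lr, true);
          for (int d = 0; d < dim; ++d) dvp[d] += err[d];
        }
      }
    }
  }
  NumericMatrix s0(vocab_size, dim), s1(vocab_size, dim), dvm(D, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int d = 0; d < dim; ++d) {
      s0(i, d) = syn0[(size_t)i * dim + d];
      s1(i, d) = syn1[(size_t)i * dim + d];
    }
  for (int i = 0; i < D; ++i)
    for (int d = 0; d < dim; ++d) dvm(i, d) = docvec[(size_t)i * dim + d];
  return List::create(_["syn0"] = s0, _["syn1"] = s1, _["docvecs"] = dvm);
}

// Infer vectors for new documents against frozen weights. Each document's
// vector is trained from a seeded random init; seeds are per-document so
// results do not depend on batch composition.
// [[Rcpp::export]]
NumericMatrix cpp_pv_infer(List docs, List codes, List points,
                           NumericMatrix syn0, NumericMatrix syn1, int dim,
                           int window, int epochs, double alpha,
                           double min_alpha, bool dm, int seed) {
  HsTree tree = unpack_tree(codes, points);
  const int D = docs.size();
  NumericMatrix out(D, dim);
  std::vector<double> h(dim), err(dim), dvp(dim);

  const int V = syn0.nrow();
  std::vector<double> s0((size_t)V * dim), s1((size_t)V * dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d) {
      s0[(size_t)i * dim + d] = syn0(i, d);
      s1[(size_t)i * dim + d] = syn1(i, d);
    }

  for (int di = 0; di < D; ++di) {
    std::vector<int> doc = as<std::vector<int>>(docs[di]);
    std::mt19937 rng((unsigned)(seed + 31 * di));
    std::uniform_real_distribution<double> u(-0.5 / dim, 0.5 / dim);
    for (int d = 0; d < dim; ++d) dvp[d] = u(rng);
    const int L = (int)doc.size();
    const long long total = (long long)epochs * std::max(L, 1);
    long long done = 0;
    for (int ep = 0; ep < epochs; ++ep) {
      for (int t = 0; t < L; ++t, ++done) {
        double lr = alpha - (alpha - min_alpha) * ((double)done / total);
        int w = doc[t];
        std::fill(err.begin(), err.end(), 0.0);
        if (dm) {
          int lo = std::max(0, t - window), hi = std::min(L - 1, t + window);
          int cw = 1;
          for (int d = 0; d < dim; ++d) h[d] = dvp[d];
          for (int c = lo; c <= hi; ++c) {
            if (c == t) continue;
            const double* wv = s0.data() + (size_t)doc[c] * dim;
            for (int d = 0; d < dim; ++d) h[d] += wv[d];
            ++cw;
          }
          for (int d = 0; d < dim; ++d) h[d] /= cw;
          hs_update(w, h.data(), err.data(), s1.data(), tree, dim, lr, false);
        } else {
          hs_update(w, dvp.data(), err.data(), s1.data(), tree, dim, lr, false);
        }
        for (int d = 0; d < dim; ++d) dvp[d] += err[d];
      }
    }
    for (int d = 0; d < dim; ++d) out(di, d) = dvp[d];
  }
  return out;
}
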