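// Tree ensembles on dense feature matrices.
//
// A single CART-style splitter serves two ensembles:
//  * random forest: bootstrap + per-node feature subsampling, Gini impurity,
//    leaf = weighted positive-class fraction, prediction = mean over trees;
//  * gradient boosted trees: second-order (Newton) boosting on the logistic
//    loss, split gain and leaf weights in the XGBoost parameterization
//    (lambda regularizer, min child hessian weight, row/column subsampling).
//
// All randomness flows from one std::mt19937 per fit, so results are
// reproducible for a fixed seed across platforms.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;    // leaf payload
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double score = 0.0;  // impurity decrease / gain; <= 0 means no split
};

// --- random forest (classification, Gini) ---------------------------------

struct RfCtx {
  const double* X;  // column-major n x p
  int n, p;
  const int* y;
  const double* w;
  int mtry, max_depth, min_split, min_leaf;
  std::mt19937* rng;
  Tree* tree;
};

SplitResult rf_best_split(RfCtx& c, const std::vector<int>& idx) {
  SplitResult best;
  const int m = (int)idx.size();
  double W = 0, W1 = 0;
  for (int i : idx) { W += c.w[i]; W1 += c.w[i] * c.y[i]; }
  double p1 = W1 / W;
  double parent_gini = 2.0 * p1 * (1.0 - p1);
  if (parent_gini <= 0) return best;

  std::vector<int> feats(c.p);
  for (int j = 0; j < c.p; ++j) feats[j] = j;
  std::shuffle(feats.begin(), feats.end(), *c.rng);

  std::vector<std::pair<double,int>> vals(m);
  int tried = 0;
  for (int fi = 0; fi < c.p && tried < c.mtry; ++fi) {
    int f = feats[fi];
    const double* col = c.X + (size_t)f * c.n;
    for (int k = 0; k < m; ++k) vals[k] = {col[idx[k]], idx[k]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;  // constant
    ++tried;
    double lW = 0, lW1 = 0;
    int nl = 0;
    for (int k = 0; k < m - 1; ++k) {
      int i = vals[k].second;
      lW += c.w[i]; lW1 += c.w[i] * c.y[i]; ++nl;
      if (vals[k].first == vals[k + 1].first) continue;
      int nr = m - nl;
      if (nl < c.min_leaf || nr < c.min_leaf) continue;
      double rW = W - lW, rW1 = W1 - lW1;
      double pl = lW1 / lW, pr = rW1 / rW;
      double child = (lW * 2.0 * pl * (1.0 - pl) + rW * 2.0 * pr * (1.0 - pr)) / W;
      double dec = parent_gini - child;
      if (dec > best.score + 1e-12) {
        best.score = dec;
        best.feature = f;
        best.threshold = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  return best;
}

int rf_build(RfCtx& c, std::vector<int>& idx, int depth) {
  Tree& t = *c.tree;
  int node = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  double W = 0, W1 = 0;
  for (int i : idx) { W += c.w[i]; W1 += c.w[i] * c.y[i]; }
  t.value.push_back(W > 0 ? W1 / W : 0.5);

  bool stop = (int)idx.size() < c.min_split ||
              (c.max_depth > 0 && depth >= c.max_depth);
  if (!stop) {
    SplitResult s = rf_best_split(c, idx);
    if (s.feature >= 0) {
      std::vector<int> li, ri;
      const double* col = c.X + (size_t)s.feature * c.n;
      for (int i : idx) (col[i] <= s.threshold ? li : ri).push_back(i);
      if (!li.empty() && !ri.empty()) {
        t.feature[node] = s.feature;
        t.threshold[node] = s.threshold;
        int l = rf_build(c, li, depth + 1);
        int r = rf_build(c, ri, depth + 1);
        t.left[node] = l;
        t.right[node] = r;
      }
    }
  }
  return node;
}

double tree_predict(const Tree& t, const double* X, int n, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    double v = X[(size_t)t.feature[node] * n + row];
    node = (v <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = t.feature, _["threshold"] = t.threshold,
                      _["left"] = t.left, _["right"] = t.right,
                      _["value"] = t.value);
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<double>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  return t;
}

int resolve_mtry(const std::string& strategy, int p) {
  int m;
  if (strategy == "log2") m = (int)std::floor(std::log2((double)p)) + 1;
  else if (strategy == "all") m = p;
  else m = (int)std::floor(std::sqrt((double)p));  // sqrt default
  if (m < 1) m = 1;
  if (m > p) m = p;
  return m;
}

// --- gradient boosting (Newton, logistic loss) -----------------------------

struct GbCtx {
  const double* X;
  int n, p;
  const double* g;
  const double* h;
  const std::vector<int>* cols;  // columns available to this tree
  int max_depth, min_split;
  double min_child_weight, lambda;
  Tree* tree;
};

SplitResult gb_best_split(GbCtx& c, const std::vector<int>& idx) {
  SplitResult best;
  const int m = (int)idx.size();
  double G = 0, H = 0;
  for (int i : idx) { G += c.g[i]; H += c.h[i]; }
  double parent = G * G / (H + c.lambda);
  std::vector<std::pair<double,int>> vals(m);
  for (int f : *c.cols) {
    const double* col = c.X + (size_t)f * c.n;
    for (int k = 0; k < m; ++k) vals[k] = {col[idx[k]], idx[k]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double GL = 0, HL = 0;
    for (int k = 0; k < m - 1; ++k) {
      int i = vals[k].second;
      GL += c.g[i]; HL += c.h[i];
      if (vals[k].first == vals[k + 1].first) continue;
      double GR = G - GL, HR = H - HL;
      if (HL < c.min_child_weight || HR < c.min_child_weight) continue;
      double gain = 0.5 * (GL * GL / (HL + c.lambda) +
                           GR * GR / (HR + c.lambda) - parent);
      if (gain > best.score + 1e-12) {
        best.score = gain;
        best.feature = f;
        best.threshold = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  return best;
}

int gb_build(GbCtx& c, std::vector<int>& idx, int depth) {
  Tree& t = *c.tree;
  int node = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  double G = 0, H = 0;
  for (int i : idx) { G += c.g[i]; H += c.h[i]; }
  t.value.push_back(-G / (H + c.lambda));

  bool stop = (int)idx.size() < c.min_split || depth >= c.max_depth;
  if (!stop) {
    SplitResult s = gb_best_split(c, idx);
    if (s.feature >= 0) {
      std::vector<int> li, ri;
      const double* col = c.X + (size_t)s.feature * c.n;
      for (int i : idx) (col[i] <= s.threshold ? li : ri).push_back(i);
      if (!li.empty() && !ri.empty()) {
        t.feature[node] = s.feature;
        t.threshold[node] = s.threshold;
        int l = gb_build(c, li, depth + 1);
        int r = gb_build(c, ri, depth + 1);
        t.left[node] = l;
        t.right[node] = r;
      }
    }
  }
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int n_trees, int max_depth,
                int min_split, int min_leaf, std::string feature_strategy,
                bool balanced, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> w(n, 1.0);
  if (balanced) {
    double n1 = 0;
    for (int i = 0; i < n; ++i) n1 += y[i];
    double w1 = n / (2.0 * n1), w0 = n / (2.0 * (n - n1));
    for (int i = 0; i < n; ++i) w[i] = y[i] ? w1 : w0;
  }
  int mtry = resolve_mtry(feature_strategy, p);

  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    Tree t;
    RfCtx c{REAL(X), n, p, INTEGER(y), w.data(), mtry, max_depth,
            min_split, min_leaf, &rng, &t};
    rf_build(c, idx, 0);
    trees[b] = tree_to_list(t);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, 0.0);
  for (int b = 0; b < trees.size(); ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict(t, REAL(X), n, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= trees.size();
  return out;
}

// [[Rcpp::export]]
List cpp_gbt_fit(NumericMatrix X, IntegerVector y, int n_rounds, double eta,
                 int max_depth, double min_child_weight, double subsample,
                 double colsample, double lambda, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> f(n, 0.0), g(n), h(n);

  List trees(n_rounds);
  std::vector<int> allrows(n), allcols(p);
  for (int i = 0; i < n; ++i) allrows[i] = i;
  for (int j = 0; j < p; ++j) allcols[j] = j;

  for (int r = 0; r < n_rounds; ++r) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-f[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    std::vector<int> rows = allrows;
    if (subsample < 1.0) {
      std::shuffle(rows.begin(), rows.end(), rng);
      rows.resize(std::max(1, (int)std::floor(subsample * n)));
    }
    std::vector<int> cols = allcols;
    if (colsample < 1.0) {
      std::shuffle(cols.begin(), cols.end(), rng);
      cols.resize(std::max(1, (int)std::floor(colsample * p)));
      std::sort(cols.begin(), cols.end());
    }
    Tree t;
    GbCtx c{REAL(X), n, p, g.data(), h.data(), &cols, max_depth, 2,
            min_child_weight, lambda, &t};
    gb_build(c, rows, 0);
    for (int i = 0; i < n; ++i)
      f[i] += eta * tree_predict(t, REAL(X), n, i);
    trees[r] = tree_to_list(t);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_gbt_predict(List trees, NumericMatrix X, double eta) {
  const int n = X.nrow();
  std::vector<double> f(n, 0.0);
  for (int r = 0; r < trees.size(); ++r) {
    Tree t = tree_from_list(trees[r]);
    for (int i = 0; i < n; ++i) f[i] += eta * tree_predict(t, REAL(X), n, i);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-f[i]));
  return out;
}
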