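#include <Rcpp.h>
#include <random>
#include <map>
#include <algorithm>
#include <vector>
#include <cmath>

// Shared tree builder for the ensemble classifiers. A binary 0/1 response
// makes Gini impurity and node variance equivalent up to a factor of two, so
// one variance-reduction builder serves both classification trees (leaf value
// = minority-class proportion) and the regression trees used inside gradient
// boosting (leaf value = mean residual, later replaced by a Newton step).

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // x <= threshold goes left
  int left, right;  // node indices, -1 for leaf
  double value;     // mean response in node
};

struct BuildParams {
  int max_depth;    // <=0 means unlimited (capped at 30)
  int min_node;     // minimum samples to attempt a split
  int mtry;         // features sampled per node
  bool random_split;// extra-trees style random thresholds
};

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const NumericVector& y,
              const BuildParams& p, std::mt19937& rng)
    : X_(X), y_(y), p_(p), rng_(rng) {}

  std::vector<Node> build(const std::vector<int>& idx) {
    nodes_.clear();
    grow(idx, 0);
    return nodes_;
  }

private:
  const NumericMatrix& X_;
  const NumericVector& y_;
  BuildParams p_;
  std::mt19937& rng_;
  std::vector<Node> nodes_;

  double node_mean(const std::vector<int>& idx) const {
    double s = 0.0;
    for (int i : idx) s += y_[i];
    return s / idx.size();
  }

  // Returns node id.
  int grow(const std::vector<int>& idx, int depth) {
    int id = (int)nodes_.size();
    nodes_.push_back(Node{-1, 0.0, -1, -1, node_mean(idx)});

    int n = (int)idx.size();
    int cap = p_.max_depth > 0 ? p_.max_depth : 30;
    if (n < p_.min_node || depth >= cap) return id;

    // pure node?
    bool pure = true;
    for (int i : idx) if (y_[i] != y_[idx[0]]) { pure = false; break; }
    if (pure) return id;

    int pfeat = X_.ncol();
    std::vector<int> feats(pfeat);
    for (int j = 0; j < pfeat; ++j) feats[j] = j;
    int mtry = std::min(p_.mtry, pfeat);
    // partial Fisher-Yates for the mtry sample
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> d(j, pfeat - 1);
      std::swap(feats[j], feats[d(rng_)]);
    }

    double best_score = -1.0, best_thr = 0.0;
    int best_feat = -1;
    double sum_all = 0.0;
    for (int i : idx) sum_all += y_[i];

    std::vector<double> xv(n);
    for (int jj = 0; jj < mtry; ++jj) {
      int f = feats[jj];
      for (int t = 0; t < n; ++t) xv[t] = X_(idx[t], f);
      double lo = *std::min_element(xv.begin(), xv.end());
      double hi = *std::max_element(xv.begin(), xv.end());
      if (lo == hi) continue;

      if (p_.random_split) {
        std::uniform_real_distribution<double> d(lo, hi);
        double thr = d(rng_);
        double sl = 0.0; int nl = 0;
        for (int t = 0; t < n; ++t) if (xv[t] <= thr) { sl += y_[idx[t]]; ++nl; }
        if (nl == 0 || nl == n) continue;
        double sr = sum_all - sl; int nr = n - nl;
        double score = sl * sl / nl + sr * sr / nr; // -SSE up to constants
        if (score > best_score) { best_score = score; best_feat = f; best_thr = thr; }
      } else {
        // exhaustive midpoint scan over the sorted feature
        std::vector<int> ord(n);
        for (int t = 0; t < n; ++t) ord[t] = t;
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return xv[a] < xv[b]; });
        double sl = 0.0;
        for (int t = 0; t < n - 1; ++t) {
          sl += y_[idx[ord[t]]];
          if (xv[ord[t + 1]] == xv[ord[t]]) continue;
          int nl = t + 1, nr = n - nl;
          double sr = sum_all - sl;
          double score = sl * sl / nl + sr * sr / nr;
          if (score > best_score) {
            best_score = score;
            best_feat = f;
            best_thr = 0.5 * (xv[ord[t]] + xv[ord[t + 1]]);
          }
        }
      }
    }

    if (best_feat < 0) return id;
    // no-gain guard: only split if SSE strictly decreases
    double parent_score = sum_all * sum_all / n;
    if (best_score <= parent_score + 1e-12) return id;

    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X_(i, best_feat) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return id;

    nodes_[id].feature = best_feat;
    nodes_[id].threshold = best_thr;
    int l = grow(lidx, depth + 1);
    nodes_[id].left = l;
    int r = grow(ridx, depth + 1);
    nodes_[id].right = r;
    return id;
  }
};

NumericMatrix pack(const std::vector<Node>& nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

double predict_one(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

std::vector<int> leaf_of(const NumericMatrix& tree, const NumericMatrix& X) {
  std::vector<int> out(X.nrow());
  for (int r = 0; r < X.nrow(); ++r) {
    int node = 0;
    while (tree(node, 0) >= 0) {
      int f = (int)tree(node, 0);
      node = (X(r, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
    }
    out[r] = node;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int max_depth, int min_node, bool bootstrap,
                    bool random_split, int seed) {
  std::mt19937 rng((unsigned)seed);
  BuildParams p{max_depth, min_node, mtry, random_split};
  int n = X.nrow();
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> d(0, n - 1);
      for (int i = 0; i < n; ++i) idx[i] = d(rng);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    TreeBuilder b(X, y, p, rng);
    trees[t] = pack(b.build(idx));
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int r = 0; r < n; ++r) out[r] += predict_one(tree, X, r);
  }
  for (int r = 0; r < n; ++r) out[r] /= T;
  return out;
}

// Gradient boosting with logistic loss: trees fit to the gradient, leaf
// values replaced by a one-step Newton update sum(r)/sum(p(1-p)).
// [[Rcpp::export(name = ".cpp_gbm_fit")]]
List cpp_gbm_fit(NumericMatrix X, NumericVector y, int ntree, int max_depth,
                 double shrinkage, int min_node, int seed) {
  std::mt19937 rng((unsigned)seed);
  int n = X.nrow();
  double ybar = mean(y);
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double f0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, f0);
  BuildParams p{max_depth, min_node, X.ncol(), false};
  List trees(ntree);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < ntree; ++t) {
    NumericVector r(n);
    std::vector<double> w(n);
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - pr;
      w[i] = std::max(pr * (1.0 - pr), 1e-10);
    }
    TreeBuilder b(X, r, p, rng);
    NumericMatrix tree = pack(b.build(all));
    // Newton leaf updates
    std::vector<int> leaves = leaf_of(tree, X);
    std::map<int, std::pair<double, double>> acc; // leaf -> (sum r, sum w)
    for (int i = 0; i < n; ++i) {
      acc[leaves[i]].first += r[i];
      acc[leaves[i]].second += w[i];
    }
    for (auto& kv : acc)
      tree(kv.first, 4) = kv.second.first / kv.second.second;
    for (int i = 0; i < n; ++i)
      F[i] += shrinkage * tree(leaves[i], 4);
    trees[t] = tree;
  }
  return List::create(Named("trees") = trees, Named("f0") = f0,
                      Named("shrinkage") = shrinkage);
}

// [[Rcpp::export(name = ".cpp_gbm_predict")]]
NumericVector cpp_gbm_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  double f0 = model["f0"], shrink = model["shrinkage"];
  int n = X.nrow();
  NumericVector out(n, f0);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int r = 0; r < n; ++r) out[r] += shrink * predict_one(tree, X, r);
  }
  return out; // log-odds scale
}
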