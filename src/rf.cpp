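// Minimal random-forest classifier for two-class OTU selection:
// bootstrap-aggregated CART trees with Gini splits and out-of-bag (OOB)
// permutation importance. Uses R's RNG so results are reproducible from
// set.seed() in the calling R code. Designed for the small-n / moderate-p
// tables this package works with.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;        // -1 => leaf
  double threshold = 0.0;  // go left if x <= threshold
  int left = -1, right = -1;
  int pred = 0;            // leaf majority class
};

// uniform integer in [0, n) from R's RNG
inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

double gini(int n0, int n1) {
  double n = n0 + n1;
  if (n == 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const IntegerVector& y, int mtry,
              int min_node)
    : X_(X), y_(y), mtry_(mtry), min_node_(min_node), p_(X.ncol()) {}

  std::vector<Node> nodes;
  std::vector<bool> used_feature;

  void build(std::vector<int>& samples) {
    nodes.clear();
    used_feature.assign(p_, false);
    grow(samples);
  }

  int predict(const double* row) const {
    int i = 0;
    while (nodes[i].feature >= 0)
      i = (row[nodes[i].feature] <= nodes[i].threshold) ? nodes[i].left
                                                        : nodes[i].right;
    return nodes[i].pred;
  }

  // predict with one feature's value overridden
  int predict_override(const double* row, int f, double v) const {
    int i = 0;
    while (nodes[i].feature >= 0) {
      double x = (nodes[i].feature == f) ? v : row[nodes[i].feature];
      i = (x <= nodes[i].threshold) ? nodes[i].left : nodes[i].right;
    }
    return nodes[i].pred;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_, p_;
  std::vector<int> feat_pool_;

  int grow(std::vector<int>& samples) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    int n0 = 0, n1 = 0;
    for (int s : samples) (y_[s] == 0 ? n0 : n1)++;
    int n = n0 + n1;
    nodes[id].pred = (n1 > n0) ? 1 : 0;
    if (n0 == 0 || n1 == 0 || n < 2 * min_node_) return id;

    // sample mtry candidate features without replacement
    if ((int)feat_pool_.size() != p_) {
      feat_pool_.resize(p_);
      for (int f = 0; f < p_; ++f) feat_pool_[f] = f;
    }
    for (int k = 0; k < mtry_; ++k)
      std::swap(feat_pool_[k], feat_pool_[k + runif_int(p_ - k)]);

    double parent_imp = gini(n0, n1) * n;
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int> > vals(n);
    for (int k = 0; k < mtry_; ++k) {
      int f = feat_pool_[k];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X_(samples[i], f), y_[samples[i]]);
      std::sort(vals.begin(), vals.end());
      int l0 = 0, l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        (vals[i].second == 0 ? l0 : l1)++;
        if (vals[i].first == vals[i + 1].first) continue;
        double child = gini(l0, l1) * (l0 + l1) +
                       gini(n0 - l0, n1 - l1) * (n - l0 - l1);
        double gain = parent_imp - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> left, right;
    for (int s : samples)
      (X_(s, best_f) <= best_thr ? left : right).push_back(s);
    if (left.empty() || right.empty()) return id;

    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    used_feature[best_f] = true;
    nodes[id].left = grow(left);
    nodes[id].right = grow(right);
    return id;
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".rf_importance")]]
List rf_importance_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                       int mtry, int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("y length must match nrow(X)");
  NumericVector importance(p);
  double oob_err_sum = 0.0;
  int oob_trees = 0;

  std::vector<int> boot(n), oob;
  std::vector<bool> inbag(n);
  std::vector<double> row(p), perm_vals;
  std::vector<int> perm_order;
  TreeBuilder tree(X, y, mtry, min_node);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), false);
    for (int i = 0; i < n; ++i) {
      boot[i] = runif_int(n);
      inbag[boot[i]] = true;
    }
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    tree.build(boot);
    int n_oob = (int)oob.size();
    if (n_oob == 0) continue;

    int correct = 0;
    std::vector<int> base_pred(n_oob);
    for (int i = 0; i < n_oob; ++i) {
      for (int f = 0; f < p; ++f) row[f] = X(oob[i], f);
      base_pred[i] = tree.predict(&row[0]);
      if (base_pred[i] == y[oob[i]]) correct++;
    }
    double acc0 = (double)correct / n_oob;
    oob_err_sum += 1.0 - acc0;
    oob_trees++;

    // permutation importance: only features the tree actually split on can
    // change predictions
    perm_order.resize(n_oob);
    for (int f = 0; f < p; ++f) {
      if (!tree.used_feature[f]) continue;
      for (int i = 0; i < n_oob; ++i) perm_order[i] = i;
      for (int i = 0; i < n_oob - 1; ++i)
        std::swap(perm_order[i], perm_order[i + runif_int(n_oob - i)]);
      int corr_f = 0;
      for (int i = 0; i < n_oob; ++i) {
        for (int ff = 0; ff < p; ++ff) row[ff] = X(oob[i], ff);
        double v = X(oob[perm_order[i]], f);
        if (tree.predict_override(&row[0], f, v) == y[oob[i]]) corr_f++;
      }
      importance[f] += acc0 - (double)corr_f / n_oob;
    }
  }
  if (oob_trees > 0)
    for (int f = 0; f < p; ++f) importance[f] /= oob_trees;
  return List::create(
      _["importance"] = importance,
      _["oob_error"] = oob_trees > 0 ? oob_err_sum / oob_trees : NA_REAL);
}
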