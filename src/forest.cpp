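// Compact random-forest Gini importance for binary classification.
// Grown only for feature importance (Boruta backend): bootstrap rows,
// per-node mtry feature sampling, best Gini split by exhaustive scan,
// importance = weighted impurity decrease summed per feature, averaged
// over trees. Uses R's RNG so set.seed() governs reproducibility.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline double gini_node(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct SplitResult {
  int feature = -1;
  double value = 0.0;   // goes left if x <= value
  double gain = 0.0;
};

static SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                              const std::vector<int>& idx,
                              const std::vector<int>& feats, int min_node) {
  SplitResult best;
  int n = idx.size();
  double tot1 = 0.0;
  for (int i : idx) tot1 += y[i];
  double tot0 = n - tot1;
  double parent = gini_node(tot0, tot1);
  if (parent <= 0.0) return best;
  std::vector<std::pair<double, int>> vals(n);
  for (int f : feats) {
    for (int k = 0; k < n; ++k) vals[k] = {X(idx[k], f), y[idx[k]]};
    std::sort(vals.begin(), vals.end());
    double l1 = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      l1 += vals[k].second;
      double nl = k + 1, nr = n - nl;
      if (vals[k].first == vals[k + 1].first) continue;  // not a cut point
      if (nl < min_node || nr < min_node) continue;
      double l0 = nl - l1;
      double r1 = tot1 - l1, r0 = tot0 - l0;
      double child = (nl / n) * gini_node(l0, l1) +
                     (nr / n) * gini_node(r0, r1);
      double gain = parent - child;
      if (gain > best.gain) {
        best.gain = gain;
        best.feature = f;
        best.value = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  return best;
}

struct NodeTask {
  std::vector<int> idx;
  int depth;
};

// [[Rcpp::export(name = ".rf_importance_cpp")]]
NumericVector rf_importance_cpp(NumericMatrix X, IntegerVector y,
                                int num_trees, int mtry, int min_node,
                                int max_depth) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  NumericVector importance(p);
  std::vector<int> featpool(p);
  for (int j = 0; j < p; ++j) featpool[j] = j;

  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i)
      boot[i] = (int)(unif_rand() * n);
    std::vector<NodeTask> stack;
    stack.push_back({boot, 0});
    while (!stack.empty()) {
      NodeTask task = std::move(stack.back());
      stack.pop_back();
      int m = task.idx.size();
      if (m < 2 * min_node || task.depth >= max_depth) continue;
      // per-node mtry sample (partial Fisher-Yates on the feature pool)
      for (int k = 0; k < mtry; ++k) {
        int r = k + (int)(unif_rand() * (p - k));
        std::swap(featpool[k], featpool[r]);
      }
      std::vector<int> feats(featpool.begin(), featpool.begin() + mtry);
      SplitResult sp = best_split(X, y, task.idx, feats, min_node);
      if (sp.feature < 0 || sp.gain <= 0.0) continue;
      importance[sp.feature] += ((double)m / n) * sp.gain;
      std::vector<int> left, right;
      left.reserve(m); right.reserve(m);
      for (int i : task.idx)
        (X(i, sp.feature) <= sp.value ? left : right).push_back(i);
      stack.push_back({std::move(left), task.depth + 1});
      stack.push_back({std::move(right), task.depth + 1});
    }
  }
  for (int j = 0; j < p; ++j) importance[j] /= num_trees;
  return importance;
}
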