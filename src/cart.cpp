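#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Classification tree grown by exact greedy Gini search.
//
// Split convention: left child takes rows with x <= threshold, right child
// rows with x > threshold; thresholds are midpoints between adjacent distinct
// observed values, so routing is reproducible from the serialized threshold
// alone. Ties in the split score keep the first candidate in scan order
// (ascending feature index, then ascending threshold), which makes the tree a
// deterministic function of (X, y).

struct BuildTask {
  int node;
  std::vector<int> idx;
  int depth;
};

// [[Rcpp::export]]
List cpp_cart_fit(const NumericMatrix& X, const IntegerVector& y, int n_class,
                  int max_depth, int min_split, double min_decrease) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");

  std::vector<int> feature, left, right, pred, n_node;
  std::vector<double> threshold;
  std::vector<std::vector<int>> counts;

  auto new_node = [&]() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(-1);
    n_node.push_back(0);
    counts.push_back(std::vector<int>(n_class, 0));
    return (int)feature.size() - 1;
  };

  std::vector<BuildTask> stack;
  {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    int root = new_node();
    stack.push_back({root, std::move(all), 0});
  }

  std::vector<std::pair<double,int>> vals;  // (x value, class) sorted per feature

  while (!stack.empty()) {
    BuildTask task = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& idx = task.idx;
    const int m = (int)idx.size();
    std::vector<int>& cnt = counts[task.node];
    for (int i = 0; i < m; ++i) cnt[y[idx[i]]]++;
    n_node[task.node] = m;

    // majority class, ties to the smallest class index
    int best_c = 0;
    for (int k = 1; k < n_class; ++k) if (cnt[k] > cnt[best_c]) best_c = k;
    pred[task.node] = best_c;

    bool pure = (cnt[best_c] == m);
    if (pure || m < min_split || (max_depth >= 0 && task.depth >= max_depth))
      continue;  // leaf

    double parent_term = 0.0;
    for (int k = 0; k < n_class; ++k)
      parent_term += (double)cnt[k] * (double)cnt[k];
    parent_term /= (double)m;

    // maximize sum_k L_k^2/n_L + R_k^2/n_R  (equivalent to Gini decrease)
    double best_score = parent_term + min_decrease;
    int best_j = -1;
    double best_thr = 0.0;
    std::vector<int> lcnt(n_class);

    for (int j = 0; j < p; ++j) {
      vals.clear();
      vals.reserve(m);
      for (int i = 0; i < m; ++i) vals.push_back({X(idx[i], j), y[idx[i]]});
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant

      std::fill(lcnt.begin(), lcnt.end(), 0);
      double sumL2 = 0.0;  // sum of squared left counts, updated incrementally
      for (int i = 0; i < m - 1; ++i) {
        int k = vals[i].second;
        sumL2 += 2.0 * lcnt[k] + 1.0;
        lcnt[k]++;
        if (vals[i].first == vals[i + 1].first) continue;
        double thr = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
        // guard against midpoint collapsing onto a boundary value
        if (!(vals[i].first <= thr && vals[i + 1].first > thr)) continue;
        double sumR2 = 0.0;
        for (int k2 = 0; k2 < n_class; ++k2) {
          double r = (double)(cnt[k2] - lcnt[k2]);
          sumR2 += r * r;
        }
        double nl = (double)(i + 1), nr = (double)(m - i - 1);
        double score = sumL2 / nl + sumR2 / nr;
        if (score > best_score) {
          best_score = score;
          best_j = j;
          best_thr = thr;
        }
      }
    }

    if (best_j < 0) continue;  // no impurity-reducing split exists

    std::vector<int> lidx, ridx;
    lidx.reserve(m);
    ridx.reserve(m);
    for (int i = 0; i < m; ++i) {
      if (X(idx[i], best_j) <= best_thr) lidx.push_back(idx[i]);
      else ridx.push_back(idx[i]);
    }
    if (lidx.empty() || ridx.empty()) continue;  // defensive; cannot happen

    feature[task.node] = best_j;
    threshold[task.node] = best_thr;
    int lnode = new_node();
    int rnode = new_node();
    left[task.node] = lnode;
    right[task.node] = rnode;
    stack.push_back({rnode, std::move(ridx), task.depth + 1});
    stack.push_back({lnode, std::move(lidx), task.depth + 1});
  }

  int n_nodes = (int)feature.size();
  IntegerMatrix cm(n_nodes, n_class);
  for (int v = 0; v < n_nodes; ++v)
    for (int k = 0; k < n_class; ++k) cm(v, k) = counts[v][k];

  return List::create(
      _["feature"] = wrap(feature), _["threshold"] = wrap(threshold),
      _["left"] = wrap(left), _["right"] = wrap(right),
      _["pred"] = wrap(pred), _["n_node"] = wrap(n_node),
      _["class_counts"] = cm);
}

// Route rows to leaves; returns 0-based node index of the leaf per row.
// [[Rcpp::export]]
IntegerVector cpp_cart_route(const IntegerVector& feature,
                             const NumericVector& threshold,
                             const IntegerVector& left,
                             const IntegerVector& right,
                             const NumericMatrix& X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int v = 0;
    while (feature[v] >= 0)
      v = (X(i, feature[v]) <= threshold[v]) ? left[v] : right[v];
    out[i] = v;
  }
  return out;
}

// Best regression stump for gradient boosting: the split minimizing the SSE
// of approximating g by per-side means. Returns feature = -1 when no split
// improves on the root mean.
// [[Rcpp::export]]
List cpp_best_stump(const NumericMatrix& X, const NumericVector& g) {
  const int n = X.nrow(), p = X.ncol();
  double gsum = 0.0;
  for (int i = 0; i < n; ++i) gsum += g[i];

  // maximize SL^2/nl + SR^2/nr - S^2/n  (SSE reduction)
  double base = gsum * gsum / (double)n;
  double best_gain = 1e-12;
  int best_j = -1;
  double best_thr = 0.0, best_lmean = 0.0, best_rmean = 0.0;

  std::vector<std::pair<double,double>> vals(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) vals[i] = {X(i, j), g[i]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      double thr = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
      if (!(vals[i].first <= thr && vals[i + 1].first > thr)) continue;
      double nl = (double)(i + 1), nr = (double)(n - i - 1);
      double sr = gsum - sl;
      double gain = sl * sl / nl + sr * sr / nr - base;
      if (gain > best_gain) {
        best_gain = gain;
        best_j = j;
        best_thr = thr;
        best_lmean = sl / nl;
        best_rmean = sr / nr;
      }
    }
  }
  return List::create(_["feature"] = best_j, _["threshold"] = best_thr,
                      _["left_value"] = best_lmean,
                      _["right_value"] = best_rmean,
                      _["gain"] = best_gain);
}
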