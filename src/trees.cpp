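// Exact greedy regression-tree learner on (gradient, hessian) pairs.
// With g = -residual, h = 1, lambda = 0 this is a classical variance-
// reduction CART tree (leaf = mean residual), used by the random forest and
// GBDT models; with lambda/gamma > 0 it is the second-order regularized
// booster tree (leaf = -G/(H+lambda), split gain the regularized formula).
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct TreeBuilder {
  const NumericMatrix &X;
  const NumericVector &g, &h;
  const IntegerVector &cols; // 0-based candidate feature columns
  double lambda, gamma, min_child_weight;
  int max_depth;
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;

  TreeBuilder(const NumericMatrix &X_, const NumericVector &g_,
              const NumericVector &h_, const IntegerVector &cols_,
              double lambda_, double gamma_, double mcw_, int max_depth_)
      : X(X_), g(g_), h(h_), cols(cols_), lambda(lambda_), gamma(gamma_),
        min_child_weight(mcw_), max_depth(max_depth_) {}

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    value.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    return (int)feature.size() - 1;
  }

  int build(std::vector<int> &rows, int depth) {
    int id = new_node();
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += g[r]; H += h[r]; }
    value[id] = -G / (H + lambda);
    if (depth >= max_depth || rows.size() < 2) return id;

    double parent_score = G * G / (H + lambda);
    double best_gain = 0.0, best_thr = 0.0;
    int best_col = -1;
    std::vector<std::pair<double, int>> vals(rows.size());

    for (int ci = 0; ci < cols.size(); ++ci) {
      int c = cols[ci];
      for (size_t i = 0; i < rows.size(); ++i)
        vals[i] = std::make_pair(X(rows[i], c), rows[i]);
      std::sort(vals.begin(), vals.end());
      double GL = 0.0, HL = 0.0;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        int r = vals[i].second;
        GL += g[r]; HL += h[r];
        if (vals[i].first == vals[i + 1].first) continue;
        double HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double GR = G - GL;
        double gain = 0.5 * (GL * GL / (HL + lambda) +
                             GR * GR / (HR + lambda) - parent_score) - gamma;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_col = c;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_col < 0) return id;

    std::vector<int> lrows, rrows;
    for (int r : rows)
      (X(r, best_col) < best_thr ? lrows : rrows).push_back(r);
    if (lrows.empty() || rrows.empty()) return id;
    feature[id] = best_col;
    threshold[id] = best_thr;
    int l = build(lrows, depth + 1);
    int rch = build(rrows, depth + 1);
    left[id] = l;
    right[id] = rch;
    return id;
  }
};

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, NumericVector g, NumericVector h,
                    IntegerVector rows, IntegerVector cols, int max_depth,
                    double lambda, double gamma, double min_child_weight) {
  TreeBuilder tb(X, g, h, cols, lambda, gamma, min_child_weight, max_depth);
  std::vector<int> rws(rows.begin(), rows.end());
  tb.build(rws, 0);
  return List::create(_["feature"] = wrap(tb.feature),
                      _["threshold"] = wrap(tb.threshold),
                      _["value"] = wrap(tb.value), _["left"] = wrap(tb.left),
                      _["right"] = wrap(tb.right));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = X(i, feature[node]) < threshold[node] ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
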