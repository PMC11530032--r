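// Depth-limited greedy regression tree (CART, squared-error splits).
// Base learner for the gradient-boosted pseudotime regressor and the
// randomized-tree bin classifier.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feat;      // -1 for leaf
  double thr;
  int left, right;
  double value;  // leaf mean
};

void grow(const NumericMatrix& X, const NumericVector& y,
          std::vector<int>& rows, int depth, int max_depth, int min_node,
          const std::vector<int>& feats, std::vector<Node>& nodes,
          int node_id) {
  const int n = rows.size();
  double sum = 0.0;
  for (int r : rows) sum += y[r];
  const double mean = sum / n;
  nodes[node_id].value = mean;
  nodes[node_id].feat = -1;
  if (depth >= max_depth || n < 2 * min_node) return;

  double best_gain = 1e-12;
  int best_feat = -1, best_pos = -1;
  std::vector<int> order(rows);
  std::vector<int> best_order;

  for (int f : feats) {
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double left_sum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      left_sum += y[order[i]];
      if (X(order[i], f) == X(order[i + 1], f)) continue;  // no gap
      const int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double right_sum = sum - left_sum;
      const double gain = left_sum * left_sum / nl +
                          right_sum * right_sum / nr -
                          sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_pos = i;
        best_order = order;
      }
    }
  }
  if (best_feat < 0) return;

  const double thr = 0.5 * (X(best_order[best_pos], best_feat) +
                            X(best_order[best_pos + 1], best_feat));
  std::vector<int> lrows(best_order.begin(),
                         best_order.begin() + best_pos + 1);
  std::vector<int> rrows(best_order.begin() + best_pos + 1,
                         best_order.end());
  const int li = nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  const int ri = nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  nodes[node_id].feat = best_feat;
  nodes[node_id].thr = thr;
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  grow(X, y, lrows, depth + 1, max_depth, min_node, feats, nodes, li);
  grow(X, y, rrows, depth + 1, max_depth, min_node, feats, nodes, ri);
}

}  // namespace

// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, IntegerVector rows,
                  IntegerVector feats, int max_depth, int min_node) {
  std::vector<int> rvec(rows.begin(), rows.end());
  std::vector<int> fvec(feats.begin(), feats.end());
  std::vector<Node> nodes;
  nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  grow(X, y, rvec, 0, max_depth, min_node, fvec, nodes, 0);
  const int m = nodes.size();
  IntegerVector feat(m), left(m), right(m);
  NumericVector thr(m), value(m);
  for (int i = 0; i < m; ++i) {
    feat[i] = nodes[i].feat;
    thr[i] = nodes[i].thr;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feat"] = feat, _["thr"] = thr, _["left"] = left,
                      _["right"] = right, _["value"] = value);
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feat"], left = tree["left"],
                right = tree["right"];
  NumericVector thr = tree["thr"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
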