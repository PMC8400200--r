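#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Flat node table, one row per node:
//   col 0: feature (1-based; 0 => leaf)
//   col 1: threshold (x <= threshold goes left)
//   col 2: left child row (1-based; 0 for leaf)
//   col 3: right child row
//   col 4: leaf vote (0/1; majority class, tie -> 0)
//   col 5: in-node count of class 0
//   col 6: in-node count of class 1
// Tie-breaking for splits: features are scanned in the (ascending) order
// given, candidate thresholds in ascending order, and a new best is accepted
// only on a strict improvement, so equal-gain ties resolve to the lowest
// feature index, then the lowest threshold.

namespace {

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &y;
  const IntegerVector &feats;  // 1-based feature indices, ascending
  int min_leaf;
  int max_depth;  // <0 => unlimited
  std::vector<std::array<double, 7>> nodes;

  Grower(const NumericMatrix &X_, const IntegerVector &y_,
         const IntegerVector &feats_, int min_leaf_, int max_depth_)
      : X(X_), y(y_), feats(feats_), min_leaf(min_leaf_),
        max_depth(max_depth_) {}

  int makeLeaf(int n0, int n1) {
    std::array<double, 7> nd{};
    nd[0] = 0.0;
    nd[4] = (n1 > n0) ? 1.0 : 0.0;
    nd[5] = n0;
    nd[6] = n1;
    nodes.push_back(nd);
    return static_cast<int>(nodes.size());
  }

  int grow(std::vector<int> &idx, int depth) {
    int n = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int n0 = n - n1;
    bool stop = (n0 == 0 || n1 == 0) || (n < 2 * min_leaf) ||
                (max_depth >= 0 && depth >= max_depth);
    if (!stop) {
      int best_f = -1;
      double best_thr = 0.0;
      // maximize S = sum over children of (c0^2 + c1^2) / child size;
      // equivalent to minimizing the summed child Gini impurity
      double best_s = (static_cast<double>(n0) * n0 +
                       static_cast<double>(n1) * n1) / n;
      std::vector<std::pair<double, int>> vals(n);
      for (int fi = 0; fi < feats.size(); ++fi) {
        int f = feats[fi] - 1;
        for (int i = 0; i < n; ++i) {
          vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
        }
        std::sort(vals.begin(), vals.end());
        int l0 = 0, l1 = 0;
        for (int i = 0; i + 1 < n; ++i) {
          if (vals[i].second == 1) ++l1; else ++l0;
          if (vals[i].first == vals[i + 1].first) continue;
          int nl = i + 1, nr = n - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          int r0 = n0 - l0, r1 = n1 - l1;
          double s =
              (static_cast<double>(l0) * l0 + static_cast<double>(l1) * l1) /
                  nl +
              (static_cast<double>(r0) * r0 + static_cast<double>(r1) * r1) /
                  nr;
          if (s > best_s) {
            double thr = (vals[i].first + vals[i + 1].first) / 2.0;
            // for ulp-adjacent values the midpoint can round up onto the
            // upper value, which would send the whole node left; clamp to
            // the lower value so "x <= thr" matches the counted partition
            if (thr >= vals[i + 1].first) thr = vals[i].first;
            best_s = s;
            best_f = f;
            best_thr = thr;
          }
        }
      }
      if (best_f >= 0) {
        std::vector<int> left, right;
        left.reserve(n);
        right.reserve(n);
        for (int i : idx) {
          if (X(i, best_f) <= best_thr) left.push_back(i);
          else right.push_back(i);
        }
        std::array<double, 7> nd{};
        nd[0] = best_f + 1;
        nd[1] = best_thr;
        nd[5] = n0;
        nd[6] = n1;
        nodes.push_back(nd);
        int me = static_cast<int>(nodes.size());
        int lc = grow(left, depth + 1);
        int rc = grow(right, depth + 1);
        nodes[me - 1][2] = lc;
        nodes[me - 1][3] = rc;
        return me;
      }
    }
    return makeLeaf(n0, n1);
  }
};

inline int treeVote(const NumericMatrix &tree, const NumericMatrix &X,
                    int row) {
  int node = 0;
  while (tree(node, 0) > 0.5) {
    int f = static_cast<int>(tree(node, 0)) - 1;
    node = (X(row, f) <= tree(node, 1))
               ? static_cast<int>(tree(node, 2)) - 1
               : static_cast<int>(tree(node, 3)) - 1;
  }
  return static_cast<int>(tree(node, 4));
}

}  // namespace

// [[Rcpp::export(name = ".cppGrowTree")]]
NumericMatrix cppGrowTree(NumericMatrix X, IntegerVector y,
                          IntegerVector bootIdx, IntegerVector feats,
                          int minLeaf, int maxDepth) {
  Grower g(X, y, feats, minLeaf, maxDepth);
  std::vector<int> idx(bootIdx.size());
  for (int i = 0; i < bootIdx.size(); ++i) idx[i] = bootIdx[i] - 1;
  g.grow(idx, 0);
  NumericMatrix out(static_cast<int>(g.nodes.size()), 7);
  for (size_t i = 0; i < g.nodes.size(); ++i) {
    for (int j = 0; j < 7; ++j) out(i, j) = g.nodes[i][j];
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "vote", "n0", "n1");
  return out;
}

// votes of every tree on every row: n x n_trees integer matrix of 0/1
// [[Rcpp::export(name = ".cppForestVotes")]]
IntegerMatrix cppForestVotes(List trees, NumericMatrix X) {
  int n = X.nrow(), m = trees.size();
  IntegerMatrix votes(n, m);
  for (int t = 0; t < m; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) votes(i, t) = treeVote(tree, X, i);
  }
  return votes;
}
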