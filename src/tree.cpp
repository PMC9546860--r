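#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// binary-class Gini impurity; n1 = count of class 1, n = total
inline double gini_bin(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

// Recursive CART builder over a restricted feature set.
// Split = (feature, midpoint threshold) maximising the Gini gain; ties are
// broken by evaluating features in column order and thresholds in ascending
// order with a strict ">" so the first maximum wins (columns must be passed
// in the caller's canonical lexicographic order).
struct Builder {
  const NumericMatrix X;
  const IntegerVector y;
  int min_leaf;
  double n_root;
  std::vector<int> feature, left, right, nn;
  std::vector<double> threshold, prob, gain;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int ml)
      : X(X_), y(y_), min_leaf(ml), n_root((double)X_.nrow()) {}

  int build(std::vector<int>& idx) {
    const int node = (int)feature.size();
    const int n = (int)idx.size();
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += y[idx[i]];
    feature.push_back(0);
    threshold.push_back(NA_REAL);
    left.push_back(0);
    right.push_back(0);
    prob.push_back((double)n1 / (double)n);
    nn.push_back(n);
    gain.push_back(0.0);
    // stop: pure node or below the minimum splittable size
    if (n1 == 0 || n1 == n || n < 2 * min_leaf) return node;

    const double g_parent = gini_bin((double)n1, (double)n);
    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    const int p = X.ncol();
    std::vector<std::pair<double, int> > v(n);
    for (int j = 0; j < p; ++j) {
      // fast path for 0/1 columns (the common case for binary omics
      // features): one counting pass, single candidate threshold 0.5
      bool binary = true;
      int bl = 0, bl1 = 0;
      for (int i = 0; i < n; ++i) {
        double x = X(idx[i], j);
        if (x == 0.0) {
          ++bl;
          bl1 += y[idx[i]];
        } else if (x != 1.0) {
          binary = false;
          break;
        }
      }
      if (binary) {
        double nl = bl, nr = n - bl;
        if (nl >= min_leaf && nr >= min_leaf && bl > 0 && bl < n) {
          double nl1 = bl1, nr1 = n1 - bl1;
          double g = g_parent - (nl / n) * gini_bin(nl1, nl) -
                     (nr / n) * gini_bin(nr1, nr);
          if (g > best_gain) {
            best_gain = g;
            best_f = j;
            best_thr = 0.5;
          }
        }
        continue;
      }
      for (int i = 0; i < n; ++i)
        v[i] = std::make_pair(X(idx[i], j), (int)y[idx[i]]);
      std::sort(v.begin(), v.end());
      double nl = 0.0, nl1 = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        nl += 1.0;
        nl1 += v[i].second;
        if (v[i + 1].first > v[i].first) {
          double nr = n - nl, nr1 = n1 - nl1;
          if (nl < min_leaf || nr < min_leaf) continue;
          double g = g_parent - (nl / n) * gini_bin(nl1, nl) -
                     (nr / n) * gini_bin(nr1, nr);
          if (g > best_gain) {
            best_gain = g;
            best_f = j;
            best_thr = 0.5 * (v[i].first + v[i + 1].first);
          }
        }
      }
    }
    // stop: no strictly positive gain
    if (best_f < 0) return node;

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    feature[node] = best_f + 1;
    threshold[node] = best_thr;
    // gain is weighted by the node's share of in-bag samples so that the
    // per-tree tally sums to the tree's total impurity decrease
    gain[node] = ((double)n / n_root) * best_gain;
    int l = build(li);
    int r = build(ri);
    left[node] = l + 1;
    right[node] = r + 1;
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List fit_tree_cpp(NumericMatrix X, IntegerVector y, int min_leaf) {
  Builder b(X, y, min_leaf);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < (int)X.nrow(); ++i) idx[i] = i;
  b.build(idx);
  return List::create(_["feature"] = wrap(b.feature),
                      _["threshold"] = wrap(b.threshold),
                      _["left"] = wrap(b.left), _["right"] = wrap(b.right),
                      _["prob"] = wrap(b.prob), _["n"] = wrap(b.nn),
                      _["gain"] = wrap(b.gain));
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector prob, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != 0) {
      node = (X(i, feature[node] - 1) <= threshold[node]) ? left[node] - 1
                                                          : right[node] - 1;
    }
    out[i] = prob[node];
  }
  return out;
}
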