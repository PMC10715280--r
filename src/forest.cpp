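#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <functional>
#include <vector>

using namespace Rcpp;

// Minimal bagged-CART binary classifier (gini impurity, random feature
// subsets per node, unlimited depth). Implemented here because no tree
// ensemble package is available in the target environment. Determinism is
// guaranteed by a seeded mt19937; same seed + same data => identical model.

static inline double gini_imp(int pos, int n) {
  if (n == 0) return 0.0;
  const double p = (double)pos / n;
  return 2.0 * p * (1.0 - p);
}

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;    // split: x[feat] <= thr goes left
  std::vector<int> left, right;
  std::vector<double> value;  // leaf: fraction of positive class
};

static double tree_predict(const Tree& t, const double* x, int ncol_stride,
                           const NumericMatrix& X, int row) {
  (void)x; (void)ncol_stride;
  int node = 0;
  while (t.feat[node] >= 0) {
    node = (X(row, t.feat[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  NumericVector importance(p);
  NumericVector oob_sum(n);
  IntegerVector oob_cnt(n);
  List trees(ntree);

  std::vector<int> featpool(p);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    std::vector<char> inbag(n, 0);
    for (int i = 0; i < n; ++i) { rows[i] = pick(rng); inbag[rows[i]] = 1; }

    Tree tr;
    std::function<int(std::vector<int>&)> build = [&](std::vector<int>& idx) -> int {
      const int node = (int)tr.feat.size();
      tr.feat.push_back(-1); tr.thr.push_back(0.0);
      tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0.0);

      const int nn = (int)idx.size();
      int npos = 0;
      for (int r : idx) npos += y[r];
      if (npos == 0 || npos == nn || nn < 2 * min_node || nn < 2) {
        tr.value[node] = (double)npos / nn;
        return node;
      }

      // sample mtry distinct candidate features (partial Fisher-Yates)
      for (int f = 0; f < p; ++f) featpool[f] = f;
      int bf = -1; double bt = 0.0, bgain = 1e-12;
      const double parent = gini_imp(npos, nn);
      for (int k = 0; k < mtry && k < p; ++k) {
        std::uniform_int_distribution<int> pf(k, p - 1);
        std::swap(featpool[k], featpool[pf(rng)]);
        const int f = featpool[k];
        std::vector<int> ord(idx);
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
          const double xa = X(a, f), xb = X(b, f);
          return xa < xb || (xa == xb && a < b);
        });
        int lp = 0;
        for (int i = 0; i < nn - 1; ++i) {
          lp += y[ord[i]];
          const double xi = X(ord[i], f), xj = X(ord[i + 1], f);
          if (xi == xj) continue;
          const int nl = i + 1, nr = nn - nl;
          if (nl < min_node || nr < min_node) continue;
          const double child =
            (nl * gini_imp(lp, nl) + nr * gini_imp(npos - lp, nr)) / nn;
          const double gain = parent - child;
          if (gain > bgain) { bgain = gain; bf = f; bt = (xi + xj) / 2.0; }
        }
      }

      if (bf < 0) { tr.value[node] = (double)npos / nn; return node; }

      std::vector<int> li, ri;
      for (int r : idx) (X(r, bf) <= bt ? li : ri).push_back(r);
      importance[bf] += bgain * nn;
      const int L = build(li);
      const int R = build(ri);
      tr.feat[node] = bf; tr.thr[node] = bt;
      tr.left[node] = L; tr.right[node] = R;
      return node;
    };
    build(rows);

    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += tree_predict(tr, nullptr, 0, X, i);
        oob_cnt[i] += 1;
      }
    }

    trees[t] = List::create(
      _["feat"] = IntegerVector(tr.feat.begin(), tr.feat.end()),
      _["thr"] = NumericVector(tr.thr.begin(), tr.thr.end()),
      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
      _["value"] = NumericVector(tr.value.begin(), tr.value.end()));
  }

  NumericVector oob_prob(n);
  for (int i = 0; i < n; ++i)
    oob_prob[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  for (int f = 0; f < p; ++f) importance[f] /= ntree;

  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["oob_prob"] = oob_prob);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    Tree tr;
    IntegerVector feat = tl["feat"], left = tl["left"], right = tl["right"];
    NumericVector thr = tl["thr"], value = tl["value"];
    tr.feat.assign(feat.begin(), feat.end());
    tr.thr.assign(thr.begin(), thr.end());
    tr.left.assign(left.begin(), left.end());
    tr.right.assign(right.begin(), right.end());
    tr.value.assign(value.begin(), value.end());
    for (int i = 0; i < n; ++i) out[i] += tree_predict(tr, nullptr, 0, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
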