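// Bagged CART classification forest: Gini splits, mtry feature subsampling,
// bootstrap resampling (optionally stratified to the minority class size),
// out-of-bag vote tracking and total-Gini-decrease importance.
//
// Kept deliberately small: numeric feature matrix only (categorical
// predictors are one-hot encoded on the R side), majority-vote leaves,
// depth-first recursive building. Deterministic for a fixed seed.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

// xorshift64* generator: self-contained so forests are reproducible across
// platforms and independent of R's RNG state.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int var;        // -1 for leaf
  double thr;     // split: x[var] <= thr goes left
  int left, right;
  int pred;       // leaf class (majority)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int nclass, mtry, minnode;
  Rng& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int nclass_,
              int mtry_, int minnode_, Rng& rng_,
              std::vector<double>& imp)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), minnode(minnode_),
        rng(rng_), importance(imp) {}

  static double gini_impurity(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double g = 1.0;
    for (int c : cnt) {
      double p = static_cast<double>(c) / n;
      g -= p * p;
    }
    return g;
  }

  int majority(const std::vector<int>& cnt) {
    int best = 0;
    for (int k = 1; k < nclass; ++k) if (cnt[k] > cnt[best]) best = k;
    return best;
  }

  // builds subtree on sample indices [lo, hi) of idx; returns node id
  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    std::vector<int> cnt(nclass, 0);
    for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
    double imp = gini_impurity(cnt, n);

    int id = static_cast<int>(nodes.size());
    nodes.push_back(Node{-1, 0.0, -1, -1, majority(cnt)});
    if (n < 2 * minnode || imp <= 0.0) return id;

    int p = X.ncol();
    double best_gain = 0.0;
    int best_var = -1;
    double best_thr = 0.0;

    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + rng.unif_int(p - j);
      std::swap(feat[j], feat[k]);
    }

    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < m; ++j) {
      int v = feat[j];
      for (int i = 0; i < n; ++i) {
        vals[i] = {X(idx[lo + i], v), y[idx[lo + i]]};
      }
      std::sort(vals.begin(), vals.end());
      std::vector<int> lcnt(nclass, 0), rcnt(cnt);
      for (int i = 0; i < n - 1; ++i) {
        int cls = vals[i].second;
        lcnt[cls]++; rcnt[cls]--;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < minnode || nr < minnode) continue;
        double g = imp -
          (nl * gini_impurity(lcnt, nl) + nr * gini_impurity(rcnt, nr)) / n;
        if (g > best_gain + 1e-12) {
          best_gain = g;
          best_var = v;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_var < 0) return id;

    // partition idx[lo, hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], best_var) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == lo || mid == hi) return id;  // degenerate (ties)

    importance[best_var] += best_gain * n;
    nodes[id].var = best_var;
    nodes[id].thr = best_thr;
    int l = build(idx, lo, mid);
    nodes[id].left = l;
    int r = build(idx, mid, hi);
    nodes[id].right = r;
    return id;
  }
};

int tree_predict(const NumericMatrix& nodes, const NumericMatrix& X, int row) {
  int id = 0;
  while (true) {
    int var = static_cast<int>(nodes(id, 0));
    if (var < 0) return static_cast<int>(nodes(id, 4));
    id = (X(row, var) <= nodes(id, 1)) ? static_cast<int>(nodes(id, 2))
                                       : static_cast<int>(nodes(id, 3));
  }
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m(static_cast<int>(nodes.size()), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].var;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].pred;
  }
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int minnode, bool balanced, double seed) {
  int n = X.nrow(), p = X.ncol();
  Rng rng(static_cast<uint64_t>(seed) * 2862933555777941757ULL + 3037000493ULL);

  // per-class row indices for stratified (balanced) bootstrap
  std::vector<std::vector<int>> by_class(nclass);
  for (int i = 0; i < n; ++i) by_class[y[i]].push_back(i);
  int nmin = n;
  for (int k = 0; k < nclass; ++k) {
    if (!by_class[k].empty())
      nmin = std::min(nmin, static_cast<int>(by_class[k].size()));
  }

  List trees(ntree);
  std::vector<double> importance(p, 0.0);
  IntegerMatrix oob_votes(n, nclass);

  std::vector<int> bag;
  std::vector<char> inbag(n);
  for (int t = 0; t < ntree; ++t) {
    bag.clear();
    std::fill(inbag.begin(), inbag.end(), 0);
    if (balanced) {
      for (int k = 0; k < nclass; ++k) {
        const std::vector<int>& rows = by_class[k];
        if (rows.empty()) continue;
        for (int i = 0; i < nmin; ++i) {
          int r = rows[rng.unif_int(static_cast<int>(rows.size()))];
          bag.push_back(r);
          inbag[r] = 1;
        }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        int r = rng.unif_int(n);
        bag.push_back(r);
        inbag[r] = 1;
      }
    }

    TreeBuilder tb(X, y, nclass, mtry, minnode, rng, importance);
    tb.nodes.reserve(2 * bag.size());
    tb.build(bag, 0, static_cast<int>(bag.size()));
    NumericMatrix packed = pack_tree(tb.nodes);
    trees[t] = packed;

    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) oob_votes(i, tree_predict(packed, X, i))++;
    }
  }

  // OOB error: majority vote over trees where the row was out of bag
  int oob_n = 0, oob_wrong = 0;
  for (int i = 0; i < n; ++i) {
    int tot = 0, best = -1, bestv = -1;
    for (int k = 0; k < nclass; ++k) {
      tot += oob_votes(i, k);
      if (oob_votes(i, k) > bestv) { bestv = oob_votes(i, k); best = k; }
    }
    if (tot > 0) {
      oob_n++;
      if (best != y[i]) oob_wrong++;
    }
  }

  return List::create(
      Named("trees") = trees,
      Named("importance") = NumericVector(importance.begin(), importance.end()),
      Named("oob_votes") = oob_votes,
      Named("oob_error") = oob_n ? static_cast<double>(oob_wrong) / oob_n
                                 : NA_REAL);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix votes(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) votes(i, tree_predict(tree, X, i))++;
  }
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < nclass; ++k) votes(i, k) /= ntree;
  }
  return votes;
}
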