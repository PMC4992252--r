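// Cross-validated classification accuracy on feature subsets.
//
// Everything here is deterministic: the SVM dual coordinate descent visits
// samples in a fixed cyclic order, kNN breaks distance ties by training-row
// index and vote ties by the lowest class code, and the random forest draws
// all randomness from an xorshift generator seeded from the EvalConfig seed,
// so results never depend on worker count or R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// --- small deterministic RNG (xorshift64*) -------------------------------
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // integer in [0, n)
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Fold {
  std::vector<int> train, test;
};

// column-major training/test matrices for one fold, standardized by
// training-fold statistics only
struct FoldData {
  int n_train, n_test, p;
  std::vector<double> Xtr, Xte;  // col-major
  std::vector<int> ytr;
  double tr(int i, int j) const { return Xtr[static_cast<size_t>(j) * n_train + i]; }
  double te(int i, int j) const { return Xte[static_cast<size_t>(j) * n_test + i]; }
};

FoldData make_fold(const NumericMatrix& X, const IntegerVector& y,
                   const std::vector<int>& cols, const Fold& fold,
                   bool standardize) {
  FoldData fd;
  fd.n_train = static_cast<int>(fold.train.size());
  fd.n_test = static_cast<int>(fold.test.size());
  fd.p = static_cast<int>(cols.size());
  fd.Xtr.resize(static_cast<size_t>(fd.n_train) * fd.p);
  fd.Xte.resize(static_cast<size_t>(fd.n_test) * fd.p);
  fd.ytr.resize(fd.n_train);
  for (int i = 0; i < fd.n_train; ++i) fd.ytr[i] = y[fold.train[i]];
  for (int j = 0; j < fd.p; ++j) {
    const int c = cols[j];
    double m = 0.0, s = 0.0;
    for (int i = 0; i < fd.n_train; ++i) m += X(fold.train[i], c);
    m /= fd.n_train;
    for (int i = 0; i < fd.n_train; ++i) {
      const double d = X(fold.train[i], c) - m;
      s += d * d;
    }
    s = std::sqrt(s / fd.n_train);
    if (!standardize) { m = 0.0; s = 1.0; }
    if (s <= 0.0) s = 1.0;  // constant feature: centred to zero
    for (int i = 0; i < fd.n_train; ++i)
      fd.Xtr[static_cast<size_t>(j) * fd.n_train + i] = (X(fold.train[i], c) - m) / s;
    for (int i = 0; i < fd.n_test; ++i)
      fd.Xte[static_cast<size_t>(j) * fd.n_test + i] = (X(fold.test[i], c) - m) / s;
  }
  return fd;
}

// --- linear SVM: L1-loss dual coordinate descent --------------------------
// Solves min_w 0.5 w'w + C sum max(0, 1 - y_i w'x_i) with a regularized bias
// term (x augmented with a constant 1). Fixed cyclic visiting order.
void svm_binary_train(const FoldData& fd, const std::vector<int>& ybin,
                      double C, std::vector<double>& w) {
  const int n = fd.n_train, p = fd.p;
  w.assign(p + 1, 0.0);
  std::vector<double> alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 1.0;  // bias feature
    for (int j = 0; j < p; ++j) {
      const double v = fd.tr(i, j);
      q += v * v;
    }
    qii[i] = q;
  }
  const int max_pass = 1000;
  const double eps = 1e-3;
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = w[p];
      for (int j = 0; j < p; ++j) wx += w[j] * fd.tr(i, j);
      const double G = ybin[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * ybin[i];
        for (int j = 0; j < p; ++j) w[j] += d * fd.tr(i, j);
        w[p] += d;
      }
    }
    if (max_viol < eps) break;
  }
}

void svm_predict(const FoldData& fd, int n_classes, double C,
                 std::vector<int>& pred) {
  const int n = fd.n_train, p = fd.p, K = n_classes;
  const int n_models = (K == 2) ? 1 : K;
  std::vector<std::vector<double>> W(n_models);
  std::vector<int> ybin(n);
  for (int c = 0; c < n_models; ++c) {
    for (int i = 0; i < n; ++i) ybin[i] = (fd.ytr[i] == c) ? 1 : -1;
    svm_binary_train(fd, ybin, C, W[c]);
  }
  pred.assign(fd.n_test, 0);
  for (int i = 0; i < fd.n_test; ++i) {
    if (K == 2) {
      double dec = W[0][p];
      for (int j = 0; j < p; ++j) dec += W[0][j] * fd.te(i, j);
      pred[i] = (dec >= 0.0) ? 0 : 1;  // exact tie -> lowest class
    } else {
      int best = 0;
      double best_dec = -1e300;
      for (int c = 0; c < K; ++c) {
        double dec = W[c][p];
        for (int j = 0; j < p; ++j) dec += W[c][j] * fd.te(i, j);
        if (dec > best_dec) { best_dec = dec; best = c; }
      }
      pred[i] = best;
    }
  }
}

// --- k-nearest neighbours --------------------------------------------------
void knn_predict(const FoldData& fd, int n_classes, int k,
                 std::vector<int>& pred) {
  const int n = fd.n_train, p = fd.p;
  if (k > n) k = n;
  pred.assign(fd.n_test, 0);
  std::vector<std::pair<double, int>> d(n);
  std::vector<int> votes(n_classes);
  for (int i = 0; i < fd.n_test; ++i) {
    for (int t = 0; t < n; ++t) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = fd.te(i, j) - fd.tr(t, j);
        s += diff * diff;
      }
      d[t] = {s, t};
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());  // (dist, index)
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < k; ++t) ++votes[fd.ytr[d[t].second]];
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[c] > votes[best]) best = c;  // vote tie -> lowest class
    pred[i] = best;
  }
}

// --- Gaussian naive Bayes --------------------------------------------------
void nb_predict(const FoldData& fd, int n_classes, std::vector<int>& pred) {
  const int n = fd.n_train, p = fd.p, K = n_classes;
  std::vector<int> cnt(K, 0);
  std::vector<double> mu(static_cast<size_t>(K) * p, 0.0),
      var(static_cast<size_t>(K) * p, 0.0);
  for (int i = 0; i < n; ++i) ++cnt[fd.ytr[i]];
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) mu[static_cast<size_t>(fd.ytr[i]) * p + j] += fd.tr(i, j);
  for (int c = 0; c < K; ++c)
    if (cnt[c] > 0)
      for (int j = 0; j < p; ++j) mu[static_cast<size_t>(c) * p + j] /= cnt[c];
  double max_var = 0.0;
  for (int j = 0; j < p; ++j) {
    double m = 0.0, v = 0.0;
    for (int i = 0; i < n; ++i) m += fd.tr(i, j);
    m /= n;
    for (int i = 0; i < n; ++i) { const double dd = fd.tr(i, j) - m; v += dd * dd; }
    v /= n;
    if (v > max_var) max_var = v;
  }
  const double eps = 1e-9 * (max_var > 0 ? max_var : 1.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) {
      const double dd = fd.tr(i, j) - mu[static_cast<size_t>(fd.ytr[i]) * p + j];
      var[static_cast<size_t>(fd.ytr[i]) * p + j] += dd * dd;
    }
  for (int c = 0; c < K; ++c)
    if (cnt[c] > 0)
      for (int j = 0; j < p; ++j)
        var[static_cast<size_t>(c) * p + j] = var[static_cast<size_t>(c) * p + j] / cnt[c] + eps;
  pred.assign(fd.n_test, 0);
  for (int i = 0; i < fd.n_test; ++i) {
    int best = 0;
    double best_lp = -1e300;
    for (int c = 0; c < K; ++c) {
      if (cnt[c] == 0) continue;
      double lp = std::log(static_cast<double>(cnt[c]) / n);
      for (int j = 0; j < p; ++j) {
        const double v = var[static_cast<size_t>(c) * p + j];
        const double dd = fd.te(i, j) - mu[static_cast<size_t>(c) * p + j];
        lp += -0.5 * std::log(2.0 * M_PI * v) - dd * dd / (2.0 * v);
      }
      if (lp > best_lp) { best_lp = lp; best = c; }
    }
    pred[i] = best;
  }
}

// --- random forest ---------------------------------------------------------
struct TreeNode {
  int feature = -1;        // -1: leaf
  double threshold = 0.0;  // go left if x <= threshold
  int left = -1, right = -1, pred = 0;
};

int rf_build_node(const FoldData& fd, std::vector<int>& idx, int lo, int hi,
                  int n_classes, int mtry, int depth, XorShift& rng,
                  std::vector<TreeNode>& tree, std::vector<int>& feat_pool) {
  TreeNode node;
  std::vector<int> cnt(n_classes, 0);
  for (int t = lo; t < hi; ++t) ++cnt[fd.ytr[idx[t]]];
  int maj = 0;
  for (int c = 1; c < n_classes; ++c) if (cnt[c] > cnt[maj]) maj = c;
  node.pred = maj;
  const int n_node = hi - lo;
  bool pure = true;
  for (int c = 0; c < n_classes; ++c)
    if (cnt[c] > 0 && cnt[c] < n_node) { pure = false; break; }
  if (pure || n_node < 2 || depth > 30) {
    tree.push_back(node);
    return static_cast<int>(tree.size()) - 1;
  }
  // sample mtry candidate features without replacement
  for (int j = 0; j < fd.p; ++j) feat_pool[j] = j;
  int n_pool = fd.p;
  double best_score = 1e300, best_thr = 0.0;
  int best_feat = -1;
  std::vector<std::pair<double, int>> vals(n_node);
  std::vector<int> left_cnt(n_classes);
  for (int m = 0; m < mtry && n_pool > 0; ++m) {
    const int pick = rng.unif_int(n_pool);
    const int f = feat_pool[pick];
    feat_pool[pick] = feat_pool[--n_pool];
    for (int t = 0; t < n_node; ++t)
      vals[t] = {fd.tr(idx[lo + t], f), fd.ytr[idx[lo + t]]};
    std::sort(vals.begin(), vals.end());
    std::fill(left_cnt.begin(), left_cnt.end(), 0);
    int n_left = 0;
    for (int t = 0; t < n_node - 1; ++t) {
      ++left_cnt[vals[t].second];
      ++n_left;
      if (vals[t + 1].first <= vals[t].first) continue;  // not a cut point
      const int n_right = n_node - n_left;
      double gl = 1.0, gr = 1.0;
      for (int c = 0; c < n_classes; ++c) {
        const double pl = static_cast<double>(left_cnt[c]) / n_left;
        const double pr = static_cast<double>(cnt[c] - left_cnt[c]) / n_right;
        gl -= pl * pl;
        gr -= pr * pr;
      }
      const double score = (n_left * gl + n_right * gr) / n_node;
      if (score < best_score - 1e-12) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_feat < 0) {
    tree.push_back(node);
    return static_cast<int>(tree.size()) - 1;
  }
  const int mid = static_cast<int>(
      std::partition(idx.begin() + lo, idx.begin() + hi,
                     [&](int t) { return fd.tr(t, best_feat) <= best_thr; }) -
      idx.begin());
  if (mid == lo || mid == hi) {
    tree.push_back(node);
    return static_cast<int>(tree.size()) - 1;
  }
  node.feature = best_feat;
  node.threshold = best_thr;
  tree.push_back(node);
  const int self = static_cast<int>(tree.size()) - 1;
  const int l = rf_build_node(fd, idx, lo, mid, n_classes, mtry, depth + 1, rng, tree, feat_pool);
  const int r = rf_build_node(fd, idx, mid, hi, n_classes, mtry, depth + 1, rng, tree, feat_pool);
  tree[self].left = l;
  tree[self].right = r;
  return self;
}

void rf_predict(const FoldData& fd, int n_classes, int n_trees, int mtry_arg,
                uint64_t seed, std::vector<int>& pred) {
  const int n = fd.n_train, p = fd.p;
  int mtry = mtry_arg > 0 ? mtry_arg : std::max(1, static_cast<int>(std::floor(std::sqrt(static_cast<double>(p)))));
  if (mtry > p) mtry = p;
  std::vector<std::vector<int>> votes(fd.n_test, std::vector<int>(n_classes, 0));
  std::vector<int> feat_pool(p);
  for (int t = 0; t < n_trees; ++t) {
    XorShift rng(seed * 0x9E3779B97F4A7C15ULL + 0x632BE59BD9B4E019ULL * (t + 1));
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);  // bootstrap
    std::vector<TreeNode> tree;
    tree.reserve(2 * n);
    const int root = rf_build_node(fd, idx, 0, n, n_classes, mtry, 0, rng, tree, feat_pool);
    for (int i = 0; i < fd.n_test; ++i) {
      int node = root;
      while (tree[node].feature >= 0)
        node = (fd.te(i, tree[node].feature) <= tree[node].threshold)
                   ? tree[node].left
                   : tree[node].right;
      ++votes[i][tree[node].pred];
    }
  }
  pred.assign(fd.n_test, 0);
  for (int i = 0; i < fd.n_test; ++i) {
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[i][c] > votes[i][best]) best = c;
    pred[i] = best;
  }
}

// --- driver ----------------------------------------------------------------
std::vector<Fold> split_folds(const IntegerVector& fold_id) {
  const int n = fold_id.size();
  int n_folds = 0;
  for (int i = 0; i < n; ++i) n_folds = std::max(n_folds, fold_id[i] + 1);
  std::vector<Fold> folds(n_folds);
  for (int f = 0; f < n_folds; ++f)
    for (int i = 0; i < n; ++i)
      (fold_id[i] == f ? folds[f].test : folds[f].train).push_back(i);
  return folds;
}

double cv_accuracy_impl(const NumericMatrix& X, const IntegerVector& y,
                        int n_classes, const std::vector<int>& cols,
                        const std::vector<Fold>& folds, int classifier,
                        double cost, int k, int n_trees, int mtry,
                        uint64_t seed, bool standardize) {
  int correct = 0, total = 0;
  std::vector<int> pred;
  for (size_t f = 0; f < folds.size(); ++f) {
    if (folds[f].test.empty()) continue;
    FoldData fd = make_fold(X, y, cols, folds[f], standardize);
    switch (classifier) {
      case 0: svm_predict(fd, n_classes, cost, pred); break;
      case 1: knn_predict(fd, n_classes, k, pred); break;
      case 2: nb_predict(fd, n_classes, pred); break;
      default: rf_predict(fd, n_classes, n_trees, mtry, seed + 1315423911ULL * (f + 1), pred); break;
    }
    for (size_t i = 0; i < folds[f].test.size(); ++i) {
      if (pred[i] == y[folds[f].test[i]]) ++correct;
      ++total;
    }
  }
  return total > 0 ? static_cast<double>(correct) / total : NA_REAL;
}

}  // namespace

// [[Rcpp::export]]
double cv_accuracy_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                       IntegerVector cols, IntegerVector fold_id,
                       int classifier, double cost, int k, int n_trees,
                       int mtry, double seed, bool standardize) {
  std::vector<int> cc(cols.begin(), cols.end());
  std::vector<Fold> folds = split_folds(fold_id);
  return cv_accuracy_impl(X, y, n_classes, cc, folds, classifier, cost, k,
                          n_trees, mtry, static_cast<uint64_t>(seed), standardize);
}

// [[Rcpp::export]]
NumericVector pair_accuracies_cpp(NumericMatrix X, IntegerVector y,
                                  int n_classes, IntegerMatrix pairs,
                                  IntegerVector fold_id, int classifier,
                                  double cost, int k, int n_trees, int mtry,
                                  double seed, bool standardize) {
  std::vector<Fold> folds = split_folds(fold_id);
  const int np = pairs.nrow();
  NumericVector out(np);
  for (int r = 0; r < np; ++r) {
    std::vector<int> cc = {pairs(r, 0), pairs(r, 1)};
    out[r] = cv_accuracy_impl(X, y, n_classes, cc, folds, classifier, cost, k,
                              n_trees, mtry, static_cast<uint64_t>(seed), standardize);
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
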