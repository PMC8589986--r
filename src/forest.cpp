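// Balanced-class random forest for binary classification.
//
// Each tree is grown on a class-stratified sample drawn WITHOUT replacement
// (sampsize[k] rows from class k), unlike standard bootstrap bagging.  Trees
// are unpruned CART with Gini splits on `mtry` randomly chosen features.
// Out-of-bag votes, permutation importance, proximities and a cumulative
// OOB error trace are accumulated during the fit.  All randomness comes
// from R's RNG stream so results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline int runif_int(int n) {
  // uniform integer on [0, n)
  int k = static_cast<int>(std::floor(R::unif_rand() * n));
  return (k >= n) ? n - 1 : k;
}

// first k elements of a partial Fisher-Yates shuffle of `pool`
void sample_k_inplace(std::vector<int>& pool, int k) {
  const int n = static_cast<int>(pool.size());
  for (int i = 0; i < k; ++i) {
    int j = i + runif_int(n - i);
    std::swap(pool[i], pool[j]);
  }
  pool.resize(k);
}

struct Tree {
  std::vector<int> splitvar;  // -1 for leaf
  std::vector<double> splitval;
  std::vector<int> left, right, pred;

  int add_node() {
    splitvar.push_back(-1);
    splitval.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0);
    return static_cast<int>(splitvar.size()) - 1;
  }

  int classify(const NumericMatrix& x, int row) const {
    int node = 0;
    while (splitvar[node] >= 0) {
      node = (x(row, splitvar[node]) <= splitval[node]) ? left[node]
                                                        : right[node];
    }
    return pred[node];
  }

  int terminal(const NumericMatrix& x, int row) const {
    int node = 0;
    while (splitvar[node] >= 0) {
      node = (x(row, splitvar[node]) <= splitval[node]) ? left[node]
                                                        : right[node];
    }
    return node;
  }

  // classify with one feature's value replaced (for permutation importance)
  int classify_swapped(const NumericMatrix& x, int row, int var,
                       double value) const {
    int node = 0;
    while (splitvar[node] >= 0) {
      double v = (splitvar[node] == var) ? value : x(row, splitvar[node]);
      node = (v <= splitval[node]) ? left[node] : right[node];
    }
    return pred[node];
  }
};

struct NodeJob {
  int node, begin, end;
};

// Grow one CART tree on rows idx[0..n) of x. Gini criterion, midpoint
// thresholds, ties broken by first candidate encountered (deterministic
// given the RNG-ordered feature draw).
void grow_tree(const NumericMatrix& x, const IntegerVector& y,
               std::vector<int>& idx, int mtry, Tree& tree) {
  const int p = x.ncol();
  std::vector<int> feat_pool(p);
  std::vector<std::pair<double, int>> vals;  // (value, class)
  std::vector<NodeJob> stack;

  tree.add_node();
  stack.push_back({0, 0, static_cast<int>(idx.size())});

  while (!stack.empty()) {
    NodeJob job = stack.back();
    stack.pop_back();
    const int n = job.end - job.begin;

    int n1 = 0;
    for (int i = job.begin; i < job.end; ++i) n1 += y[idx[i]];
    const int n0 = n - n1;
    // majority prediction, ties to class 0
    tree.pred[job.node] = (n1 > n0) ? 1 : 0;
    if (n0 == 0 || n1 == 0 || n < 2) continue;  // pure or too small: leaf

    const double gini_parent =
        1.0 - (double(n0) * n0 + double(n1) * n1) / (double(n) * n);

    for (int f = 0; f < p; ++f) feat_pool[f] = f;
    int m = std::min(mtry, p);
    // partial shuffle; try the m drawn features
    for (int i = 0; i < m; ++i) {
      int j = i + runif_int(p - i);
      std::swap(feat_pool[i], feat_pool[j]);
    }

    double best_dec = 0.0, best_thr = 0.0;
    int best_var = -1;

    for (int fi = 0; fi < m; ++fi) {
      const int f = feat_pool[fi];
      vals.clear();
      for (int i = job.begin; i < job.end; ++i)
        vals.emplace_back(x(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant

      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const int l0 = nl - l1, r1 = n1 - l1, r0 = nr - r1;
        const double gini_l =
            1.0 - (double(l0) * l0 + double(l1) * l1) / (double(nl) * nl);
        const double gini_r =
            1.0 - (double(r0) * r0 + double(r1) * r1) / (double(nr) * nr);
        const double dec =
            gini_parent - (nl * gini_l + nr * gini_r) / double(n);
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_var = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_var < 0) continue;  // no improving split among drawn features

    // partition idx[begin..end) by the chosen split
    int mid = job.begin;
    for (int i = job.begin; i < job.end; ++i) {
      if (x(idx[i], best_var) <= best_thr) std::swap(idx[mid++], idx[i]);
    }
    if (mid == job.begin || mid == job.end) continue;  // degenerate

    tree.splitvar[job.node] = best_var;
    tree.splitval[job.node] = best_thr;
    const int lnode = tree.add_node();
    const int rnode = tree.add_node();
    tree.left[job.node] = lnode;
    tree.right[job.node] = rnode;
    stack.push_back({lnode, job.begin, mid});
    stack.push_back({rnode, mid, job.end});
  }
}

List pack_tree(const Tree& t) {
  const int nn = static_cast<int>(t.splitvar.size());
  IntegerMatrix nodes(nn, 4);
  NumericVector sv(nn);
  for (int i = 0; i < nn; ++i) {
    nodes(i, 0) = t.splitvar[i];
    nodes(i, 1) = t.left[i];
    nodes(i, 2) = t.right[i];
    nodes(i, 3) = t.pred[i];
    sv[i] = t.splitval[i];
  }
  return List::create(_["nodes"] = nodes, _["splitval"] = sv);
}

Tree unpack_tree(const List& lt) {
  IntegerMatrix nodes = lt["nodes"];
  NumericVector sv = lt["splitval"];
  Tree t;
  const int nn = nodes.nrow();
  t.splitvar.resize(nn);
  t.splitval.resize(nn);
  t.left.resize(nn);
  t.right.resize(nn);
  t.pred.resize(nn);
  for (int i = 0; i < nn; ++i) {
    t.splitvar[i] = nodes(i, 0);
    t.left[i] = nodes(i, 1);
    t.right[i] = nodes(i, 2);
    t.pred[i] = nodes(i, 3);
    t.splitval[i] = sv[i];
  }
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix x, IntegerVector y, int ntree, int mtry,
                IntegerVector sampsize, bool keep_forest, bool importance,
                bool proximity, bool oob_trace) {
  const int n = x.nrow(), p = x.ncol();
  std::vector<int> class0, class1;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? class1 : class0).push_back(i);
  const int s0 = sampsize[0], s1 = sampsize[1];
  if (s0 < 1 || s1 < 1 || s0 > static_cast<int>(class0.size()) ||
      s1 > static_cast<int>(class1.size()))
    stop("sampsize exceeds a class size (or is < 1)");

  IntegerMatrix votes(n, 2);           // OOB votes per class
  IntegerVector inbag_count(n);        // times each row was in-bag
  NumericVector imp(p), imp_sq(p);     // permutation importance accumulators
  NumericMatrix prox;
  if (proximity) prox = NumericMatrix(n, n);
  NumericVector trace(oob_trace ? ntree : 0);
  List forest(keep_forest ? ntree : 0);

  std::vector<char> inbag(n);
  std::vector<int> oob_idx, term(n), perm;

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> bag0 = class0, bag1 = class1;
    sample_k_inplace(bag0, s0);
    sample_k_inplace(bag1, s1);
    std::vector<int> idx(bag0);
    idx.insert(idx.end(), bag1.begin(), bag1.end());

    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i : idx) {
      inbag[i] = 1;
      ++inbag_count[i];
    }

    Tree tree;
    grow_tree(x, y, idx, mtry, tree);

    oob_idx.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_idx.push_back(i);

    int correct = 0;
    for (int i : oob_idx) {
      int cls = tree.classify(x, i);
      ++votes(i, cls);
      if (cls == y[i]) ++correct;
    }

    if (importance && !oob_idx.empty()) {
      const int no = static_cast<int>(oob_idx.size());
      perm.resize(no);
      for (int f = 0; f < p; ++f) {
        for (int i = 0; i < no; ++i) perm[i] = i;
        for (int i = 0; i < no - 1; ++i) {
          int j = i + runif_int(no - i);
          std::swap(perm[i], perm[j]);
        }
        int correct_perm = 0;
        for (int i = 0; i < no; ++i) {
          double v = x(oob_idx[perm[i]], f);
          if (tree.classify_swapped(x, oob_idx[i], f, v) == y[oob_idx[i]])
            ++correct_perm;
        }
        double d = double(correct - correct_perm) / no;
        imp[f] += d;
        imp_sq[f] += d * d;
      }
    }

    if (proximity) {
      for (int i = 0; i < n; ++i) term[i] = tree.terminal(x, i);
      for (int i = 0; i < n; ++i)
        for (int j = i; j < n; ++j)
          if (term[i] == term[j]) {
            prox(i, j) += 1.0;
            if (j > i) prox(j, i) += 1.0;
          }
    }

    if (oob_trace) {
      int err = 0, avail = 0;
      for (int i = 0; i < n; ++i) {
        if (votes(i, 0) + votes(i, 1) == 0) continue;
        ++avail;
        int pred = (votes(i, 1) > votes(i, 0)) ? 1 : 0;
        if (pred != y[i]) ++err;
      }
      trace[t] = avail ? double(err) / avail : NA_REAL;
    }

    if (keep_forest) forest[t] = pack_tree(tree);
  }

  if (proximity) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) prox(i, j) /= ntree;
  }

  NumericVector imp_mean(p), imp_sd(p);
  if (importance) {
    for (int f = 0; f < p; ++f) {
      imp_mean[f] = imp[f] / ntree;
      double var = imp_sq[f] / ntree - imp_mean[f] * imp_mean[f];
      imp_sd[f] = std::sqrt(std::max(var, 0.0) / ntree);
    }
  }

  return List::create(
      _["votes"] = votes, _["inbag_count"] = inbag_count,
      _["importance"] = importance ? (SEXP)imp_mean : R_NilValue,
      _["importance_sd"] = importance ? (SEXP)imp_sd : R_NilValue,
      _["proximity"] = proximity ? (SEXP)prox : R_NilValue,
      _["oob_trace"] = oob_trace ? (SEXP)trace : R_NilValue,
      _["forest"] = keep_forest ? (SEXP)forest : R_NilValue);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix newx) {
  const int n = newx.nrow(), ntree = forest.size();
  NumericMatrix votes(n, 2);
  for (int t = 0; t < ntree; ++t) {
    Tree tree = unpack_tree(forest[t]);
    for (int i = 0; i < n; ++i) votes(i, tree.classify(newx, i)) += 1.0;
  }
  for (int i = 0; i < n; ++i) {
    votes(i, 0) /= ntree;
    votes(i, 1) /= ntree;
  }
  return votes;
}
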