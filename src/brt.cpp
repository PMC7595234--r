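// Stagewise gradient boosting with best-first regression trees.
//
// Each tree is grown by executing `tree_complexity` best-first splits
// (so a tree has tree_complexity + 1 terminal nodes), fit to the current
// residuals on a random bag of rows, squared-error loss throughout.
// Categorical predictors are split by level subsets: levels present in a
// node are ordered by their mean residual and scanned as if ordered,
// which yields the optimal subset split for squared error.
//
// Numeric split search uses histogram binning: candidate thresholds are
// the (at most 1023) value quantiles of each column, computed once per
// call; when a column has at most 1024 distinct values the bins are the
// exact values and the search is exact. Split thresholds are stored as
// actual data values with a `x <= thr` left convention.
//
// Trees are exported as plain numeric matrices (one row per node) so a
// fit can be continued across calls: the caller keeps the running
// predictions and the accumulated tree list on the R side. Randomness
// (bagging) comes from R's RNG, so fits are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// tree matrix column layout
enum { COL_VAR = 0, COL_THR, COL_LMASK, COL_RMASK, COL_LEFT, COL_RIGHT,
       COL_MAJ, COL_VALUE, N_COL };

static const int MAX_BINS = 1024;

struct FeatureBins {
  bool is_cat;
  int n_bins;                   // categorical: number of levels
  std::vector<uint16_t> code;   // per-row bin / level code
  std::vector<double> thr;      // numeric: threshold after bin b (size n_bins-1)
};

struct BuildNode {
  std::vector<int> rows;
  double sum;
  int node_id;
  bool has_split;
  int var;
  double thr;
  uint64_t lmask, rmask;
  int split_bin;                // numeric: bin index of the chosen threshold
  double improve;
};

static void make_bins(const double *x, int n, FeatureBins &fb) {
  fb.is_cat = false;
  std::vector<double> v(x, x + n);
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  fb.thr.clear();
  if ((int)v.size() <= MAX_BINS) {
    fb.thr.assign(v.begin(), v.end() - 1);   // exact: one bin per value
  } else {
    for (int q = 1; q < MAX_BINS; ++q) {
      double t = v[(size_t)((double)q * v.size() / MAX_BINS)];
      if (fb.thr.empty() || t > fb.thr.back()) fb.thr.push_back(t);
    }
  }
  fb.n_bins = (int)fb.thr.size() + 1;
  fb.code.resize(n);
  for (int i = 0; i < n; ++i)
    fb.code[i] = (uint16_t)(std::lower_bound(fb.thr.begin(), fb.thr.end(),
                                             x[i]) - fb.thr.begin());
}

static void best_split(BuildNode &nd, const std::vector<FeatureBins> &bins,
                       const std::vector<double> &resid, int min_obs,
                       std::vector<double> &hsum, std::vector<double> &hcnt) {
  nd.has_split = false;
  nd.improve = 0.0;
  const int n = (int)nd.rows.size();
  if (n < 2 * min_obs) return;
  const double s_all = nd.sum;
  const double base = s_all * s_all / n;
  const int p = (int)bins.size();

  std::vector<int> lev_id;

  for (int j = 0; j < p; ++j) {
    const FeatureBins &fb = bins[j];
    const int nb = fb.n_bins;
    if (nb < 2) continue;
    std::fill(hsum.begin(), hsum.begin() + nb, 0.0);
    std::fill(hcnt.begin(), hcnt.begin() + nb, 0.0);
    for (int k = 0; k < n; ++k) {
      int r = nd.rows[k];
      int b = fb.code[r];
      hsum[b] += resid[r];
      hcnt[b] += 1.0;
    }
    if (fb.is_cat) {
      lev_id.clear();
      for (int b = 0; b < nb; ++b) if (hcnt[b] > 0) lev_id.push_back(b);
      if ((int)lev_id.size() < 2) continue;
      std::sort(lev_id.begin(), lev_id.end(), [&](int a, int b) {
        return hsum[a] / hcnt[a] < hsum[b] / hcnt[b];
      });
      double sl = 0.0, cl = 0.0;
      uint64_t mask = 0;
      for (size_t k = 0; k + 1 < lev_id.size(); ++k) {
        sl += hsum[lev_id[k]];
        cl += hcnt[lev_id[k]];
        mask |= (1ULL << lev_id[k]);
        double cr = n - cl;
        if (cl < min_obs || cr < min_obs) continue;
        double sr = s_all - sl;
        double imp = sl * sl / cl + sr * sr / cr - base;
        if (imp > nd.improve) {
          nd.improve = imp;
          nd.has_split = true;
          nd.var = j;
          nd.thr = NA_REAL;
          nd.lmask = mask;
          uint64_t rm = 0;
          for (size_t q = k + 1; q < lev_id.size(); ++q)
            rm |= (1ULL << lev_id[q]);
          nd.rmask = rm;
        }
      }
    } else {
      double sl = 0.0, cl = 0.0;
      for (int b = 0; b < nb - 1; ++b) {
        sl += hsum[b];
        cl += hcnt[b];
        double cr = n - cl;
        if (cl < min_obs || cr < min_obs || hcnt[b] == 0) continue;
        double sr = s_all - sl;
        double imp = sl * sl / cl + sr * sr / cr - base;
        if (imp > nd.improve) {
          nd.improve = imp;
          nd.has_split = true;
          nd.var = j;
          nd.thr = fb.thr[b];
          nd.split_bin = b;
          nd.lmask = 0;
          nd.rmask = 0;
        }
      }
    }
  }
}

static double node_value(const NumericMatrix &tree, const double *X, int n,
                         const IntegerVector &cat_levels, int i,
                         long *n_unseen) {
  int node = 0;
  while (tree(node, COL_VAR) >= 0) {
    int j = (int)tree(node, COL_VAR);
    double x = X[(size_t)j * n + i];
    bool goleft;
    if (cat_levels[j] > 0) {
      uint64_t lm = (uint64_t)tree(node, COL_LMASK);
      uint64_t rm = (uint64_t)tree(node, COL_RMASK);
      int lv = (int)x;
      uint64_t bit = (lv >= 0 && lv < 53) ? (1ULL << lv) : 0;
      if (lm & bit) goleft = true;
      else if (rm & bit) goleft = false;
      else { goleft = tree(node, COL_MAJ) == 0.0; if (n_unseen) ++*n_unseen; }
    } else {
      goleft = x <= tree(node, COL_THR);
    }
    node = (int)tree(node, goleft ? COL_LEFT : COL_RIGHT);
  }
  return tree(node, COL_VALUE);
}

// [[Rcpp::export]]
List boost_more_cpp(NumericMatrix X, IntegerVector cat_levels,
                    NumericVector y, NumericVector pred_in,
                    int n_trees, int tree_complexity, double learning_rate,
                    double bag_fraction, int min_obs) {
  const int n = X.nrow(), p = X.ncol();
  const double *Xp = X.begin();
  std::vector<double> pred(pred_in.begin(), pred_in.end());
  std::vector<double> resid(n);
  NumericVector influence(p);
  List trees(n_trees);
  std::vector<int> idx(n);

  std::vector<FeatureBins> bins(p);
  int max_bins = 2;
  for (int j = 0; j < p; ++j) {
    if (cat_levels[j] > 0) {
      bins[j].is_cat = true;
      bins[j].n_bins = cat_levels[j];
      bins[j].code.resize(n);
      for (int i = 0; i < n; ++i) {
        int lv = (int)Xp[(size_t)j * n + i];
        bins[j].code[i] = (uint16_t)((lv >= 0 && lv < cat_levels[j]) ? lv : 0);
      }
    } else {
      make_bins(Xp + (size_t)j * n, n, bins[j]);
    }
    if (bins[j].n_bins > max_bins) max_bins = bins[j].n_bins;
  }
  std::vector<double> hsum(max_bins), hcnt(max_bins);

  int m = (int)std::lround(bag_fraction * n);
  if (m < 2) m = 2;
  if (m > n) m = n;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];

    // bag: m distinct rows via partial Fisher-Yates on R's RNG
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int k = 0; k < m; ++k) {
      int j = k + (int)(unif_rand() * (n - k));
      if (j >= n) j = n - 1;
      std::swap(idx[k], idx[j]);
    }

    std::vector<double> var_v, thr_v, lm_v, rm_v, left_v, right_v, maj_v, val_v;
    auto push_leaf = [&]() {
      var_v.push_back(-1); thr_v.push_back(NA_REAL);
      lm_v.push_back(0); rm_v.push_back(0);
      left_v.push_back(-1); right_v.push_back(-1);
      maj_v.push_back(0); val_v.push_back(0);
      return (int)var_v.size() - 1;
    };

    std::vector<BuildNode> leaves;
    {
      BuildNode root;
      root.rows.assign(idx.begin(), idx.begin() + m);
      root.sum = 0.0;
      for (int k = 0; k < m; ++k) root.sum += resid[root.rows[k]];
      root.node_id = push_leaf();
      best_split(root, bins, resid, min_obs, hsum, hcnt);
      leaves.push_back(std::move(root));
    }

    for (int s = 0; s < tree_complexity; ++s) {
      int best = -1;
      double best_imp = 0.0;
      for (size_t k = 0; k < leaves.size(); ++k)
        if (leaves[k].has_split && leaves[k].improve > best_imp) {
          best_imp = leaves[k].improve;
          best = (int)k;
        }
      if (best < 0) break;

      BuildNode nd = std::move(leaves[best]);
      leaves.erase(leaves.begin() + best);

      BuildNode lchild, rchild;
      lchild.sum = rchild.sum = 0.0;
      const FeatureBins &fb = bins[nd.var];
      for (int r : nd.rows) {
        bool goleft;
        if (fb.is_cat) goleft = (nd.lmask >> fb.code[r]) & 1ULL;
        else goleft = fb.code[r] <= nd.split_bin;
        if (goleft) { lchild.rows.push_back(r); lchild.sum += resid[r]; }
        else        { rchild.rows.push_back(r); rchild.sum += resid[r]; }
      }
      lchild.node_id = push_leaf();
      rchild.node_id = push_leaf();

      var_v[nd.node_id] = nd.var;
      thr_v[nd.node_id] = nd.thr;
      lm_v[nd.node_id] = (double)nd.lmask;
      rm_v[nd.node_id] = (double)nd.rmask;
      left_v[nd.node_id] = lchild.node_id;
      right_v[nd.node_id] = rchild.node_id;
      maj_v[nd.node_id] = lchild.rows.size() >= rchild.rows.size() ? 0 : 1;
      influence[nd.var] += nd.improve;

      best_split(lchild, bins, resid, min_obs, hsum, hcnt);
      best_split(rchild, bins, resid, min_obs, hsum, hcnt);
      leaves.push_back(std::move(lchild));
      leaves.push_back(std::move(rchild));
    }

    for (const BuildNode &lf : leaves)
      if (!lf.rows.empty())
        val_v[lf.node_id] = lf.sum / (double)lf.rows.size();

    const int nn = (int)var_v.size();
    NumericMatrix tree(nn, N_COL);
    for (int q = 0; q < nn; ++q) {
      tree(q, COL_VAR) = var_v[q];   tree(q, COL_THR) = thr_v[q];
      tree(q, COL_LMASK) = lm_v[q];  tree(q, COL_RMASK) = rm_v[q];
      tree(q, COL_LEFT) = left_v[q]; tree(q, COL_RIGHT) = right_v[q];
      tree(q, COL_MAJ) = maj_v[q];   tree(q, COL_VALUE) = val_v[q];
    }
    trees[t] = tree;

    for (int i = 0; i < n; ++i)
      pred[i] += learning_rate * node_value(tree, Xp, n, cat_levels, i,
                                            nullptr);
  }

  return List::create(_["trees"] = trees,
                      _["pred"] = NumericVector(pred.begin(), pred.end()),
                      _["influence"] = influence);
}

// [[Rcpp::export]]
List predict_trees_cpp(List trees, NumericMatrix X, IntegerVector cat_levels,
                       double learning_rate) {
  const int n = X.nrow();
  const double *Xp = X.begin();
  NumericVector out(n);
  long n_unseen = 0;
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i)
      out[i] += learning_rate * node_value(tree, Xp, n, cat_levels, i,
                                           &n_unseen);
  }
  return List::create(_["pred"] = out, _["n_unseen"] = (double)n_unseen);
}
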