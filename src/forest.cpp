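// A compact random-forest classifier (binary, Gini criterion) with
// bootstrap sampling, out-of-bag scoring, warm-start growth across a grid
// of ensemble sizes, and normalized Gini (mean-decrease-impurity) feature
// importances. Deterministic for a given seed: the RNG is a self-contained
// splitmix64/xoshiro generator, so results do not depend on the platform's
// std::random_distribution implementations.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // seed expansion via splitmix64
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() { // xoshiro256**
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform integer in [0, n) without modulo bias
  int unif_int(int n) {
    uint64_t bound = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t r;
    do { r = next(); } while (r >= bound);
    return (int)(r % (uint64_t)n);
  }
};

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // child indices
  int pred;        // leaf prediction (0/1)
};

struct Tree {
  std::vector<Node> nodes;
  int predict(const std::vector<double>& xcol, int n, int row) const {
    int k = 0;
    while (nodes[k].feature >= 0) {
      double v = xcol[(size_t)nodes[k].feature * n + row];
      k = (v <= nodes[k].threshold) ? nodes[k].left : nodes[k].right;
    }
    return nodes[k].pred;
  }
};

inline double gini_imp(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

class Builder {
public:
  Builder(const std::vector<double>& xcol, const IntegerVector& y, int n,
          int p, int mtry, Rng& rng, std::vector<double>& importance)
      : x_(xcol), y_(y), n_all_(n), p_(p), mtry_(mtry), rng_(rng),
        imp_(importance) {}

  Tree build(const std::vector<int>& samples) {
    tree_.nodes.clear();
    n_root_ = (int)samples.size();
    std::vector<int> s(samples);
    grow(s);
    return tree_;
  }

private:
  inline double xv(int row, int f) const { return x_[(size_t)f * n_all_ + row]; }

  int grow(std::vector<int>& samples) {
    int n = (int)samples.size();
    int n1 = 0;
    for (int i : samples) n1 += y_[i];
    int node_id = (int)tree_.nodes.size();
    tree_.nodes.push_back(Node{-1, 0.0, -1, -1, (2 * n1 > n) ? 1 : 0});
    if (n < 2 || n1 == 0 || n1 == n) return node_id;

    double imp_node = gini_imp(n1, n);
    // sample mtry distinct features
    std::vector<int> feats(p_);
    for (int j = 0; j < p_; ++j) feats[j] = j;
    for (int j = 0; j < mtry_ && j < p_; ++j) {
      int k = j + rng_.unif_int(p_ - j);
      std::swap(feats[j], feats[k]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_dec = 1e-12;
    // buffer of (value, sample index) pairs; index gives a deterministic
    // tie order and carries the label
    std::vector<std::pair<double, int> > buf(n);
    for (int jj = 0; jj < mtry_ && jj < p_; ++jj) {
      int f = feats[jj];
      for (int k = 0; k < n; ++k) buf[k] = std::make_pair(xv(samples[k], f),
                                                          samples[k]);
      std::sort(buf.begin(), buf.end());
      int nl = 0, nl1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        ++nl;
        nl1 += y_[buf[k].second];
        if (buf[k].first == buf[k + 1].first) continue;
        int nr = n - nl, nr1 = n1 - nl1;
        double child = ((double)nl * gini_imp(nl1, nl) +
                        (double)nr * gini_imp(nr1, nr)) / n;
        double dec = imp_node - child;
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (buf[k].first + buf[k + 1].first);
        }
      }
    }
    if (best_f < 0) return node_id;

    imp_[best_f] += ((double)n / n_root_) * best_dec;
    std::vector<int> left, right;
    left.reserve(n);
    right.reserve(n);
    for (int i : samples) {
      if (xv(i, best_f) <= best_thr) left.push_back(i);
      else right.push_back(i);
    }
    int l = grow(left);
    int r = grow(right);
    tree_.nodes[node_id].feature = best_f;
    tree_.nodes[node_id].threshold = best_thr;
    tree_.nodes[node_id].left = l;
    tree_.nodes[node_id].right = r;
    return node_id;
  }

  const std::vector<double>& x_;
  const IntegerVector& y_;
  int n_all_, p_, mtry_;
  Rng& rng_;
  std::vector<double>& imp_;
  int n_root_ = 0;
  Tree tree_;
};

} // namespace

// Grow a forest to max(grid) trees (warm start), snapshotting OOB accuracy,
// normalized importances and test-set class-1 vote fractions at each grid
// point. y must be 0/1; grid must be increasing.
// [[Rcpp::export(name = ".rf_forest")]]
List rf_forest(NumericMatrix X, IntegerVector y, IntegerVector grid,
               int mtry, double seed,
               Nullable<NumericMatrix> xtest = R_NilValue) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least two rows");
  int ngrid = grid.size();
  for (int g = 1; g < ngrid; ++g)
    if (grid[g] <= grid[g - 1]) stop("grid must be strictly increasing");
  int ntree_max = grid[ngrid - 1];
  Rng rng((uint64_t)seed);

  bool has_test = xtest.isNotNull();
  NumericMatrix Xt;
  int ntest = 0;
  if (has_test) {
    Xt = NumericMatrix(xtest);
    ntest = Xt.nrow();
    if (ntest > 0 && Xt.ncol() != p) stop("xtest has wrong number of columns");
  }

  std::vector<double> imp(p, 0.0);          // cumulative over trees
  std::vector<int> oob_vote1(n, 0), oob_cnt(n, 0);
  std::vector<int> test_vote1(ntest, 0);

  NumericVector oob_acc(ngrid);
  NumericMatrix imp_snap(p, ngrid);
  NumericMatrix votes_test(ntest, ngrid);

  std::vector<double> xcol(X.begin(), X.end()); // column-major copy
  std::vector<double> xtcol;
  if (has_test) xtcol.assign(Xt.begin(), Xt.end());
  std::vector<char> inbag(n);
  std::vector<int> samples;
  samples.reserve(n);
  Builder builder(xcol, y, n, p, mtry, rng, imp);

  int g = 0;
  for (int t = 0; t < ntree_max; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    samples.clear();
    for (int i = 0; i < n; ++i) {
      int k = rng.unif_int(n);
      samples.push_back(k);
      inbag[k] = 1;
    }
    Tree tree = builder.build(samples);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_cnt[i]++;
        oob_vote1[i] += tree.predict(xcol, n, i);
      }
    }
    for (int i = 0; i < ntest; ++i) test_vote1[i] += tree.predict(xtcol, ntest, i);

    if (t + 1 == grid[g]) {
      int ok = 0, tot = 0;
      for (int i = 0; i < n; ++i) {
        if (oob_cnt[i] == 0) continue;
        ++tot;
        int pred = (2 * oob_vote1[i] > oob_cnt[i]) ? 1 : 0;
        if (pred == y[i]) ++ok;
      }
      oob_acc[g] = tot > 0 ? (double)ok / tot : NA_REAL;
      double tot_imp = 0.0;
      for (int j = 0; j < p; ++j) tot_imp += imp[j];
      for (int j = 0; j < p; ++j)
        imp_snap(j, g) = tot_imp > 0 ? imp[j] / tot_imp : 1.0 / p;
      for (int i = 0; i < ntest; ++i)
        votes_test(i, g) = (double)test_vote1[i] / (t + 1);
      ++g;
    }
  }

  return List::create(_["oob"] = oob_acc, _["importance"] = imp_snap,
                      _["votes_test"] = votes_test);
}
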