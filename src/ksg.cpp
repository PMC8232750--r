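#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Minimal kd-tree over points in row-major storage, max-norm metric.
// Supports k-nearest-neighbour search with a temporal (Theiler) exclusion
// window on the original sample index. Nodes are median splits stored as
// index ranges over a permutation array, so construction is O(n log n) and
// needs no per-node allocation.
// ---------------------------------------------------------------------------
struct KdTree {
  const double *pts; // n x d, row-major (point-major)
  int n, d;
  std::vector<int> perm;      // permutation of point ids, tree order
  std::vector<int> split_dim; // per node
  std::vector<double> split_val;
  // node layout: implicit binary tree over ranges; leaves hold <= 16 points
  struct Node { int lo, hi, left, right, dim; double val; };
  std::vector<Node> nodes;

  KdTree(const double *pts_, int n_, int d_) : pts(pts_), n(n_), d(d_) {
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    nodes.reserve(2 * n / 16 + 4);
    build(0, n);
  }

  int build(int lo, int hi) {
    int id = (int)nodes.size();
    nodes.push_back({lo, hi, -1, -1, -1, 0.0});
    if (hi - lo <= 16) return id;
    // split on the dimension with the largest spread over this range
    int bd = 0; double bspread = -1.0;
    for (int c = 0; c < d; ++c) {
      double mn = pts[perm[lo] * d + c], mx = mn;
      for (int t = lo + 1; t < hi; ++t) {
        double v = pts[perm[t] * d + c];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > bspread) { bspread = mx - mn; bd = c; }
    }
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) { return pts[a * d + bd] < pts[b * d + bd]; });
    nodes[id].dim = bd;
    nodes[id].val = pts[perm[mid] * d + bd];
    int left = build(lo, mid);
    int right = build(mid, hi);
    nodes[id].left = left;
    nodes[id].right = right;
    return id;
  }

  // k-th NN max-norm distance from query point q (original index qi),
  // excluding samples with |index - qi| <= theiler (and the point itself).
  double knn_dist(const double *q, int qi, int k, int theiler) const {
    std::vector<double> heap; // max-heap of current k best distances
    heap.reserve(k + 1);
    search(0, q, qi, k, theiler, heap);
    return heap.front();
  }

  void search(int node, const double *q, int qi, int k, int theiler,
              std::vector<double> &heap) const {
    const Node &nd = nodes[node];
    if (nd.left < 0) { // leaf
      for (int t = nd.lo; t < nd.hi; ++t) {
        int j = perm[t];
        if (std::abs(j - qi) <= theiler) continue;
        double dist = 0.0;
        const double *pj = pts + (size_t)j * d;
        for (int c = 0; c < d; ++c) {
          double dd = std::fabs(pj[c] - q[c]);
          if (dd > dist) dist = dd;
        }
        if ((int)heap.size() < k) {
          heap.push_back(dist);
          std::push_heap(heap.begin(), heap.end());
        } else if (dist < heap.front()) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = dist;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double diff = q[nd.dim] - nd.val;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search(near, q, qi, k, theiler, heap);
    if ((int)heap.size() < k || std::fabs(diff) < heap.front())
      search(far, q, qi, k, theiler, heap);
  }
};

// Count samples j (excluding the Theiler window around i) whose max-norm
// distance to sample i is strictly below eps in the subspace given by
// `cols`, using an order sorted by the first conditioning coordinate to
// restrict candidates.
static inline int range_count(const double *pts, int n, int d, int i,
                              double eps, const std::vector<int> &cols,
                              const std::vector<int> &order,
                              const std::vector<double> &sorted_z,
                              int theiler) {
  const double zi = pts[(size_t)i * d + cols[0]];
  // binary search bounds on the sorted first coordinate
  int lo = (int)(std::lower_bound(sorted_z.begin(), sorted_z.end(), zi - eps) -
                 sorted_z.begin());
  int hi = (int)(std::upper_bound(sorted_z.begin(), sorted_z.end(), zi + eps) -
                 sorted_z.begin());
  int count = 0;
  for (int t = lo; t < hi; ++t) {
    int j = order[t];
    if (std::abs(j - i) <= theiler) continue;
    const double *pj = pts + (size_t)j * d;
    const double *pi = pts + (size_t)i * d;
    bool ok = true;
    for (size_t c = 0; c < cols.size(); ++c) {
      if (std::fabs(pj[cols[c]] - pi[cols[c]]) >= eps) { ok = false; break; }
    }
    if (ok) ++count;
  }
  return count;
}

// Kraskov-Stoegbauer-Grassberger conditional mutual information
// I(f ; S | Z) in nats, algorithm-1 neighbour counting under the max-norm
// (Frenzel-Pompe extension of KSG to the conditional case):
//
//   I = psi(k) - < psi(n_fz + 1) + psi(n_sz + 1) - psi(n_z + 1) >
//
// where, for each sample i, eps_i is the max-norm distance to its k-th
// nearest neighbour in the full joint space (f, S, Z) and n_* count the
// neighbours strictly inside eps_i in the marginal subspaces (f,Z), (S,Z)
// and (Z). `theiler` excludes temporal neighbours |i - j| <= theiler from
// the search and all counts (dynamic-correlation exclusion for serially
// dependent series). kd-tree k-NN search; marginal counts via a sort on the
// first conditioning coordinate.
//
// f: length-n future samples of the target.
// S: n x ds source embedding.  Z: n x dz target-history embedding.
// Ties in distances are broken by the caller adding a tiny jitter.
// [[Rcpp::export]]
double ksg_cmi_cpp(NumericVector f, NumericMatrix S, NumericMatrix Z, int k,
                   int theiler = 0) {
  const int n = f.size();
  const int ds = S.ncol(), dz = Z.ncol();
  if (S.nrow() != n || Z.nrow() != n)
    stop("f, S and Z must have the same number of rows");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  if (theiler < 0 || n - 2 * theiler <= k)
    stop("theiler window too large for the series length");

  const int d = 1 + ds + dz;
  // row-major joint points: [f, S..., Z...]
  std::vector<double> pts((size_t)n * d);
  for (int i = 0; i < n; ++i) {
    double *p = &pts[(size_t)i * d];
    p[0] = f[i];
    for (int c = 0; c < ds; ++c) p[1 + c] = S(i, c);
    for (int c = 0; c < dz; ++c) p[1 + ds + c] = Z(i, c);
  }
  KdTree tree(pts.data(), n, d);

  // subspace column sets; first column of each must be the shared
  // conditioning coordinate Z[,1] used for the sorted candidate window
  const int z0 = 1 + ds;
  std::vector<int> cols_z(dz), cols_fz, cols_sz;
  for (int c = 0; c < dz; ++c) cols_z[c] = z0 + c;
  cols_fz = cols_z; cols_fz.push_back(0);
  cols_sz = cols_z;
  for (int c = 0; c < ds; ++c) cols_sz.push_back(1 + c);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return pts[(size_t)a * d + z0] < pts[(size_t)b * d + z0];
  });
  std::vector<double> sorted_z(n);
  for (int t = 0; t < n; ++t)
    sorted_z[t] = pts[(size_t)order[t] * d + z0];

  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *q = &pts[(size_t)i * d];
    double eps = tree.knn_dist(q, i, k, theiler);
    int n_z = range_count(pts.data(), n, d, i, eps, cols_z, order,
                          sorted_z, theiler);
    int n_fz = range_count(pts.data(), n, d, i, eps, cols_fz, order,
                           sorted_z, theiler);
    int n_sz = range_count(pts.data(), n, d, i, eps, cols_sz, order,
                           sorted_z, theiler);
    acc += R::digamma(n_fz + 1) + R::digamma(n_sz + 1) - R::digamma(n_z + 1);
  }
  return R::digamma(k) - acc / n;
}

// Deterministic tie-breaking jitter: N(0, sd) from a Mersenne Twister seeded
// by the caller (seed derived from the series content so repeated calls on
// identical data agree bit-for-bit). Does not touch R's RNG stream.
// [[Rcpp::export]]
NumericVector add_jitter_cpp(NumericVector x, double sd, unsigned int seed) {
  std::mt19937 rng(seed);
  std::normal_distribution<double> gauss(0.0, sd);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] + gauss(rng);
  return out;
}
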