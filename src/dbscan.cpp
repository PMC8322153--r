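#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// DBSCAN labels for one epsilon given, per point, its neighbours sorted by
// distance (prefix of length cnt[i] lies within eps). A point is core if at
// least min_pts points (itself included) lie within eps; clusters are
// connected components of core points, with non-core neighbours attached as
// border points (first-come). Label 0 is noise.
static void dbscan_from_prefix(const std::vector< std::vector<int> > &order,
                               const std::vector<int> &cnt, int min_pts,
                               int *labels, std::vector<int> &stack) {
  const int n = static_cast<int>(order.size());
  for (int i = 0; i < n; ++i) labels[i] = 0;
  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != 0 || cnt[i] < min_pts) continue;
    ++cl;
    labels[i] = cl;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      const std::vector<int> &nb = order[j];
      const int m = cnt[j];
      for (int q = 0; q < m; ++q) {
        int k = nb[q];
        if (labels[k] == 0) {
          labels[k] = cl;
          if (cnt[k] >= min_pts) stack.push_back(k);
        }
      }
    }
  }
}

// Sweep DBSCAN over a grid of epsilon values on a precomputed (symmetric)
// distance matrix. Returns an n x length(epsilons) matrix of labels.
// Sorting each point's distances once makes the per-epsilon neighbour sets
// prefix lookups.
// [[Rcpp::export]]
IntegerMatrix dbscan_sweep_cpp(NumericMatrix D, NumericVector epsilons,
                               int min_pts) {
  const int n = D.nrow();
  const int ne = epsilons.size();
  std::vector< std::vector<int> > order(n);
  std::vector< std::vector<double> > dists(n);
  const double *pd = REAL(D);
  for (int i = 0; i < n; ++i) {
    std::vector<int> idx(n);
    for (int j = 0; j < n; ++j) idx[j] = j;
    const double *col = pd + static_cast<size_t>(i) * n;
    std::sort(idx.begin(), idx.end(),
              [col](int a, int b) { return col[a] < col[b]; });
    std::vector<double> dd(n);
    for (int j = 0; j < n; ++j) dd[j] = col[idx[j]];
    order[i] = std::move(idx);
    dists[i] = std::move(dd);
  }
  IntegerMatrix out(n, ne);
  std::vector<int> cnt(n);
  std::vector<int> stack;
  for (int e = 0; e < ne; ++e) {
    const double eps = epsilons[e];
    for (int i = 0; i < n; ++i)
      cnt[i] = static_cast<int>(std::upper_bound(dists[i].begin(),
                                                 dists[i].end(), eps) -
                                dists[i].begin());
    dbscan_from_prefix(order, cnt, min_pts, &out(0, e), stack);
  }
  return out;
}

// Single-epsilon variant (kept for direct use and testing).
// [[Rcpp::export]]
IntegerVector dbscan_labels_cpp(NumericMatrix D, double eps, int min_pts) {
  NumericVector e(1);
  e[0] = eps;
  IntegerMatrix m = dbscan_sweep_cpp(D, e, min_pts);
  return m(_, 0);
}
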