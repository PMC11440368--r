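// Distance-heavy kernels for the HDBSCAN implementation: k-th nearest
// neighbour core distances and the minimum spanning tree of the mutual
// reachability graph (Prim's algorithm, O(n^2) time, O(n) memory).
// Points are copied into a contiguous row-major buffer so the inner
// distance loops stream through memory.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static std::vector<double> row_major(const NumericMatrix& X) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> P(static_cast<size_t>(n) * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      P[static_cast<size_t>(i) * d + j] = X(i, j);
  return P;
}

static inline double sqdist(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = a[k] - b[k];
    s += diff * diff;
  }
  return s;
}

// core distance = distance to the k-th nearest neighbour, counting the
// point itself as its first neighbour (k = 1 gives 0)
// [[Rcpp::export(name = ".core_distances")]]
NumericVector core_distances(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1) stop("min_samples must be >= 1");
  if (k > n) stop("min_samples exceeds the number of points");
  const std::vector<double> P = row_major(X);
  NumericVector out(n);
  std::vector<double> dist(n);
  for (int i = 0; i < n; ++i) {
    const double* pi = &P[static_cast<size_t>(i) * d];
    for (int j = 0; j < n; ++j)
      dist[j] = sqdist(pi, &P[static_cast<size_t>(j) * d], d);
    std::nth_element(dist.begin(), dist.begin() + (k - 1), dist.end());
    out[i] = std::sqrt(dist[k - 1]);
  }
  return out;
}

// MST of the complete mutual reachability graph
// d_mr(a, b) = max(core[a], core[b], d(a, b))
// [[Rcpp::export(name = ".mutual_reachability_mst")]]
DataFrame mutual_reachability_mst(NumericMatrix X, NumericVector core) {
  const int n = X.nrow(), d = X.ncol();
  const std::vector<double> P = row_major(X);
  std::vector<double> core2(n);  // squared core distances
  for (int i = 0; i < n; ++i) core2[i] = core[i] * core[i];
  // best[] tracks squared mutual reachability so the inner loop avoids
  // sqrt; weights are rooted on output
  std::vector<double> best(n, R_PosInf);
  std::vector<int> parent(n, -1);
  std::vector<char> in_tree(n, 0);
  IntegerVector from(n - 1), to(n - 1);
  NumericVector weight(n - 1);
  int current = 0;
  in_tree[0] = 1;
  for (int e = 0; e < n - 1; ++e) {
    const double* pc = &P[static_cast<size_t>(current) * d];
    const double cc = core2[current];
    for (int j = 0; j < n; ++j) {
      if (in_tree[j]) continue;
      double mr = sqdist(pc, &P[static_cast<size_t>(j) * d], d);
      if (mr < cc) mr = cc;
      if (mr < core2[j]) mr = core2[j];
      if (mr < best[j]) { best[j] = mr; parent[j] = current; }
    }
    int next = -1;
    double bw = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (!in_tree[j] && best[j] < bw) { bw = best[j]; next = j; }
    from[e] = parent[next] + 1;  // 1-based for R
    to[e] = next + 1;
    weight[e] = std::sqrt(bw);
    in_tree[next] = 1;
    current = next;
  }
  return DataFrame::create(_["from"] = from, _["to"] = to,
                           _["weight"] = weight);
}
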