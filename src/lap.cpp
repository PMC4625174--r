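#include <Rcpp.h>
#include <vector>
#include <limits>

// Dense linear assignment by shortest augmenting paths with dual
// potentials (Hungarian, O(n^3)). Rows are assigned to columns of a
// square cost matrix; inadmissible pairs carry a large finite cost
// supplied by the caller, never Inf, so the duals stay finite.
// [[Rcpp::export(name = ".solveLAP")]]
Rcpp::IntegerVector solveLAP(Rcpp::NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) Rcpp::stop("cost matrix must be square");
  if (n == 0) return Rcpp::IntegerVector(0);
  const double INF = std::numeric_limits<double>::infinity();
  // 1-based internally; p[j] = row matched to column j (0 = free)
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  std::vector<char> used(n + 1);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = 0;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  // return, per row, the assigned column (1-based)
  Rcpp::IntegerVector assign(n);
  for (int j = 1; j <= n; ++j) assign[p[j] - 1] = j;
  return assign;
}
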