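#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

//' Minimum-cost one-to-one assignment on a square cost matrix
//'
//' Hungarian algorithm with row/column potentials and shortest augmenting
//' paths, O(n^3). Infeasible pairings should be encoded as a large finite
//' cost (not Inf) so the problem stays feasible.
//'
//' @param cost square numeric cost matrix
//' @return integer vector: for each row, the 1-based column assigned to it
//' @keywords internal
// [[Rcpp::export]]
IntegerVector lap_solve(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  IntegerVector res(n);
  if (n == 0) return res;
  const double INF = std::numeric_limits<double>::infinity();

  // p[j]: row currently matched to column j (-1 if free); column n is a
  // virtual source column used to seed each augmenting search.
  std::vector<double> u(n, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, -1), way(n + 1, 0);

  for (int i = 0; i < n; ++i) {
    p[n] = i;
    int j0 = n;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = -1;
      for (int j = 0; j < n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0, j) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (j1 < 0) stop("assignment infeasible (non-finite costs?)");
      for (int j = 0; j <= n; ++j) {
        if (used[j]) {
          if (p[j] >= 0) u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != -1);
    // augment along the alternating path back to the virtual column
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0 != n);
  }

  for (int j = 0; j < n; ++j)
    if (p[j] >= 0) res[p[j]] = j + 1;
  return res;
}
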