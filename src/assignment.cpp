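#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Rectangular Hungarian algorithm (Jonker-Volgenant style shortest augmenting
// paths with dual potentials), O(M^2 N) for an M x N cost matrix, M <= N.
// Returns the column assigned to each row (0-based) and the minimal total cost.
static void solve_hungarian(const NumericMatrix& cost,
                            std::vector<int>& row_to_col,
                            double& total) {
  const int M = cost.nrow(), N = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  // 1-based potentials; p[j] = row assigned to column j (0 = none)
  std::vector<double> u(M + 1, 0.0), v(N + 1, 0.0);
  std::vector<int> p(N + 1, 0), way(N + 1, 0);
  for (int i = 1; i <= M; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(N + 1, INF);
    std::vector<char> used(N + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= N; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= N; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else          minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  row_to_col.assign(M, -1);
  for (int j = 1; j <= N; ++j)
    if (p[j] != 0) row_to_col[p[j] - 1] = j - 1;
  // accumulate in row order so the total is bit-identical to a row-wise
  // summation over the assigned pairs (as an enumeration oracle computes it)
  total = 0.0;
  for (int i = 0; i < M; ++i) total += cost(i, row_to_col[i]);
}

// [[Rcpp::export(name = ".hungarian_cpp")]]
List hungarian_cpp(NumericMatrix cost) {
  const int M = cost.nrow(), N = cost.ncol();
  if (M == 0 || N == 0) stop("cost matrix must be non-empty");
  if (M > N) stop("cost matrix must have nrow <= ncol; swap the inputs");
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j)
      if (!R_finite(cost(i, j))) stop("cost matrix entries must be finite");
  std::vector<int> rc;
  double total;
  solve_hungarian(cost, rc, total);
  IntegerVector cols(M);
  for (int i = 0; i < M; ++i) cols[i] = rc[i] + 1;  // 1-based for R
  return List::create(_["cols"] = cols, _["total_cost"] = total);
}

// Minimum assignment cost of `query` (length M) onto each candidate shift
// vector (length >= M) under squared-difference cost, returned as RMSE over
// the M assigned pairs. Batched to keep the per-candidate overhead out of R.
// [[Rcpp::export(name = ".assignment_rmse_cpp")]]
NumericVector assignment_rmse_cpp(NumericVector query, List candidates) {
  const int M = query.size();
  const int K = candidates.size();
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    NumericVector cand = candidates[k];
    const int N = cand.size();
    if (M > N) stop("query longer than candidate shift list");
    NumericMatrix cost(M, N);
    for (int i = 0; i < M; ++i) {
      double q = query[i];
      for (int j = 0; j < N; ++j) {
        double d = q - cand[j];
        cost(i, j) = d * d;
      }
    }
    std::vector<int> rc;
    double total;
    solve_hungarian(cost, rc, total);
    out[k] = std::sqrt(total / M);
  }
  return out;
}
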