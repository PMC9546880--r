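#include <Rcpp.h>
using namespace Rcpp;

// Hard least-squares consensus of an ensemble of k-cluster partitions.
// Objective: sum over members of || C - M_j P_j ||_F^2 over hard membership
// matrices, with the label permutation P_j solved exactly per member
// (Hungarian assignment on the contingency table). Since ||C - M P||^2 =
// 2 * (n - overlap), minimizing the objective maximizes total matched labels.

// Min-cost square assignment, O(k^3) shortest augmenting path with potentials.
static std::vector<int> hungarian(const std::vector<std::vector<double> >& a, int k) {
  const double INF = 1e100;
  std::vector<double> u(k + 1, 0.0), v(k + 1, 0.0);
  std::vector<int> p(k + 1, 0), way(k + 1, 0);
  for (int i = 1; i <= k; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(k + 1, INF);
    std::vector<bool> used(k + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= k; ++j) if (!used[j]) {
        double cur = a[i0 - 1][j - 1] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= k; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> row_to_col(k);
  for (int j = 1; j <= k; ++j) row_to_col[p[j] - 1] = j - 1;
  return row_to_col;
}

// For member labels L (1..k) and consensus C (0..k-1): permutation sigma
// mapping member label l (0-based) -> consensus label maximizing overlap.
static std::vector<int> match_labels(const std::vector<int>& C, const int* L,
                                     int n, int k, long& overlap) {
  std::vector<std::vector<double> > T(k, std::vector<double>(k, 0.0));
  for (int x = 0; x < n; ++x) T[L[x] - 1][C[x]] += 1.0;  // rows: member label
  double mx = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) if (T[i][j] > mx) mx = T[i][j];
  std::vector<std::vector<double> > cost(k, std::vector<double>(k));
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) cost[i][j] = mx - T[i][j];
  std::vector<int> sigma = hungarian(cost, k);
  overlap = 0;
  for (int i = 0; i < k; ++i) overlap += (long)T[i][sigma[i]];
  return sigma;
}

// [[Rcpp::export]]
List consensus_fit_cpp(IntegerMatrix labels, int k, IntegerMatrix starts,
                       int maxit = 100) {
  const int n = labels.nrow(), m = labels.ncol(), r = starts.ncol();
  std::vector<const int*> cols(m);
  for (int j = 0; j < m; ++j) cols[j] = &labels(0, j);

  std::vector<int> bestC;
  double best_obj = R_PosInf;

  for (int s = 0; s < r; ++s) {
    std::vector<int> C(n);
    for (int x = 0; x < n; ++x) C[x] = starts(x, s) - 1;
    std::vector<std::vector<int> > sig(m);
    for (int it = 0; it < maxit; ++it) {
      long ov;
      for (int j = 0; j < m; ++j) sig[j] = match_labels(C, cols[j], n, k, ov);
      bool changed = false;
      std::vector<int> votes(k);
      for (int x = 0; x < n; ++x) {
        std::fill(votes.begin(), votes.end(), 0);
        for (int j = 0; j < m; ++j) votes[sig[j][cols[j][x] - 1]]++;
        int arg = 0;
        for (int c = 1; c < k; ++c) if (votes[c] > votes[arg]) arg = c;
        if (arg != C[x]) { C[x] = arg; changed = true; }
      }
      if (!changed) break;
    }
    double obj = 0.0;
    for (int j = 0; j < m; ++j) {
      long ov;
      match_labels(C, cols[j], n, k, ov);
      obj += 2.0 * (n - ov);
    }
    if (obj < best_obj - 1e-9) { best_obj = obj; bestC = C; }
  }

  IntegerVector out(n);
  for (int x = 0; x < n; ++x) out[x] = bestC[x] + 1;
  return List::create(_["labels"] = out, _["objective"] = best_obj);
}

// Objective of a fixed candidate consensus against the ensemble (used by the
// brute-force oracle route and the member-dominance invariant).
// [[Rcpp::export]]
double consensus_objective_cpp(IntegerVector consensus, IntegerMatrix labels, int k) {
  const int n = labels.nrow(), m = labels.ncol();
  std::vector<int> C(n);
  for (int x = 0; x < n; ++x) C[x] = consensus[x] - 1;
  double obj = 0.0;
  for (int j = 0; j < m; ++j) {
    long ov;
    match_labels(C, &labels(0, j), n, k, ov);
    obj += 2.0 * (n - ov);
  }
  return obj;
}

// Accumulate pairwise co-assignment counts for one partition.
// [[Rcpp::export]]
NumericMatrix coassign_add_cpp(NumericMatrix acc, IntegerVector labels) {
  const int n = labels.size();
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      if (labels[i] == labels[j]) { acc(i, j) += 1.0; if (j > i) acc(j, i) = acc(i, j); }
  return acc;
}
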