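#include <Rcpp.h>
using namespace Rcpp;

// k-medoids SWAP phase on a precomputed distance matrix (FastPAM1-style
// delta accumulation: one O(n) pass per candidate evaluates all k removals).
// Initial medoids come from the caller so all randomness stays in R's RNG.
// Ties between equal-cost swaps resolve to the lowest candidate index, then
// the lowest medoid slot, making the local optimum deterministic.
//
// Decomposition used per candidate j (d1/d2 = nearest/second-nearest medoid
// distances, n1 = nearest medoid slot, R_i = cost of removing medoid i):
//   dTD(i, j) = R_i + S_j + T_ij,
//   S_j  = sum_o min(d(o,j) - d1[o], 0),
//   T_ij = sum_{o: n1[o]=i} [ (d(o,j) - d2[o]) - min(d(o,j) - d1[o], 0) ],
// where only points with d(o,j) < d2[o] contribute to S_j or T_ij, so the
// inner loop skips most points once medoids are good.

static void update_nearest(const double* D, int n, const std::vector<int>& med,
                           std::vector<int>& n1, std::vector<double>& d1,
                           std::vector<double>& d2) {
  const int k = (int)med.size();
  for (int o = 0; o < n; ++o) {
    double b1 = R_PosInf, b2 = R_PosInf; int i1 = -1;
    for (int i = 0; i < k; ++i) {
      double dd = D[o + (size_t)med[i] * n];
      if (dd < b1) { b2 = b1; b1 = dd; i1 = i; }
      else if (dd < b2) { b2 = dd; }
    }
    n1[o] = i1; d1[o] = b1; d2[o] = b2;
  }
}

// [[Rcpp::export]]
List pam_fit_cpp(NumericMatrix d, IntegerVector init_medoids, int maxit = 200) {
  const int n = d.nrow();
  const int k = init_medoids.size();
  const double* D = d.begin();
  std::vector<int> med(k);
  std::vector<bool> is_med(n, false);
  for (int i = 0; i < k; ++i) {
    med[i] = init_medoids[i] - 1;
    is_med[med[i]] = true;
  }
  std::vector<int> n1(n);
  std::vector<double> d1(n), d2(n);
  update_nearest(D, n, med, n1, d1, d2);

  const double eps = 1e-12;
  std::vector<double> removal(k), Ti(k);
  const double* d1p = d1.data();
  const double* d2p = d2.data();
  const int* n1p = n1.data();
  for (int it = 0; it < maxit; ++it) {
    std::fill(removal.begin(), removal.end(), 0.0);
    for (int o = 0; o < n; ++o) removal[n1p[o]] += d2p[o] - d1p[o];
    double best = -eps; int bi = -1, bj = -1;
    for (int j = 0; j < n; ++j) {
      if (is_med[j]) continue;
      const double* dj = D + (size_t)j * n;
      double S = 0.0;
      std::fill(Ti.begin(), Ti.end(), 0.0);
      for (int o = 0; o < n; ++o) {
        double v = dj[o];
        if (v < d2p[o]) {
          double g1 = v < d1p[o] ? v - d1p[o] : 0.0;
          S += g1;
          Ti[n1p[o]] += (v - d2p[o]) - g1;
        }
      }
      for (int i = 0; i < k; ++i) {
        double td = removal[i] + S + Ti[i];
        if (td < best - eps) { best = td; bi = i; bj = j; }
      }
    }
    if (bi < 0) break;
    is_med[med[bi]] = false;
    med[bi] = bj;
    is_med[bj] = true;
    update_nearest(D, n, med, n1, d1, d2);
  }

  // canonical labels: clusters ordered by medoid row index
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b){ return med[a] < med[b]; });
  std::vector<int> rank(k);
  for (int r = 0; r < k; ++r) rank[ord[r]] = r;

  IntegerVector labels(n), medoids(k);
  double cost = 0.0, wss = 0.0;
  for (int r = 0; r < k; ++r) medoids[r] = med[ord[r]] + 1;
  for (int o = 0; o < n; ++o) {
    labels[o] = rank[n1[o]] + 1;
    cost += d1[o];
    wss += d1[o] * d1[o];
  }
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["cost"] = cost, _["wss"] = wss);
}
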