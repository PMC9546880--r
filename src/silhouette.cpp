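#include <Rcpp.h>
using namespace Rcpp;

// Mean silhouette width of a categorical grouping of 1-D PC scores, plus a
// permutation null. Permutations (generated in R so seeding follows R's RNG)
// shuffle labels. With group_center = true, scores are re-centered by the
// median of their (observed or permuted) group before distances are taken:
// this matches a pipeline that removed the grouping's location effects, and
// keeps the null exchangeable with the observed statistic.

static double group_median(std::vector<double>& v) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  return n % 2 ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

static double mean_sil(const double* x0, const int* g, int n, int G,
                       bool group_center, std::vector<double>& xbuf) {
  const double* x = x0;
  if (group_center) {
    std::vector<std::vector<double> > vals(G);
    for (int i = 0; i < n; ++i) vals[g[i] - 1].push_back(x0[i]);
    std::vector<double> med(G, 0.0);
    for (int c = 0; c < G; ++c)
      if (!vals[c].empty()) med[c] = group_median(vals[c]);
    for (int i = 0; i < n; ++i) xbuf[i] = x0[i] - med[g[i] - 1];
    x = xbuf.data();
  }
  std::vector<double> rowsum(G);
  std::vector<int> cnt(G, 0);
  for (int i = 0; i < n; ++i) cnt[g[i] - 1]++;
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    std::fill(rowsum.begin(), rowsum.end(), 0.0);
    for (int j = 0; j < n; ++j) rowsum[g[j] - 1] += std::fabs(x[i] - x[j]);
    int gi = g[i] - 1;
    if (cnt[gi] <= 1) continue;  // singleton: s = 0
    double a = rowsum[gi] / (cnt[gi] - 1);
    double b = R_PosInf;
    for (int c = 0; c < G; ++c) {
      if (c == gi || cnt[c] == 0) continue;
      double m = rowsum[c] / cnt[c];
      if (m < b) b = m;
    }
    double mx = a > b ? a : b;
    if (mx > 0) tot += (b - a) / mx;
  }
  return tot / n;
}

// [[Rcpp::export]]
List silhouette_perm_cpp(NumericVector x, IntegerVector g, IntegerMatrix perms,
                         bool group_center = false) {
  const int n = x.size();
  int G = 0;
  for (int i = 0; i < n; ++i) if (g[i] > G) G = g[i];
  std::vector<double> xbuf(n);
  double obs = mean_sil(&x[0], &g[0], n, G, group_center, xbuf);
  const int B = perms.ncol();
  NumericVector nullv(B);
  for (int b = 0; b < B; ++b)
    nullv[b] = mean_sil(&x[0], &perms(0, b), n, G, group_center, xbuf);
  return List::create(_["observed"] = obs, _["null"] = nullv);
}
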