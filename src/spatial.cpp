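#include <Rcpp.h>
using namespace Rcpp;

// Spatial point-pattern kernels for the phenotype metrics: exact k-NN
// distances, fixed-radius neighbor counts, and flat-kernel mean shift.

// [[Rcpp::export]]
NumericMatrix knn_dist_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (k >= n) stop("k must be smaller than the number of points");
  NumericMatrix out(n, k);
  std::vector<double> best(k);
  for (int i = 0; i < n; ++i) {
    std::fill(best.begin(), best.end(), R_PosInf);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best[k - 1]) {  // insertion into sorted top-k
        int p = k - 1;
        while (p > 0 && best[p - 1] > d2) { best[p] = best[p - 1]; --p; }
        best[p] = d2;
      }
    }
    for (int c = 0; c < k; ++c) out(i, c) = std::sqrt(best[c]);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector radius_count_cpp(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  const double r2 = r * r;
  IntegerVector cnt(n);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) ++c;
    }
    cnt[i] = c;
  }
  return cnt;
}

// Flat-kernel mean shift: every point iterates to the mean of points within
// `bandwidth` of its current position until the shift is below tol; converged
// positions within bandwidth/2 merge into one mode.
// [[Rcpp::export]]
List mean_shift_cpp(NumericVector x, NumericVector y, double bandwidth,
                    double tol = 1e-3, int maxit = 200) {
  const int n = x.size();
  const double h2 = bandwidth * bandwidth;
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  for (int i = 0; i < n; ++i) {
    double cx = px[i], cy = py[i];
    for (int it = 0; it < maxit; ++it) {
      double sx = 0.0, sy = 0.0; int m = 0;
      for (int j = 0; j < n; ++j) {
        double dx = cx - x[j], dy = cy - y[j];
        if (dx * dx + dy * dy <= h2) { sx += x[j]; sy += y[j]; ++m; }
      }
      double nx = sx / m, ny = sy / m;
      double shift = std::sqrt((nx - cx) * (nx - cx) + (ny - cy) * (ny - cy));
      cx = nx; cy = ny;
      if (shift < tol) break;
    }
    px[i] = cx; py[i] = cy;
  }
  // merge modes closer than bandwidth / 2 (first-come canonical mode)
  std::vector<double> mx, my;
  IntegerVector labels(n);
  const double merge2 = h2 / 4.0;
  for (int i = 0; i < n; ++i) {
    int lab = -1;
    double bd = R_PosInf;
    for (size_t c = 0; c < mx.size(); ++c) {
      double dx = px[i] - mx[c], dy = py[i] - my[c];
      double d2 = dx * dx + dy * dy;
      if (d2 <= merge2 && d2 < bd) { bd = d2; lab = (int)c; }
    }
    if (lab < 0) { mx.push_back(px[i]); my.push_back(py[i]); lab = (int)mx.size() - 1; }
    labels[i] = lab + 1;
  }
  return List::create(_["labels"] = labels,
                      _["modes_x"] = NumericVector(mx.begin(), mx.end()),
                      _["modes_y"] = NumericVector(my.begin(), my.end()));
}
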