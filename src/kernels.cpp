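#include <Rcpp.h>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// 3x3 median filter with edge replication. Input/output are numeric
// matrices in R's column-major layout.
// [[Rcpp::export(name = ".median3x3_cpp")]]
NumericMatrix median3x3_cpp(const NumericMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int idx = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          w[idx++] = x(ii, jj);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}

// Connected-component labelling of a logical mask, 8- or 4-connectivity.
// Labels are assigned in raster scan order starting at 1; background is 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<int> q;
  const bool eight = (connectivity == 8);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(j * nr + i);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            if (!eight && di != 0 && dj != 0) continue;
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(jj * nr + ii);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Lloyd's algorithm for 1-D k-means from given initial centres.
// Exploits the 1-D structure: cluster boundaries are midpoints between
// sorted centres, so each assignment pass is a binary search.
// Returns list(centers, withinss_total, iterations).
// [[Rcpp::export(name = ".kmeans1d_lloyd_cpp")]]
List kmeans1d_lloyd_cpp(const NumericVector& x, NumericVector centers_init,
                        int max_iter, double tol) {
  const int n = x.size();
  std::vector<double> cen(centers_init.begin(), centers_init.end());
  std::sort(cen.begin(), cen.end());
  cen.erase(std::unique(cen.begin(), cen.end()), cen.end());
  int k = cen.size();
  std::vector<double> sums(k);
  std::vector<int> cnts(k);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    std::fill(sums.begin(), sums.end(), 0.0);
    std::fill(cnts.begin(), cnts.end(), 0);
    // boundaries between consecutive centres
    std::vector<double> bnd(k - 1);
    for (int c = 0; c + 1 < k; ++c) bnd[c] = 0.5 * (cen[c] + cen[c + 1]);
    for (int i = 0; i < n; ++i) {
      int a = std::upper_bound(bnd.begin(), bnd.end(), x[i]) - bnd.begin();
      sums[a] += x[i];
      cnts[a] += 1;
    }
    double shift = 0.0;
    std::vector<double> newc;
    newc.reserve(k);
    for (int c = 0; c < k; ++c) {
      if (cnts[c] > 0) {
        double m = sums[c] / cnts[c];
        shift = std::max(shift, std::abs(m - cen[c]));
        newc.push_back(m);
      }
      // empty clusters are dropped (can occur with degenerate support)
    }
    std::sort(newc.begin(), newc.end());
    newc.erase(std::unique(newc.begin(), newc.end()), newc.end());
    if ((int)newc.size() != k) shift = tol + 1.0;
    cen = newc;
    k = cen.size();
    if (shift <= tol) { ++iter; break; }
  }
  // final assignment + within-cluster SS
  std::vector<double> bnd(k - 1);
  for (int c = 0; c + 1 < k; ++c) bnd[c] = 0.5 * (cen[c] + cen[c + 1]);
  double wss = 0.0;
  for (int i = 0; i < n; ++i) {
    int a = std::upper_bound(bnd.begin(), bnd.end(), x[i]) - bnd.begin();
    double d = x[i] - cen[a];
    wss += d * d;
  }
  return List::create(_["centers"] = NumericVector(cen.begin(), cen.end()),
                      _["withinss"] = wss, _["iterations"] = iter);
}

// Assign each value to the nearest of the sorted centres; returns 1-based
// cluster indices (1 = smallest centre).
// [[Rcpp::export(name = ".assign1d_cpp")]]
IntegerVector assign1d_cpp(const NumericVector& x, const NumericVector& centers) {
  const int n = x.size(), k = centers.size();
  std::vector<double> bnd(k - 1);
  for (int c = 0; c + 1 < k; ++c) bnd[c] = 0.5 * (centers[c] + centers[c + 1]);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (std::upper_bound(bnd.begin(), bnd.end(), x[i]) - bnd.begin()) + 1;
  return out;
}
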