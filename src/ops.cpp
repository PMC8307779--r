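#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Distance from each query point to its k-th nearest point in `pts`.
// exclude_self: queries are the points themselves (row i skips row i).
// [[Rcpp::export(name = ".knn_kth_dist")]]
NumericVector knn_kth_dist(NumericMatrix query, NumericMatrix pts, int k,
                           bool exclude_self) {
  const int nq = query.nrow(), np = pts.nrow(), d = pts.ncol();
  if (query.ncol() != d) stop("dimension mismatch between query and points");
  if (k < 1) stop("k must be >= 1");
  const int avail = exclude_self ? np - 1 : np;
  if (k > avail) stop("k exceeds the number of available neighbours");
  NumericVector out(nq);
  std::vector<double> d2(np);
  for (int i = 0; i < nq; ++i) {
    int m = 0;
    for (int j = 0; j < np; ++j) {
      if (exclude_self && j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = query(i, c) - pts(j, c);
        s += t * t;
      }
      d2[m++] = s;
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.begin() + m);
    out[i] = std::sqrt(d2[k - 1]);
  }
  return out;
}

// Shrake-Rupley solvent accessible surface area for one frame.
// xyz: n x 3, radii: vdW radii (Angstrom), sphere: s x 3 unit vectors.
// [[Rcpp::export(name = ".sasa_frame")]]
NumericVector sasa_frame(NumericMatrix xyz, NumericVector radii,
                         double probe, NumericMatrix sphere) {
  const int n = xyz.nrow(), s = sphere.nrow();
  NumericVector area(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    nb.clear();
    const double reach = ri + rmax + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      if (dx * dx + dy * dy + dz * dz < reach * reach) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < s; ++p) {
      const double px = xyz(i, 0) + ri * sphere(p, 0),
                   py = xyz(i, 1) + ri * sphere(p, 1),
                   pz = xyz(i, 2) + ri * sphere(p, 2);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double rj = radii[j] + probe;
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)s;
  }
  return area;
}
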