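#include <Rcpp.h>
using namespace Rcpp;

// Straight-segment Biot-Savart kernels. All routines take an n x 3 matrix of
// evaluation points, m x 3 matrices of segment start/end points and a length-m
// vector of signed per-segment currents (one polyline turn = unit current),
// and return the field WITHOUT the mu0/(4*pi) prefactor, which is applied on
// the R side together with the drive scaling.

// [[Rcpp::export]]
NumericMatrix bs_vector_potential(NumericMatrix points, NumericMatrix starts,
                                  NumericMatrix ends, NumericVector cur) {
  const int n = points.nrow(), m = starts.nrow();
  NumericMatrix A(n, 3);
  const double eps = 1e-12;
  for (int s = 0; s < m; ++s) {
    const double ax = starts(s, 0), ay = starts(s, 1), az = starts(s, 2);
    const double bx = ends(s, 0), by = ends(s, 1), bz = ends(s, 2);
    double lx = bx - ax, ly = by - ay, lz = bz - az;
    const double L = std::sqrt(lx * lx + ly * ly + lz * lz);
    if (L <= 0) continue;
    lx /= L; ly /= L; lz /= L;
    const double I = cur[s];
    for (int i = 0; i < n; ++i) {
      const double r1x = points(i, 0) - ax, r1y = points(i, 1) - ay,
                   r1z = points(i, 2) - az;
      const double r2x = points(i, 0) - bx, r2y = points(i, 1) - by,
                   r2z = points(i, 2) - bz;
      const double R1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      const double R2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      const double num = R1 + R2 + L, den = R1 + R2 - L;
      const double v = I * std::log(num / (den > eps ? den : eps));
      A(i, 0) += v * lx; A(i, 1) += v * ly; A(i, 2) += v * lz;
    }
  }
  return A;
}

// [[Rcpp::export]]
NumericMatrix bs_flux_density(NumericMatrix points, NumericMatrix starts,
                              NumericMatrix ends, NumericVector cur) {
  const int n = points.nrow(), m = starts.nrow();
  NumericMatrix B(n, 3);
  const double eps = 1e-24;
  for (int s = 0; s < m; ++s) {
    const double ax = starts(s, 0), ay = starts(s, 1), az = starts(s, 2);
    const double bx = ends(s, 0), by = ends(s, 1), bz = ends(s, 2);
    const double I = cur[s];
    for (int i = 0; i < n; ++i) {
      const double r1x = points(i, 0) - ax, r1y = points(i, 1) - ay,
                   r1z = points(i, 2) - az;
      const double r2x = points(i, 0) - bx, r2y = points(i, 1) - by,
                   r2z = points(i, 2) - bz;
      const double R1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      const double R2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      // Hanson-Hirshman: B ~ (R1+R2) (r1 x r2) / (R1 R2 (R1 R2 + r1.r2))
      const double cx = r1y * r2z - r1z * r2y;
      const double cy = r1z * r2x - r1x * r2z;
      const double cz = r1x * r2y - r1y * r2x;
      const double dot = r1x * r2x + r1y * r2y + r1z * r2z;
      double den = R1 * R2 * (R1 * R2 + dot);
      if (den < eps) den = eps;
      const double f = I * (R1 + R2) / den;
      B(i, 0) += f * cx; B(i, 1) += f * cy; B(i, 2) += f * cz;
    }
  }
  return B;
}

// [[Rcpp::export]]
NumericVector bs_min_distance(NumericMatrix points, NumericMatrix starts,
                              NumericMatrix ends) {
  const int n = points.nrow(), m = starts.nrow();
  NumericVector d(n, R_PosInf);
  for (int s = 0; s < m; ++s) {
    const double ax = starts(s, 0), ay = starts(s, 1), az = starts(s, 2);
    double lx = ends(s, 0) - ax, ly = ends(s, 1) - ay, lz = ends(s, 2) - az;
    const double L2 = lx * lx + ly * ly + lz * lz;
    for (int i = 0; i < n; ++i) {
      const double px = points(i, 0) - ax, py = points(i, 1) - ay,
                   pz = points(i, 2) - az;
      double t = L2 > 0 ? (px * lx + py * ly + pz * lz) / L2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      const double dx = px - t * lx, dy = py - t * ly, dz = pz - t * lz;
      const double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dd < d[i]) d[i] = dd;
    }
  }
  return d;
}
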