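#include <Rcpp.h>
using namespace Rcpp;

// Plain Gauss-Seidel sweeps for the conservative 7-point face-flux operator
// L phi = sum_faces g * (phi_nb - phi_c), with harmonic-mean face
// conductivities g = harm(sigma_c, sigma_nb) * V / h_a^2. Cells with
// sigma <= 0 are outside the conducting body and never touched; a missing
// face (zero harmonic mean) carries zero flux, which realises the natural
// Neumann boundary condition automatically.

static inline double harm(double a, double b) {
  const double s = a + b;
  return s > 0 ? 2.0 * a * b / s : 0.0;
}

// [[Rcpp::export]]
List gs_solve(NumericVector sigma, NumericVector rhs, IntegerVector dims,
              NumericVector pitch, double tol, int max_sweeps,
              int check_every) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double V = pitch[0] * pitch[1] * pitch[2];
  const double cx = V / (pitch[0] * pitch[0]);
  const double cy = V / (pitch[1] * pitch[1]);
  const double cz = V / (pitch[2] * pitch[2]);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector phi(n);
  const int sx = 1, sy = nx, sz = nx * ny;

  double rhs_norm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) rhs_norm += rhs[i] * rhs[i];
  rhs_norm = std::sqrt(rhs_norm);
  if (rhs_norm == 0.0)
    return List::create(_["phi"] = phi, _["iterations"] = 0,
                        _["residual"] = 0.0);

  int sweep = 0;
  double rel = R_PosInf;
  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t c = i + (R_xlen_t)j * sy + (R_xlen_t)k * sz;
          const double sc = sigma[c];
          if (sc <= 0) continue;
          double diag = 0.0, acc = 0.0, g;
          if (i > 0)      { g = cx * harm(sc, sigma[c - sx]); diag += g; acc += g * phi[c - sx]; }
          if (i < nx - 1) { g = cx * harm(sc, sigma[c + sx]); diag += g; acc += g * phi[c + sx]; }
          if (j > 0)      { g = cy * harm(sc, sigma[c - sy]); diag += g; acc += g * phi[c - sy]; }
          if (j < ny - 1) { g = cy * harm(sc, sigma[c + sy]); diag += g; acc += g * phi[c + sy]; }
          if (k > 0)      { g = cz * harm(sc, sigma[c - sz]); diag += g; acc += g * phi[c - sz]; }
          if (k < nz - 1) { g = cz * harm(sc, sigma[c + sz]); diag += g; acc += g * phi[c + sz]; }
          if (diag > 0) phi[c] = (acc - rhs[c]) / diag;
        }
    if (sweep % check_every == 0 || sweep == max_sweeps) {
      double rn = 0.0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            const R_xlen_t c = i + (R_xlen_t)j * sy + (R_xlen_t)k * sz;
            const double sc = sigma[c];
            if (sc <= 0) continue;
            double acc = -rhs[c], g;
            if (i > 0)      { g = cx * harm(sc, sigma[c - sx]); acc += g * (phi[c - sx] - phi[c]); }
            if (i < nx - 1) { g = cx * harm(sc, sigma[c + sx]); acc += g * (phi[c + sx] - phi[c]); }
            if (j > 0)      { g = cy * harm(sc, sigma[c - sy]); acc += g * (phi[c - sy] - phi[c]); }
            if (j < ny - 1) { g = cy * harm(sc, sigma[c + sy]); acc += g * (phi[c + sy] - phi[c]); }
            if (k > 0)      { g = cz * harm(sc, sigma[c - sz]); acc += g * (phi[c - sz] - phi[c]); }
            if (k < nz - 1) { g = cz * harm(sc, sigma[c + sz]); acc += g * (phi[c + sz] - phi[c]); }
            rn += acc * acc;
          }
      rel = std::sqrt(rn) / rhs_norm;
      if (rel <= tol) break;
    }
  }
  return List::create(_["phi"] = phi,
                      _["iterations"] = std::min(sweep, max_sweeps),
                      _["residual"] = rel);
}
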