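#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black Gauss-Seidel / SOR sweep over the 7-point stencil
//
//   phi0 <- (sum_k eps_k * phi_k + src0) / diag0
//
// followed by over-relaxation with factor omega. `diag` holds
// sum_k eps_k + (kappa0*h)^2 precomputed per node, `src` holds
// 4*pi*q0*beta/h. Midpoint dielectric arrays have full node dims; the entry
// at index i along their own axis is the midpoint between nodes i and i+1
// (wrapping for periodic axes). Nodes with update == FALSE hold fixed
// (Dirichlet) values. Both colors are swept in one call; newly computed
// values of the first color are used by the second (Gauss-Seidel
// semantics). Returns c(rmsc, maxc) with rmsc normalized by the total node
// count.
// [[Rcpp::export]]
NumericVector pb_sor_sweep(NumericVector phi,
                           NumericVector epsx, NumericVector epsy,
                           NumericVector epsz,
                           NumericVector diag, NumericVector src,
                           LogicalVector update, LogicalVector periodic,
                           double omega) {
  IntegerVector dims = phi.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const bool px = periodic[0], py = periodic[1], pz = periodic[2];
  double ssq = 0.0, mx = 0.0;

  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *dg = REAL(diag), *sc = REAL(src);
  const int *up = LOGICAL(update);

  for (int color = 0; color < 2; ++color) {
    for (int k = 0; k < nz; ++k) {
      const int km = (k > 0) ? k - 1 : (pz ? nz - 1 : -1);
      const int kp = (k < nz - 1) ? k + 1 : (pz ? 0 : -1);
      for (int j = 0; j < ny; ++j) {
        const int jm = (j > 0) ? j - 1 : (py ? ny - 1 : -1);
        const int jp = (j < ny - 1) ? j + 1 : (py ? 0 : -1);
        const R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nxy;
        int i0 = ((j + k) % 2 == color) ? 0 : 1;
        for (int i = i0; i < nx; i += 2) {
          const R_xlen_t idx = base + i;
          if (!up[idx]) continue;
          const int im = (i > 0) ? i - 1 : (px ? nx - 1 : -1);
          const int ip = (i < nx - 1) ? i + 1 : (px ? 0 : -1);
          // non-periodic boundary nodes are never flagged for update,
          // so im/ip/jm/jp/km/kp are valid here
          double num = sc[idx];
          num += ex[base + im] * p[base + im];
          num += ex[idx]       * p[base + ip];
          num += ey[(R_xlen_t)jm * nx + (R_xlen_t)k * nxy + i] *
                 p[(R_xlen_t)jm * nx + (R_xlen_t)k * nxy + i];
          num += ey[idx] * p[(R_xlen_t)jp * nx + (R_xlen_t)k * nxy + i];
          num += ez[(R_xlen_t)j * nx + (R_xlen_t)km * nxy + i] *
                 p[(R_xlen_t)j * nx + (R_xlen_t)km * nxy + i];
          num += ez[idx] * p[(R_xlen_t)j * nx + (R_xlen_t)kp * nxy + i];
          const double val = num / dg[idx];
          const double nw = omega * val + (1.0 - omega) * p[idx];
          const double diff = nw - p[idx];
          ssq += diff * diff;
          if (std::fabs(diff) > mx) mx = std::fabs(diff);
          p[idx] = nw;
        }
      }
    }
  }
  const double M = (double)nx * ny * nz;
  return NumericVector::create(std::sqrt(ssq / M), mx);
}

// One application of the Jacobi iteration operator implied by the stencil:
//   (M x)_0 = sum_k eps_k x_k / diag_0   on update nodes, 0 elsewhere.
// Used matrix-free by the spectral-radius power iteration.
// [[Rcpp::export]]
NumericVector pb_jacobi_apply(NumericVector x,
                              NumericVector epsx, NumericVector epsy,
                              NumericVector epsz, NumericVector diag,
                              LogicalVector update, LogicalVector periodic) {
  IntegerVector dims = x.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const bool px = periodic[0], py = periodic[1], pz = periodic[2];
  NumericVector out(x.size());
  out.attr("dim") = dims;
  const double *p = REAL(x);
  double *o = REAL(out);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *dg = REAL(diag);
  const int *up = LOGICAL(update);

  for (int k = 0; k < nz; ++k) {
    const int km = (k > 0) ? k - 1 : (pz ? nz - 1 : -1);
    const int kp = (k < nz - 1) ? k + 1 : (pz ? 0 : -1);
    for (int j = 0; j < ny; ++j) {
      const int jm = (j > 0) ? j - 1 : (py ? ny - 1 : -1);
      const int jp = (j < ny - 1) ? j + 1 : (py ? 0 : -1);
      const R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nxy;
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = base + i;
        if (!up[idx]) { o[idx] = 0.0; continue; }
        const int im = (i > 0) ? i - 1 : (px ? nx - 1 : -1);
        const int ip = (i < nx - 1) ? i + 1 : (px ? 0 : -1);
        double num = 0.0;
        // fixed (non-update) neighbors contribute zero to the iteration
        // operator: their values are part of the affine term, not of M
        if (up[base + im]) num += ex[base + im] * p[base + im];
        if (up[base + ip]) num += ex[idx] * p[base + ip];
        R_xlen_t idjm = (R_xlen_t)jm * nx + (R_xlen_t)k * nxy + i;
        R_xlen_t idjp = (R_xlen_t)jp * nx + (R_xlen_t)k * nxy + i;
        if (up[idjm]) num += ey[idjm] * p[idjm];
        if (up[idjp]) num += ey[idx] * p[idjp];
        R_xlen_t idkm = (R_xlen_t)j * nx + (R_xlen_t)km * nxy + i;
        R_xlen_t idkp = (R_xlen_t)j * nx + (R_xlen_t)kp * nxy + i;
        if (up[idkm]) num += ez[idkm] * p[idkm];
        if (up[idkp]) num += ez[idx] * p[idkp];
        o[idx] = num / dg[idx];
      }
    }
  }
  return out;
}
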