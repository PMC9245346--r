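#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-centered finite-volume discretization of the quasi-static conduction
// problem div(sigma grad phi) = 0 on a regular voxel lattice.
//
// Face conductances use the harmonic mean of the two adjacent cell
// conductivities, which is exact for a series resistor across the face and
// makes the scheme conservative by construction. Voxels with sigma == 0 are
// outside the conductive domain; the missing face term realizes the zero-flux
// (insulating) boundary condition on the head surface. Electrode voxels are
// Dirichlet-fixed to terminal potentials.
//
// Length units are mm and sigma is in S/m, so a face conductance
// sigma * A / h carries units S*mm^2/(m*mm) = 1e-3 S; currents returned here
// are in units of 1e-3 A and are rescaled on the R side.

namespace {

struct FVSystem {
  int nx, ny, nz;
  R_xlen_t n;
  std::vector<double> wx, wy, wz;   // face conductances to +x/+y/+z neighbor
  std::vector<double> diag;         // sum of incident face conductances
  std::vector<signed char> state;   // 0 = outside, 1 = free, 2 = fixed
  std::vector<double> phifix;       // fixed potential where state == 2

  inline R_xlen_t id(int ix, int iy, int iz) const {
    return ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
  }
};

inline double harm(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

void build_system(const NumericVector& sigma, const NumericVector& h,
                  const IntegerVector& fixed_idx, const NumericVector& fixed_val,
                  FVSystem& S) {
  IntegerVector dim = sigma.attr("dim");
  if (dim.size() != 3) stop("sigma must be a 3-D array");
  S.nx = dim[0]; S.ny = dim[1]; S.nz = dim[2];
  S.n = (R_xlen_t)S.nx * S.ny * S.nz;
  const double hx = h[0], hy = h[1], hz = h[2];
  // conductance factor per axis: sigma_face * area / spacing
  const double fx = (hy * hz) / hx, fy = (hx * hz) / hy, fz = (hx * hy) / hz;

  S.state.assign(S.n, 0);
  S.phifix.assign(S.n, 0.0);
  for (R_xlen_t k = 0; k < S.n; ++k) if (sigma[k] > 0.0) S.state[k] = 1;
  for (R_xlen_t i = 0; i < fixed_idx.size(); ++i) {
    R_xlen_t k = (R_xlen_t)fixed_idx[i] - 1;  // 1-based from R
    if (k < 0 || k >= S.n) stop("fixed voxel index out of range");
    if (S.state[k] == 0) stop("fixed voxel lies outside the conductive domain");
    S.state[k] = 2;
    S.phifix[k] = fixed_val[i];
  }

  S.wx.assign(S.n, 0.0); S.wy.assign(S.n, 0.0); S.wz.assign(S.n, 0.0);
  S.diag.assign(S.n, 0.0);
  for (int iz = 0; iz < S.nz; ++iz)
    for (int iy = 0; iy < S.ny; ++iy)
      for (int ix = 0; ix < S.nx; ++ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] == 0) continue;
        if (ix + 1 < S.nx) {
          R_xlen_t kk = k + 1;
          if (S.state[kk] != 0) S.wx[k] = fx * harm(sigma[k], sigma[kk]);
        }
        if (iy + 1 < S.ny) {
          R_xlen_t kk = k + S.nx;
          if (S.state[kk] != 0) S.wy[k] = fy * harm(sigma[k], sigma[kk]);
        }
        if (iz + 1 < S.nz) {
          R_xlen_t kk = k + (R_xlen_t)S.nx * S.ny;
          if (S.state[kk] != 0) S.wz[k] = fz * harm(sigma[k], sigma[kk]);
        }
      }
  const R_xlen_t sx = 1, sy = S.nx, sz = (R_xlen_t)S.nx * S.ny;
  for (int iz = 0; iz < S.nz; ++iz)
    for (int iy = 0; iy < S.ny; ++iy)
      for (int ix = 0; ix < S.nx; ++ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] == 0) continue;
        double d = S.wx[k] + S.wy[k] + S.wz[k];
        if (ix > 0) d += S.wx[k - sx];
        if (iy > 0) d += S.wy[k - sy];
        if (iz > 0) d += S.wz[k - sz];
        S.diag[k] = d;
      }
}

// y = A x on free voxels (x is zero-extended over fixed/outside voxels)
void matvec(const FVSystem& S, const std::vector<double>& x,
            std::vector<double>& y) {
  const R_xlen_t sx = 1, sy = S.nx, sz = (R_xlen_t)S.nx * S.ny;
  for (int iz = 0; iz < S.nz; ++iz)
    for (int iy = 0; iy < S.ny; ++iy)
      for (int ix = 0; ix < S.nx; ++ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] != 1) { y[k] = 0.0; continue; }
        double acc = S.diag[k] * x[k];
        if (ix + 1 < S.nx && S.state[k + sx] == 1) acc -= S.wx[k] * x[k + sx];
        if (iy + 1 < S.ny && S.state[k + sy] == 1) acc -= S.wy[k] * x[k + sy];
        if (iz + 1 < S.nz && S.state[k + sz] == 1) acc -= S.wz[k] * x[k + sz];
        if (ix > 0 && S.state[k - sx] == 1) acc -= S.wx[k - sx] * x[k - sx];
        if (iy > 0 && S.state[k - sy] == 1) acc -= S.wy[k - sy] * x[k - sy];
        if (iz > 0 && S.state[k - sz] == 1) acc -= S.wz[k - sz] * x[k - sz];
        y[k] = acc;
      }
}

// right-hand side from Dirichlet neighbors
void rhs(const FVSystem& S, std::vector<double>& b) {
  const R_xlen_t sx = 1, sy = S.nx, sz = (R_xlen_t)S.nx * S.ny;
  b.assign(S.n, 0.0);
  for (int iz = 0; iz < S.nz; ++iz)
    for (int iy = 0; iy < S.ny; ++iy)
      for (int ix = 0; ix < S.nx; ++ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] != 1) continue;
        double acc = 0.0;
        if (ix + 1 < S.nx && S.state[k + sx] == 2) acc += S.wx[k] * S.phifix[k + sx];
        if (iy + 1 < S.ny && S.state[k + sy] == 2) acc += S.wy[k] * S.phifix[k + sy];
        if (iz + 1 < S.nz && S.state[k + sz] == 2) acc += S.wz[k] * S.phifix[k + sz];
        if (ix > 0 && S.state[k - sx] == 2) acc += S.wx[k - sx] * S.phifix[k - sx];
        if (iy > 0 && S.state[k - sy] == 2) acc += S.wy[k - sy] * S.phifix[k - sy];
        if (iz > 0 && S.state[k - sz] == 2) acc += S.wz[k - sz] * S.phifix[k - sz];
        b[k] = acc;
      }
}

// symmetric Gauss-Seidel preconditioner: solve (D+L) D^-1 (D+U) z = r
void sgs_apply(const FVSystem& S, const std::vector<double>& r,
               std::vector<double>& z, std::vector<double>& tmp) {
  const R_xlen_t sx = 1, sy = S.nx, sz = (R_xlen_t)S.nx * S.ny;
  // forward: (D+L) y = r, stored in tmp
  for (int iz = 0; iz < S.nz; ++iz)
    for (int iy = 0; iy < S.ny; ++iy)
      for (int ix = 0; ix < S.nx; ++ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] != 1) { tmp[k] = 0.0; continue; }
        double acc = r[k];
        if (ix > 0 && S.state[k - sx] == 1) acc += S.wx[k - sx] * tmp[k - sx];
        if (iy > 0 && S.state[k - sy] == 1) acc += S.wy[k - sy] * tmp[k - sy];
        if (iz > 0 && S.state[k - sz] == 1) acc += S.wz[k - sz] * tmp[k - sz];
        tmp[k] = acc / S.diag[k];
      }
  // backward: (D+U) z = D y
  for (int iz = S.nz - 1; iz >= 0; --iz)
    for (int iy = S.ny - 1; iy >= 0; --iy)
      for (int ix = S.nx - 1; ix >= 0; --ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] != 1) { z[k] = 0.0; continue; }
        double acc = S.diag[k] * tmp[k];
        if (ix + 1 < S.nx && S.state[k + sx] == 1) acc += S.wx[k] * z[k + sx];
        if (iy + 1 < S.ny && S.state[k + sy] == 1) acc += S.wy[k] * z[k + sy];
        if (iz + 1 < S.nz && S.state[k + sz] == 1) acc += S.wz[k] * z[k + sz];
        z[k] = acc / S.diag[k];
      }
}

double dot(const std::vector<double>& a, const std::vector<double>& b) {
  double s = 0.0;
  for (R_xlen_t k = 0; k < (R_xlen_t)a.size(); ++k) s += a[k] * b[k];
  return s;
}

}  // namespace

//' @name fv_solve_cpp
//' @title Low-level finite-volume conduction solve (internal)
//' @keywords internal
// [[Rcpp::export]]
List fv_solve_cpp(NumericVector sigma, NumericVector h,
                  IntegerVector fixed_idx, NumericVector fixed_val,
                  IntegerVector terminal, double tol, int maxit,
                  int precond, Nullable<NumericVector> x0_ = R_NilValue) {
  FVSystem S;
  build_system(sigma, h, fixed_idx, fixed_val, S);

  std::vector<double> b;
  rhs(S, b);
  double bnorm = std::sqrt(dot(b, b));

  std::vector<double> x(S.n, 0.0), r(S.n, 0.0), z(S.n, 0.0), p(S.n, 0.0),
      Ap(S.n, 0.0), tmp(S.n, 0.0);
  if (x0_.isNotNull()) {
    NumericVector x0(x0_);
    if ((R_xlen_t)x0.size() != S.n) stop("x0 has wrong length");
    for (R_xlen_t k = 0; k < S.n; ++k)
      x[k] = (S.state[k] == 1 && R_finite(x0[k])) ? x0[k] : 0.0;
  }

  // r = b - A x
  matvec(S, x, r);
  for (R_xlen_t k = 0; k < S.n; ++k) r[k] = b[k] - r[k];

  int it = 0;
  double relres = 1.0;
  if (bnorm == 0.0) {
    std::fill(x.begin(), x.end(), 0.0);
    relres = 0.0;
  } else {
    if (precond == 1) sgs_apply(S, r, z, tmp);
    else for (R_xlen_t k = 0; k < S.n; ++k)
      z[k] = (S.state[k] == 1) ? r[k] / S.diag[k] : 0.0;
    p = z;
    double rz = dot(r, z);
    for (it = 0; it < maxit; ++it) {
      matvec(S, p, Ap);
      double pAp = dot(p, Ap);
      if (pAp <= 0.0) break;  // should not happen for SPD system
      double alpha = rz / pAp;
      for (R_xlen_t k = 0; k < S.n; ++k) { x[k] += alpha * p[k]; r[k] -= alpha * Ap[k]; }
      relres = std::sqrt(dot(r, r)) / bnorm;
      if (relres <= tol) { ++it; break; }
      if (precond == 1) sgs_apply(S, r, z, tmp);
      else for (R_xlen_t k = 0; k < S.n; ++k)
        z[k] = (S.state[k] == 1) ? r[k] / S.diag[k] : 0.0;
      double rz_new = dot(r, z);
      double beta = rz_new / rz;
      rz = rz_new;
      for (R_xlen_t k = 0; k < S.n; ++k) p[k] = z[k] + beta * p[k];
      if (it % 200 == 0) Rcpp::checkUserInterrupt();
    }
  }

  // assemble the full potential grid: free + fixed, NA outside the domain
  NumericVector phi(S.n, NA_REAL);
  for (R_xlen_t k = 0; k < S.n; ++k) {
    if (S.state[k] == 1) phi[k] = x[k];
    else if (S.state[k] == 2) phi[k] = S.phifix[k];
  }
  phi.attr("dim") = sigma.attr("dim");

  // terminal currents: net flux leaving each terminal's fixed voxel set
  // (units 1e-3 A; rescaled in R)
  std::vector<signed char> term(S.n, 0);
  for (R_xlen_t i = 0; i < fixed_idx.size(); ++i)
    term[(R_xlen_t)fixed_idx[i] - 1] = (signed char)terminal[i];
  const R_xlen_t sx = 1, sy = S.nx, sz = (R_xlen_t)S.nx * S.ny;
  double Isrc = 0.0, Isnk = 0.0;
  std::vector<double> full(S.n, 0.0);
  for (R_xlen_t k = 0; k < S.n; ++k)
    full[k] = (S.state[k] == 1) ? x[k] : (S.state[k] == 2 ? S.phifix[k] : 0.0);
  for (int iz = 0; iz < S.nz; ++iz)
    for (int iy = 0; iy < S.ny; ++iy)
      for (int ix = 0; ix < S.nx; ++ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] != 2) continue;
        double out = 0.0;
        if (ix + 1 < S.nx && S.state[k + sx] != 0 && term[k + sx] != term[k])
          out += S.wx[k] * (full[k] - full[k + sx]);
        if (iy + 1 < S.ny && S.state[k + sy] != 0 && term[k + sy] != term[k])
          out += S.wy[k] * (full[k] - full[k + sy]);
        if (iz + 1 < S.nz && S.state[k + sz] != 0 && term[k + sz] != term[k])
          out += S.wz[k] * (full[k] - full[k + sz]);
        if (ix > 0 && S.state[k - sx] != 0 && term[k - sx] != term[k])
          out += S.wx[k - sx] * (full[k] - full[k - sx]);
        if (iy > 0 && S.state[k - sy] != 0 && term[k - sy] != term[k])
          out += S.wy[k - sy] * (full[k] - full[k - sy]);
        if (iz > 0 && S.state[k - sz] != 0 && term[k - sz] != term[k])
          out += S.wz[k - sz] * (full[k] - full[k - sz]);
        if (term[k] == 1) Isrc += out; else if (term[k] == 2) Isnk += out;
      }

  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = (relres <= tol),
                      _["I_src_raw"] = Isrc, _["I_snk_raw"] = Isnk,
                      _["n_free"] = (double)std::count(S.state.begin(), S.state.end(), 1));
}

//' @name fv_system_cpp
//' @title Export the assembled linear system in triplet form (internal)
//' @keywords internal
// [[Rcpp::export]]
List fv_system_cpp(NumericVector sigma, NumericVector h,
                   IntegerVector fixed_idx, NumericVector fixed_val) {
  FVSystem S;
  build_system(sigma, h, fixed_idx, fixed_val, S);
  // map free voxels to consecutive equation indices
  std::vector<R_xlen_t> eq(S.n, -1);
  R_xlen_t nfree = 0;
  for (R_xlen_t k = 0; k < S.n; ++k) if (S.state[k] == 1) eq[k] = nfree++;
  std::vector<double> b;
  rhs(S, b);

  std::vector<int> ti, tj;
  std::vector<double> tx;
  NumericVector bb(nfree);
  IntegerVector vox(nfree);
  const R_xlen_t sx = 1, sy = S.nx, sz = (R_xlen_t)S.nx * S.ny;
  for (int iz = 0; iz < S.nz; ++iz)
    for (int iy = 0; iy < S.ny; ++iy)
      for (int ix = 0; ix < S.nx; ++ix) {
        R_xlen_t k = S.id(ix, iy, iz);
        if (S.state[k] != 1) continue;
        R_xlen_t i = eq[k];
        bb[i] = b[k];
        vox[i] = (int)(k + 1);
        ti.push_back((int)i + 1); tj.push_back((int)i + 1); tx.push_back(S.diag[k]);
        if (ix + 1 < S.nx && S.state[k + sx] == 1) {
          ti.push_back((int)i + 1); tj.push_back((int)eq[k + sx] + 1); tx.push_back(-S.wx[k]);
          ti.push_back((int)eq[k + sx] + 1); tj.push_back((int)i + 1); tx.push_back(-S.wx[k]);
        }
        if (iy + 1 < S.ny && S.state[k + sy] == 1) {
          ti.push_back((int)i + 1); tj.push_back((int)eq[k + sy] + 1); tx.push_back(-S.wy[k]);
          ti.push_back((int)eq[k + sy] + 1); tj.push_back((int)i + 1); tx.push_back(-S.wy[k]);
        }
        if (iz + 1 < S.nz && S.state[k + sz] == 1) {
          ti.push_back((int)i + 1); tj.push_back((int)eq[k + sz] + 1); tx.push_back(-S.wz[k]);
          ti.push_back((int)eq[k + sz] + 1); tj.push_back((int)i + 1); tx.push_back(-S.wz[k]);
        }
      }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx),
                      _["b"] = bb, _["n_free"] = (int)nfree, _["voxel"] = vox);
}
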