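// Compiled inner kernels: D3Q19 lattice Boltzmann collide-stream with
// semi-implicit Brinkman drag and Guo forcing, Skalak membrane force
// assembly over constant-strain triangles, and immersed-boundary
// spread/interpolation with the 4-point cosine delta kernel.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// D3Q19 velocity set; OPP[q] is the antiparallel direction.
static const int EX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int EY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int EZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const int OPP[19] = {0, 2,1, 4,3, 6,5, 8,7, 10,9, 12,11, 14,13, 16,15, 18,17};
static const double WQ[19] = {
  1.0/3.0,
  1.0/18.0, 1.0/18.0, 1.0/18.0, 1.0/18.0, 1.0/18.0, 1.0/18.0,
  1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0,
  1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0};

// One BGK collide + stream cycle over the indexed fluid cells, fused as a
// push scheme: each cell collides in registers and scatters post-collision
// values to its downstream neighbors (halfway bounce-back into its own
// reversed slot at solid walls). The caller must swap f and fpost after
// the call. f, fpost are length 19*nf, cell-major (f[i*19 + q]);
// nbr[q*nf + i] is the fluid index of the pull source (cell at x_i - e_q),
// or -1 when that site is solid; the push target for direction q is the
// pull source of OPP[q].
// ctype: 1 = pericellular (the drive acts there), 2 = intracellular.
// cdv: per-cell lattice drag coefficient (Brinkman drag in pericellular
// cells; optionally a pure numerical damping elsewhere, which vanishes
// with u at steady state).
// Fx/Fy/Fz: immersed-boundary force density per cell, lattice units.
// Macroscopic rho and the force-corrected velocity are written out.
// [[Rcpp::export]]
void lbm_collide_stream_cpp(NumericVector f, NumericVector fpost,
                            IntegerVector nbr, IntegerVector ctype,
                            NumericVector Fx, NumericVector Fy, NumericVector Fz,
                            double drive_z, double tau, NumericVector cdv,
                            NumericVector rho, NumericVector ux,
                            NumericVector uy, NumericVector uz) {
  const R_xlen_t nf = rho.size();
  const double om = 1.0 / tau;
  const double sc = 1.0 - 0.5 * om;
  double fi[19];
  double* pf = REAL(f);
  double* pp = REAL(fpost);
  const int* pn = INTEGER(nbr);
  for (R_xlen_t i = 0; i < nf; ++i) {
    const double* fc = pf + i * 19;
    for (int q = 0; q < 19; ++q) fi[q] = fc[q];
    const double r = fi[0] + fi[1] + fi[2] + fi[3] + fi[4] + fi[5] + fi[6] +
      fi[7] + fi[8] + fi[9] + fi[10] + fi[11] + fi[12] + fi[13] + fi[14] +
      fi[15] + fi[16] + fi[17] + fi[18];
    const double mx = fi[1] - fi[2] + fi[7] - fi[8] + fi[9] - fi[10] +
      fi[11] - fi[12] + fi[13] - fi[14];
    const double my = fi[3] - fi[4] + fi[7] - fi[8] - fi[9] + fi[10] +
      fi[15] - fi[16] + fi[17] - fi[18];
    const double mz = fi[5] - fi[6] + fi[11] - fi[12] - fi[13] + fi[14] +
      fi[15] - fi[16] - fi[17] + fi[18];
    const bool peri = (ctype[i] == 1);
    const double fx = Fx[i];
    const double fy = Fy[i];
    const double fz = Fz[i] + (peri ? drive_z : 0.0);
    const double cdi = cdv[i];
    const double inv = 1.0 / (r * (1.0 + 0.5 * cdi));
    const double u = (mx + 0.5 * fx) * inv;
    const double v = (my + 0.5 * fy) * inv;
    const double w = (mz + 0.5 * fz) * inv;
    // total force including the (now explicitly known) Brinkman drag
    const double Ftx = fx - cdi * r * u;
    const double Fty = fy - cdi * r * v;
    const double Ftz = fz - cdi * r * w;
    rho[i] = r; ux[i] = u; uy[i] = v; uz[i] = w;
    const double usq = 1.5 * (u * u + v * v + w * w);
    const double uF3 = 3.0 * (u * Ftx + v * Fty + w * Ftz);
    const double om1 = 1.0 - om;
    // rest population
    {
      const double feq = WQ[0] * r * (1.0 - usq);
      const double val = om1 * fi[0] + om * feq + sc * WQ[0] * (-uF3);
      pp[i * 19 + 0] = val;  // q = 0 streams to itself
    }
    // antiparallel pairs share their even/odd parts: for +/-(eu, eF)
    // feq(+/-) = base +/- dlt, S(+/-) = sa +/- sb
#define CF_LBMP(qp, qm, eu, eF)                                             \
    {                                                                       \
      const double base = WQ[qp] * r * (1.0 + 4.5 * (eu) * (eu) - usq);     \
      const double dlt = WQ[qp] * r * 3.0 * (eu);                           \
      const double sa = sc * WQ[qp] * (9.0 * (eu) * (eF) - uF3);            \
      const double sb = sc * WQ[qp] * 3.0 * (eF);                           \
      const double vp = om1 * fi[qp] + om * (base + dlt) + sa + sb;         \
      const double vm = om1 * fi[qm] + om * (base - dlt) + sa - sb;         \
      const int jp = pn[(R_xlen_t)qm * nf + i];                             \
      if (jp >= 0) pp[(R_xlen_t)jp * 19 + qp] = vp;                         \
      else pp[i * 19 + qm] = vp;                                            \
      const int jm = pn[(R_xlen_t)qp * nf + i];                             \
      if (jm >= 0) pp[(R_xlen_t)jm * 19 + qm] = vm;                         \
      else pp[i * 19 + qp] = vm;                                            \
    }
    CF_LBMP(1, 2, u, Ftx)
    CF_LBMP(3, 4, v, Fty)
    CF_LBMP(5, 6, w, Ftz)
    CF_LBMP(7, 8, u + v, Ftx + Fty)
    CF_LBMP(9, 10, u - v, Ftx - Fty)
    CF_LBMP(11, 12, u + w, Ftx + Ftz)
    CF_LBMP(13, 14, u - w, Ftx - Ftz)
    CF_LBMP(15, 16, v + w, Fty + Ftz)
    CF_LBMP(17, 18, v - w, Fty - Ftz)
#undef CF_LBMP
  }
}

// Skalak membrane: nodal force assembly and (optionally) per-element
// strain state over constant-strain triangles.
// V: current vertex coordinates (n x 3, nm), already containing any
//    displacement; zoff (m x 3) unwraps triangles crossing the z seam.
// tri: 1-based vertex indices (m x 3); refinv: rows of Dm^-1 stored as
//    (a11, a21, a12, a22); refA: reference areas (nm^2).
// force is zeroed and accumulated in place (pN).
// strain (m x 5): lambda1, lambda2, I1, I2, max principal Green-Lagrange.
// [[Rcpp::export]]
List membrane_forces_cpp(NumericMatrix V, IntegerMatrix tri, NumericMatrix zoff,
                         NumericMatrix refinv, NumericVector refA,
                         double Gs, double Csk,
                         NumericMatrix force, bool want_strain,
                         NumericMatrix strain) {
  const int m = tri.nrow();
  const int n = V.nrow();
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < n; ++i) force(i, j) = 0.0;
  double energy = 0.0;
  int ndeg = 0;
  for (int t = 0; t < m; ++t) {
    const int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    const double ax = V(a, 0), ay = V(a, 1), az = V(a, 2) + zoff(t, 0);
    const double d1x = V(b, 0) - ax, d1y = V(b, 1) - ay;
    const double d1z = V(b, 2) + zoff(t, 1) - az;
    const double d2x = V(c, 0) - ax, d2y = V(c, 1) - ay;
    const double d2z = V(c, 2) + zoff(t, 2) - az;
    const double i11 = refinv(t, 0), i21 = refinv(t, 1);
    const double i12 = refinv(t, 2), i22 = refinv(t, 3);
    // deformation gradient F (3 x 2) = [d1 d2] %*% Dm^-1
    const double F1x = d1x * i11 + d2x * i21;
    const double F1y = d1y * i11 + d2y * i21;
    const double F1z = d1z * i11 + d2z * i21;
    const double F2x = d1x * i12 + d2x * i22;
    const double F2y = d1y * i12 + d2y * i22;
    const double F2z = d1z * i12 + d2z * i22;
    const double c11 = F1x * F1x + F1y * F1y + F1z * F1z;
    const double c22 = F2x * F2x + F2y * F2y + F2z * F2z;
    const double c12 = F1x * F2x + F1y * F2y + F1z * F2z;
    const double detC = c11 * c22 - c12 * c12;
    if (!(detC > 1e-12)) {
      ++ndeg;
      if (want_strain) {
        strain(t, 0) = NA_REAL; strain(t, 1) = NA_REAL;
        strain(t, 2) = NA_REAL; strain(t, 3) = NA_REAL; strain(t, 4) = NA_REAL;
      }
      continue;
    }
    const double I1 = c11 + c22 - 2.0;
    const double I2 = detC - 1.0;
    const double A = refA[t];
    energy += 0.25 * Gs * (I1 * I1 + 2.0 * I1 - 2.0 * I2 + Csk * I2 * I2) * A;
    const double W1 = 0.5 * Gs * (I1 + 1.0);
    const double W2 = 0.5 * Gs * (Csk * I2 - 1.0);
    // second Piola-Kirchhoff S = 2 W1 I + 2 W2 adj(C)
    const double S11 = 2.0 * (W1 + W2 * c22);
    const double S22 = 2.0 * (W1 + W2 * c11);
    const double S12 = -2.0 * W2 * c12;
    // P = F S (3 x 2)
    const double P1x = F1x * S11 + F2x * S12;
    const double P1y = F1y * S11 + F2y * S12;
    const double P1z = F1z * S11 + F2z * S12;
    const double P2x = F1x * S12 + F2x * S22;
    const double P2y = F1y * S12 + F2y * S22;
    const double P2z = F1z * S12 + F2z * S22;
    const double fbx = -A * (P1x * i11 + P2x * i12);
    const double fby = -A * (P1y * i11 + P2y * i12);
    const double fbz = -A * (P1z * i11 + P2z * i12);
    const double fcx = -A * (P1x * i21 + P2x * i22);
    const double fcy = -A * (P1y * i21 + P2y * i22);
    const double fcz = -A * (P1z * i21 + P2z * i22);
    force(b, 0) += fbx; force(b, 1) += fby; force(b, 2) += fbz;
    force(c, 0) += fcx; force(c, 1) += fcy; force(c, 2) += fcz;
    force(a, 0) -= fbx + fcx; force(a, 1) -= fby + fcy; force(a, 2) -= fbz + fcz;
    if (want_strain) {
      const double tr = 0.5 * (c11 + c22);
      const double dd = std::sqrt(std::max(0.0, tr * tr - detC));
      const double lc1 = tr + dd, lc2 = std::max(0.0, tr - dd);
      strain(t, 0) = std::sqrt(lc1);
      strain(t, 1) = std::sqrt(lc2);
      strain(t, 2) = I1;
      strain(t, 3) = I2;
      strain(t, 4) = 0.5 * (lc1 - 1.0);  // max principal Green-Lagrange
    }
  }
  return List::create(_["energy"] = energy, _["n_degenerate"] = ndeg);
}

static inline double ibw(double d) {
  if (d <= -2.0 || d >= 2.0) return 0.0;
  return 0.25 * (1.0 + std::cos(M_PI * d * 0.5));
}

static inline int wrap_idx(int i, int n) {
  int r = i % n;
  return (r < 0) ? r + n : r;
}

// Spread nodal forces q (pN) to the lattice as a force density (pN/nm^3).
// fidx maps full-grid voxel -> fluid cell index (0-based) or -1 (solid).
// Force landing on solid (or, on a non-periodic axis, outside the grid)
// is accumulated into `leak` instead of the field.
// [[Rcpp::export]]
NumericVector ibm_spread_cpp(NumericMatrix nodes, NumericMatrix q,
                             NumericVector origin, double dx, IntegerVector dims,
                             IntegerVector fidx, LogicalVector periodic,
                             NumericVector Fx, NumericVector Fy, NumericVector Fz,
                             double scale = 1.0) {
  const int n = nodes.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nf = Fx.size();
  for (R_xlen_t i = 0; i < nf; ++i) { Fx[i] = 0.0; Fy[i] = 0.0; Fz[i] = 0.0; }
  NumericVector leak(3);
  const double inv3 = 1.0 / (dx * dx * dx);
  int idx[3][4];
  double wgt[3][4];
  const int nn[3] = {nx, ny, nz};
  for (int p = 0; p < n; ++p) {
    for (int a = 0; a < 3; ++a) {
      const double t = (nodes(p, a) - origin[a]) / dx - 0.5;
      const int i0 = (int)std::floor(t) - 1;
      for (int k = 0; k < 4; ++k) {
        const int ii = i0 + k;
        wgt[a][k] = ibw((double)ii - t);
        if (periodic[a]) {
          idx[a][k] = wrap_idx(ii, nn[a]);
        } else {
          idx[a][k] = (ii >= 0 && ii < nn[a]) ? ii : -1;
        }
      }
    }
    const double qx = q(p, 0) * scale, qy = q(p, 1) * scale,
                 qz = q(p, 2) * scale;
    for (int kz = 0; kz < 4; ++kz) {
      if (wgt[2][kz] == 0.0) continue;
      for (int ky = 0; ky < 4; ++ky) {
        const double wyz = wgt[2][kz] * wgt[1][ky];
        if (wyz == 0.0) continue;
        for (int kx = 0; kx < 4; ++kx) {
          const double w = wyz * wgt[0][kx];
          if (w == 0.0) continue;
          const int ix = idx[0][kx], iy = idx[1][ky], iz = idx[2][kz];
          int fi = -1;
          if (ix >= 0 && iy >= 0 && iz >= 0)
            fi = fidx[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)];
          if (fi >= 0) {
            Fx[fi] += w * qx * inv3;
            Fy[fi] += w * qy * inv3;
            Fz[fi] += w * qz * inv3;
          } else {
            leak[0] += w * qx; leak[1] += w * qy; leak[2] += w * qz;
          }
        }
      }
    }
  }
  return leak;
}

// Interpolate a per-fluid-cell velocity field to the membrane nodes:
// U(x_m) = sum_f D(x_m - x_f) u(x_f) dx^3. Solid cells contribute zero.
// [[Rcpp::export]]
NumericMatrix ibm_interp_cpp(NumericMatrix nodes,
                             NumericVector ux, NumericVector uy, NumericVector uz,
                             NumericVector origin, double dx, IntegerVector dims,
                             IntegerVector fidx, LogicalVector periodic) {
  const int n = nodes.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix U(n, 3);
  int idx[3][4];
  double wgt[3][4];
  const int nn[3] = {nx, ny, nz};
  for (int p = 0; p < n; ++p) {
    for (int a = 0; a < 3; ++a) {
      const double t = (nodes(p, a) - origin[a]) / dx - 0.5;
      const int i0 = (int)std::floor(t) - 1;
      for (int k = 0; k < 4; ++k) {
        const int ii = i0 + k;
        wgt[a][k] = ibw((double)ii - t);
        if (periodic[a]) {
          idx[a][k] = wrap_idx(ii, nn[a]);
        } else {
          idx[a][k] = (ii >= 0 && ii < nn[a]) ? ii : -1;
        }
      }
    }
    double sx = 0.0, sy = 0.0, sz = 0.0;
    for (int kz = 0; kz < 4; ++kz) {
      if (wgt[2][kz] == 0.0) continue;
      for (int ky = 0; ky < 4; ++ky) {
        const double wyz = wgt[2][kz] * wgt[1][ky];
        if (wyz == 0.0) continue;
        for (int kx = 0; kx < 4; ++kx) {
          const double w = wyz * wgt[0][kx];
          if (w == 0.0) continue;
          const int ix = idx[0][kx], iy = idx[1][ky], iz = idx[2][kz];
          if (ix < 0 || iy < 0 || iz < 0) continue;
          const int fi = fidx[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)];
          if (fi >= 0) {
            sx += w * ux[fi]; sy += w * uy[fi]; sz += w * uz[fi];
          }
        }
      }
    }
    U(p, 0) = sx; U(p, 1) = sy; U(p, 2) = sz;
  }
  return U;
}

// As ibm_interp_cpp, but writing into a preallocated output matrix
// (allocation-free inner loop for the coupled solver).
// [[Rcpp::export]]
void ibm_interp_into_cpp(NumericMatrix nodes,
                         NumericVector ux, NumericVector uy, NumericVector uz,
                         NumericVector origin, double dx, IntegerVector dims,
                         IntegerVector fidx, LogicalVector periodic,
                         NumericMatrix U) {
  const int n = nodes.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int idx[3][4];
  double wgt[3][4];
  const int nn[3] = {nx, ny, nz};
  for (int p = 0; p < n; ++p) {
    for (int a = 0; a < 3; ++a) {
      const double t = (nodes(p, a) - origin[a]) / dx - 0.5;
      const int i0 = (int)std::floor(t) - 1;
      for (int k = 0; k < 4; ++k) {
        const int ii = i0 + k;
        wgt[a][k] = ibw((double)ii - t);
        if (periodic[a]) idx[a][k] = wrap_idx(ii, nn[a]);
        else idx[a][k] = (ii >= 0 && ii < nn[a]) ? ii : -1;
      }
    }
    double sx = 0.0, sy = 0.0, sz = 0.0;
    for (int kz = 0; kz < 4; ++kz) {
      if (wgt[2][kz] == 0.0) continue;
      for (int ky = 0; ky < 4; ++ky) {
        const double wyz = wgt[2][kz] * wgt[1][ky];
        if (wyz == 0.0) continue;
        for (int kx = 0; kx < 4; ++kx) {
          const double w = wyz * wgt[0][kx];
          if (w == 0.0) continue;
          const int ix = idx[0][kx], iy = idx[1][ky], iz = idx[2][kz];
          if (ix < 0 || iy < 0 || iz < 0) continue;
          const int fi = fidx[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)];
          if (fi >= 0) { sx += w * ux[fi]; sy += w * uy[fi]; sz += w * uz[fi]; }
        }
      }
    }
    U(p, 0) = sx; U(p, 1) = sy; U(p, 2) = sz;
  }
}

// One fused coupling cycle of the fluid-structure solver: Skalak membrane
// forces + tension-only tether forces -> IBM spreading (scaled to lattice
// units) -> one Brinkman LBM step -> velocity interpolation -> heavy-ball
// momentum advection of the membrane with per-node pseudo-time scaling.
// Composes the operations of membrane_forces_cpp, ibm_spread_cpp,
// lbm_collide_stream_cpp and ibm_interp_into_cpp without intermediate
// allocation. The caller must swap f and fpost afterwards.
// qbuf, U are scratch (n x 3); tension is overwritten (length n_te).
// Returns membrane energy, degenerate-element count and the largest
// per-step node displacement (nm).
// [[Rcpp::export]]
List fsi_step_cpp(NumericMatrix V, NumericMatrix mom,
                  IntegerMatrix tri, NumericMatrix zoff,
                  NumericMatrix refinv, NumericVector refA,
                  double Gs, double Csk,
                  IntegerVector att, NumericMatrix xw,
                  NumericVector ksp, NumericVector l0,
                  NumericVector tension, NumericMatrix qbuf,
                  NumericVector f, NumericVector fpost,
                  IntegerVector nbr, IntegerVector ctype,
                  NumericVector Fx, NumericVector Fy, NumericVector Fz,
                  NumericVector cdv, double drive_z, double tau,
                  NumericVector rho, NumericVector ux,
                  NumericVector uy, NumericVector uz,
                  NumericVector origin, double dx, IntegerVector dims,
                  IntegerVector fidx, LogicalVector periodic,
                  NumericMatrix U, NumericVector gamma,
                  NumericVector beta, double qscale) {
  NumericMatrix dummy(0, 0);
  List mres = membrane_forces_cpp(V, tri, zoff, refinv, refA, Gs, Csk,
                                  qbuf, false, dummy);
  const int n_te = att.size();
  for (int t = 0; t < n_te; ++t) {
    const int a = att[t];
    const double dxw = V(a, 0) - xw(t, 0);
    const double dyw = V(a, 1) - xw(t, 1);
    const double dzw = V(a, 2) - xw(t, 2);
    const double len = std::sqrt(dxw * dxw + dyw * dyw + dzw * dzw);
    const double ext = len - l0[t];
    if (ext > 0.0 && len > 0.0) {
      const double T = ksp[t] * ext;
      tension[t] = T;
      const double s = T / len;
      qbuf(a, 0) -= s * dxw;
      qbuf(a, 1) -= s * dyw;
      qbuf(a, 2) -= s * dzw;
    } else {
      tension[t] = 0.0;
    }
  }
  // spread with node weights retained for the post-step interpolation
  const int n = V.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nn[3] = {nx, ny, nz};
  std::vector<double> wall(n * 12);
  std::vector<int> iall(n * 12);
  {
    const R_xlen_t nfl = Fx.size();
    for (R_xlen_t i = 0; i < nfl; ++i) { Fx[i] = 0.0; Fy[i] = 0.0; Fz[i] = 0.0; }
    const double inv3 = qscale / (dx * dx * dx);
    for (int p = 0; p < n; ++p) {
      double* wp = wall.data() + p * 12;
      int* ip = iall.data() + p * 12;
      for (int a = 0; a < 3; ++a) {
        const double t = (V(p, a) - origin[a]) / dx - 0.5;
        const int i0 = (int)std::floor(t) - 1;
        for (int k = 0; k < 4; ++k) {
          const int ii = i0 + k;
          wp[a * 4 + k] = ibw((double)ii - t);
          if (periodic[a]) ip[a * 4 + k] = wrap_idx(ii, nn[a]);
          else ip[a * 4 + k] = (ii >= 0 && ii < nn[a]) ? ii : -1;
        }
      }
      const double qx = qbuf(p, 0) * inv3, qy = qbuf(p, 1) * inv3,
                   qz = qbuf(p, 2) * inv3;
      for (int kz = 0; kz < 4; ++kz) {
        if (wp[8 + kz] == 0.0 || ip[8 + kz] < 0) continue;
        const R_xlen_t offz = nx * ((R_xlen_t)ny * ip[8 + kz]);
        for (int ky = 0; ky < 4; ++ky) {
          const double wyz = wp[8 + kz] * wp[4 + ky];
          if (wyz == 0.0 || ip[4 + ky] < 0) continue;
          const R_xlen_t offyz = offz + (R_xlen_t)nx * ip[4 + ky];
          for (int kx = 0; kx < 4; ++kx) {
            const double w = wyz * wp[kx];
            if (w == 0.0 || ip[kx] < 0) continue;
            const int fi = fidx[offyz + ip[kx]];
            if (fi >= 0) {
              Fx[fi] += w * qx; Fy[fi] += w * qy; Fz[fi] += w * qz;
            }
          }
        }
      }
    }
  }
  lbm_collide_stream_cpp(f, fpost, nbr, ctype, Fx, Fy, Fz, drive_z, tau,
                         cdv, rho, ux, uy, uz);
  // interpolate with the stored weights (same node positions)
  for (int p = 0; p < n; ++p) {
    const double* wp = wall.data() + p * 12;
    const int* ip = iall.data() + p * 12;
    double sx = 0.0, sy = 0.0, sz = 0.0;
    for (int kz = 0; kz < 4; ++kz) {
      if (wp[8 + kz] == 0.0 || ip[8 + kz] < 0) continue;
      const R_xlen_t offz = nx * ((R_xlen_t)ny * ip[8 + kz]);
      for (int ky = 0; ky < 4; ++ky) {
        const double wyz = wp[8 + kz] * wp[4 + ky];
        if (wyz == 0.0 || ip[4 + ky] < 0) continue;
        const R_xlen_t offyz = offz + (R_xlen_t)nx * ip[4 + ky];
        for (int kx = 0; kx < 4; ++kx) {
          const double w = wyz * wp[kx];
          if (w == 0.0 || ip[kx] < 0) continue;
          const int fi = fidx[offyz + ip[kx]];
          if (fi >= 0) { sx += w * ux[fi]; sy += w * uy[fi]; sz += w * uz[fi]; }
        }
      }
    }
    U(p, 0) = sx; U(p, 1) = sy; U(p, 2) = sz;
  }
  double dmax = 0.0;
  for (int k = 0; k < 3; ++k) {
    for (int i = 0; i < n; ++i) {
      const double m = beta[i] * mom(i, k) + U(i, k) * gamma[i] * dx;
      mom(i, k) = m;
      V(i, k) += m;
      const double am = std::fabs(m);
      if (am > dmax) dmax = am;
    }
  }
  return List::create(_["energy"] = mres["energy"],
                      _["n_degenerate"] = mres["n_degenerate"],
                      _["dmax"] = dmax);
}
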