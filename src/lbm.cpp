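// Central-moment lattice Boltzmann kernels (D2Q9 / D3Q27).
//
// Velocity ordering (fixed, documented in ?build_stencil):
//   q = (a+1)*3 + (b+1)            for D2Q9,  c_q = (a, b)
//   q = (a+1)*9 + (b+1)*3 + (c+1)  for D3Q27, c_q = (a, b, c)
// with a, b, c in {-1, 0, 1}.  The opposite direction is Q-1-q.
//
// Central moments are handled internally on the monomial basis
//   kappa[m*3+n] (2D) / kappa[m*9+n*3+p] (3D), exponents in {0,1,2},
// and relaxed group-wise on the combined basis named in
// ?relaxation_frequencies (trace / deviatoric second moments combined).
//
// Equilibrium central moments and the central moments of the Guo forcing
// term are closed forms of (rho, u, F); they were derived symbolically
// from the third-order truncated equilibrium and are hard-coded below.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double CS2 = 1.0 / 3.0;

// ---------------------------------------------------------------------------
// small helpers

static inline double magic_omega(double tau) {
  double s = 1.0 / tau;
  return 8.0 * (2.0 - s) / (8.0 - s);
}

static void check_tau(double tau) {
  if (!(tau > 0.5))
    stop("tau must exceed 0.5 (kinematic viscosity cs2*(tau - 1/2) would not be positive)");
}

// equilibrium populations, Eq. third-order truncated form
static void feq_populations(int dim, double rho, const double* u, double* f) {
  int Q = (dim == 2) ? 9 : 27;
  double u2 = 0.0;
  for (int d = 0; d < dim; ++d) u2 += u[d] * u[d];
  for (int q = 0; q < Q; ++q) {
    int c[3] = {0, 0, 0};
    if (dim == 2) { c[0] = q / 3 - 1; c[1] = q % 3 - 1; }
    else          { c[0] = q / 9 - 1; c[1] = (q / 3) % 3 - 1; c[2] = q % 3 - 1; }
    double w = 1.0;
    for (int d = 0; d < dim; ++d) w *= (c[d] == 0) ? (2.0 / 3.0) : (1.0 / 6.0);
    double cu = 0.0;
    for (int d = 0; d < dim; ++d) cu += c[d] * u[d];
    f[q] = w * rho * (1.0 + cu / CS2 + cu * cu / (2.0 * CS2 * CS2) - u2 / (2.0 * CS2)
                      + cu * cu * cu / (6.0 * CS2 * CS2 * CS2)
                      - cu * u2 / (2.0 * CS2 * CS2));
  }
}

// ---------------------------------------------------------------------------
// factorised central-moment transforms (tensor-product D1Q3 stencil)

// forward 2D: f[9] -> kappa[9] (kappa[m*3+n])
static inline void cm_forward2(const double* f, double ux, double uy, double* k) {
  double xa[3] = {-1.0 - ux, -ux, 1.0 - ux};
  double ya[3] = {-1.0 - uy, -uy, 1.0 - uy};
  double g0[3], g1[3], g2[3];
  for (int b = 0; b < 3; ++b) {
    double f0 = f[b], f1 = f[3 + b], f2 = f[6 + b];
    g0[b] = f0 + f1 + f2;
    g1[b] = xa[0] * f0 + xa[1] * f1 + xa[2] * f2;
    g2[b] = xa[0] * xa[0] * f0 + xa[1] * xa[1] * f1 + xa[2] * xa[2] * f2;
  }
  const double* g[3] = {g0, g1, g2};
  for (int m = 0; m < 3; ++m) {
    const double* gm = g[m];
    k[m * 3 + 0] = gm[0] + gm[1] + gm[2];
    k[m * 3 + 1] = ya[0] * gm[0] + ya[1] * gm[1] + ya[2] * gm[2];
    k[m * 3 + 2] = ya[0] * ya[0] * gm[0] + ya[1] * ya[1] * gm[1] + ya[2] * ya[2] * gm[2];
  }
}

// inverse of the 1D Vandermonde stage at shift u: rows a = -1, 0, +1
static inline void inv_rows(double u, double r[3][3]) {
  double xm = -1.0 - u, x0 = -u, xp = 1.0 - u;
  r[0][0] = 0.5 * x0 * xp;  r[0][1] = -0.5 * (x0 + xp); r[0][2] = 0.5;
  r[1][0] = -xm * xp;       r[1][1] = xm + xp;          r[1][2] = -1.0;
  r[2][0] = 0.5 * xm * x0;  r[2][1] = -0.5 * (xm + x0); r[2][2] = 0.5;
}

static inline void cm_backward2(const double* k, double ux, double uy, double* f) {
  double rx[3][3], ry[3][3];
  inv_rows(ux, rx); inv_rows(uy, ry);
  // contract n -> b
  double h[3][3]; // [m][b]
  for (int m = 0; m < 3; ++m)
    for (int b = 0; b < 3; ++b)
      h[m][b] = ry[b][0] * k[m * 3] + ry[b][1] * k[m * 3 + 1] + ry[b][2] * k[m * 3 + 2];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      f[a * 3 + b] = rx[a][0] * h[0][b] + rx[a][1] * h[1][b] + rx[a][2] * h[2][b];
}

// forward 3D: f[27] -> kappa[27] (kappa[m*9+n*3+p])
static inline void cm_forward3(const double* f, double ux, double uy, double uz, double* k) {
  double xa[3] = {-1.0 - ux, -ux, 1.0 - ux};
  double ya[3] = {-1.0 - uy, -uy, 1.0 - uy};
  double za[3] = {-1.0 - uz, -uz, 1.0 - uz};
  double xs[3] = {xa[0] * xa[0], xa[1] * xa[1], xa[2] * xa[2]};
  double ys[3] = {ya[0] * ya[0], ya[1] * ya[1], ya[2] * ya[2]};
  double zs[3] = {za[0] * za[0], za[1] * za[1], za[2] * za[2]};
  double g[3][9]; // [m][b*3+c]
  for (int bc = 0; bc < 9; ++bc) {
    double f0 = f[bc], f1 = f[9 + bc], f2 = f[18 + bc];
    g[0][bc] = f0 + f1 + f2;
    g[1][bc] = xa[0] * f0 + xa[1] * f1 + xa[2] * f2;
    g[2][bc] = xs[0] * f0 + xs[1] * f1 + xs[2] * f2;
  }
  double h[3][3][3]; // [m][n][c]
  for (int m = 0; m < 3; ++m)
    for (int c = 0; c < 3; ++c) {
      double f0 = g[m][c], f1 = g[m][3 + c], f2 = g[m][6 + c];
      h[m][0][c] = f0 + f1 + f2;
      h[m][1][c] = ya[0] * f0 + ya[1] * f1 + ya[2] * f2;
      h[m][2][c] = ys[0] * f0 + ys[1] * f1 + ys[2] * f2;
    }
  for (int m = 0; m < 3; ++m)
    for (int n = 0; n < 3; ++n) {
      double f0 = h[m][n][0], f1 = h[m][n][1], f2 = h[m][n][2];
      k[m * 9 + n * 3 + 0] = f0 + f1 + f2;
      k[m * 9 + n * 3 + 1] = za[0] * f0 + za[1] * f1 + za[2] * f2;
      k[m * 9 + n * 3 + 2] = zs[0] * f0 + zs[1] * f1 + zs[2] * f2;
    }
}

static inline void cm_backward3(const double* k, double ux, double uy, double uz, double* f) {
  double rx[3][3], ry[3][3], rz[3][3];
  inv_rows(ux, rx); inv_rows(uy, ry); inv_rows(uz, rz);
  double g[3][3][3]; // [m][n][c]
  for (int m = 0; m < 3; ++m)
    for (int n = 0; n < 3; ++n) {
      const double* kk = k + m * 9 + n * 3;
      for (int c = 0; c < 3; ++c)
        g[m][n][c] = rz[c][0] * kk[0] + rz[c][1] * kk[1] + rz[c][2] * kk[2];
    }
  double h[3][3][3]; // [m][b][c]
  for (int m = 0; m < 3; ++m)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c)
        h[m][b][c] = ry[b][0] * g[m][0][c] + ry[b][1] * g[m][1][c] + ry[b][2] * g[m][2][c];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c)
        f[a * 9 + b * 3 + c] = rx[a][0] * h[0][b][c] + rx[a][1] * h[1][b][c] + rx[a][2] * h[2][b][c];
}

// ---------------------------------------------------------------------------
// equilibrium central moments (closed forms, monomial basis)

static void keq2(double rho, double ux, double uy, double* e) {
  for (int i = 0; i < 9; ++i) e[i] = 0.0;
  e[0] = rho;                       // k00
  e[2] = rho * CS2;                 // k02
  e[6] = rho * CS2;                 // k20
  e[8] = rho * (1.0 / 9.0 - ux * ux * uy * uy); // k22
}

static void keq3(double rho, double ux, double uy, double uz, double* e) {
  double x2 = ux * ux, y2 = uy * uy, z2 = uz * uz;
  for (int i = 0; i < 27; ++i) e[i] = 0.0;
  e[0]  = rho;             // 000
  e[2]  = rho * CS2;       // 002
  e[6]  = rho * CS2;       // 020
  e[18] = rho * CS2;       // 200
  e[8]  = rho * (1.0 / 9.0 - y2 * z2);          // 022
  e[20] = rho * (1.0 / 9.0 - x2 * z2);          // 202
  e[24] = rho * (1.0 / 9.0 - x2 * y2);          // 220
  e[14] = -rho * ux * uy * z2;                  // 112
  e[16] = -rho * ux * y2 * uz;                  // 121
  e[22] = -rho * x2 * uy * uz;                  // 211
  e[17] = 4.0 * rho * ux * y2 * z2;             // 122
  e[23] = 4.0 * rho * x2 * uy * z2;             // 212
  e[25] = 4.0 * rho * x2 * y2 * uz;             // 221
  e[26] = rho * (1.0 - 9.0 * x2 * y2 - 9.0 * x2 * z2 - 9.0 * y2 * z2
                 - 270.0 * x2 * y2 * z2) / 27.0; // 222
}

// central moments of the Guo forcing term (closed forms, monomial basis)

static void fcm2(double ux, double uy, double Fx, double Fy, double* C) {
  for (int i = 0; i < 9; ++i) C[i] = 0.0;
  C[3] = Fx;  // 10
  C[1] = Fy;  // 01
  C[5] = Fx / 3.0 - Fx * uy * uy - 2.0 * Fy * ux * uy;   // 12
  C[7] = Fy / 3.0 - Fy * ux * ux - 2.0 * Fx * ux * uy;   // 21
  C[8] = 4.0 * ux * uy * (Fx * uy + Fy * ux);            // 22
}

static void fcm3(double ux, double uy, double uz, double Fx, double Fy, double Fz, double* C) {
  double x2 = ux * ux, y2 = uy * uy, z2 = uz * uz;
  for (int i = 0; i < 27; ++i) C[i] = 0.0;
  C[9] = Fx; C[3] = Fy; C[1] = Fz;                       // 100, 010, 001
  C[21] = Fy / 3.0 - Fy * x2 - 2.0 * Fx * ux * uy;       // 210
  C[19] = Fz / 3.0 - Fz * x2 - 2.0 * Fx * ux * uz;       // 201
  C[15] = Fx / 3.0 - Fx * y2 - 2.0 * Fy * ux * uy;       // 120
  C[7]  = Fz / 3.0 - Fz * y2 - 2.0 * Fy * uy * uz;       // 021
  C[11] = Fx / 3.0 - Fx * z2 - 2.0 * Fz * ux * uz;       // 102
  C[5]  = Fy / 3.0 - Fy * z2 - 2.0 * Fz * uy * uz;       // 012
  C[13] = -(Fx * uy * uz + Fy * ux * uz + Fz * ux * uy); // 111
  C[24] = 4.0 * ux * uy * (Fx * uy + Fy * ux);           // 220
  C[20] = 4.0 * ux * uz * (Fx * uz + Fz * ux);           // 202
  C[8]  = 4.0 * uy * uz * (Fy * uz + Fz * uy);           // 022
  C[22] = 2.0 * ux * (2.0 * Fx * uy * uz + Fy * ux * uz + Fz * ux * uy); // 211
  C[16] = 2.0 * uy * (Fx * uy * uz + 2.0 * Fy * ux * uz + Fz * ux * uy); // 121
  C[14] = 2.0 * uz * (Fx * uy * uz + Fy * ux * uz + 2.0 * Fz * ux * uy); // 112
  C[25] = -6.0 * Fx * ux * y2 * uz - (2.0 / 3.0) * Fx * ux * uz
          - 6.0 * Fy * x2 * uy * uz - (2.0 / 3.0) * Fy * uy * uz
          - 3.0 * Fz * x2 * y2 - Fz * x2 / 3.0 - Fz * y2 / 3.0 + Fz / 9.0;  // 221
  C[23] = -6.0 * Fx * ux * uy * z2 - (2.0 / 3.0) * Fx * ux * uy
          - 3.0 * Fy * x2 * z2 - Fy * x2 / 3.0 - Fy * z2 / 3.0 + Fy / 9.0
          - 6.0 * Fz * x2 * uy * uz - (2.0 / 3.0) * Fz * uy * uz;           // 212
  C[17] = -3.0 * Fx * y2 * z2 - Fx * y2 / 3.0 - Fx * z2 / 3.0 + Fx / 9.0
          - 6.0 * Fy * ux * uy * z2 - (2.0 / 3.0) * Fy * ux * uy
          - 6.0 * Fz * ux * y2 * uz - (2.0 / 3.0) * Fz * ux * uz;           // 122
  C[26] = 8.0 * Fx * ux * y2 * z2 + (4.0 / 3.0) * Fx * ux * y2 + (4.0 / 3.0) * Fx * ux * z2
        + 8.0 * Fy * x2 * uy * z2 + (4.0 / 3.0) * Fy * x2 * uy + (4.0 / 3.0) * Fy * uy * z2
        + 8.0 * Fz * x2 * y2 * uz + (4.0 / 3.0) * Fz * x2 * uz + (4.0 / 3.0) * Fz * y2 * uz; // 222
}

// ---------------------------------------------------------------------------
// single-node collision (relax + Guo forcing), u already half-force corrected

static inline void relax2(double* k, double rho, double ux, double uy,
                          double Fx, double Fy,
                          double wb, double wv, double wm, double w4) {
  double C[9];
  fcm2(ux, uy, Fx, Fy, C);
  // conserved
  k[0] = rho;
  k[3] = 0.5 * Fx;   // k10* : -Fx/2 relaxed to 0, plus (1 - 1/2) Fx
  k[1] = 0.5 * Fy;
  // second order: trace (bulk) and deviator/off-diagonal (shear)
  double s = k[6] + k[2], d = k[6] - k[2];
  s += wb * (2.0 * rho * CS2 - s);
  d *= (1.0 - wv);
  k[6] = 0.5 * (s + d);
  k[2] = 0.5 * (s - d);
  k[4] *= (1.0 - wv);                                    // k11
  // third order (magic set)
  double hm = 1.0 - 0.5 * wm;
  k[7] = (1.0 - wm) * k[7] + hm * C[7];                  // k21
  k[5] = (1.0 - wm) * k[5] + hm * C[5];                  // k12
  // fourth order
  double e22 = rho * (1.0 / 9.0 - ux * ux * uy * uy);
  k[8] = (1.0 - w4) * k[8] + w4 * e22 + (1.0 - 0.5 * w4) * C[8];
}

static inline void relax3(double* k, double rho, double ux, double uy, double uz,
                          double Fx, double Fy, double Fz,
                          double wb, double wv, double wm) {
  double e[27], C[27];
  keq3(rho, ux, uy, uz, e);
  fcm3(ux, uy, uz, Fx, Fy, Fz, C);
  k[0] = rho;
  k[9] = 0.5 * Fx; k[3] = 0.5 * Fy; k[1] = 0.5 * Fz;
  // shear: off-diagonal + two diagonal differences at 1/tau; trace at wb
  double ov = 1.0 - wv;
  k[12] *= ov; k[10] *= ov; k[4] *= ov;                  // 110, 101, 011
  double t = k[18] + k[6] + k[2];
  double d1 = k[18] - k[6], d2 = k[18] - k[2];
  t += wb * (rho - t);
  d1 *= ov; d2 *= ov;
  k[18] = (t + d1 + d2) / 3.0;
  k[6] = k[18] - d1;
  k[2] = k[18] - d2;
  // third order (magic set)
  double om = 1.0 - wm, hm = 1.0 - 0.5 * wm;
  static const int third[7] = {21, 19, 15, 7, 11, 5, 13};
  for (int i = 0; i < 7; ++i) {
    int j = third[i];
    k[j] = om * k[j] + hm * C[j];
  }
  // fourth and higher, all at omega = 1: k* = keq + C/2
  static const int high[10] = {24, 20, 8, 22, 16, 14, 25, 23, 17, 26};
  for (int i = 0; i < 10; ++i) {
    int j = high[i];
    k[j] = e[j] + 0.5 * C[j];
  }
}

// full Guo-forced collision of one node; returns corrected u
static void collide_node(int dim, double* f, const double* F, double tau,
                         double* u_out, double wb2, double w42) {
  int Q = (dim == 2) ? 9 : 27;
  double wv = 1.0 / tau, wm = magic_omega(tau);
  double rho = 0.0, mom[3] = {0.0, 0.0, 0.0};
  for (int q = 0; q < Q; ++q) {
    rho += f[q];
    if (dim == 2) { mom[0] += (q / 3 - 1) * f[q]; mom[1] += (q % 3 - 1) * f[q]; }
    else { mom[0] += (q / 9 - 1) * f[q]; mom[1] += ((q / 3) % 3 - 1) * f[q]; mom[2] += (q % 3 - 1) * f[q]; }
  }
  double u[3] = {0.0, 0.0, 0.0};
  for (int d = 0; d < dim; ++d) u[d] = (mom[d] + 0.5 * F[d]) / rho;
  double k[27];
  if (dim == 2) {
    cm_forward2(f, u[0], u[1], k);
    relax2(k, rho, u[0], u[1], F[0], F[1], wb2, wv, wm, w42);
    cm_backward2(k, u[0], u[1], f);
  } else {
    cm_forward3(f, u[0], u[1], u[2], k);
    relax3(k, rho, u[0], u[1], u[2], F[0], F[1], F[2], 1.0, wv, wm);
    cm_backward3(k, u[0], u[1], u[2], f);
  }
  for (int d = 0; d < dim; ++d) u_out[d] = u[d];
}

// ---------------------------------------------------------------------------
// exported node-level operations

// [[Rcpp::export]]
NumericVector cpp_equilibrium(double rho, NumericVector u, int dim) {
  double uu[3] = {0, 0, 0};
  for (int d = 0; d < dim; ++d) uu[d] = u[d];
  int Q = (dim == 2) ? 9 : 27;
  NumericVector f(Q);
  std::vector<double> buf(Q);
  feq_populations(dim, rho, uu, buf.data());
  for (int q = 0; q < Q; ++q) f[q] = buf[q];
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_to_central(NumericVector f, NumericVector u, int dim) {
  int Q = (dim == 2) ? 9 : 27;
  NumericVector k(Q);
  if (dim == 2) cm_forward2(f.begin(), u[0], u[1], k.begin());
  else cm_forward3(f.begin(), u[0], u[1], u[2], k.begin());
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_from_central(NumericVector k, NumericVector u, int dim) {
  int Q = (dim == 2) ? 9 : 27;
  NumericVector f(Q);
  if (dim == 2) cm_backward2(k.begin(), u[0], u[1], f.begin());
  else cm_backward3(k.begin(), u[0], u[1], u[2], f.begin());
  return f;
}

// generic collision with an arbitrary relaxation vector in the combined
// (documented) moment ordering; no forcing.  Used by the R-level collide().
// [[Rcpp::export]]
NumericVector cpp_collide_cm(NumericVector f, NumericVector u, NumericVector omega, int dim) {
  int Q = (dim == 2) ? 9 : 27;
  double rho = 0.0;
  for (int q = 0; q < Q; ++q) rho += f[q];
  double k[27], e[27];
  NumericVector out(Q);
  if (dim == 2) {
    cm_forward2(f.begin(), u[0], u[1], k);
    keq2(rho, u[0], u[1], e);
    // combined ordering: k00,k10,k01, k20+k02, k20-k02, k11, k21, k12, k22
    double s = k[6] + k[2], d = k[6] - k[2];
    double se = e[6] + e[2], de = e[6] - e[2];
    k[0] += omega[0] * (e[0] - k[0]);
    k[3] += omega[1] * (e[3] - k[3]);
    k[1] += omega[2] * (e[1] - k[1]);
    s += omega[3] * (se - s);
    d += omega[4] * (de - d);
    k[4] += omega[5] * (e[4] - k[4]);
    k[7] += omega[6] * (e[7] - k[7]);
    k[5] += omega[7] * (e[5] - k[5]);
    k[8] += omega[8] * (e[8] - k[8]);
    k[6] = 0.5 * (s + d); k[2] = 0.5 * (s - d);
    cm_backward2(k, u[0], u[1], out.begin());
  } else {
    cm_forward3(f.begin(), u[0], u[1], u[2], k);
    keq3(rho, u[0], u[1], u[2], e);
    double t = k[18] + k[6] + k[2], d1 = k[18] - k[6], d2 = k[18] - k[2];
    double te = e[18] + e[6] + e[2], d1e = e[18] - e[6], d2e = e[18] - e[2];
    static const int mono[27] = {0, 9, 3, 1, 12, 10, 4, -1, -2, -3,
                                 21, 19, 15, 7, 11, 5, 13,
                                 24, 20, 8, 22, 16, 14, 25, 23, 17, 26};
    for (int i = 0; i < 27; ++i) {
      int j = mono[i];
      if (j >= 0) k[j] += omega[i] * (e[j] - k[j]);
      else if (j == -1) d1 += omega[i] * (d1e - d1);
      else if (j == -2) d2 += omega[i] * (d2e - d2);
      else t += omega[i] * (te - t);
    }
    k[18] = (t + d1 + d2) / 3.0;
    k[6] = k[18] - d1;
    k[2] = k[18] - d2;
    cm_backward3(k, u[0], u[1], u[2], out.begin());
  }
  return out;
}

// central moments of the Guo forcing term, monomial ordering
// [[Rcpp::export]]
NumericVector cpp_force_cm(NumericVector u, NumericVector F, int dim) {
  int Q = (dim == 2) ? 9 : 27;
  NumericVector C(Q);
  if (dim == 2) fcm2(u[0], u[1], F[0], F[1], C.begin());
  else fcm3(u[0], u[1], u[2], F[0], F[1], F[2], C.begin());
  return C;
}

// full forced collision of one node (engine path), for parity tests
// [[Rcpp::export]]
List cpp_collide_node(NumericVector f, double tau, NumericVector F, int dim) {
  check_tau(tau);
  int Q = (dim == 2) ? 9 : 27;
  NumericVector out(Q);
  double FF[3] = {0, 0, 0};
  for (int d = 0; d < dim; ++d) FF[d] = F[d];
  std::vector<double> buf(f.begin(), f.end());
  double u[3];
  collide_node(dim, buf.data(), FF, tau, u, 1.6, 1.8);
  for (int q = 0; q < Q; ++q) out[q] = buf[q];
  NumericVector uu(dim);
  for (int d = 0; d < dim; ++d) uu[d] = u[d];
  return List::create(_["f"] = out, _["u"] = uu);
}

// ---------------------------------------------------------------------------
// the solver engine: collide -> stream with half-way bounce-back, periodic
// wrap on all faces (walls are encoded as solid layers in the mask)

// [[Rcpp::export]]
List cpp_run_lbm(LogicalVector solid, IntegerVector dims, double tau,
                 NumericVector force, double eps, int check_every,
                 int max_iter, double mach_guard, bool return_field) {
  check_tau(tau);
  const int dim = dims.size();
  const int Q = (dim == 2) ? 9 : 27;
  const int nx = dims[0], ny = dims[1], nz = (dim == 3) ? dims[2] : 1;
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;

  // fluid node list and grid -> fluid index map
  std::vector<int> fmap(ncell, -1);
  std::vector<int> fx, fy, fz;
  int nf = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t g = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!solid[g]) {
          fmap[g] = nf++;
          fx.push_back(x); fy.push_back(y); fz.push_back(z);
        }
      }
  if (nf == 0) stop("geometry has no fluid nodes");

  // pull-scheme neighbour list: nb >= 0 -> pull fpost[nb][q],
  // nb < 0 -> half-way bounce-back: pull own fpost[., Q-1-q]
  std::vector<int32_t> nb((size_t)nf * Q);
  for (int k = 0; k < nf; ++k) {
    for (int q = 0; q < Q; ++q) {
      int a, b, c = 0;
      if (dim == 2) { a = q / 3 - 1; b = q % 3 - 1; }
      else { a = q / 9 - 1; b = (q / 3) % 3 - 1; c = q % 3 - 1; }
      int sx = (fx[k] - a + nx) % nx;
      int sy = (fy[k] - b + ny) % ny;
      int sz = (fz[k] - c + nz) % nz;
      R_xlen_t g = sx + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz);
      nb[(size_t)k * Q + q] = fmap[g];
    }
  }

  std::vector<double> f((size_t)nf * Q), fpost((size_t)nf * Q);
  {
    double u0[3] = {0, 0, 0};
    std::vector<double> feq(Q);
    feq_populations(dim, 1.0, u0, feq.data());
    for (int k = 0; k < nf; ++k)
      for (int q = 0; q < Q; ++q) f[(size_t)k * Q + q] = feq[q];
  }

  double FF[3] = {0, 0, 0};
  for (int d = 0; d < dim; ++d) FF[d] = force[d];

  std::vector<double> u((size_t)nf * dim, 0.0), uprev((size_t)nf * dim, 0.0);
  std::vector<double> hist_iter, hist_el2, hist_umean;
  bool converged = false, diverged = false;
  int iter = 0;
  double last_el2 = NA_REAL;

  while (iter < max_iter) {
    ++iter;
    // collide
    for (int k = 0; k < nf; ++k) {
      double* fk = &f[(size_t)k * Q];
      double uk[3];
      collide_node(dim, fk, FF, tau, uk, 1.6, 1.8);
      for (int d = 0; d < dim; ++d) u[(size_t)k * dim + d] = uk[d];
      double* pk = &fpost[(size_t)k * Q];
      for (int q = 0; q < Q; ++q) pk[q] = fk[q];
    }
    // stream (pull) with bounce-back
    for (int k = 0; k < nf; ++k) {
      double* fk = &f[(size_t)k * Q];
      const int32_t* nbk = &nb[(size_t)k * Q];
      const double* own = &fpost[(size_t)k * Q];
      for (int q = 0; q < Q; ++q) {
        int s = nbk[q];
        fk[q] = (s >= 0) ? fpost[(size_t)s * Q + q] : own[Q - 1 - q];
      }
    }
    if (iter % check_every == 0) {
      double num = 0.0, den = 0.0, umean = 0.0;
      bool bad = false;
      for (int k = 0; k < nf; ++k) {
        double mag2 = 0.0;
        for (int d = 0; d < dim; ++d) {
          double uu = u[(size_t)k * dim + d];
          double dd = uu - uprev[(size_t)k * dim + d];
          num += dd * dd; den += uu * uu; mag2 += uu * uu;
          if (!std::isfinite(uu)) bad = true;
        }
        if (mag2 > mach_guard * mach_guard) bad = true;
        umean += u[(size_t)k * dim + 0];
      }
      umean /= nf;
      double el2 = (den > 0.0) ? std::sqrt(num / den) / check_every : 0.0;
      last_el2 = el2;
      hist_iter.push_back(iter);
      hist_el2.push_back(el2);
      hist_umean.push_back(umean);
      if (bad) { diverged = true; break; }
      if (el2 < eps) { converged = true; break; }
      std::copy(u.begin(), u.end(), uprev.begin());
      Rcpp::checkUserInterrupt();
    }
  }

  // scatter macroscopic fields to full grid
  IntegerVector odim(dims.begin(), dims.end());
  NumericVector rho_out(ncell);
  List uarr(dim);
  std::vector<NumericVector> uvecs;
  for (int d = 0; d < dim; ++d) uvecs.push_back(NumericVector(ncell));
  double rho_mean = 0.0;
  for (int k = 0; k < nf; ++k) {
    R_xlen_t g = fx[k] + (R_xlen_t)nx * (fy[k] + (R_xlen_t)ny * fz[k]);
    double* fk = &f[(size_t)k * Q];
    double rk = 0.0, mom[3] = {0, 0, 0};
    for (int q = 0; q < Q; ++q) {
      rk += fk[q];
      if (dim == 2) { mom[0] += (q / 3 - 1) * fk[q]; mom[1] += (q % 3 - 1) * fk[q]; }
      else { mom[0] += (q / 9 - 1) * fk[q]; mom[1] += ((q / 3) % 3 - 1) * fk[q]; mom[2] += (q % 3 - 1) * fk[q]; }
    }
    rho_out[g] = rk;
    rho_mean += rk;
    for (int d = 0; d < dim; ++d) uvecs[d][g] = (mom[d] + 0.5 * FF[d]) / rk;
  }
  rho_mean /= nf;
  for (int d = 0; d < dim; ++d) { uvecs[d].attr("dim") = odim; uarr[d] = uvecs[d]; }
  rho_out.attr("dim") = odim;

  List out = List::create(
    _["u"] = uarr, _["rho"] = rho_out, _["iterations"] = iter,
    _["converged"] = converged, _["diverged"] = diverged,
    _["el2"] = last_el2, _["rho_mean"] = rho_mean, _["n_fluid"] = nf,
    _["history"] = List::create(_["iteration"] = hist_iter, _["el2"] = hist_el2,
                                _["mean_ux"] = hist_umean));
  if (return_field) {
    NumericMatrix fout(nf, Q);
    IntegerMatrix coords(nf, dim);
    for (int k = 0; k < nf; ++k) {
      for (int q = 0; q < Q; ++q) fout(k, q) = f[(size_t)k * Q + q];
      coords(k, 0) = fx[k] + 1; coords(k, 1) = fy[k] + 1;
      if (dim == 3) coords(k, 2) = fz[k] + 1;
    }
    out["f"] = fout;
    out["coords"] = coords;
  }
  return out;
}

// ---------------------------------------------------------------------------
// FCC unit-cell voxeliser (close-packed spheres, node-centre-in-solid rule)

// [[Rcpp::export]]
LogicalVector cpp_make_fcc(int L) {
  const double r = std::sqrt(2.0) / 4.0;   // sphere radius in cell units
  const double r2 = r * r;
  // sphere centres modulo the periodic cell
  const double cx[4] = {0.0, 0.5, 0.5, 0.0};
  const double cy[4] = {0.0, 0.5, 0.0, 0.5};
  const double cz[4] = {0.0, 0.0, 0.5, 0.5};
  LogicalVector out((R_xlen_t)L * L * L);
  R_xlen_t idx = 0;
  for (int z = 0; z < L; ++z) {
    double pz = (z + 0.5) / L;
    for (int y = 0; y < L; ++y) {
      double py = (y + 0.5) / L;
      for (int x = 0; x < L; ++x, ++idx) {
        double px = (x + 0.5) / L;
        bool in = false;
        for (int s = 0; s < 4 && !in; ++s) {
          double dx = std::fabs(px - cx[s]); if (dx > 0.5) dx = 1.0 - dx;
          double dy = std::fabs(py - cy[s]); if (dy > 0.5) dy = 1.0 - dy;
          double dz = std::fabs(pz - cz[s]); if (dz > 0.5) dz = 1.0 - dz;
          if (dx * dx + dy * dy + dz * dz <= r2) in = true;
        }
        out[idx] = in;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(L, L, L);
  return out;
}
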