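#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Implicit (backward Euler) time stepping for the nondimensional system
//   u_t = (s u_x)_x + u(1-u),   s_t = r1 u - r2 s
// on a uniform node-centred grid with no-flux at x=0 and u=0 at x=X.
// The degenerate flux coefficient s and the logistic factor (1-u) are frozen
// at the previous Picard iterate, giving a tridiagonal system per iterate;
// s is updated implicitly (pointwise linear ODE) inside the same loop.
//
// Returns snapshots every store_every steps (plus the initial state).

static void thomas_solve(std::vector<double> &a, std::vector<double> &b,
                         std::vector<double> &c, std::vector<double> &d,
                         std::vector<double> &x, int n) {
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

// [[Rcpp::export(name = ".solve1d_core")]]
List solve1d_core(NumericVector u0, NumericVector s0,
                  double dx, double dt, int nsteps,
                  double r1, double r2,
                  double tol, int max_picard, int store_every,
                  int scheme) {
  const int n = u0.size();
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> s(s0.begin(), s0.end());
  std::vector<double> uk(n), sk(n), un(n), sface(n + 1);
  std::vector<double> uprev(u), A(n), B(n), C(n), D(n);

  // nodes beyond the last strictly positive u or s never change (exact
  // zeros are invariant); the solve is restricted to the active window,
  // re-extended a few nodes each step as the front invades
  int i_act = 0;
  for (int i = 0; i < n; ++i)
    if (u[i] > 0.0 || s[i] > 0.0) i_act = i;

  const int nstore = nsteps / store_every + 1;
  NumericMatrix usnap(n, nstore), ssnap(n, nstore);
  NumericVector tsnap(nstore);
  IntegerVector iters(nsteps);
  int isnap = 0;
  for (int i = 0; i < n; ++i) { usnap(i, 0) = u[i]; ssnap(i, 0) = s[i]; }
  tsnap[0] = 0.0;
  ++isnap;

  const double r = dt / (dx * dx);
  bool failed = false;
  int fail_step = -1;
  double fail_res = NA_REAL;

  for (int step = 0; step < nsteps && !failed; ++step) {
    // active window: [0, na); all nodes at/beyond na hold exact zeros.
    // The buffer scales with dt/dx so a front moving several nodes per
    // step is never throttled by the window edge.
    int na = std::min(n, i_act + 8 + (int)std::ceil(10.0 * dt / dx));
    for (int i = 0; i < na; ++i) { uk[i] = u[i]; sk[i] = s[i]; }
    // linear-extrapolation predictor seeds the Picard iteration
    if (step > 0)
      for (int i = 0; i < na; ++i) {
        double g = 2.0 * uk[i] - uprev[i];
        u[i] = (g < 0.0) ? 0.0 : (g > 1.0 ? 1.0 : g);
      }
    double res = R_PosInf;
    int m = 0;
    for (; m < max_picard; ++m) {
      // implicit substrate update driven by current u iterate
      for (int i = 0; i < na; ++i)
        s[i] = (sk[i] + dt * r1 * u[i]) / (1.0 + dt * r2);
      // arithmetic-mean face coefficients; boundary faces unused
      for (int i = 1; i < na; ++i) sface[i] = 0.5 * (s[i - 1] + s[i]);
      sface[0] = 0.0; sface[na] = 0.0;
      // assemble tridiagonal: (I - dt L(s) - dt (1-u_m)) u = u^k
      // left node: no-flux (zero flux across face 0)
      if (scheme == 0) {
        // conservative finite-volume, arithmetic-mean face coefficients
        for (int i = 0; i < na - 1; ++i) {
          double wl = (i == 0) ? 0.0 : r * sface[i];
          double wr = r * sface[i + 1];
          A[i] = -wl;
          C[i] = -wr;
          B[i] = 1.0 + wl + wr - dt * (1.0 - u[i]);
          D[i] = uk[i];
        }
      } else {
        // non-conservative central differences: s u_xx + s_x u_x
        for (int i = 0; i < na - 1; ++i) {
          double sgrad = (i == 0) ? 0.0
                         : 0.25 * (s[i + 1] - s[i - 1]);
          double wl, wr;
          if (i == 0) { wl = 0.0; wr = 2.0 * r * s[i]; }
          else { wl = r * (s[i] - sgrad); wr = r * (s[i] + sgrad); }
          A[i] = -wl;
          C[i] = -wr;
          B[i] = 1.0 + wl + wr - dt * (1.0 - u[i]);
          D[i] = uk[i];
        }
      }
      // last active node: Dirichlet u = 0 (coincides with the x = X
      // boundary condition when the window spans the whole grid)
      A[na - 1] = 0.0; B[na - 1] = 1.0; C[na - 1] = 0.0; D[na - 1] = 0.0;
      thomas_solve(A, B, C, D, un, na);
      res = 0.0;
      for (int i = 0; i < na; ++i) {
        double d = std::fabs(un[i] - u[i]);
        if (d > res) res = d;
        u[i] = un[i];
      }
      if (res < tol) { ++m; break; }
    }
    iters[step] = m;
    if (res >= tol) { failed = true; fail_step = step + 1; fail_res = res; break; }
    for (int i = 0; i < na; ++i) uprev[i] = uk[i];
    // round-off undershoot policy: clip tiny negatives, flag real ones
    double umin = 0.0, smin = 0.0;
    for (int i = 0; i < na; ++i) {
      if (u[i] < umin) umin = u[i];
      if (s[i] < smin) smin = s[i];
      if (u[i] < 0.0 && u[i] > -1e-9) u[i] = 0.0;
      if (s[i] < 0.0 && s[i] > -1e-9) s[i] = 0.0;
    }
    while (i_act < n - 1 && (u[i_act + 1] > 0.0 || s[i_act + 1] > 0.0))
      ++i_act;
    if (umin < -1e-6 || smin < -1e-6) {
      failed = true; fail_step = step + 1; fail_res = std::min(umin, smin);
      break;
    }
    if ((step + 1) % store_every == 0) {
      for (int i = 0; i < n; ++i) { usnap(i, isnap) = u[i]; ssnap(i, isnap) = s[i]; }
      tsnap[isnap] = (step + 1) * dt;
      ++isnap;
    }
  }

  return List::create(_["u"] = usnap, _["s"] = ssnap, _["t"] = tsnap,
                      _["iterations"] = iters, _["failed"] = failed,
                      _["fail_step"] = fail_step, _["fail_residual"] = fail_res);
}

// 2D dimensional solver on the unit-square pore geometry:
//   u_t = D div((s/Ks) grad u) + lam u (1 - u/Ku),  s_t = r1h u - r2h s
// Dirichlet u = Ku on the whole boundary, interior u = s = 0 at t = 0.
// Backward Euler with Picard linearisation; the symmetric inner linear
// solves use damped Jacobi so the discrete square symmetries are preserved.

// [[Rcpp::export(name = ".solve2d_core")]]
List solve2d_core(int nx, double dx, double dt, int nsteps,
                  double D, double lam, double Ku, double Ks,
                  double r1h, double r2h,
                  double tol, int max_picard, IntegerVector store_steps) {
  const int N = nx * nx;
  std::vector<double> u(N, 0.0), s(N, 0.0), uk(N), sk(N), un(N);
  // boundary held at carrying capacity from the first step onward
  auto on_boundary = [&](int i, int j) {
    return i == 0 || j == 0 || i == nx - 1 || j == nx - 1;
  };
  const int nstore = store_steps.size();
  NumericMatrix usnap(N, nstore), ssnap(N, nstore);
  int isnap = 0;
  const double r = D * dt / (dx * dx);
  bool failed = false;
  int fail_step = -1;

  for (int step = 0; step < nsteps && !failed; ++step) {
    for (int q = 0; q < N; ++q) { uk[q] = u[q]; sk[q] = s[q]; }
    // impose boundary data on the iterate
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < nx; ++j)
        if (on_boundary(i, j)) u[i + nx * j] = Ku;
    double res = R_PosInf;
    int m = 0;
    for (; m < max_picard; ++m) {
      for (int q = 0; q < N; ++q)
        s[q] = (sk[q] + dt * r1h * u[q]) / (1.0 + dt * r2h);
      // damped Jacobi on (I - dt L(s) - dt lam (1 - u_m/Ku)) u = u^k
      std::vector<double> v(u);
      double lin_res = R_PosInf;
      for (int sweep = 0; sweep < 500 && lin_res > 0.1 * tol; ++sweep) {
        lin_res = 0.0;
        for (int j = 0; j < nx; ++j) {
          for (int i = 0; i < nx; ++i) {
            int q = i + nx * j;
            if (on_boundary(i, j)) { un[q] = Ku; continue; }
            double se = 0.5 * (s[q] + s[q + 1])   / Ks;
            double sw = 0.5 * (s[q] + s[q - 1])   / Ks;
            double sn = 0.5 * (s[q] + s[q + nx])  / Ks;
            double ss = 0.5 * (s[q] + s[q - nx])  / Ks;
            double diag = 1.0 + r * (se + sw + sn + ss)
                          - dt * lam * (1.0 - u[q] / Ku);
            double off = r * (se * v[q + 1] + sw * v[q - 1]
                              + sn * v[q + nx] + ss * v[q - nx]);
            un[q] = (uk[q] + off) / diag;
            double d = std::fabs(un[q] - v[q]);
            if (d > lin_res) lin_res = d;
          }
        }
        std::swap(v, un);
      }
      res = 0.0;
      for (int q = 0; q < N; ++q) {
        double d = std::fabs(v[q] - u[q]);
        if (d > res) res = d;
        u[q] = v[q];
      }
      if (res < tol) { ++m; break; }
    }
    if (res >= tol) { failed = true; fail_step = step + 1; break; }
    for (int q = 0; q < N; ++q) {
      if (u[q] < 0.0 && u[q] > -1e-9) u[q] = 0.0;
      if (s[q] < 0.0 && s[q] > -1e-9) s[q] = 0.0;
    }
    for (int k = 0; k < nstore; ++k) {
      if (store_steps[k] == step + 1) {
        for (int q = 0; q < N; ++q) { usnap(q, isnap) = u[q]; ssnap(q, isnap) = s[q]; }
        ++isnap;
      }
    }
  }

  return List::create(_["u"] = usnap, _["s"] = ssnap,
                      _["failed"] = failed, _["fail_step"] = fail_step);
}
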