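// Numerical kernels.
//
// Thermal integration works on full-box arrays with the 7-point stencil
// expressed through fixed index offsets (+-1, +-nx, +-nx*ny): face
// conductance arrays gx/gy/gz hold the conductance of the +axis face of
// each cell (zero on inactive or boundary faces), so sweeps are
// sequential, branch-free and vectorisable.  Inactive cells carry zero
// conductances, zero sources and idt = 0, which pins them at their value.
//
// The electric potential solve reuses the same stencil machinery through
// box_pcg: non-tissue cells are pinned, Dirichlet electrode faces enter
// through the diagonal and the right-hand side.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// offset-stencil helpers (padded by one z-plane on each side)

static int stencil_pcg(const int n, const int sx, const int sy, const int sz,
                       const double* gx, const double* gy, const double* gz,
                       const double* adiag, const double* pdiag,
                       const double* b, double* x,
                       double tol, int maxit, struct Pad& work1);

struct Pad {
  int n, P;
  std::vector<double> buf;
  Pad(int n_, int P_) : n(n_), P(P_), buf(n_ + 2 * P_, 0.0) {}
  double* ptr() { return buf.data() + P; }
};

// y = K x: conduction stencil application, y_i = sum_f g_f (x_nb - x_i)
static inline void stencil_apply(const int n, const int sx, const int sy,
                                 const int sz, const double* gx,
                                 const double* gy, const double* gz,
                                 const double* x, double* y) {
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    y[i] = gx[i] * (x[i + sx] - xi) + gx[i - sx] * (x[i - sx] - xi) +
           gy[i] * (x[i + sy] - xi) + gy[i - sy] * (x[i - sy] - xi) +
           gz[i] * (x[i + sz] - xi) + gz[i - sz] * (x[i - sz] - xi);
  }
}

// Forward-Euler steps of C dT/dt = K T + P (Tb - T) + S_base + gate * S_joule.
// idt = dt / C (zero on inactive cells).  gate: one duty value per step.
// [[Rcpp::export]]
NumericVector explicit_steps(IntegerVector dim, NumericVector gx,
                             NumericVector gy, NumericVector gz,
                             NumericVector idt, NumericVector perf,
                             NumericVector s_base, NumericVector s_joule,
                             NumericVector gate, double t_b,
                             NumericVector temp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz, P = nx * ny;
  const int sx = 1, sy = nx, sz = nx * ny;
  const int nsteps = gate.size();
  Pad Tp(n, P), Gx(n, P), Gy(n, P), Gz(n, P), Kp(n, P);
  double* T = Tp.ptr();
  std::copy(temp.begin(), temp.end(), T);
  std::copy(gx.begin(), gx.end(), Gx.ptr());
  std::copy(gy.begin(), gy.end(), Gy.ptr());
  std::copy(gz.begin(), gz.end(), Gz.ptr());
  double* K = Kp.ptr();
  const double* pf = REAL(perf);
  const double* sb = REAL(s_base);
  const double* sj = REAL(s_joule);
  const double* id = REAL(idt);
  for (int k = 0; k < nsteps; ++k) {
    const double gk = gate[k];
    stencil_apply(n, sx, sy, sz, Gx.ptr(), Gy.ptr(), Gz.ptr(), T, K);
    for (int i = 0; i < n; ++i)
      T[i] += id[i] * (K[i] + pf[i] * (t_b - T[i]) + sb[i] + gk * sj[i]);
  }
  NumericVector out(n);
  std::copy(T, T + n, out.begin());
  return out;
}

// Stencil-form PCG exposed to R for the quasi-static potential solve:
// solves (adiag I - K) x = b with Jacobi preconditioner pdiag.
// [[Rcpp::export]]
List box_pcg(IntegerVector dim, NumericVector gx, NumericVector gy,
             NumericVector gz, NumericVector adiag, NumericVector pdiag,
             NumericVector b, NumericVector x0, double tol, int maxit) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz, P = nx * ny;
  Pad Gx(n, P), Gy(n, P), Gz(n, P), Xp(n, P), Wp(n, P);
  std::copy(gx.begin(), gx.end(), Gx.ptr());
  std::copy(gy.begin(), gy.end(), Gy.ptr());
  std::copy(gz.begin(), gz.end(), Gz.ptr());
  double* x = Xp.ptr();
  std::copy(x0.begin(), x0.end(), x);
  int it = stencil_pcg(n, 1, nx, nx * ny, Gx.ptr(), Gy.ptr(), Gz.ptr(),
                       REAL(adiag), REAL(pdiag), REAL(b), x, tol, maxit, Wp);
  // residual check for the caller
  std::vector<double> Ax(n);
  stencil_apply(n, 1, nx, nx * ny, Gx.ptr(), Gy.ptr(), Gz.ptr(), x,
                Ax.data());
  double rn = 0.0, bn = 0.0;
  for (int i = 0; i < n; ++i) {
    const double r = b[i] - (adiag[i] * x[i] - Ax[i]);
    rn += r * r;
    bn += b[i] * b[i];
  }
  NumericVector out(n);
  std::copy(x, x + n, out.begin());
  return List::create(_["x"] = out, _["iterations"] = it,
                      _["relres"] = bn > 0 ? std::sqrt(rn / bn) : 0.0);
}

static inline double arrh(double T, double a_fac, double e_over_r) {
  return a_fac * std::exp(-e_over_r / (T + 273.15));
}

// Burst-phase driver: forward-Euler stepping with trapezoidal Arrhenius
// accumulation, (time, max tumor, max domain) recording at macro-step
// boundaries, and an early return once the temperature has drifted more
// than drift_tol from t_ref (the field solved last) so the caller can
// refresh the electric solution.  gate covers the steps remaining in the
// burst, starting at step step0 of the burst (time step0 * dt).
// rate_prev carries the Arrhenius rate at entry for trapezoid continuity.
// [[Rcpp::export]]
List burst_phase(IntegerVector dim, NumericVector gx, NumericVector gy,
                 NumericVector gz, NumericVector idt, NumericVector perf,
                 NumericVector s_base, NumericVector s_joule,
                 NumericVector gate, double t_b, double dt, int step0,
                 NumericVector temp, NumericVector omega0,
                 NumericVector rate_prev0, double a_fac, double e_over_r,
                 IntegerVector active, IntegerVector tumor_cells,
                 int macro_steps, NumericVector t_ref, double drift_tol) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz, P = nx * ny;
  const int sx = 1, sy = nx, sz = nx * ny;
  const int nsteps = gate.size();
  Pad Tp(n, P), Gx(n, P), Gy(n, P), Gz(n, P), Kp(n, P);
  double* T = Tp.ptr();
  std::copy(temp.begin(), temp.end(), T);
  std::copy(gx.begin(), gx.end(), Gx.ptr());
  std::copy(gy.begin(), gy.end(), Gy.ptr());
  std::copy(gz.begin(), gz.end(), Gz.ptr());
  double* K = Kp.ptr();
  NumericVector omega = clone(omega0);
  NumericVector rate_prev = clone(rate_prev0);
  const double* pf = REAL(perf);
  const double* sb = REAL(s_base);
  const double* sj = REAL(s_joule);
  const double* id = REAL(idt);
  const double* tr = REAL(t_ref);
  std::vector<double> ser_t, ser_tum, ser_dom;
  int done = 0;
  bool diverged = false;
  while (done < nsteps) {
    const int chunk = std::min(macro_steps, nsteps - done);
    for (int k = 0; k < chunk; ++k) {
      const double gk = gate[done + k];
      stencil_apply(n, sx, sy, sz, Gx.ptr(), Gy.ptr(), Gz.ptr(), T, K);
      for (int i = 0; i < n; ++i)
        T[i] += id[i] * (K[i] + pf[i] * (t_b - T[i]) + sb[i] + gk * sj[i]);
    }
    done += chunk;
    const double span = chunk * dt;
    double drift = 0.0, mtum = R_NegInf, mdom = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      const double rnew = arrh(T[i], a_fac, e_over_r);
      omega[i] += 0.5 * span * (rate_prev[i] + rnew);
      rate_prev[i] = rnew;
      drift = std::max(drift, std::abs(T[i] - tr[i]));
      mdom = std::max(mdom, T[i]);
      if (!std::isfinite(T[i]) || T[i] < -273.15) diverged = true;
    }
    for (int j = 0; j < tumor_cells.size(); ++j)
      mtum = std::max(mtum, T[tumor_cells[j] - 1]);
    ser_t.push_back((step0 + done) * dt);
    ser_tum.push_back(mtum);
    ser_dom.push_back(mdom);
    if (diverged) break;
    if (drift > drift_tol && done < nsteps) break;
  }
  NumericVector Tout(n);
  std::copy(T, T + n, Tout.begin());
  return List::create(_["temperature"] = Tout, _["omega"] = omega,
                      _["rate_prev"] = rate_prev,
                      _["steps_done"] = done,
                      _["series_t"] = wrap(ser_t),
                      _["series_max_tumor"] = wrap(ser_tum),
                      _["series_max_domain"] = wrap(ser_dom),
                      _["diverged"] = diverged);
}

// Jacobi-PCG for (adiag I - K) x = b on the padded stencil, K the
// conduction operator applied by stencil_apply (it already carries the
// row-sum term); pdiag = adiag + sum g is the Jacobi preconditioner.
// Inactive cells must have adiag = 1, b = x so they stay fixed.
static int stencil_pcg(const int n, const int sx, const int sy, const int sz,
                       const double* gx, const double* gy, const double* gz,
                       const double* adiag, const double* pdiag,
                       const double* b, double* x,
                       double tol, int maxit, Pad& work1) {
  std::vector<double> r(n), z(n), Ap(n);
  Pad& Pp = work1;  // padded search direction
  double* p = Pp.ptr();
  std::fill(Pp.buf.begin(), Pp.buf.end(), 0.0);
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    for (int i = 0; i < n; ++i) x[i] = 0.0;
    return 0;
  }
  stencil_apply(n, sx, sy, sz, gx, gy, gz, x, Ap.data());
  double rz = 0.0, rnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    double Ax = adiag[i] * x[i] - Ap[i];
    r[i] = b[i] - Ax;
    z[i] = r[i] / pdiag[i];
    p[i] = z[i];
    rz += r[i] * z[i];
    rnorm += r[i] * r[i];
  }
  rnorm = std::sqrt(rnorm);
  int it = 0;
  while (rnorm / bnorm > tol && it < maxit) {
    stencil_apply(n, sx, sy, sz, gx, gy, gz, p, Ap.data());
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) {
      Ap[i] = adiag[i] * p[i] - Ap[i];
      pAp += p[i] * Ap[i];
    }
    if (pAp <= 0.0) break;
    const double alpha = rz / pAp;
    rnorm = 0.0;
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      z[i] = r[i] / pdiag[i];
      rz_new += r[i] * z[i];
      rnorm += r[i] * r[i];
    }
    rnorm = std::sqrt(rnorm);
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    ++it;
  }
  return it;
}

// Backward-Euler cooling with trapezoidal Arrhenius accumulation and a
// recorded (time, max tumor T, max domain T) series.  Per step:
// (C/dt + P + sum g) T_new - K_off T_new = C/dt T_old + P Tb + S_base.
// active: 1 for solved cells (others pinned).  tumor_cells: 1-based box
// indices.  Damage is accumulated on active cells only.
// [[Rcpp::export]]
List cool_phase(IntegerVector dim, NumericVector gx, NumericVector gy,
                NumericVector gz, NumericVector cheat, NumericVector perf,
                NumericVector s_base, IntegerVector active, double t_b,
                double dt, int nsteps, double t_start, NumericVector temp,
                NumericVector omega0, double a_fac, double e_over_r,
                IntegerVector tumor_cells, int record_stride,
                double tol, int maxit) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz, P = nx * ny;
  const int sx = 1, sy = nx, sz = nx * ny;
  NumericVector omega = clone(omega0);
  Pad Gx(n, P), Gy(n, P), Gz(n, P), Xp(n, P), Wp(n, P);
  std::copy(gx.begin(), gx.end(), Gx.ptr());
  std::copy(gy.begin(), gy.end(), Gy.ptr());
  std::copy(gz.begin(), gz.end(), Gz.ptr());
  double* x = Xp.ptr();
  std::copy(temp.begin(), temp.end(), x);

  std::vector<double> adiag(n), pdiag(n), b(n), rate_prev(n);
  const double* gxp = Gx.ptr();
  const double* gyp = Gy.ptr();
  const double* gzp = Gz.ptr();
  for (int i = 0; i < n; ++i) {
    if (active[i]) {
      const double gsum = gxp[i] + gxp[i - sx] + gyp[i] + gyp[i - sy] +
                          gzp[i] + gzp[i - sz];
      adiag[i] = cheat[i] / dt + perf[i];
      pdiag[i] = adiag[i] + gsum;
      rate_prev[i] = arrh(x[i], a_fac, e_over_r);
    } else {
      adiag[i] = 1.0;
      pdiag[i] = 1.0;
      rate_prev[i] = 0.0;
    }
  }

  std::vector<double> ser_t, ser_tum, ser_dom;
  long total_iters = 0;
  for (int k = 0; k < nsteps; ++k) {
    for (int i = 0; i < n; ++i)
      b[i] = active[i] ? cheat[i] / dt * x[i] + perf[i] * t_b + s_base[i]
                       : x[i];
    total_iters += stencil_pcg(n, sx, sy, sz, gxp, gyp, gzp, adiag.data(),
                               pdiag.data(), b.data(), x, tol, maxit, Wp);
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      const double rnew = arrh(x[i], a_fac, e_over_r);
      omega[i] += 0.5 * dt * (rate_prev[i] + rnew);
      rate_prev[i] = rnew;
    }
    if ((k + 1) % record_stride == 0 || k == nsteps - 1) {
      double mt = R_NegInf, md = R_NegInf;
      for (int i = 0; i < n; ++i)
        if (active[i]) md = std::max(md, x[i]);
      for (int j = 0; j < tumor_cells.size(); ++j)
        mt = std::max(mt, x[tumor_cells[j] - 1]);
      ser_t.push_back(t_start + (k + 1) * dt);
      ser_tum.push_back(mt);
      ser_dom.push_back(md);
    }
  }
  NumericVector Tout(n);
  std::copy(x, x + n, Tout.begin());
  return List::create(_["temperature"] = Tout, _["omega"] = omega,
                      _["series_t"] = wrap(ser_t),
                      _["series_max_tumor"] = wrap(ser_tum),
                      _["series_max_domain"] = wrap(ser_dom),
                      _["cg_iterations"] = (double)total_iters);
}
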