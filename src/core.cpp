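// Core numerics: Womersley viscous factor and the two-step Lax-Wendroff
// network solver for the 1D coronary model. All quantities in CGS units.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const double PI_ = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Womersley factor K = 1 - 2 J1(z) / (z J0(z)), z = i^{3/2} w0.
// J1/J0 via modified Lentz continued fraction (small/moderate w0) or the
// Hankel asymptotic ratio (large w0). arg(z) = 3pi/4 keeps z away from the
// real-axis zeros of J0, so the continued fraction is well behaved.
// ---------------------------------------------------------------------------
static cplx bessel_ratio_cf(const cplx& z) {
  // J1(z)/J0(z) = 1/(2/z - 1/(4/z - 1/(6/z - ...)))
  const double tiny = 1e-30;
  cplx f(tiny, 0.0), C = f, D(0.0, 0.0);
  for (int k = 1; k < 400; ++k) {
    cplx b = (2.0 * k) / z;
    cplx a = (k == 1) ? cplx(1.0, 0.0) : cplx(-1.0, 0.0);
    D = b + a * D;
    if (std::abs(D) < tiny) D = tiny;
    C = b + a / C;
    if (std::abs(C) < tiny) C = tiny;
    D = 1.0 / D;
    cplx delta = C * D;
    f *= delta;
    if (std::abs(delta - 1.0) < 1e-16) break;
  }
  return f;
}

static cplx bessel_ratio_asym(const cplx& z) {
  // J1/J0 -> i * S1/S0 for Im(z) >> 1, Hankel expansion coefficients.
  const double a0[] = {1.0, -0.125, 9.0 / 128.0, -75.0 / 1024.0};
  const double a1[] = {1.0, 0.375, -15.0 / 128.0, 105.0 / 1024.0};
  cplx iz = 1.0 / z, mi(0.0, -1.0);
  cplx t = mi * iz;
  cplx S0 = a0[0] + a0[1] * t + a0[2] * t * t + a0[3] * t * t * t;
  cplx S1 = a1[0] + a1[1] * t + a1[2] * t * t + a1[3] * t * t * t;
  return cplx(0.0, 1.0) * S1 / S0;
}

static cplx womersley_K1(double w0) {
  if (w0 < 1e-6) {
    // K -> i w0^2 / 8 (viscous-dominated limit)
    return cplx(0.0, w0 * w0 / 8.0);
  }
  cplx z = w0 * std::polar(1.0, 3.0 * PI_ / 4.0);
  cplx r = (w0 <= 40.0) ? bessel_ratio_cf(z) : bessel_ratio_asym(z);
  cplx F = 2.0 * r / z;
  return 1.0 - F;
}

// [[Rcpp::export]]
ComplexVector cw_womersley_K(NumericVector w0) {
  int n = w0.size();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    if (w0[i] < 0) stop("Womersley number must be non-negative");
    cplx K = womersley_K1(w0[i]);
    out[i].r = K.real();
    out[i].i = K.imag();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Tube law helpers: p = p0 + f (1 - sqrt(A0/A)), c^2 = (f/2rho) sqrt(A0/A).
// ---------------------------------------------------------------------------
struct Wall {
  double A0, f, p0;
};

static inline double pres(double A, const Wall& w) {
  return w.p0 + w.f * (1.0 - std::sqrt(w.A0 / A));
}
static inline double dpdA(double A, const Wall& w) {
  return 0.5 * w.f * std::sqrt(w.A0) / (A * std::sqrt(A));
}
static inline double cspd(double A, const Wall& w, double rho) {
  return std::sqrt(0.5 * w.f / rho * std::sqrt(w.A0 / A));
}
static inline double area_from_p(double p, const Wall& w) {
  double s = 1.0 - (p - w.p0) / w.f;
  if (s <= 0.0) stop("pressure beyond tube-law asymptote at inlet");
  return w.A0 / (s * s);
}

// Network solver ------------------------------------------------------------

struct Vessel {
  int off, n;
  double dx;
};

class Net {
public:
  // geometry per node
  std::vector<double> A0, f, dA0dx, dfdx, p0;
  std::vector<Vessel> ves;
  double rho, nu, delta, dt;

  double pressure(int g, double A) const {
    Wall w = {A0[g], f[g], p0[g]};
    return pres(A, w);
  }
  double cnode(int g, double A) const {
    Wall w = {A0[g], f[g], p0[g]};
    return cspd(A, w, rho);
  }

  static inline double visc_term(double A, double q, double nu, double delta) {
    double r = std::sqrt(A / PI_);
    return -2.0 * PI_ * nu * r * q / (delta * A);
  }

  // Two-step Lax-Wendroff with the momentum equation in the
  // pressure-gradient (non-conservative) form
  //   dq/dt + d(q^2/A)/dx + (A/rho) dp/dx = visc,
  // which is exactly well balanced for hydrostatic states (p = const,
  // q = 0) on tapered, radius-dependent-stiffness vessels. Continuity
  // stays in conservation form. Returns half-step A fluxes in qhalf.
  void step_interior(int v, const std::vector<double>& A,
                     const std::vector<double>& q,
                     std::vector<double>& An, std::vector<double>& qn,
                     std::vector<double>& qhalf) const {
    const Vessel& V = ves[v];
    int o = V.off, n = V.n;
    double dx = V.dx;
    std::vector<double> Ah(n - 1), qh(n - 1), ph(n - 1);
    std::vector<double> F2(n), S2(n), pn(n);
    for (int j = 0; j < n; ++j) {
      int g = o + j;
      if (!(A[g] > 0.0)) stop("negative area in vessel %d node %d", v + 1, j + 1);
      Wall w = {A0[g], f[g], p0[g]};
      pn[j] = pres(A[g], w);
      F2[j] = q[g] * q[g] / A[g];
      S2[j] = visc_term(A[g], q[g], nu, delta);
    }
    for (int j = 0; j < n - 1; ++j) {
      int g = o + j;
      double Abar = 0.5 * (A[g] + A[g + 1]);
      double Am = Abar - 0.5 * dt / dx * (q[g + 1] - q[g]);
      double qm = 0.5 * (q[g] + q[g + 1])
                - 0.5 * dt / dx * (F2[j + 1] - F2[j])
                - 0.5 * dt * Abar / rho * (pn[j + 1] - pn[j]) / dx
                + 0.25 * dt * (S2[j] + S2[j + 1]);
      if (!(Am > 0.0)) stop("negative area (half step) in vessel %d node %d", v + 1, j + 1);
      Ah[j] = Am;
      qh[j] = qm;
      // half-node pressure: average of nodal pressures plus the nonlinear
      // increment of the half state, so p = const, q = 0 stays exact
      Wall wm = {0.5 * (A0[g] + A0[g + 1]), 0.5 * (f[g] + f[g + 1]), p0[g]};
      ph[j] = 0.5 * (pn[j] + pn[j + 1]) + pres(Am, wm) - pres(Abar, wm);
    }
    for (int j = 1; j < n - 1; ++j) {
      double F2l = qh[j - 1] * qh[j - 1] / Ah[j - 1];
      double F2r = qh[j] * qh[j] / Ah[j];
      double Ast = 0.5 * (Ah[j - 1] + Ah[j]);
      double Svl = visc_term(Ah[j - 1], qh[j - 1], nu, delta);
      double Svr = visc_term(Ah[j], qh[j], nu, delta);
      An[o + j] = A[o + j] - dt / dx * (qh[j] - qh[j - 1]);
      qn[o + j] = q[o + j] - dt / dx * (F2r - F2l)
                - dt * Ast / rho * (ph[j] - ph[j - 1]) / dx
                + 0.5 * dt * (Svl + Svr);
      if (!(An[o + j] > 0.0)) stop("negative area in vessel %d node %d", v + 1, j + 1);
    }
    for (int j = 0; j < n - 1; ++j) qhalf[j] = qh[j];
  }
};

// characteristic foot state (linear interpolation from the boundary) with
// the source terms integrated along the characteristic over dt:
//   dW±/dt = Sv/A + Gx ± (u ± c)(-4 dc/dx|A),
// where Gx collects the explicit x-dependence of the tube law (taper and
// stiffness gradients). Omitting these biases tapered-vessel boundaries
// by O(dt * S), which excites a standing odd-even mode.
struct Foot {
  double u, c, W; // W: corrected invariant value carried to the boundary
};

static inline double quad_interp(double y0, double y1, double y2, double xi) {
  // quadratic through nodes at xi = 0, 1, 2
  return y0 + xi * (y1 - y0) + 0.5 * xi * (xi - 1) * (y2 - 2 * y1 + y0);
}

static Foot foot_make(const Net& net, const std::vector<double>& A,
                      const std::vector<double>& q,
                      int g_b, int g_i, int g_i2, double dx, bool forward) {
  double ub = q[g_b] / A[g_b], cb = net.cnode(g_b, A[g_b]);
  double lam = forward ? (ub + cb) : (cb - ub);
  double xi = std::max(0.0, std::min(1.0, lam * net.dt / dx));
  double Af = quad_interp(A[g_b], A[g_i], A[g_i2], xi);
  double qf = quad_interp(q[g_b], q[g_i], q[g_i2], xi);
  if (!(Af > 0.0)) { // fall back to linear if the parabola misbehaves
    Af = (1 - xi) * A[g_b] + xi * A[g_i];
    qf = (1 - xi) * q[g_b] + xi * q[g_i];
  }
  double uf = qf / Af;
  double A0f = (1 - xi) * net.A0[g_b] + xi * net.A0[g_i];
  double ff = (1 - xi) * net.f[g_b] + xi * net.f[g_i];
  Wall w = {A0f, ff, 0.0};
  double cf = cspd(Af, w, net.rho);
  // geometry gradients (stored in the vessel's own x direction)
  double fx = (1 - xi) * net.dfdx[g_b] + xi * net.dfdx[g_i];
  double A0x = (1 - xi) * net.dA0dx[g_b] + xi * net.dA0dx[g_i];
  double sq = std::sqrt(A0f / Af);
  double visc_u = -2.0 * PI_ * net.nu * std::sqrt(Af / PI_) * uf
                  / (net.delta * Af);
  double Gx = -((1.0 - sq) * fx - ff * A0x / (2.0 * std::sqrt(A0f * Af)))
              / net.rho;
  double Ix = -4.0 * cf * (fx / (2.0 * ff) + A0x / (4.0 * A0f));
  Foot ft;
  ft.u = uf; ft.c = cf;
  if (forward) {
    ft.W = (uf - 4.0 * cf) + net.dt * (visc_u + Gx + (uf + cf) * Ix);
  } else {
    ft.W = (uf + 4.0 * cf) + net.dt * (visc_u + Gx - (uf - cf) * Ix);
  }
  return ft;
}

static Foot foot_prox(const Net& net, int v, const std::vector<double>& A,
                      const std::vector<double>& q) {
  const Vessel& V = net.ves[v];
  return foot_make(net, A, q, V.off, V.off + 1,
                   V.off + (V.n > 2 ? 2 : 1), V.dx, false);
}

static Foot foot_dist(const Net& net, int v, const std::vector<double>& A,
                      const std::vector<double>& q) {
  const Vessel& V = net.ves[v];
  return foot_make(net, A, q, V.off + V.n - 1, V.off + V.n - 2,
                   V.off + (V.n > 2 ? V.n - 3 : V.n - 2), V.dx, true);
}

static void solve3(double J[3][3], double R[3], double d[3]) {
  // Gaussian elimination with partial pivoting on a 3x3 system J d = R
  int idx[3] = {0, 1, 2};
  for (int k = 0; k < 3; ++k) {
    int piv = k;
    for (int i = k + 1; i < 3; ++i)
      if (std::fabs(J[idx[i]][k]) > std::fabs(J[idx[piv]][k])) piv = i;
    std::swap(idx[k], idx[piv]);
    double akk = J[idx[k]][k];
    if (std::fabs(akk) < 1e-300) stop("singular junction Jacobian");
    for (int i = k + 1; i < 3; ++i) {
      double m = J[idx[i]][k] / akk;
      for (int jj = k; jj < 3; ++jj) J[idx[i]][jj] -= m * J[idx[k]][jj];
      R[idx[i]] -= m * R[idx[k]];
    }
  }
  for (int k = 2; k >= 0; --k) {
    double s = R[idx[k]];
    for (int jj = k + 1; jj < 3; ++jj) s -= J[idx[k]][jj] * d[jj];
    d[k] = s / J[idx[k]][k];
  }
}

// [[Rcpp::export]]
List cw_run_network(List vessels, NumericVector node_A0, NumericVector node_f,
                    NumericVector node_dA0dx, NumericVector node_dfdx,
                    NumericVector node_p0,
                    double rho, double nu, double delta, double dt,
                    int n_steps, int n_rec,
                    IntegerMatrix junctions,
                    IntegerVector inlet_vessel, int inlet_mode,
                    NumericMatrix inlet_wave,
                    IntegerVector outlet_vessel, NumericMatrix outlet_kernel,
                    NumericMatrix outlet_pf,
                    int max_cycles, double tol, double newton_tol,
                    int newton_maxit) {
  Net net;
  int nv = vessels.size();
  net.ves.resize(nv);
  int N = node_A0.size();
  net.A0.assign(node_A0.begin(), node_A0.end());
  net.f.assign(node_f.begin(), node_f.end());
  net.dA0dx.assign(node_dA0dx.begin(), node_dA0dx.end());
  net.dfdx.assign(node_dfdx.begin(), node_dfdx.end());
  net.p0.assign(node_p0.begin(), node_p0.end());
  net.rho = rho; net.nu = nu; net.delta = delta; net.dt = dt;
  for (int v = 0; v < nv; ++v) {
    List vs = vessels[v];
    net.ves[v].off = as<int>(vs["off"]);
    net.ves[v].n = as<int>(vs["n"]);
    net.ves[v].dx = as<double>(vs["dx"]);
  }
  if (n_steps % n_rec != 0) stop("n_steps must be a multiple of n_rec");
  int stride = n_steps / n_rec;
  double dtk = dt * stride; // kernel sampling interval

  int n_j = junctions.nrow();
  int n_in = inlet_vessel.size();
  int n_out = outlet_vessel.size();
  if (outlet_kernel.nrow() != n_rec) stop("kernel length must equal n_rec");

  std::vector<double> A(N), q(N, 0.0), An(N), qn(N);
  for (int g = 0; g < N; ++g) A[g] = net.A0[g];

  // outlet history ring buffers (per outlet, by kernel bin)
  std::vector<std::vector<double>> qh(n_out, std::vector<double>(n_rec, 0.0));
  std::vector<double> Shist(n_out, 0.0);

  NumericMatrix recA(n_rec, N), recq(n_rec, N), recp(n_rec, N);
  std::vector<double> p_prev(n_rec * N, 0.0);
  NumericVector conv_hist(max_cycles);
  std::vector<double> qhalf_buf(2048);

  double max_junc_res = 0.0, cfl_max = 0.0;
  bool converged = false;
  int cycles_done = 0;
  std::vector<double> vol_in(nv, 0.0), vol_out(nv, 0.0), thru(nv, 0.0);
  std::vector<double> vol_prev(nv, 0.0), vol_delta(nv, 0.0);
  bool first_cycle_padded = true;

  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    std::fill(vol_in.begin(), vol_in.end(), 0.0);
    std::fill(vol_out.begin(), vol_out.end(), 0.0);
    std::fill(thru.begin(), thru.end(), 0.0);
    // stored volume at cycle start (trapezoidal): net change per cycle is
    // the mass-balance measure for the converged period
    for (int v = 0; v < nv; ++v) {
      int o = net.ves[v].off, nn = net.ves[v].n;
      double V = 0.5 * (A[o] + A[o + nn - 1]);
      for (int j2 = 1; j2 < nn - 1; ++j2) V += A[o + j2];
      V *= net.ves[v].dx;
      vol_delta[v] = V - vol_prev[v];
      vol_prev[v] = V;
    }
    for (int n = 0; n < n_steps; ++n) {
      int bin = n / stride;
      bool at_bin = (n % stride == 0);
      if (at_bin) {
        // refresh convolution history term for each outlet
        for (int o = 0; o < n_out; ++o) {
          double s = 0.0;
          for (int k = 1; k < n_rec; ++k) {
            int idx = (bin - k + 2 * n_rec) % n_rec;
            s += outlet_kernel(k, o) * qh[o][idx];
          }
          Shist[o] = s * dtk;
        }
      }
      // interior update (uses state at time level n)
      for (int v = 0; v < nv; ++v) {
        int nn = net.ves[v].n;
        if ((int)qhalf_buf.size() < nn) qhalf_buf.resize(nn);
        net.step_interior(v, A, q, An, qn, qhalf_buf);
      }
      // inlets
      for (int ii = 0; ii < n_in; ++ii) {
        int v = inlet_vessel[ii];
        int g = net.ves[v].off;
        Foot ft = foot_prox(net, v, A, q);
        Wall w = {net.A0[g], net.f[g], net.p0[g]};
        if (inlet_mode == 1) { // prescribed pressure
          double Anew = area_from_p(inlet_wave(n, ii), w);
          double unew = ft.W - 4.0 * cspd(Anew, w, rho);
          An[g] = Anew; qn[g] = Anew * unew;
        } else { // prescribed flow
          double qin = inlet_wave(n, ii);
          double Ax = A[g];
          for (int it = 0; it < newton_maxit; ++it) {
            double c = cspd(Ax, w, rho);
            double u = ft.W - 4.0 * c;
            double gfun = Ax * u - qin;
            double dg = u + c;
            double dA = -gfun / dg;
            if (std::fabs(dA) > 0.2 * Ax) dA = (dA > 0 ? 0.2 : -0.2) * Ax;
            Ax += dA;
            if (std::fabs(dA) < 1e-14 * Ax) break;
          }
          An[g] = Ax; qn[g] = Ax * (ft.W - 4.0 * cspd(Ax, w, rho));
        }
      }
      // junctions: parent distal node + daughters' proximal nodes
      for (int jj = 0; jj < n_j; ++jj) {
        int vp = junctions(jj, 0), v1 = junctions(jj, 1), v2 = junctions(jj, 2);
        int gp = net.ves[vp].off + net.ves[vp].n - 1;
        int g1 = net.ves[v1].off, g2 = net.ves[v2].off;
        Foot fp = foot_dist(net, vp, A, q);
        Foot f1 = foot_prox(net, v1, A, q);
        Foot f2 = foot_prox(net, v2, A, q);
        Wall wp = {net.A0[gp], net.f[gp], net.p0[gp]};
        Wall w1 = {net.A0[g1], net.f[g1], net.p0[g1]};
        Wall w2 = {net.A0[g2], net.f[g2], net.p0[g2]};
        double Ap = A[gp], A1 = A[g1], A2 = A[g2];
        double qs = std::max({1.0, std::fabs(q[gp]), std::fabs(q[g1]) + std::fabs(q[g2])});
        double ps = std::max({wp.f, w1.f, w2.f});
        bool ok = false;
        double res = 0.0;
        for (int it = 0; it < newton_maxit; ++it) {
          double cp = cspd(Ap, wp, rho), c1 = cspd(A1, w1, rho), c2 = cspd(A2, w2, rho);
          double up = fp.W + 4.0 * cp;
          double u1 = f1.W - 4.0 * c1;
          double u2 = f2.W - 4.0 * c2;
          double R[3] = {Ap * up - A1 * u1 - A2 * u2,
                         pres(Ap, wp) - pres(A1, w1),
                         pres(Ap, wp) - pres(A2, w2)};
          res = std::max(std::fabs(R[0]) / qs,
                std::max(std::fabs(R[1]) / ps, std::fabs(R[2]) / ps));
          if (res < newton_tol) { ok = true; break; }
          double J[3][3] = {
            {up - cp, -(u1 + c1), -(u2 + c2)},
            {dpdA(Ap, wp), -dpdA(A1, w1), 0.0},
            {dpdA(Ap, wp), 0.0, -dpdA(A2, w2)}
          };
          double d[3];
          double Rn[3] = {-R[0], -R[1], -R[2]};
          solve3(J, Rn, d);
          double lim = 1.0;
          if (std::fabs(d[0]) > 0.2 * Ap) lim = std::min(lim, 0.2 * Ap / std::fabs(d[0]));
          if (std::fabs(d[1]) > 0.2 * A1) lim = std::min(lim, 0.2 * A1 / std::fabs(d[1]));
          if (std::fabs(d[2]) > 0.2 * A2) lim = std::min(lim, 0.2 * A2 / std::fabs(d[2]));
          Ap += lim * d[0]; A1 += lim * d[1]; A2 += lim * d[2];
        }
        if (!ok) stop("junction Newton failed (residual %e) at junction %d", res, jj + 1);
        if (res > max_junc_res) max_junc_res = res;
        double cp = cspd(Ap, wp, rho), c1 = cspd(A1, w1, rho), c2 = cspd(A2, w2, rho);
        An[gp] = Ap; qn[gp] = Ap * (fp.W + 4.0 * cp);
        An[g1] = A1; qn[g1] = A1 * (f1.W - 4.0 * c1);
        An[g2] = A2; qn[g2] = A2 * (f2.W - 4.0 * c2);
      }
      // terminal outlets: impedance convolution + feedback pressure
      for (int o = 0; o < n_out; ++o) {
        int v = outlet_vessel[o];
        int g = net.ves[v].off + net.ves[v].n - 1;
        Foot ft = foot_dist(net, v, A, q);
        Wall w = {net.A0[g], net.f[g], net.p0[g]};
        double zc = outlet_kernel(0, o) * dtk;
        double rhs = Shist[o] + outlet_pf(n, o);
        double Ax = A[g];
        bool ok = false;
        for (int it = 0; it < newton_maxit; ++it) {
          double c = cspd(Ax, w, rho);
          double u = ft.W + 4.0 * c;
          double gfun = pres(Ax, w) - zc * Ax * u - rhs;
          double dg = dpdA(Ax, w) - zc * (u - c);
          double dA = -gfun / dg;
          if (std::fabs(dA) > 0.2 * Ax) dA = (dA > 0 ? 0.2 : -0.2) * Ax;
          Ax += dA;
          if (std::fabs(dA) < 1e-13 * Ax) { ok = true; break; }
        }
        if (!ok) stop("outlet Newton failed at outlet %d", o + 1);
        An[g] = Ax; qn[g] = Ax * (ft.W + 4.0 * cspd(Ax, w, rho));
        if (at_bin) qh[o][bin] = qn[g];
      }
      A.swap(An); q.swap(qn);
      // diagnostics + recording (state is now at time level n+1; record the
      // bin-start state of the next bin on the next pass)
      for (int v = 0; v < nv; ++v) {
        int o = net.ves[v].off, nn = net.ves[v].n;
        vol_in[v] += q[o] * dt;
        vol_out[v] += q[o + nn - 1] * dt;
        thru[v] += std::fabs(q[o]) * dt;
      }
      if (at_bin) {
        double cfl = 0.0;
        for (int v = 0; v < nv; ++v) {
          int o = net.ves[v].off, nn = net.ves[v].n;
          for (int j2 = 0; j2 < nn; ++j2) {
            double u = q[o + j2] / A[o + j2];
            double c = net.cnode(o + j2, A[o + j2]);
            double r = (std::fabs(u) + c) * dt / net.ves[v].dx;
            if (r > cfl) cfl = r;
          }
        }
        if (cfl > cfl_max) cfl_max = cfl;
        if (cfl > 1.0) stop("CFL violation (%.3f) during cycle %d", cfl, cyc + 1);
        for (int g = 0; g < N; ++g) {
          recA(bin, g) = A[g];
          recq(bin, g) = q[g];
          recp(bin, g) = net.pressure(g, A[g]);
        }
      }
    }
    // convergence: L-inf pressure change between consecutive cycles
    double dmax = 0.0;
    for (int b = 0; b < n_rec; ++b)
      for (int g = 0; g < N; ++g) {
        double d = std::fabs(recp(b, g) - p_prev[b * N + g]);
        if (d > dmax) dmax = d;
        p_prev[b * N + g] = recp(b, g);
      }
    conv_hist[cyc] = dmax;
    cycles_done = cyc + 1;
    if (cyc > 0 && dmax < tol) { converged = true; break; }
  }
  first_cycle_padded = (cycles_done == 1);

  NumericVector mass_net(nv), mass_thru(nv), flux_imb(nv);
  for (int v = 0; v < nv; ++v) {
    mass_net[v] = vol_delta[v];
    flux_imb[v] = vol_in[v] - vol_out[v];
    mass_thru[v] = thru[v];
  }
  return List::create(
    _["A"] = recA, _["q"] = recq, _["p"] = recp,
    _["cycles"] = cycles_done, _["converged"] = converged,
    _["conv_history"] = conv_hist[Range(0, cycles_done - 1)],
    _["max_junction_residual"] = max_junc_res,
    _["cfl_max"] = cfl_max,
    _["mass_net"] = mass_net, _["mass_throughput"] = mass_thru,
    _["flux_imbalance"] = flux_imb,
    _["zero_padded_first_cycle"] = first_cycle_padded);
}

// ---------------------------------------------------------------------------
// Single-vessel driver with Dirichlet boundaries and prescribed forcing,
// used for manufactured-solution convergence studies and scheme unit tests.
// bc: (n_steps+1) x 4 matrix [A_left, q_left, A_right, q_right].
// Forcing matrices are evaluated at full nodes (time level n) and at half
// nodes (time level n+1/2) to preserve second-order accuracy.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cw_run_single(int n, double dx, NumericVector node_A0, NumericVector node_f,
                   NumericVector node_dA0dx, NumericVector node_dfdx,
                   double p0, double rho, double nu, double delta,
                   double dt, int n_steps,
                   NumericVector A_init, NumericVector q_init,
                   NumericMatrix bc,
                   NumericMatrix fA_full, NumericMatrix fq_full,
                   NumericMatrix fA_half, NumericMatrix fq_half) {
  Net net;
  net.rho = rho; net.nu = nu; net.delta = delta; net.dt = dt;
  net.A0.assign(node_A0.begin(), node_A0.end());
  net.f.assign(node_f.begin(), node_f.end());
  net.dA0dx.assign(node_dA0dx.begin(), node_dA0dx.end());
  net.dfdx.assign(node_dfdx.begin(), node_dfdx.end());
  net.p0.assign(n, p0);
  net.ves.resize(1);
  net.ves[0].off = 0; net.ves[0].n = n; net.ves[0].dx = dx;

  std::vector<double> A(A_init.begin(), A_init.end());
  std::vector<double> q(q_init.begin(), q_init.end());
  std::vector<double> An(n), qn(n);
  bool use_force = fA_full.nrow() > 0;

  NumericVector last_qhalf(n - 1);
  for (int s = 0; s < n_steps; ++s) {
    std::vector<double> F2(n), S2(n), pn(n);
    for (int j = 0; j < n; ++j) {
      Wall w = {net.A0[j], net.f[j], p0};
      pn[j] = pres(A[j], w);
      F2[j] = q[j] * q[j] / A[j];
      S2[j] = Net::visc_term(A[j], q[j], nu, delta);
    }
    std::vector<double> Ah(n - 1), qh(n - 1), ph(n - 1);
    for (int j = 0; j < n - 1; ++j) {
      double Abar = 0.5 * (A[j] + A[j + 1]);
      double fa = use_force ? 0.5 * (fA_full(s, j) + fA_full(s, j + 1)) : 0.0;
      double fq = use_force ? 0.5 * (fq_full(s, j) + fq_full(s, j + 1)) : 0.0;
      Ah[j] = Abar - 0.5 * dt / dx * (q[j + 1] - q[j]) + 0.5 * dt * fa;
      qh[j] = 0.5 * (q[j] + q[j + 1]) - 0.5 * dt / dx * (F2[j + 1] - F2[j])
            - 0.5 * dt * Abar / rho * (pn[j + 1] - pn[j]) / dx
            + 0.25 * dt * (S2[j] + S2[j + 1]) + 0.5 * dt * fq;
      if (!(Ah[j] > 0.0)) stop("negative area at half step");
      Wall wm = {0.5 * (net.A0[j] + net.A0[j + 1]),
                 0.5 * (net.f[j] + net.f[j + 1]), p0};
      ph[j] = 0.5 * (pn[j] + pn[j + 1]) + pres(Ah[j], wm) - pres(Abar, wm);
    }
    for (int j = 1; j < n - 1; ++j) {
      double fa = use_force ? 0.5 * (fA_half(s, j - 1) + fA_half(s, j)) : 0.0;
      double fq = use_force ? 0.5 * (fq_half(s, j - 1) + fq_half(s, j)) : 0.0;
      double F2l = qh[j - 1] * qh[j - 1] / Ah[j - 1];
      double F2r = qh[j] * qh[j] / Ah[j];
      double Ast = 0.5 * (Ah[j - 1] + Ah[j]);
      double Svl = Net::visc_term(Ah[j - 1], qh[j - 1], nu, delta);
      double Svr = Net::visc_term(Ah[j], qh[j], nu, delta);
      An[j] = A[j] - dt / dx * (qh[j] - qh[j - 1]) + dt * fa;
      qn[j] = q[j] - dt / dx * (F2r - F2l)
            - dt * Ast / rho * (ph[j] - ph[j - 1]) / dx
            + 0.5 * dt * (Svl + Svr) + dt * fq;
      if (!(An[j] > 0.0)) stop("negative area at node %d", j + 1);
    }
    An[0] = bc(s + 1, 0); qn[0] = bc(s + 1, 1);
    An[n - 1] = bc(s + 1, 2); qn[n - 1] = bc(s + 1, 3);
    if (s == n_steps - 1)
      for (int j = 0; j < n - 1; ++j) last_qhalf[j] = qh[j];
    A.swap(An); q.swap(qn);
  }
  return List::create(_["A"] = NumericVector(A.begin(), A.end()),
                      _["q"] = NumericVector(q.begin(), q.end()),
                      _["qhalf"] = last_qhalf);
}
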