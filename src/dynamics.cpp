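// Constrained Langevin dynamics for the toy branching active site.
//
// Coordinates in Angstrom, time in fs, masses in amu, energies in kcal/mol.
// KCAL_CONV converts (kcal/mol/A)/amu to acceleration in A/fs^2.
//
// The reactive potential V(d1, d2) acts on three core atoms
//   A = nucleophile O2' (d1 = |A - P|),
//   P = scissile phosphorus,
//   B = leaving O3'     (d2 = |B - P|),
// and is parameterised as Gaussian basins in the rotated coordinates
// xi = d2 - d1 (the reaction coordinate) and s = d1 + d2, plus an r^-12
// inner wall and a quadratic outer confinement on each bond length.
// All remaining atoms are spectators held by harmonic site restraints that
// are independent of xi.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KCAL_CONV = 4.184e-4;    // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 0.0019872041;       // kcal/(mol K)
static const double HARD_WALL = 0.5;         // A; below this the PES is invalid

struct PES {
  int nb, ns;
  std::vector<double> depth, xic, sc, wxi, ws;
  // 1D reaction-coordinate shaping term U(xi): uniform-knot cubic Hermite
  double sx0, sh;
  std::vector<double> uval, uder;
  double wall_a, wall_r0, confine_k, confine_d;
};

static PES parse_pes(const List& p) {
  PES q;
  NumericMatrix b = p["basins"];   // columns: depth, xi_c, s_c, w_xi, w_s
  q.nb = b.nrow();
  for (int k = 0; k < q.nb; ++k) {
    q.depth.push_back(b(k, 0));
    q.xic.push_back(b(k, 1));
    q.sc.push_back(b(k, 2));
    q.wxi.push_back(b(k, 3));
    q.ws.push_back(b(k, 4));
  }
  q.ns = 0;
  if (p.containsElementNamed("shape") && !Rf_isNull(p["shape"])) {
    List sp = p["shape"];
    q.sx0 = as<double>(sp["x0"]);
    q.sh = as<double>(sp["h"]);
    NumericVector uv = sp["value"], ud = sp["deriv"];
    q.ns = uv.size();
    for (int k = 0; k < q.ns; ++k) {
      q.uval.push_back(uv[k]);
      q.uder.push_back(ud[k]);
    }
  }
  q.wall_a = as<double>(p["wall_a"]);
  q.wall_r0 = as<double>(p["wall_r0"]);
  q.confine_k = as<double>(p["confine_k"]);
  q.confine_d = as<double>(p["confine_d"]);
  return q;
}

// U(xi) and dU/dxi; clamped with zero slope outside the knot range
static void shape_eval(const PES& q, double xi, double* U, double* dU) {
  *U = 0.0; *dU = 0.0;
  if (q.ns == 0) return;
  double t = (xi - q.sx0) / q.sh;
  if (t <= 0.0) { *U = q.uval[0]; return; }
  if (t >= q.ns - 1) { *U = q.uval[q.ns - 1]; return; }
  int i = (int)t;
  double u = t - i;
  double h00 = (1 + 2 * u) * (1 - u) * (1 - u);
  double h10 = u * (1 - u) * (1 - u);
  double h01 = u * u * (3 - 2 * u);
  double h11 = u * u * (u - 1);
  *U = h00 * q.uval[i] + q.sh * h10 * q.uder[i] +
       h01 * q.uval[i + 1] + q.sh * h11 * q.uder[i + 1];
  double d00 = 6 * u * u - 6 * u;
  double d10 = 3 * u * u - 4 * u + 1;
  double d01 = -6 * u * u + 6 * u;
  double d11 = 3 * u * u - 2 * u;
  *dU = (d00 * q.uval[i] + q.sh * d10 * q.uder[i] +
         d01 * q.uval[i + 1] + q.sh * d11 * q.uder[i + 1]) / q.sh;
}

// V(d1, d2) and its partials. Returns energy; fills dV/dd1, dV/dd2.
static double pes_eval(const PES& q, double d1, double d2,
                       double* dVd1, double* dVd2, bool hard_error = true) {
  if (hard_error && (d1 < HARD_WALL || d2 < HARD_WALL))
    stop("reactive atoms overlap: d1 or d2 below %.2f A", HARD_WALL);
  double xi = d2 - d1, s = d1 + d2;
  double V = 0.0, dVdxi = 0.0, dVds = 0.0;
  for (int k = 0; k < q.nb; ++k) {
    double ax = (xi - q.xic[k]) / q.wxi[k];
    double as_ = (s - q.sc[k]) / q.ws[k];
    double e = q.depth[k] * std::exp(-0.5 * (ax * ax + as_ * as_));
    V += e;
    dVdxi += -e * ax / q.wxi[k];
    dVds += -e * as_ / q.ws[k];
  }
  if (q.ns > 0) {
    double U, dU;
    shape_eval(q, xi, &U, &dU);
    V += U;
    dVdxi += dU;
  }
  double dwall1 = 0.0, dwall2 = 0.0;
  if (q.wall_a > 0.0) {
    double t1 = std::pow(q.wall_r0 / d1, 12.0);
    double t2 = std::pow(q.wall_r0 / d2, 12.0);
    V += q.wall_a * (t1 + t2);
    dwall1 = -12.0 * q.wall_a * t1 / d1;
    dwall2 = -12.0 * q.wall_a * t2 / d2;
  }
  double dcon1 = 0.0, dcon2 = 0.0;
  if (q.confine_k > 0.0) {
    if (d1 > q.confine_d) {
      double e1 = d1 - q.confine_d;
      V += 0.5 * q.confine_k * e1 * e1;
      dcon1 = q.confine_k * e1;
    }
    if (d2 > q.confine_d) {
      double e2 = d2 - q.confine_d;
      V += 0.5 * q.confine_k * e2 * e2;
      dcon2 = q.confine_k * e2;
    }
  }
  *dVd1 = -dVdxi + dVds + dwall1 + dcon1;
  *dVd2 = dVdxi + dVds + dwall2 + dcon2;
  return V;
}

// [[Rcpp::export]]
NumericVector cpp_pes_profile(NumericVector d1, double xi, List pes) {
  // V along the constraint line d2 = d1 + xi; used by the quadrature oracle.
  PES q = parse_pes(pes);
  int n = d1.size();
  NumericVector out(n);
  double g1, g2;
  for (int i = 0; i < n; ++i)
    out[i] = pes_eval(q, d1[i], d1[i] + xi, &g1, &g2, false);
  return out;
}

// [[Rcpp::export]]
List cpp_energy_force(NumericMatrix pos, NumericVector restraint_k,
                      NumericMatrix restraint_c, IntegerVector core, List pes) {
  // core = 0-based indices (A, P, B). Full-model energy and forces.
  PES q = parse_pes(pes);
  int n = pos.nrow();
  int ia = core[0], ip = core[1], ib = core[2];
  double d1 = 0.0, d2 = 0.0;
  double u[3], w[3];
  for (int k = 0; k < 3; ++k) {
    u[k] = pos(ia, k) - pos(ip, k);
    w[k] = pos(ib, k) - pos(ip, k);
    d1 += u[k] * u[k];
    d2 += w[k] * w[k];
  }
  d1 = std::sqrt(d1); d2 = std::sqrt(d2);
  double g1, g2;
  double V = pes_eval(q, d1, d2, &g1, &g2);
  NumericMatrix f(n, 3);
  for (int k = 0; k < 3; ++k) {
    double uk = u[k] / d1, wk = w[k] / d2;
    f(ia, k) += -g1 * uk;
    f(ib, k) += -g2 * wk;
    f(ip, k) += g1 * uk + g2 * wk;
  }
  for (int i = 0; i < n; ++i) {
    if (restraint_k[i] > 0.0) {
      for (int k = 0; k < 3; ++k) {
        double dx = pos(i, k) - restraint_c(i, k);
        V += 0.5 * restraint_k[i] * dx * dx;
        f(i, k) += -restraint_k[i] * dx;
      }
    }
  }
  return List::create(_["energy"] = V, _["force"] = f,
                      _["d1"] = d1, _["d2"] = d2);
}

// Gradient of sigma = d2 - d1 - xi w.r.t. the three core atoms.
// g is 3x3 (rows A, P, B).
static void sigma_grad(const std::vector<double>& r, int ia, int ip, int ib,
                       double g[3][3], double* d1o, double* d2o) {
  double u[3], w[3], d1 = 0.0, d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    u[k] = r[3 * ia + k] - r[3 * ip + k];
    w[k] = r[3 * ib + k] - r[3 * ip + k];
    d1 += u[k] * u[k];
    d2 += w[k] * w[k];
  }
  d1 = std::sqrt(d1); d2 = std::sqrt(d2);
  for (int k = 0; k < 3; ++k) {
    double uk = u[k] / d1, wk = w[k] / d2;
    g[0][k] = -uk;          // d sigma / d r_A
    g[1][k] = uk - wk;      // d sigma / d r_P
    g[2][k] = wk;           // d sigma / d r_B
  }
  *d1o = d1; *d2o = d2;
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
             NumericVector restraint_k, NumericMatrix restraint_c,
             IntegerVector core, List pes,
             bool constrained, double xi_from, double xi_to,
             int nsteps, double dt, double gamma, double temperature,
             int stride, double tol, int maxiter, bool record_frames) {
  PES q = parse_pes(pes);
  int n = pos0.nrow();
  int ia = core[0], ip = core[1], ib = core[2];
  std::vector<double> r(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      r[3 * i + k] = pos0(i, k);
      v[3 * i + k] = vel0(i, k);
    }

  // forces at current positions
  auto forces = [&](double* pe_out) {
    double u[3], w[3], d1 = 0.0, d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      u[k] = r[3 * ia + k] - r[3 * ip + k];
      w[k] = r[3 * ib + k] - r[3 * ip + k];
      d1 += u[k] * u[k]; d2 += w[k] * w[k];
    }
    d1 = std::sqrt(d1); d2 = std::sqrt(d2);
    double g1, g2;
    double V = pes_eval(q, d1, d2, &g1, &g2);
    std::fill(f.begin(), f.end(), 0.0);
    for (int k = 0; k < 3; ++k) {
      double uk = u[k] / d1, wk = w[k] / d2;
      f[3 * ia + k] += -g1 * uk;
      f[3 * ib + k] += -g2 * wk;
      f[3 * ip + k] += g1 * uk + g2 * wk;
    }
    for (int i = 0; i < n; ++i)
      if (restraint_k[i] > 0.0)
        for (int k = 0; k < 3; ++k) {
          double dx = r[3 * i + k] - restraint_c(i, k);
          V += 0.5 * restraint_k[i] * dx * dx;
          f[3 * i + k] += -restraint_k[i] * dx;
        }
    if (pe_out) *pe_out = V;
  };

  double ou_a = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  double ou_b = (gamma > 0.0) ? std::sqrt(1.0 - ou_a * ou_a) : 0.0;

  int nstore = record_frames ? (nsteps + stride - 1) / stride : 0;
  NumericMatrix frames(nstore, record_frames ? 3 * n : 0);
  NumericVector fr_xi(nstore), fr_ke(nstore), fr_pe(nstore), fr_lambda(nstore);
  IntegerVector fr_step(nstore);
  NumericVector lambda(nsteps);
  double sigma_max = 0.0;

  double pe = 0.0;
  forces(&pe);

  int istore = 0;
  for (int step = 0; step < nsteps; ++step) {
    double xi_t = constrained
      ? xi_from + (xi_to - xi_from) * (double)(step + 1) / (double)nsteps
      : 0.0;

    // half kick
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * KCAL_CONV * f[3 * i + k] / mass[i];

    // drift
    std::vector<double> r_old(r);
    for (int i = 0; i < 3 * n; ++i) r[i] += dt * v[i];

    double lam_rec = 0.0;
    if (constrained) {
      // SHAKE: project positions back to sigma = 0 along grad sigma(r_old)
      double g_old[3][3], d1o, d2o;
      sigma_grad(r_old, ia, ip, ib, g_old, &d1o, &d2o);
      int idx[3] = {ia, ip, ib};
      double m3[3] = {mass[ia], mass[ip], mass[ib]};
      double lam_pos = 0.0;
      int it = 0;
      for (; it < maxiter; ++it) {
        double gc[3][3], d1c, d2c;
        sigma_grad(r, ia, ip, ib, gc, &d1c, &d2c);
        double sig = (d2c - d1c) - xi_t;
        if (std::fabs(sig) < tol) break;
        double denom = 0.0;
        for (int a = 0; a < 3; ++a)
          for (int k = 0; k < 3; ++k)
            denom += (KCAL_CONV * dt * dt / m3[a]) * g_old[a][k] * gc[a][k];
        if (std::fabs(denom) < 1e-14)
          stop("constraint projection singular at step %d", step + 1);
        double dlam = -sig / denom;
        lam_pos += dlam;
        for (int a = 0; a < 3; ++a)
          for (int k = 0; k < 3; ++k)
            r[3 * idx[a] + k] += KCAL_CONV * dt * dt / m3[a] * dlam * g_old[a][k];
      }
      if (it == maxiter)
        stop("SHAKE did not converge in %d iterations at step %d",
             maxiter, step + 1);
      // velocities consistent with the projected positions
      for (int i = 0; i < 3 * n; ++i) v[i] = (r[i] - r_old[i]) / dt;
      lam_rec += lam_pos;
    }

    forces(&pe);

    // half kick
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * KCAL_CONV * f[3 * i + k] / mass[i];

    if (constrained) {
      // RATTLE: remove velocity along grad sigma(r)
      double g[3][3], d1c, d2c;
      sigma_grad(r, ia, ip, ib, g, &d1c, &d2c);
      int idx[3] = {ia, ip, ib};
      double m3[3] = {mass[ia], mass[ip], mass[ib]};
      double num = 0.0, den = 0.0;
      for (int a = 0; a < 3; ++a)
        for (int k = 0; k < 3; ++k) {
          num += g[a][k] * v[3 * idx[a] + k];
          den += KCAL_CONV * g[a][k] * g[a][k] / m3[a];
        }
      double c = -num / den;
      for (int a = 0; a < 3; ++a)
        for (int k = 0; k < 3; ++k)
          v[3 * idx[a] + k] += KCAL_CONV * c * g[a][k] / m3[a];
      lam_rec += c / dt;
    }
    lambda[step] = lam_rec;

    if (gamma > 0.0) {
      // Ornstein-Uhlenbeck velocity refresh, then re-project
      for (int i = 0; i < n; ++i) {
        double vth = std::sqrt(KB * temperature * KCAL_CONV / mass[i]);
        for (int k = 0; k < 3; ++k)
          v[3 * i + k] = ou_a * v[3 * i + k] + ou_b * vth * R::norm_rand();
      }
      if (constrained) {
        double g[3][3], d1c, d2c;
        sigma_grad(r, ia, ip, ib, g, &d1c, &d2c);
        int idx[3] = {ia, ip, ib};
        double m3[3] = {mass[ia], mass[ip], mass[ib]};
        double num = 0.0, den = 0.0;
        for (int a = 0; a < 3; ++a)
          for (int k = 0; k < 3; ++k) {
            num += g[a][k] * v[3 * idx[a] + k];
            den += KCAL_CONV * g[a][k] * g[a][k] / m3[a];
          }
        double c = -num / den;
        for (int a = 0; a < 3; ++a)
          for (int k = 0; k < 3; ++k)
            v[3 * idx[a] + k] += KCAL_CONV * c * g[a][k] / m3[a];
      }
    }

    if (record_frames && ((step + 1) % stride == 0)) {
      double gd[3][3], d1c, d2c;
      sigma_grad(r, ia, ip, ib, gd, &d1c, &d2c);
      double sig = (d2c - d1c) - xi_t;
      if (constrained && std::fabs(sig) > sigma_max) sigma_max = std::fabs(sig);
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          ke += 0.5 * mass[i] * v[3 * i + k] * v[3 * i + k];
      ke /= KCAL_CONV;
      for (int i = 0; i < 3 * n; ++i) frames(istore, i) = r[i];
      fr_xi[istore] = d2c - d1c;
      fr_ke[istore] = ke;
      fr_pe[istore] = pe;
      fr_lambda[istore] = lam_rec;
      fr_step[istore] = step + 1;
      ++istore;
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      pos_out(i, k) = r[3 * i + k];
      vel_out(i, k) = v[3 * i + k];
    }
  return List::create(
    _["pos"] = pos_out, _["vel"] = vel_out, _["lambda"] = lambda,
    _["frames"] = frames, _["frame_xi"] = fr_xi, _["frame_ke"] = fr_ke,
    _["frame_pe"] = fr_pe, _["frame_lambda"] = fr_lambda,
    _["frame_step"] = fr_step, _["sigma_max"] = sigma_max);
}
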