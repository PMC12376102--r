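// Overdamped Langevin dynamics on analytic 2D landscapes, with optional
// well-tempered metadynamics bias.  Coordinates are the two collective
// variables: X (angstrom) and theta (degrees).  Energies in kJ/mol,
// time in ps.  The metadynamics bias is accumulated on a regular grid
// (value plus both analytic partial derivatives) so that a step costs
// O(1) regardless of the number of deposited hills; hills themselves are
// recorded exactly for file output and FES reconstruction.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// component columns: amp, cx, ct, sx, st (sx/st may be +Inf => uniform)
static inline double pot_value(const NumericMatrix &comps, double baseline,
                               double x, double th) {
  double v = baseline;
  for (int k = 0; k < comps.nrow(); ++k) {
    double e = 0.0;
    double sx = comps(k, 3), st = comps(k, 4);
    if (R_finite(sx)) {
      double dx = (x - comps(k, 1)) / sx;
      e += 0.5 * dx * dx;
    }
    if (R_finite(st)) {
      double dt = (th - comps(k, 2)) / st;
      e += 0.5 * dt * dt;
    }
    v += comps(k, 0) * std::exp(-e);
  }
  return v;
}

static inline void pot_grad(const NumericMatrix &comps, double x, double th,
                            double &gx, double &gt) {
  gx = 0.0; gt = 0.0;
  for (int k = 0; k < comps.nrow(); ++k) {
    double e = 0.0;
    double sx = comps(k, 3), st = comps(k, 4);
    double dx = 0.0, dt = 0.0;
    if (R_finite(sx)) { dx = (x - comps(k, 1)); e += 0.5 * dx * dx / (sx * sx); }
    if (R_finite(st)) { dt = (th - comps(k, 2)); e += 0.5 * dt * dt / (st * st); }
    double g = comps(k, 0) * std::exp(-e);
    if (R_finite(sx)) gx += g * (-dx / (sx * sx));
    if (R_finite(st)) gt += g * (-dt / (st * st));
  }
}

// [[Rcpp::export(name = ".potential_eval_cpp")]]
NumericVector potential_eval_cpp(NumericMatrix comps, double baseline,
                                 NumericVector x, NumericVector th) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pot_value(comps, baseline, x[i], th[i]);
  return out;
}

// [[Rcpp::export(name = ".potential_grad_cpp")]]
NumericMatrix potential_grad_cpp(NumericMatrix comps, NumericVector x,
                                 NumericVector th) {
  int n = x.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double gx, gt;
    pot_grad(comps, x[i], th[i], gx, gt);
    out(i, 0) = gx; out(i, 1) = gt;
  }
  return out;
}

static inline double reflect(double z, double lo, double hi) {
  // displacements are small compared with the box, so a few bounces suffice
  for (int it = 0; it < 64; ++it) {
    if (z < lo) z = 2.0 * lo - z;
    else if (z > hi) z = 2.0 * hi - z;
    else return z;
  }
  return std::min(std::max(z, lo), hi);
}

struct BiasGrid {
  int nx, nt;
  double xlo, tlo, dx, dt;
  std::vector<double> v, gx, gt;
  BiasGrid(double xlo_, double xhi, double tlo_, double thi,
           double dx_, double dt_) : xlo(xlo_), tlo(tlo_), dx(dx_), dt(dt_) {
    nx = (int)std::ceil((xhi - xlo_) / dx_) + 1;
    nt = (int)std::ceil((thi - tlo_) / dt_) + 1;
    v.assign((size_t)nx * nt, 0.0);
    gx.assign((size_t)nx * nt, 0.0);
    gt.assign((size_t)nx * nt, 0.0);
  }
  inline size_t idx(int i, int j) const { return (size_t)j * nx + i; }
  void deposit(double h, double cx, double ct, double sx, double st) {
    int i0 = std::max(0, (int)std::floor((cx - 5.0 * sx - xlo) / dx));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + 5.0 * sx - xlo) / dx));
    int j0 = std::max(0, (int)std::floor((ct - 5.0 * st - tlo) / dt));
    int j1 = std::min(nt - 1, (int)std::ceil((ct + 5.0 * st - tlo) / dt));
    for (int j = j0; j <= j1; ++j) {
      double tt = tlo + j * dt;
      double dtt = tt - ct;
      double et = std::exp(-0.5 * dtt * dtt / (st * st));
      for (int i = i0; i <= i1; ++i) {
        double xx = xlo + i * dx;
        double dxx = xx - cx;
        double g = h * std::exp(-0.5 * dxx * dxx / (sx * sx)) * et;
        size_t p = idx(i, j);
        v[p] += g;
        gx[p] += g * (-dxx / (sx * sx));
        gt[p] += g * (-dtt / (st * st));
      }
    }
  }
  inline void interp(double x, double th, double &V, double &Gx, double &Gt) const {
    double fx = (x - xlo) / dx, ft = (th - tlo) / dt;
    int i = std::min(std::max((int)std::floor(fx), 0), nx - 2);
    int j = std::min(std::max((int)std::floor(ft), 0), nt - 2);
    double ax = fx - i, at = ft - j;
    ax = std::min(std::max(ax, 0.0), 1.0);
    at = std::min(std::max(at, 0.0), 1.0);
    double w00 = (1 - ax) * (1 - at), w10 = ax * (1 - at);
    double w01 = (1 - ax) * at, w11 = ax * at;
    size_t p00 = idx(i, j), p10 = idx(i + 1, j);
    size_t p01 = idx(i, j + 1), p11 = idx(i + 1, j + 1);
    V  = w00 * v[p00]  + w10 * v[p10]  + w01 * v[p01]  + w11 * v[p11];
    Gx = w00 * gx[p00] + w10 * gx[p10] + w01 * gx[p01] + w11 * gx[p11];
    Gt = w00 * gt[p00] + w10 * gt[p10] + w01 * gt[p01] + w11 * gt[p11];
  }
};

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericMatrix comps, double baseline,
                  double x0, double th0, double dt,
                  double Dx, double Dth, double kBT, double nsteps_d,
                  double xlo, double xhi, double tlo, double thi,
                  int sample_stride,
                  bool metad, double h0, int dep_stride, double kB_dT,
                  double biasf, double hsx, double hst,
                  double grid_dx, double grid_dt) {
  long nsteps = (long)nsteps_d;
  double cx = std::sqrt(2.0 * Dx * dt), ct = std::sqrt(2.0 * Dth * dt);
  double bx = Dx * dt / kBT, bt = Dth * dt / kBT;
  long nrec = nsteps / sample_stride + 1;
  NumericVector rt(nrec), rx(nrec), rth(nrec), rb(nrec);
  std::vector<double> h_time, h_cx, h_ct, h_h;
  BiasGrid *grid = NULL;
  if (metad) grid = new BiasGrid(xlo, xhi, tlo, thi, grid_dx, grid_dt);

  double x = x0, th = th0;
  long rec = 0;
  for (long step = 0; step <= nsteps; ++step) {
    double V = 0.0, bGx = 0.0, bGt = 0.0;
    if (metad) grid->interp(x, th, V, bGx, bGt);
    if (metad && step > 0 && step % dep_stride == 0) {
      double h = h0 * std::exp(-V / kB_dT);
      grid->deposit(h, x, th, hsx, hst);
      h_time.push_back(step * dt);
      h_cx.push_back(x); h_ct.push_back(th); h_h.push_back(h);
      grid->interp(x, th, V, bGx, bGt);  // refresh after deposition
    }
    if (step % sample_stride == 0) {
      rt[rec] = step * dt; rx[rec] = x; rth[rec] = th; rb[rec] = V;
      ++rec;
    }
    if (step == nsteps) break;
    double gx, gt;
    pot_grad(comps, x, th, gx, gt);
    if (!R_finite(gx) || !R_finite(gt))
      stop("non-finite potential gradient at step %ld (X=%g, theta=%g)",
           step, x, th);
    x  = reflect(x  - bx * (gx + bGx) + cx * norm_rand(), xlo, xhi);
    th = reflect(th - bt * (gt + bGt) + ct * norm_rand(), tlo, thi);
  }

  List out;
  out["traj"] = DataFrame::create(_["time"] = rt, _["X"] = rx,
                                  _["theta"] = rth, _["bias"] = rb);
  if (metad) {
    int nh = h_time.size();
    NumericMatrix hm(nh, 7);
    for (int i = 0; i < nh; ++i) {
      hm(i, 0) = h_time[i]; hm(i, 1) = h_cx[i]; hm(i, 2) = h_ct[i];
      hm(i, 3) = hsx; hm(i, 4) = hst; hm(i, 5) = h_h[i]; hm(i, 6) = biasf;
    }
    out["hills"] = hm;
    delete grid;
  }
  return out;
}

// [[Rcpp::export(name = ".first_passage_cpp")]]
List first_passage_cpp(NumericMatrix comps, double x0, double th0, double dt,
                       double Dx, double Dth, double kBT,
                       double x_boundary, double max_steps_d,
                       double xlo, double xhi, double tlo, double thi) {
  long max_steps = (long)max_steps_d;
  double cx = std::sqrt(2.0 * Dx * dt), ct = std::sqrt(2.0 * Dth * dt);
  double bx = Dx * dt / kBT, bt = Dth * dt / kBT;
  double x = x0, th = th0;
  for (long step = 1; step <= max_steps; ++step) {
    double gx, gt;
    pot_grad(comps, x, th, gx, gt);
    x  = reflect(x  - bx * gx + cx * norm_rand(), xlo, xhi);
    th = reflect(th - bt * gt + ct * norm_rand(), tlo, thi);
    if (x >= x_boundary)
      return List::create(_["time"] = step * dt, _["censored"] = false);
  }
  return List::create(_["time"] = max_steps * dt, _["censored"] = true);
}

// Exact bias sum over hills; no cutoff so that it can serve as the
// reference Gaussian summation for tests and FES reconstruction.
// hills columns: time, cx, ct, sx, st, height (extra columns ignored)
// [[Rcpp::export(name = ".evaluate_bias_cpp")]]
NumericVector evaluate_bias_cpp(NumericMatrix hills, NumericVector x,
                                NumericVector th, double t_cutoff) {
  int n = x.size(), nh = hills.nrow();
  NumericVector out(n);
  for (int k = 0; k < nh; ++k) {
    if (hills(k, 0) > t_cutoff) continue;
    double hcx = hills(k, 1), hct = hills(k, 2);
    double sx2 = 2.0 * hills(k, 3) * hills(k, 3);
    double st2 = 2.0 * hills(k, 4) * hills(k, 4);
    double h = hills(k, 5);
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - hcx, dt = th[i] - hct;
      out[i] += h * std::exp(-dx * dx / sx2 - dt * dt / st2);
    }
  }
  return out;
}
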