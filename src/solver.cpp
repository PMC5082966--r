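#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-variable cardiac ionic models.
//
// Generalised form (model = 0; the classic Mitchell-Schaeffer model is the
// special case a = lambda = 0):
//   dvm/dt = h (vm+a)(vm+a-lambda)(1-vm)/tau_in - vm/tau_out + j_stim
// Modified MS (model = 1), outward current gated by (1-h):
//   dvm/dt = h vm (vm-v_gate)(1-vm)/tau_in - (1-h) vm/tau_out + j_stim
// Both share the gate equation
//   dh/dt = (1-h)/tau_open  if vm <= v_gate   (open branch, tie -> open)
//         = -h/tau_close    if vm >  v_gate

struct Params {
  double tin, tout, topen, tclose, vg, a, lam;
  int mms; // 0 = generalised/MS, 1 = mMS
};

static inline Params make_params(int mms, const NumericVector &par) {
  Params P;
  P.tin = par[0]; P.tout = par[1]; P.topen = par[2]; P.tclose = par[3];
  P.vg = par[4]; P.a = par[5]; P.lam = par[6]; P.mms = mms;
  return P;
}

static inline double f_ion(const Params &P, double v, double h) {
  if (P.mms)
    return h * v * (v - P.vg) * (1.0 - v) / P.tin - (1.0 - h) * v / P.tout;
  double u = v + P.a;
  return h * u * (u - P.lam) * (1.0 - v) / P.tin - v / P.tout;
}

static inline double df_ion(const Params &P, double v, double h) {
  if (P.mms) {
    // d/dv [v(v-vg)(1-v)] = -3v^2 + 2(1+vg)v - vg
    double d = -3.0 * v * v + 2.0 * (1.0 + P.vg) * v - P.vg;
    return h * d / P.tin - (1.0 - h) / P.tout;
  }
  double u = v + P.a;
  double d = (2.0 * u - P.lam) * (1.0 - v) - u * (u - P.lam);
  return h * d / P.tin - 1.0 / P.tout;
}

// One backward Euler step.  The gate branch is frozen from the previous
// step's converged vm, which makes the h-update linear (solved exactly) and
// reduces the vm-update to a scalar Newton solve on the cubic.  If Newton
// fails to converge the root is bracketed and bisected; only failure of both
// reports non-convergence.
static inline bool be_step(const Params &P, double &v, double &h, double j,
                           double dt, double tol, int maxit) {
  double vprev = v;
  if (vprev <= P.vg)
    h = (h + dt / P.topen) / (1.0 + dt / P.topen);
  else
    h = h / (1.0 + dt / P.tclose);

  double x = vprev;
  for (int it = 0; it <= maxit; ++it) {
    double F = x - vprev - dt * (f_ion(P, x, h) + j);
    if (std::fabs(F) < tol) { v = x; return true; }
    double dF = 1.0 - dt * df_ion(P, x, h);
    if (dF == 0.0) break;
    double step = F / dF;
    if (!std::isfinite(step) || std::fabs(step) > 1.0) break;
    x -= step;
  }

  // Bisection fallback on an expanding bracket around vprev.
  double lo = vprev - 0.5, hi = vprev + 0.5;
  double Flo, Fhi;
  for (int k = 0; k < 12; ++k) {
    Flo = lo - vprev - dt * (f_ion(P, lo, h) + j);
    Fhi = hi - vprev - dt * (f_ion(P, hi, h) + j);
    if (Flo * Fhi <= 0.0) break;
    lo -= 0.5; hi += 0.5;
  }
  if (Flo * Fhi > 0.0) return false;
  for (int k = 0; k < 200; ++k) {
    double mid = 0.5 * (lo + hi);
    double Fm = mid - vprev - dt * (f_ion(P, mid, h) + j);
    if (std::fabs(Fm) < tol) { v = mid; return true; }
    if (Flo * Fm <= 0.0) { hi = mid; Fhi = Fm; } else { lo = mid; Flo = Fm; }
  }
  v = 0.5 * (lo + hi);
  return std::fabs(v - vprev - dt * (f_ion(P, v, h) + j)) < tol;
}

// [[Rcpp::export]]
NumericVector be_step_cpp(int mms, NumericVector par, double vm, double h,
                          double j_stim, double dt, double tol, int maxit) {
  Params P = make_params(mms, par);
  double v = vm, hh = h;
  if (!be_step(P, v, hh, j_stim, dt, tol, maxit))
    stop("Newton iteration failed to converge (vm = %g, h = %g, dt = %g)",
         vm, h, dt);
  return NumericVector::create(v, hh);
}

// [[Rcpp::export]]
NumericVector rhs_cpp(int mms, NumericVector par, double vm, double h,
                      double j_stim) {
  Params P = make_params(mms, par);
  double dv = f_ion(P, vm, h) + j_stim;
  double dh = (vm <= P.vg) ? (1.0 - h) / P.topen : -h / P.tclose;
  return NumericVector::create(dv, dh);
}

// Integrate a single cell.  Stimuli are additive constant currents over
// [onset, onset + dur); a time step is stimulated when its midpoint lies in
// the window.  The state is recorded every `stride` steps.
// [[Rcpp::export]]
List simulate_cell_cpp(int mms, NumericVector par, double v0, double h0,
                       double dt, double t_end, NumericVector stim_onset,
                       double stim_amp, double stim_dur, double tol,
                       int maxit, int stride) {
  Params P = make_params(mms, par);
  int n_steps = (int)std::llround(t_end / dt);
  int n_rec = n_steps / stride + 1;
  NumericVector vm(n_rec), hh(n_rec);
  double v = v0, h = h0;
  vm[0] = v; hh[0] = h;
  int si = 0, ns = stim_onset.size(), ri = 1;
  for (int k = 0; k < n_steps; ++k) {
    double tmid = (k + 0.5) * dt;
    while (si < ns && tmid >= stim_onset[si] + stim_dur) ++si;
    double j = (si < ns && tmid >= stim_onset[si]) ? stim_amp : 0.0;
    if (!be_step(P, v, h, j, dt, tol, maxit))
      stop("Newton iteration failed to converge at t = %g ms (vm = %g, h = %g)",
           (k + 1) * dt, v, h);
    if ((k + 1) % stride == 0) { vm[ri] = v; hh[ri] = h; ++ri; }
    if ((k & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["vm"] = vm, _["h"] = hh,
                      _["final"] = NumericVector::create(v, h));
}

// Pacemaker sweep: for each parameter row (tau_in, tau_out, tau_open,
// tau_close), apply one stimulus at t = 0 and count upward v_gate crossings
// over [0, t_end], merging crossings closer than `debounce` ms.  Crossing
// times are linearly interpolated.  Each set is integrated independently, so
// results are identical for any batching of the rows.
// [[Rcpp::export]]
IntegerVector sweep_cpp(int mms, NumericMatrix tau, double vg, double dt,
                        double t_end, double stim_amp, double stim_dur,
                        double debounce, double tol, int maxit) {
  int n = tau.nrow();
  IntegerVector out(n);
  int n_steps = (int)std::llround(t_end / dt);
  for (int i = 0; i < n; ++i) {
    Params P;
    P.tin = tau(i, 0); P.tout = tau(i, 1);
    P.topen = tau(i, 2); P.tclose = tau(i, 3);
    P.vg = vg; P.a = 0.0; P.lam = 0.0; P.mms = mms;
    double v = 0.0, h = 1.0;
    int count = 0;
    double last = R_NegInf;
    bool failed = false;
    for (int k = 0; k < n_steps; ++k) {
      double tmid = (k + 0.5) * dt;
      double j = (tmid < stim_dur) ? stim_amp : 0.0;
      double vprev = v;
      if (!be_step(P, v, h, j, dt, tol, maxit)) { failed = true; break; }
      if (vprev < P.vg && v >= P.vg) {
        double tc = k * dt + dt * (P.vg - vprev) / (v - vprev);
        if (tc - last > debounce) ++count;
        last = tc;
      }
    }
    out[i] = failed ? NA_INTEGER : count;
    if ((i & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// One ionic (reaction) step on every node of a field; used by the monodomain
// splitting.  Returns updated vm and h.
// [[Rcpp::export]]
List ionic_step_field_cpp(int mms, NumericVector par, NumericVector vm,
                          NumericVector h, NumericVector j_stim, double dt,
                          double tol, int maxit) {
  Params P = make_params(mms, par);
  int n = vm.size();
  NumericVector v_out(n), h_out(n);
  for (int i = 0; i < n; ++i) {
    double v = vm[i], hh = h[i];
    if (!be_step(P, v, hh, j_stim[i], dt, tol, maxit))
      stop("Newton iteration failed to converge at node %d (vm = %g, h = %g)",
           i + 1, vm[i], h[i]);
    v_out[i] = v; h_out[i] = hh;
  }
  return List::create(_["vm"] = v_out, _["h"] = h_out);
}
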