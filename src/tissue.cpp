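#include <Rcpp.h>
#include "models.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cw_ov_names() {
  CharacterVector out(N_OV);
  for (int i = 0; i < N_OV; ++i) out[i] = OV_NAMES[i];
  return out;
}

// [[Rcpp::export]]
NumericVector cw_initial_state_cpp(int kind) {
  if (kind == 0) {
    NumericVector st(1 + N_GPB_Y);
    double vm;
    std::vector<double> y(N_GPB_Y);
    gpb_initial_state(&vm, y.data());
    st[0] = vm;
    for (int i = 0; i < N_GPB_Y; ++i) st[1 + i] = y[i];
    return st;
  }
  NumericVector st(1 + N_FIB_Y);
  double vm;
  std::vector<double> y(N_FIB_Y);
  fib_initial_state(&vm, y.data());
  st[0] = vm;
  for (int i = 0; i < N_FIB_Y; ++i) st[1 + i] = y[i];
  return st;
}

namespace {

GpbParams make_gpb_params(bool epi, const NumericVector& ov) {
  GpbParams p;
  p.epi = epi;
  if (ov.size() != N_OV) stop("override vector must have length %d", N_OV);
  for (int i = 0; i < N_OV; ++i) {
    if (!(ov[i] > 0)) stop("non-positive override factor for %s", OV_NAMES[i]);
    p.scale[i] = ov[i];
  }
  return p;
}

FibParams make_fib_params(const NumericVector& ov) {
  FibParams p;
  if (ov.size() != 4) stop("fibroblast override vector must have length 4");
  p.scale_gkv = ov[0]; p.scale_gk1 = ov[1];
  p.scale_gbna = ov[2]; p.scale_inak = ov[3];
  return p;
}

const char* gpb_state_name(int i) {
  static const char* nm[N_GPB_Y] = {
    "m", "h", "j", "d", "f", "fcaBj", "fcaBsl",
    "xtos", "ytos", "xtof", "ytof", "xkr", "xks", "mL", "hL",
    "RyRr", "RyRo", "RyRi", "NaBj", "NaBsl",
    "TnCL", "TnCHc", "TnCHm", "CaM", "Myoc", "Myom", "SRB",
    "SLLj", "SLLsl", "SLHj", "SLHsl", "Csqnb",
    "Naj", "Nasl", "Nai", "Ki", "Caj", "Casl", "Cai", "Casr"
  };
  return nm[i];
}

void check_finite_gpb(double vm, const double* y, double t) {
  if (!std::isfinite(vm))
    stop("non-finite membrane potential at t = %.4f ms", t);
  for (int i = 0; i < N_GPB_Y; ++i)
    if (!std::isfinite(y[i]))
      stop("non-finite state variable '%s' at t = %.4f ms", gpb_state_name(i), t);
}

} // namespace

// ---------------------------------------------------------------------------
// single-cell integrator
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cw_cell_run(NumericVector state0, int kind, bool epi, NumericVector ov,
                 double dt, double duration, NumericVector stim_onsets,
                 double stim_dur, double stim_amp, double record_dt,
                 bool use_exact, double t0) {
  if (dt <= 0) stop("dt must be positive");
  long n_steps = (long)std::llround(duration / dt);
  long rec_every = record_dt > 0 ? std::max(1L, (long)std::llround(record_dt / dt)) : 0;
  long n_rec = rec_every > 0 ? n_steps / rec_every + 1 : 0;
  NumericVector rec_t(n_rec), rec_vm(n_rec);

  double vm = state0[0];
  std::vector<double> y(state0.size() - 1);
  for (size_t i = 0; i < y.size(); ++i) y[i] = state0[i + 1];

  std::vector<double> on(stim_onsets.begin(), stim_onsets.end());

  if (kind == 0) {
    if ((int)y.size() != N_GPB_Y) stop("myocyte state must have length %d", 1 + N_GPB_Y);
    GpbParams p = make_gpb_params(epi, ov);
    GpbTables tabs;
    if (!use_exact) tabs.build(dt);
    GpbVdep vd;
    long ri = 0;
    for (long k = 0; k < n_steps; ++k) {
      double t = t0 + k * dt;
      if (rec_every > 0 && k % rec_every == 0) { rec_t[ri] = t; rec_vm[ri] = vm; ++ri; }
      double istim = 0.0;
      for (size_t si = 0; si < on.size(); ++si)
        if (t >= on[si] && t < on[si] + stim_dur) { istim += stim_amp; break; }
      if (use_exact) gpb_vdep_exact(vm, dt, vd); else tabs.lookup(vm, vd);
      vm = gpb_step(vm, y.data(), vd, p, dt, istim);
      if (!std::isfinite(vm)) check_finite_gpb(vm, y.data(), t + dt);
      if ((k & 0x3FF) == 0) check_finite_gpb(vm, y.data(), t + dt);
    }
    if (rec_every > 0 && ri < n_rec) { rec_t[ri] = t0 + n_steps * dt; rec_vm[ri] = vm; ++ri; }
    check_finite_gpb(vm, y.data(), t0 + n_steps * dt);
  } else {
    if ((int)y.size() != N_FIB_Y) stop("fibroblast state must have length %d", 1 + N_FIB_Y);
    FibParams p = make_fib_params(ov);
    FibTables tabs;
    if (!use_exact) tabs.build(dt);
    FibVdep vd;
    long ri = 0;
    for (long k = 0; k < n_steps; ++k) {
      double t = t0 + k * dt;
      if (rec_every > 0 && k % rec_every == 0) { rec_t[ri] = t; rec_vm[ri] = vm; ++ri; }
      double istim = 0.0;
      for (size_t si = 0; si < on.size(); ++si)
        if (t >= on[si] && t < on[si] + stim_dur) { istim += stim_amp; break; }
      if (use_exact) fib_vdep_exact(vm, dt, vd); else tabs.lookup(vm, vd);
      vm = fib_step(vm, y.data(), vd, p, dt, istim);
      if (!std::isfinite(vm))
        stop("non-finite membrane potential at t = %.4f ms", t + dt);
    }
    if (rec_every > 0 && ri < n_rec) { rec_t[ri] = t0 + n_steps * dt; rec_vm[ri] = vm; ++ri; }
  }

  NumericVector out_state(1 + y.size());
  out_state[0] = vm;
  for (size_t i = 0; i < y.size(); ++i) out_state[i + 1] = y[i];
  return List::create(_["state"] = out_state, _["t"] = rec_t, _["vm"] = rec_vm);
}

// ---------------------------------------------------------------------------
// pure diffusion stepping (flux-conservative finite differences,
// element-wise anisotropic coefficients, no-flux boundaries)
// ---------------------------------------------------------------------------

namespace {

struct FaceCoefs {
  // facx[(i, j)]: coefficient on the edge between nodes (i,j) and (i+1,j)
  // facy[(i, j)]: coefficient on the edge between nodes (i,j) and (i,j+1)
  std::vector<double> facx, facy;
  int nx, ny;

  void build(const NumericMatrix& dlong, const NumericMatrix& dtrans,
             int nx_, int ny_) {
    nx = nx_; ny = ny_;
    int ex = nx - 1, ey = std::max(ny - 1, 1);
    if (dlong.nrow() != ex || dlong.ncol() != ey)
      stop("diffusion field shape (%d x %d) does not match mesh elements (%d x %d)",
           dlong.nrow(), dlong.ncol(), ex, ey);
    facx.assign((size_t)ex * ny, 0.0);
    facy.assign((size_t)nx * std::max(ny - 1, 0), 0.0);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < ex; ++i) {
        double sum = 0.0; int n = 0;
        if (ny == 1) { sum += dlong(i, 0); n = 1; }
        else {
          if (j - 1 >= 0)    { sum += dlong(i, j - 1); ++n; }
          if (j <= ny - 2)   { sum += dlong(i, j); ++n; }
        }
        facx[(size_t)i + (size_t)ex * j] = sum / n;
      }
    }
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double sum = 0.0; int n = 0;
        if (i - 1 >= 0)  { sum += dtrans(i - 1, j); ++n; }
        if (i <= nx - 2) { sum += dtrans(i, j); ++n; }
        facy[(size_t)i + (size_t)nx * j] = sum / n;
      }
    }
  }

  void apply(const double* vin, double* vout, double r) const {
    // r = dt / dx^2; vout must not alias vin
    int ex = nx - 1;
    for (int j = 0; j < ny; ++j) {
      const double* row = vin + (size_t)nx * j;
      double* orow = vout + (size_t)nx * j;
      const double* fx = facx.data() + (size_t)ex * j;
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        if (i < nx - 1) acc += fx[i] * (row[i + 1] - row[i]);
        if (i > 0)      acc -= fx[i - 1] * (row[i] - row[i - 1]);
        if (j < ny - 1) {
          const double* fy = facy.data() + (size_t)nx * j;
          acc += fy[i] * (vin[(size_t)nx * (j + 1) + i] - row[i]);
        }
        if (j > 0) {
          const double* fy = facy.data() + (size_t)nx * (j - 1);
          acc -= fy[i] * (row[i] - vin[(size_t)nx * (j - 1) + i]);
        }
        orow[i] = row[i] + r * acc;
      }
    }
  }
};

void check_stability(const NumericMatrix& dlong, double dx, double dt) {
  double dmax = 0.0; int im = 0, jm = 0;
  for (int j = 0; j < dlong.ncol(); ++j)
    for (int i = 0; i < dlong.nrow(); ++i)
      if (dlong(i, j) > dmax) { dmax = dlong(i, j); im = i; jm = j; }
  if (!(dt < dx * dx / (2.0 * dmax)))
    stop("diffusion step unstable: dt = %g >= dx^2/(2 D) = %g "
         "(limiting element [%d, %d], d_long = %g)",
         dt, dx * dx / (2.0 * dmax), im + 1, jm + 1, dmax);
}

} // namespace

// [[Rcpp::export]]
NumericVector cw_diffusion_steps(NumericVector vm, int nx, int ny,
                                 NumericMatrix dlong, NumericMatrix dtrans,
                                 double dx, double dt, int n_steps) {
  if (vm.size() != (R_xlen_t)nx * ny) stop("vm length does not match mesh");
  check_stability(dlong, dx, dt);
  FaceCoefs fc;
  fc.build(dlong, dtrans, nx, ny);
  std::vector<double> a(vm.begin(), vm.end()), b(a.size());
  double r = dt / (dx * dx);
  for (int k = 0; k < n_steps; ++k) {
    fc.apply(a.data(), b.data(), r);
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// coupled tissue run (Lie splitting: reaction step then diffusion step)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cw_tissue_run(NumericVector vm0, NumericMatrix myo_y0, NumericMatrix fib_y0,
                   IntegerVector kind, int nx, int ny,
                   NumericMatrix dlong, NumericMatrix dtrans, double dx,
                   double dt, double duration, double t0,
                   List stim_nodes, NumericMatrix stim_tda,
                   NumericVector ov_myo, NumericVector ov_fib,
                   double sample_dt, bool record_frames,
                   double act_thresh, double act_dvdt, double act_lockout,
                   NumericVector act_last0) {
  int n = nx * ny;
  if (vm0.size() != n || kind.size() != n) stop("vm/kind length mismatch");
  if (dt <= 0) stop("dt must be positive");
  check_stability(dlong, dx, dt);

  // node bookkeeping
  std::vector<int> myo_nodes, fib_nodes;
  std::vector<char> is_epi;
  for (int i = 0; i < n; ++i) {
    if (kind[i] == 2) fib_nodes.push_back(i);
    else { myo_nodes.push_back(i); is_epi.push_back(kind[i] == 1); }
  }
  int n_myo = (int)myo_nodes.size(), n_fib = (int)fib_nodes.size();
  if (myo_y0.nrow() != n_myo || (n_myo && myo_y0.ncol() != N_GPB_Y))
    stop("myocyte state matrix must be %d x %d", n_myo, N_GPB_Y);
  if (fib_y0.nrow() != n_fib || (n_fib && fib_y0.ncol() != N_FIB_Y))
    stop("fibroblast state matrix must be %d x %d", n_fib, N_FIB_Y);

  // node-major state copies for cache locality
  std::vector<double> ym((size_t)n_myo * N_GPB_Y), yf((size_t)n_fib * N_FIB_Y);
  for (int r = 0; r < n_myo; ++r)
    for (int c = 0; c < N_GPB_Y; ++c) ym[(size_t)r * N_GPB_Y + c] = myo_y0(r, c);
  for (int r = 0; r < n_fib; ++r)
    for (int c = 0; c < N_FIB_Y; ++c) yf[(size_t)r * N_FIB_Y + c] = fib_y0(r, c);

  GpbParams p_endo = make_gpb_params(false, ov_myo);
  GpbParams p_epi  = make_gpb_params(true, ov_myo);
  FibParams p_fib  = make_fib_params(ov_fib);
  GpbTables gtab; gtab.build(dt);
  FibTables ftab; ftab.build(dt);

  FaceCoefs fc;
  fc.build(dlong, dtrans, nx, ny);
  double rdiff = dt / (dx * dx);

  std::vector<double> vm(vm0.begin(), vm0.end()), vtmp(vm.size());
  std::vector<double> istim(n, 0.0);

  // stimulus schedule
  int n_stim = stim_tda.nrow();
  std::vector<std::vector<int>> snodes(n_stim);
  for (int s = 0; s < n_stim; ++s) {
    IntegerVector v = stim_nodes[s];
    snodes[s].assign(v.begin(), v.end());
    for (int& id : snodes[s]) {
      if (id < 1 || id > n) stop("stimulus node index out of range");
      --id;
    }
  }

  long n_steps = (long)std::llround(duration / dt);
  long samp_every = sample_dt > 0 ? std::max(1L, (long)std::llround(sample_dt / dt)) : 0;
  long n_frames = (record_frames && samp_every > 0) ? n_steps / samp_every + 1 : 0;
  NumericMatrix frames(record_frames ? n : 0, n_frames);
  NumericVector frame_times(n_frames);

  // activation bookkeeping
  std::vector<double> last_act(act_last0.begin(), act_last0.end());
  if ((int)last_act.size() != n) last_act.assign(n, -1e18);
  std::vector<double> vprev(vm);
  std::vector<int> act_node;
  std::vector<double> act_time;

  bool stim_was_active = false;
  long fi = 0;
  GpbVdep gvd; FibVdep fvd;

  for (long k = 0; k < n_steps; ++k) {
    double t = t0 + k * dt;
    if (record_frames && samp_every > 0 && k % samp_every == 0) {
      for (int i = 0; i < n; ++i) frames(i, fi) = vm[i];
      frame_times[fi] = t;
      ++fi;
    }

    // stimulus currents (myocyte nodes only; protocol targets myocardium)
    bool any_active = false;
    for (int s = 0; s < n_stim; ++s)
      if (t >= stim_tda(s, 0) && t < stim_tda(s, 0) + stim_tda(s, 1)) { any_active = true; break; }
    if (any_active || stim_was_active) {
      std::fill(istim.begin(), istim.end(), 0.0);
      for (int s = 0; s < n_stim; ++s)
        if (t >= stim_tda(s, 0) && t < stim_tda(s, 0) + stim_tda(s, 1))
          for (int id : snodes[s])
            if (kind[id] != 2) istim[id] += stim_tda(s, 2);
    }
    stim_was_active = any_active;

    // reaction
    for (int r = 0; r < n_myo; ++r) {
      int id = myo_nodes[r];
      gtab.lookup(vm[id], gvd);
      vm[id] = gpb_step(vm[id], &ym[(size_t)r * N_GPB_Y], gvd,
                        is_epi[r] ? p_epi : p_endo, dt, istim[id]);
    }
    for (int r = 0; r < n_fib; ++r) {
      int id = fib_nodes[r];
      ftab.lookup(vm[id], fvd);
      vm[id] = fib_step(vm[id], &yf[(size_t)r * N_FIB_Y], fvd, p_fib, dt,
                        istim[id]);
    }

    // diffusion
    fc.apply(vm.data(), vtmp.data(), rdiff);
    std::swap(vm, vtmp);

    // NaN guard (cheap scalar probe each step, full scan periodically)
    if (!std::isfinite(vm[n / 2]) || (k & 0x3FF) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(vm[i]))
          stop("non-finite membrane potential at node %d, t = %.3f ms (last good frame %ld)",
               i + 1, t + dt, (long)(fi - 1));
    }

    // upstroke detection
    double tnew = t + dt;
    for (int i = 0; i < n; ++i) {
      if (vprev[i] < act_thresh && vm[i] >= act_thresh
          && (vm[i] - vprev[i]) / dt > act_dvdt
          && tnew - last_act[i] > act_lockout) {
        last_act[i] = tnew;
        act_node.push_back(i + 1);
        act_time.push_back(tnew);
      }
      vprev[i] = vm[i];
    }

    if ((k & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }

  double t_end = t0 + n_steps * dt;
  if (record_frames && samp_every > 0 && fi < n_frames) {
    for (int i = 0; i < n; ++i) frames(i, fi) = vm[i];
    frame_times[fi] = t_end;
    ++fi;
  }

  NumericMatrix myo_out(n_myo, n_myo ? N_GPB_Y : 0);
  for (int r = 0; r < n_myo; ++r)
    for (int c = 0; c < N_GPB_Y; ++c) myo_out(r, c) = ym[(size_t)r * N_GPB_Y + c];
  NumericMatrix fib_out(n_fib, n_fib ? N_FIB_Y : 0);
  for (int r = 0; r < n_fib; ++r)
    for (int c = 0; c < N_FIB_Y; ++c) fib_out(r, c) = yf[(size_t)r * N_FIB_Y + c];

  return List::create(
    _["vm"] = NumericVector(vm.begin(), vm.end()),
    _["myo_y"] = myo_out,
    _["fib_y"] = fib_out,
    _["t_end"] = t_end,
    _["frames"] = frames,
    _["frame_times"] = frame_times,
    _["act_node"] = IntegerVector(act_node.begin(), act_node.end()),
    _["act_time"] = NumericVector(act_time.begin(), act_time.end()),
    _["act_last"] = NumericVector(last_act.begin(), last_act.end()));
}

// LUT accuracy oracle: one exact vs one table-driven step from a given state
// [[Rcpp::export]]
NumericVector cw_cell_step_once(NumericVector state0, int kind, bool epi,
                                NumericVector ov, double dt, double istim,
                                bool use_exact) {
  double vm = state0[0];
  std::vector<double> y(state0.size() - 1);
  for (size_t i = 0; i < y.size(); ++i) y[i] = state0[i + 1];
  if (kind == 0) {
    GpbParams p = make_gpb_params(epi, ov);
    GpbVdep vd;
    if (use_exact) gpb_vdep_exact(vm, dt, vd);
    else { GpbTables tb; tb.build(dt); tb.lookup(vm, vd); }
    vm = gpb_step(vm, y.data(), vd, p, dt, istim);
    check_finite_gpb(vm, y.data(), dt);
  } else {
    FibParams p = make_fib_params(ov);
    FibVdep vd;
    if (use_exact) fib_vdep_exact(vm, dt, vd);
    else { FibTables tb; tb.build(dt); tb.lookup(vm, vd); }
    vm = fib_step(vm, y.data(), vd, p, dt, istim);
  }
  NumericVector out(1 + y.size());
  out[0] = vm;
  for (size_t i = 0; i < y.size(); ++i) out[i + 1] = y[i];
  return out;
}
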