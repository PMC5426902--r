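// Core integrator: operator-split 1-D reaction-diffusion on a tree of
// well-mixed compartments.  Local chemistry is advanced per compartment by an
// adaptive Runge-Kutta-Fehlberg (Cash-Karp 4(5)) scheme; diffusion is advanced
// by one backward-Euler (implicit) step solved exactly on the compartment tree
// (no fill-in under leaf-first elimination).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// chemistry
// ---------------------------------------------------------------------------

enum Family { FAM_NONE = 0, FAM_NEGFB = 1, FAM_NEGFF = 2, FAM_FHN = 3,
              FAM_SWITCH = 4, FAM_MASSACTION = 5 };

struct MassAction {
  // reversible mass-action reactions; a species listed twice counts twice
  std::vector<int> sub, prod;          // concatenated species indices
  std::vector<int> sub_ptr, prod_ptr;  // offsets, length n_reac + 1
  std::vector<double> kf, kb;
  // irreversible Michaelis-Menten enzyme steps: E converts S -> P
  std::vector<int> enz_e, enz_s, enz_p;
  std::vector<double> kcat, km;
};

struct Stim {
  int site;          // compartment index
  int species;       // species index receiving the input (Ca)
  double phase;      // s; pulse centre (gaussian) or onset (square)
  double width;      // s; gaussian sigma or square duration
  double amp;
  double krelax;     // 1/s; relaxation rate toward the commanded value
  int kind;          // 0 = gaussian, 1 = square
};

struct Problem {
  int family;
  std::vector<double> par;     // abstract-family rate constants
  MassAction ma;
  int n_species, n_comp;
  std::vector<double> D;       // per species, um^2/s
  std::vector<int> parent;     // -1 at root; parent[i] > i elsewhere
  std::vector<double> gfac;    // edge geometry factor A/L to parent, um
  std::vector<double> vol;     // compartment volume (arbitrary-but-consistent)
  std::vector<int> reactive;   // 0/1 per compartment
  std::vector<int> nonneg;     // 0/1 per species: clamp to >= 0
  std::vector<Stim> stim;
  double ca_decay;             // 1/s, first-order removal of the input species
  int ca_species;              // index of the input species (-1 if none)
  double rtol, atol;
  long clamp_count;
};

// an event is active only within its commanded window (square: the pulse;
// gaussian: +/- 4 sigma); outside it exerts no force on the input species
static inline bool stim_active(const Stim& s, double t) {
  if (s.kind == 1) return t >= s.phase && t <= s.phase + s.width;
  return std::fabs(t - s.phase) <= 4.0 * s.width;
}

static inline double stim_cmd(const Stim& s, double t) {
  if (!stim_active(s, t)) return 0.0;
  if (s.kind == 1) return s.amp;
  const double d = t - s.phase;
  return s.amp * std::exp(-(d * d) / (2.0 * s.width * s.width));
}

// dy/dt for one compartment.  `stims` lists the stimuli targeting this
// compartment; `reactive` gates the A/B (or network) chemistry.
static void deriv(const Problem& pb, int comp, bool reactive,
                  const std::vector<const Stim*>& stims,
                  double t, const double* y, double* dy) {
  const int ns = pb.n_species;
  for (int s = 0; s < ns; ++s) dy[s] = 0.0;

  if (pb.family >= FAM_NEGFB && pb.family <= FAM_SWITCH) {
    const double A = y[0], B = y[1], Ca = y[2];
    const std::vector<double>& p = pb.par;
    if (reactive) {
      switch (pb.family) {
      case FAM_NEGFB:
        // Ca excites A; A excites B; B inhibits A (multiplicative)
        // par: k_act, k_deg, k_inh, k_ab, k_db
        dy[0] = p[0] * Ca - p[1] * A - p[2] * A * B;
        dy[1] = p[3] * A - p[4] * B;
        break;
      case FAM_NEGFF:
        // Ca excites both A and B; B inhibits A; B slower than A
        // par: k_act, k_deg, k_inh, k_b, k_db
        dy[0] = p[0] * Ca - p[1] * A - p[2] * A * B;
        dy[1] = p[3] * Ca - p[4] * B;
        break;
      case FAM_FHN:
        // par: k_a, k_t, a, b, offset_A, offset_B
        dy[0] = p[0] * (A - A * A * A / 3.0 - B + p[4] + Ca);
        dy[1] = p[1] * (p[2] * A - p[3] * B + p[5]);
        break;
      case FAM_SWITCH:
        // par: k1a (input gain), k2a/k2b (self-activation Vmax / K),
        //      k4a (self-inhibition), k4b (multiplicative boost by B),
        //      k3a/k3b (B production / decay)
        dy[0] = p[0] * Ca + p[1] * A * A / (p[2] * p[2] + A * A)
                - p[3] * A * (1.0 + p[4] * B);
        dy[1] = p[5] * A - p[6] * B;
        break;
      }
    }
    dy[2] = -pb.ca_decay * Ca;
  } else if (pb.family == FAM_MASSACTION && reactive) {
    const MassAction& m = pb.ma;
    const int nr = (int)m.kf.size();
    for (int r = 0; r < nr; ++r) {
      double vf = m.kf[r], vb = m.kb[r];
      for (int k = m.sub_ptr[r]; k < m.sub_ptr[r + 1]; ++k) vf *= y[m.sub[k]];
      for (int k = m.prod_ptr[r]; k < m.prod_ptr[r + 1]; ++k) vb *= y[m.prod[k]];
      const double v = vf - vb;
      for (int k = m.sub_ptr[r]; k < m.sub_ptr[r + 1]; ++k) dy[m.sub[k]] -= v;
      for (int k = m.prod_ptr[r]; k < m.prod_ptr[r + 1]; ++k) dy[m.prod[k]] += v;
    }
    const int ne = (int)m.kcat.size();
    for (int e = 0; e < ne; ++e) {
      const double S = y[m.enz_s[e]];
      const double v = m.kcat[e] * y[m.enz_e[e]] * S / (m.km[e] + S);
      dy[m.enz_s[e]] -= v;
      dy[m.enz_p[e]] += v;
    }
  }

  for (size_t i = 0; i < stims.size(); ++i) {
    const Stim& s = *stims[i];
    if (stim_active(s, t))
      dy[s.species] += s.krelax * (stim_cmd(s, t) - y[s.species]);
  }
}

// ---------------------------------------------------------------------------
// Cash-Karp RKF45, one compartment over [t0, t0 + dt]
// ---------------------------------------------------------------------------

static void rkf45(Problem& pb, int comp, bool reactive,
                  const std::vector<const Stim*>& stims,
                  double t0, double dt, double* y) {
  static const double a21 = 1. / 5;
  static const double a31 = 3. / 40, a32 = 9. / 40;
  static const double a41 = 3. / 10, a42 = -9. / 10, a43 = 6. / 5;
  static const double a51 = -11. / 54, a52 = 5. / 2, a53 = -70. / 27,
                      a54 = 35. / 27;
  static const double a61 = 1631. / 55296, a62 = 175. / 512, a63 = 575. / 13824,
                      a64 = 44275. / 110592, a65 = 253. / 4096;
  static const double c2 = 1. / 5, c3 = 3. / 10, c4 = 3. / 5, c5 = 1.,
                      c6 = 7. / 8;
  static const double b1 = 37. / 378, b3 = 250. / 621, b4 = 125. / 594,
                      b6 = 512. / 1771;
  static const double d1 = b1 - 2825. / 27648, d3 = b3 - 18575. / 48384,
                      d4 = b4 - 13525. / 55296, d5 = -277. / 14336,
                      d6 = b6 - 1. / 4;

  const int ns = pb.n_species;
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns),
      ytmp(ns), ynew(ns);
  double t = 0.0;               // local time within the step
  double h = dt;
  const double hmin = dt * 1e-12;
  int guard = 0;

  while (t < dt) {
    if (dt - t <= hmin) break;           // interval exhausted to round-off
    if (h > dt - t) h = dt - t;
    // at the floor the step is accepted regardless of the error estimate:
    // this absorbs commanded-input discontinuities (pulse truncation edges)
    const bool at_floor = (h <= 64.0 * hmin);
    deriv(pb, comp, reactive, stims, t0 + t, y, k1.data());
    for (int s = 0; s < ns; ++s) ytmp[s] = y[s] + h * a21 * k1[s];
    deriv(pb, comp, reactive, stims, t0 + t + c2 * h, ytmp.data(), k2.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a31 * k1[s] + a32 * k2[s]);
    deriv(pb, comp, reactive, stims, t0 + t + c3 * h, ytmp.data(), k3.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a41 * k1[s] + a42 * k2[s] + a43 * k3[s]);
    deriv(pb, comp, reactive, stims, t0 + t + c4 * h, ytmp.data(), k4.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a51 * k1[s] + a52 * k2[s] + a53 * k3[s] +
                            a54 * k4[s]);
    deriv(pb, comp, reactive, stims, t0 + t + c5 * h, ytmp.data(), k5.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a61 * k1[s] + a62 * k2[s] + a63 * k3[s] +
                            a64 * k4[s] + a65 * k5[s]);
    deriv(pb, comp, reactive, stims, t0 + t + c6 * h, ytmp.data(), k6.data());

    double errmax = 0.0;
    bool finite = true;
    for (int s = 0; s < ns; ++s) {
      ynew[s] = y[s] + h * (b1 * k1[s] + b3 * k3[s] + b4 * k4[s] + b6 * k6[s]);
      const double err = h * (d1 * k1[s] + d3 * k3[s] + d4 * k4[s] +
                              d5 * k5[s] + d6 * k6[s]);
      const double sc = pb.atol +
          pb.rtol * std::max(std::fabs(y[s]), std::fabs(ynew[s]));
      const double e = std::fabs(err) / sc;
      if (e > errmax) errmax = e;
      if (!std::isfinite(ynew[s]) || !std::isfinite(err)) finite = false;
    }
    if (!finite) {
      // overshoot in a stiff trial step: retry with a much smaller step
      if (at_floor)
        stop("integration failure: non-finite value (compartment %d, t = %g s)",
             comp + 1, t0 + t);
      h *= 0.1;
      if (h < hmin)
        stop("integration failure: step-size underflow (compartment %d, t = %g s)",
             comp + 1, t0 + t);
      continue;
    }
    if (errmax <= 1.0 || at_floor) {
      t += h;
      for (int s = 0; s < ns; ++s) {
        y[s] = ynew[s];
        if (pb.nonneg[s] && y[s] < 0.0) { y[s] = 0.0; ++pb.clamp_count; }
      }
      double fac = (errmax > 0.0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errmax, -0.25));
    }
    if (h < hmin)
      stop("integration failure: step-size underflow (compartment %d, t = %g s)",
           comp + 1, t0 + t);
    if (++guard > 1000000)
      stop("integration failure: too many substeps (compartment %d)", comp + 1);
  }
}

// ---------------------------------------------------------------------------
// backward-Euler diffusion on the tree (exact sparse solve, no fill-in)
// ---------------------------------------------------------------------------

static void diffuse_species(const Problem& pb, double D, double dt,
                            double* c, std::vector<double>& dwork,
                            std::vector<double>& bwork,
                            std::vector<double>& awork) {
  const int n = pb.n_comp;
  if (D <= 0.0 || n == 1) return;
  for (int i = 0; i < n; ++i) {
    dwork[i] = pb.vol[i];
    bwork[i] = pb.vol[i] * c[i];
    awork[i] = 0.0;
  }
  for (int i = 0; i < n; ++i) {
    const int p = pb.parent[i];
    if (p < 0) continue;
    const double a = dt * D * pb.gfac[i];
    awork[i] = a;
    dwork[i] += a;
    dwork[p] += a;
  }
  int root = -1;
  for (int i = 0; i < n; ++i) {            // children precede parents
    const int p = pb.parent[i];
    if (p < 0) { root = i; continue; }
    const double f = awork[i] / dwork[i];
    dwork[p] -= f * awork[i];
    bwork[p] += f * bwork[i];
  }
  c[root] = bwork[root] / dwork[root];
  for (int i = n - 1; i >= 0; --i) {
    const int p = pb.parent[i];
    if (p < 0) continue;
    c[i] = (bwork[i] + awork[i] * c[p]) / dwork[i];
  }
}

// ---------------------------------------------------------------------------
// parsing
// ---------------------------------------------------------------------------

static Problem parse_problem(List chem, NumericVector D, IntegerVector parent,
                             NumericVector gfac, NumericVector vol,
                             LogicalVector reactive, LogicalVector nonneg,
                             List stim, double rtol, double atol) {
  Problem pb;
  pb.family = as<int>(chem["family"]);
  if (chem.containsElementNamed("par"))
    pb.par = as<std::vector<double> >(chem["par"]);
  if (pb.family == FAM_MASSACTION) {
    List net = chem["network"];
    pb.ma.sub = as<std::vector<int> >(net["sub"]);
    pb.ma.prod = as<std::vector<int> >(net["prod"]);
    pb.ma.sub_ptr = as<std::vector<int> >(net["sub_ptr"]);
    pb.ma.prod_ptr = as<std::vector<int> >(net["prod_ptr"]);
    pb.ma.kf = as<std::vector<double> >(net["kf"]);
    pb.ma.kb = as<std::vector<double> >(net["kb"]);
    pb.ma.enz_e = as<std::vector<int> >(net["enz_e"]);
    pb.ma.enz_s = as<std::vector<int> >(net["enz_s"]);
    pb.ma.enz_p = as<std::vector<int> >(net["enz_p"]);
    pb.ma.kcat = as<std::vector<double> >(net["kcat"]);
    pb.ma.km = as<std::vector<double> >(net["km"]);
  }
  pb.ca_decay = chem.containsElementNamed("ca_decay")
                    ? as<double>(chem["ca_decay"]) : 0.0;
  pb.ca_species = chem.containsElementNamed("ca_species")
                      ? as<int>(chem["ca_species"]) : -1;
  pb.D = as<std::vector<double> >(D);
  pb.parent = as<std::vector<int> >(parent);
  pb.gfac = as<std::vector<double> >(gfac);
  pb.vol = as<std::vector<double> >(vol);
  pb.reactive.assign(reactive.begin(), reactive.end());
  pb.nonneg.assign(nonneg.begin(), nonneg.end());
  pb.n_comp = (int)pb.parent.size();
  pb.n_species = (int)pb.D.size();
  pb.rtol = rtol;
  pb.atol = atol;
  pb.clamp_count = 0;
  for (int i = 0; i < stim.size(); ++i) {
    List s = stim[i];
    Stim st;
    st.site = as<int>(s["site"]);
    st.species = as<int>(s["species"]);
    st.phase = as<double>(s["phase"]);
    st.width = as<double>(s["width"]);
    st.amp = as<double>(s["amp"]);
    st.krelax = as<double>(s["krelax"]);
    st.kind = as<int>(s["kind"]);
    pb.stim.push_back(st);
  }
  return pb;
}

static void react_all(Problem& pb, NumericMatrix& state, double t, double dt) {
  const int n = pb.n_comp, ns = pb.n_species;
  std::vector<double> y(ns);
  std::vector<const Stim*> stims;
  for (int i = 0; i < n; ++i) {
    stims.clear();
    for (size_t k = 0; k < pb.stim.size(); ++k)
      if (pb.stim[k].site == i) stims.push_back(&pb.stim[k]);
    const bool reactive = pb.reactive[i] != 0;
    const bool has_ca = pb.ca_species >= 0;
    if (!reactive && stims.empty()) {
      // only first-order removal of the input species acts here: exact update
      if (has_ca && pb.ca_decay > 0.0)
        state(pb.ca_species, i) *= std::exp(-pb.ca_decay * dt);
      continue;
    }
    for (int s = 0; s < ns; ++s) y[s] = state(s, i);
    for (int s = 0; s < ns; ++s)
      if (!std::isfinite(y[s]))
        stop("integration failure: non-finite value (species %d, compartment %d)",
             s + 1, i + 1);
    rkf45(pb, i, reactive, stims, t, dt, y.data());
    if (reactive) {
      for (int s = 0; s < ns; ++s) state(s, i) = y[s];
    } else {
      // masked compartment: only stimulus deposition and input decay apply
      if (has_ca) state(pb.ca_species, i) = y[pb.ca_species];
      for (size_t k = 0; k < stims.size(); ++k)
        state(stims[k]->species, i) = y[stims[k]->species];
    }
  }
}

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_step(NumericMatrix state, NumericVector D, double dt,
                               IntegerVector parent, NumericVector gfac,
                               NumericVector vol) {
  const int ns = state.nrow(), n = state.ncol();
  Problem pb;
  pb.parent = as<std::vector<int> >(parent);
  pb.gfac = as<std::vector<double> >(gfac);
  pb.vol = as<std::vector<double> >(vol);
  pb.n_comp = n;
  NumericMatrix out(clone(state));
  std::vector<double> dwork(n), bwork(n), awork(n), c(n);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < n; ++i) {
      c[i] = out(s, i);
      if (!std::isfinite(c[i]))
        stop("integration failure: non-finite value (species %d, compartment %d)",
             s + 1, i + 1);
    }
    diffuse_species(pb, D[s], dt, c.data(), dwork, bwork, awork);
    for (int i = 0; i < n; ++i) out(s, i) = c[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_react_step(NumericMatrix state, List chem, NumericVector D,
                    IntegerVector parent, NumericVector gfac, NumericVector vol,
                    LogicalVector reactive, LogicalVector nonneg, List stim,
                    double t, double dt, double rtol, double atol) {
  Problem pb = parse_problem(chem, D, parent, gfac, vol, reactive, nonneg,
                             stim, rtol, atol);
  NumericMatrix out(clone(state));
  react_all(pb, out, t, dt);
  return List::create(_["state"] = out, _["n_clamped"] = (double)pb.clamp_count);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix state0, List chem, NumericVector D,
             IntegerVector parent, NumericVector gfac, NumericVector vol,
             LogicalVector reactive, LogicalVector nonneg, List stim,
             double dt_diff, double dt_rec, double t_end, double rtol,
             double atol, bool strang) {
  Problem pb = parse_problem(chem, D, parent, gfac, vol, reactive, nonneg,
                             stim, rtol, atol);
  const int ns = pb.n_species, n = pb.n_comp;
  NumericMatrix state(clone(state0));

  const int n_steps = (int)std::lround(t_end / dt_diff);
  const int rec_every = (int)std::lround(dt_rec / dt_diff);
  const int n_rec = n_steps / rec_every + 1;
  NumericVector traj(Dimension(n_rec, ns, n));
  NumericVector times(n_rec);

  std::vector<double> dwork(n), bwork(n), awork(n), c(n);
  int irec = 0;
  times[0] = 0.0;
  for (int s = 0; s < ns; ++s)
    for (int i = 0; i < n; ++i) traj[0 + n_rec * (s + ns * i)] = state(s, i);
  ++irec;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt_diff;
    if (strang) {
      react_all(pb, state, t, dt_diff / 2.0);
    } else {
      react_all(pb, state, t, dt_diff);
    }
    for (int s = 0; s < ns; ++s) {
      if (pb.D[s] <= 0.0) continue;
      for (int i = 0; i < n; ++i) c[i] = state(s, i);
      diffuse_species(pb, pb.D[s], dt_diff, c.data(), dwork, bwork, awork);
      for (int i = 0; i < n; ++i) state(s, i) = c[i];
    }
    if (strang) react_all(pb, state, t + dt_diff / 2.0, dt_diff / 2.0);

    if ((step + 1) % rec_every == 0) {
      times[irec] = (step + 1) * dt_diff;
      for (int s = 0; s < ns; ++s)
        for (int i = 0; i < n; ++i)
          traj[irec + n_rec * (s + ns * i)] = state(s, i);
      ++irec;
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = times, _["traj"] = traj,
                      _["final"] = state,
                      _["n_clamped"] = (double)pb.clamp_count);
}
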