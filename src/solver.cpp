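// Branched cable solver: Crank-Nicolson voltage update on a Hines-ordered
// tree, staggered exponential-integrator gate updates, bi-exponential
// synapses, submembrane Ca pools, current injection and ideal waveform clamp.
//
// Units: V mV, t ms, I nA, g uS, C nF, axial resistance MOhm, area um2,
// densities S/cm2, [Ca] uM. Outward membrane current positive.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TAU_MIN = 0.05;   // ms, stiffness clamp on gate taus
static const double V_LO = -150.0, V_HI = 80.0;   // divergence guard
static const double TBL_LO = -150.0, TBL_HI = 80.0, TBL_DV = 0.02;

struct Gate {
  double vhalf, k, tau_base, tau_amp, tau_center, tau_width;
  int power;
  // lookup tables on the voltage grid: steady state and exp(-dt/tau)
  std::vector<double> xinf_tbl, edt_tbl;
};

struct Channel {
  std::string name;
  double erev;
  bool is_ca;        // contributes to the Ca pool
  int ca_dep;        // 0 none, 1 Hill activation by [Ca]
  double ca50, hill;
  std::vector<Gate> gates;
  std::vector<int> comps;        // compartments with nonzero density
  std::vector<double> gbar_uS;   // density * area * 1e-2, per listed comp
  std::vector<double> gdens;     // S/cm2, per listed comp (for Ca flux)
  int gate0;                     // column offset into the gate state matrix
};

static inline double gate_xinf(const Gate& g, double v) {
  return 1.0 / (1.0 + std::exp(-(v - g.vhalf) / g.k));
}
static inline double gate_tau(const Gate& g, double v) {
  double z = (v - g.tau_center) / g.tau_width;
  double tau = g.tau_base + g.tau_amp * std::exp(-z * z);
  return tau < TAU_MIN ? TAU_MIN : tau;
}
static inline double tbl_interp(const std::vector<double>& tbl, double v) {
  if (v <= TBL_LO) return tbl.front();
  if (v >= TBL_HI) return tbl.back();
  double x = (v - TBL_LO) / TBL_DV;
  int i = (int)x;
  double f = x - i;
  return tbl[i] * (1.0 - f) + tbl[i + 1] * f;
}
static inline double powi(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List morph, List chans_in, NumericMatrix gdens,
                  List capool, List syn, List iclamps, RObject vclamp,
                  List record, double tstop, double dt, double dt_out,
                  RObject state0, int spike_comp, double spike_thresh,
                  double refractory) {
  // ---- morphology ----
  IntegerVector parent = morph["parent"];     // 0-based, -1 root
  NumericVector ra     = morph["ra"];         // MOhm to parent
  NumericVector area   = morph["area"];       // um2
  NumericVector cmv    = morph["cm"];         // uF/cm2
  const int n = parent.size();

  std::vector<double> cap(n);                 // nF
  for (int i = 0; i < n; ++i) cap[i] = cmv[i] * area[i] * 1e-5;
  std::vector<double> kax(n, 0.0);            // 1/ra coupling to parent
  for (int i = 0; i < n; ++i) if (parent[i] >= 0) kax[i] = 1.0 / ra[i];

  // ---- channels ----
  const int nch = chans_in.size();
  std::vector<Channel> ch(nch);
  int ngate_tot = 0;
  for (int c = 0; c < nch; ++c) {
    List L = chans_in[c];
    ch[c].name  = as<std::string>(L["name"]);
    ch[c].erev  = as<double>(L["erev"]);
    ch[c].is_ca = as<bool>(L["is_ca"]);
    ch[c].ca_dep = as<int>(L["ca_dep"]);
    ch[c].ca50 = as<double>(L["ca50"]);
    ch[c].hill = as<double>(L["hill"]);
    List gl = L["gates"];
    ch[c].gate0 = ngate_tot;
    for (int g = 0; g < gl.size(); ++g) {
      List G = gl[g];
      Gate gg;
      gg.vhalf = as<double>(G["vhalf"]);
      gg.k     = as<double>(G["k"]);
      gg.power = as<int>(G["power"]);
      gg.tau_base   = as<double>(G["tau_base"]);
      gg.tau_amp    = as<double>(G["tau_amp"]);
      gg.tau_center = as<double>(G["tau_center"]);
      gg.tau_width  = as<double>(G["tau_width"]);
      int ntbl = (int)((TBL_HI - TBL_LO) / TBL_DV) + 2;
      gg.xinf_tbl.resize(ntbl);
      gg.edt_tbl.resize(ntbl);
      for (int t = 0; t < ntbl; ++t) {
        double v = TBL_LO + t * TBL_DV;
        gg.xinf_tbl[t] = gate_xinf(gg, v);
        gg.edt_tbl[t]  = std::exp(-dt / gate_tau(gg, v));
      }
      ch[c].gates.push_back(gg);
      ++ngate_tot;
    }
    for (int i = 0; i < n; ++i) {
      double gd = gdens(i, c);
      if (gd > 0.0) {
        ch[c].comps.push_back(i);
        ch[c].gbar_uS.push_back(gd * area[i] * 1e-2);
        ch[c].gdens.push_back(gd);
      }
    }
  }

  // ---- Ca pools (per compartment: regions may differ in kinetics) ----
  NumericVector ca_tau_v = capool["tau"];
  NumericVector ca_beta_v = capool["beta"];      // uM per (mA/cm2 * ms)
  double ca_rest = as<double>(capool["rest"]);
  std::vector<double> ca_edt_v(n);
  for (int i = 0; i < n; ++i) ca_edt_v[i] = std::exp(-dt / ca_tau_v[i]);

  // ---- synapses ----
  IntegerVector s_comp = syn["comp"];
  NumericVector s_tr = syn["tau_rise"], s_td = syn["tau_decay"];
  NumericVector s_gp = syn["gpeak"], s_er = syn["erev"];
  NumericVector s_ev = syn["events"];
  IntegerVector s_off = syn["ev_offset"];       // length nsyn+1, 0-based
  const int nsyn = s_comp.size();
  std::vector<double> sA(nsyn, 0.0), sB(nsyn, 0.0);
  std::vector<double> s_da(nsyn), s_db(nsyn), s_norm(nsyn);
  std::vector<int> s_ptr(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    double tr = s_tr[s], td = s_td[s];
    s_da[s] = std::exp(-0.5 * dt / tr);
    s_db[s] = std::exp(-0.5 * dt / td);
    double tp = tr * td / (td - tr) * std::log(td / tr);
    s_norm[s] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    s_ptr[s] = s_off[s];
  }

  // ---- current injections ----
  IntegerVector ic_comp = iclamps["comp"];
  NumericVector ic_amp = iclamps["amp"], ic_t0 = iclamps["t0"],
                ic_t1 = iclamps["t1"];
  const int nic = ic_comp.size();

  // ---- voltage clamp (at most one compartment) ----
  bool has_vc = !vclamp.isNULL();
  int vc_comp = -1;
  NumericVector vc_t, vc_v;
  int vc_ptr = 0;
  if (has_vc) {
    List vc(vclamp);
    vc_comp = as<int>(vc["comp"]);
    vc_t = vc["t"];
    vc_v = vc["v"];
  }

  // ---- recorders ----
  IntegerVector rec_v = record["v"];
  IntegerVector rec_ca = record["ca"];
  List rec_iax = record["iax"];     // list(a=, b=, r=) adjacent pairs
  IntegerVector ax_a = rec_iax["a"], ax_b = rec_iax["b"];
  NumericVector ax_r = rec_iax["r"];
  List rec_ich = record["ichan"];   // list(comp=, chan=) 0-based
  IntegerVector ich_comp = rec_ich["comp"], ich_chan = rec_ich["chan"];

  const long nstep = (long)std::floor(tstop / dt + 0.5);
  const int every = (int)std::floor(dt_out / dt + 0.5);
  const long nout = nstep / every + 1;
  NumericMatrix out_v(nout, rec_v.size());
  NumericMatrix out_ca(nout, rec_ca.size());
  NumericMatrix out_iax(nout, ax_a.size());
  NumericMatrix out_ich(nout, ich_comp.size());
  NumericVector out_t(nout);
  NumericVector out_ivc(has_vc ? nout : 0);
  std::vector<double> spikes;

  // ---- state ----
  std::vector<double> V(n), Ca(n, ca_rest);
  std::vector<double> X((size_t)n * ngate_tot);
  if (state0.isNULL()) {
    stop("state0 must be supplied (list(v=, gates=, ca=) or v_init scalar handled in R)");
  }
  {
    List st(state0);
    NumericVector v0 = st["v"];
    NumericMatrix x0 = st["gates"];
    NumericVector c0 = st["ca"];
    for (int i = 0; i < n; ++i) { V[i] = v0[i]; Ca[i] = c0[i]; }
    for (int g = 0; g < ngate_tot; ++g)
      for (int i = 0; i < n; ++i) X[(size_t)g * n + i] = x0(i, g);
  }

  std::vector<double> Gm(n), bm(n), Iinj(n);
  std::vector<double> diag(n), rhs(n), Vnew(n);
  double last_spike = -1e9;
  double v_prev_soma = V[spike_comp];

  // sample t = 0
  long orow = 0;
  {
    out_t[orow] = 0.0;
    for (int j = 0; j < rec_v.size(); ++j) out_v(orow, j) = V[rec_v[j]];
    for (int j = 0; j < rec_ca.size(); ++j) out_ca(orow, j) = Ca[rec_ca[j]];
    for (int j = 0; j < ax_a.size(); ++j)
      out_iax(orow, j) = (V[ax_a[j]] - V[ax_b[j]]) / ax_r[j];
    for (int j = 0; j < ich_comp.size(); ++j) out_ich(orow, j) = 0.0;
    if (has_vc) out_ivc[orow] = 0.0;
    ++orow;
  }

  for (long step = 0; step < nstep; ++step) {
    double t = step * dt;
    double t_half = t + 0.5 * dt;
    double t_new = t + dt;

    // --- gates: exponential integrator against V(t) ---
    for (int c = 0; c < nch; ++c) {
      Channel& C = ch[c];
      for (size_t g = 0; g < C.gates.size(); ++g) {
        Gate& G = C.gates[g];
        double* x = &X[(size_t)(C.gate0 + g) * n];
        const std::vector<int>& idx = C.comps;
        for (size_t q = 0; q < idx.size(); ++q) {
          int i = idx[q];
          double xinf = tbl_interp(G.xinf_tbl, V[i]);
          double edt = tbl_interp(G.edt_tbl, V[i]);
          x[i] = xinf + (x[i] - xinf) * edt;
        }
      }
    }

    // --- membrane conductances/currents (gates frozen) ---
    std::fill(Gm.begin(), Gm.end(), 0.0);
    std::fill(bm.begin(), bm.end(), 0.0);
    std::fill(Iinj.begin(), Iinj.end(), 0.0);

    for (int c = 0; c < nch; ++c) {
      Channel& C = ch[c];
      const std::vector<int>& idx = C.comps;
      for (size_t q = 0; q < idx.size(); ++q) {
        int i = idx[q];
        double p = 1.0;
        for (size_t g = 0; g < C.gates.size(); ++g)
          p *= powi(X[(size_t)(C.gate0 + g) * n + i], C.gates[g].power);
        if (C.ca_dep == 1) {
          double cn = std::pow(Ca[i], C.hill);
          p *= cn / (cn + std::pow(C.ca50, C.hill));
        }
        double g_uS = C.gbar_uS[q] * p;
        Gm[i] += g_uS;
        bm[i] += g_uS * C.erev;
      }
    }

    // --- synapses: advance to half step, add events ---
    for (int s = 0; s < nsyn; ++s) {
      sA[s] *= s_da[s]; sB[s] *= s_db[s];
      while (s_ptr[s] < s_off[s + 1] && s_ev[s_ptr[s]] <= t_half) {
        sA[s] += 1.0; sB[s] += 1.0; ++s_ptr[s];
      }
      double g_uS = s_gp[s] * 1e-3 * s_norm[s] * (sB[s] - sA[s]);
      if (g_uS < 0) g_uS = 0;
      int i = s_comp[s];
      Gm[i] += g_uS;
      bm[i] += g_uS * s_er[s];
    }

    // --- injections active at half step ---
    for (int j = 0; j < nic; ++j)
      if (t_half >= ic_t0[j] && t_half < ic_t1[j]) Iinj[ic_comp[j]] += ic_amp[j];

    // --- clamp target at t_new (piecewise-linear waveform) ---
    double vc_target = 0.0;
    if (has_vc) {
      while (vc_ptr + 1 < vc_t.size() - 0 && vc_t[vc_ptr + 1] < t_new) ++vc_ptr;
      if (vc_ptr + 1 >= vc_t.size()) {
        vc_target = vc_v[vc_t.size() - 1];
      } else {
        double t0 = vc_t[vc_ptr], t1 = vc_t[vc_ptr + 1];
        double f = (t_new - t0) / (t1 - t0);
        if (f < 0) f = 0; if (f > 1) f = 1;
        vc_target = vc_v[vc_ptr] * (1 - f) + vc_v[vc_ptr + 1] * f;
      }
    }

    // --- Crank-Nicolson tree solve ---
    // (C/dt + G/2 + sum_k/2) V+ - sum (k/2) V+_nb =
    //   C/dt V - G/2 V + b + Iinj + sum (k/2)(V_nb - V)
    for (int i = 0; i < n; ++i) {
      diag[i] = cap[i] / dt + 0.5 * Gm[i];
      rhs[i] = cap[i] / dt * V[i] - 0.5 * Gm[i] * V[i] + bm[i] + Iinj[i];
    }
    for (int i = 0; i < n; ++i) {
      int p = parent[i];
      if (p >= 0) {
        double k2 = 0.5 * kax[i];
        diag[i] += k2; diag[p] += k2;
        rhs[i] += k2 * (V[p] - V[i]);
        rhs[p] += k2 * (V[i] - V[p]);
      }
    }
    if (has_vc) { diag[vc_comp] = 1.0; rhs[vc_comp] = vc_target; }
    // eliminate children into parents (reverse Hines order)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double k2 = 0.5 * kax[i];
      if (has_vc && i == vc_comp) {
        rhs[p] += k2 * vc_target;          // known value moves to rhs
      } else if (has_vc && p == vc_comp) {
        // parent row is identity; drop coupling (child keeps its term)
        ;
      } else {
        diag[p] -= k2 * k2 / diag[i];
        rhs[p] += k2 * rhs[i] / diag[i];
      }
    }
    Vnew[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      if (has_vc && i == vc_comp) { Vnew[i] = vc_target; continue; }
      Vnew[i] = (rhs[i] + 0.5 * kax[i] * Vnew[p]) / diag[i];
    }

    // --- divergence guard ---
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(Vnew[i]) || Vnew[i] < V_LO || Vnew[i] > V_HI) {
        stop("solver divergence at t=%.3f ms, compartment %d, V=%.1f mV",
             t_new, i + 1, Vnew[i]);
      }
    }

    // --- Ca pools: flux from Ca channels at the half-step voltage ---
    for (int c = 0; c < nch; ++c) {
      Channel& C = ch[c];
      if (!C.is_ca) continue;
      const std::vector<int>& idx = C.comps;
      for (size_t q = 0; q < idx.size(); ++q) {
        int i = idx[q];
        double p = 1.0;
        for (size_t g = 0; g < C.gates.size(); ++g)
          p *= powi(X[(size_t)(C.gate0 + g) * n + i], C.gates[g].power);
        double vh = 0.5 * (V[i] + Vnew[i]);
        double ica = C.gdens[q] * p * (vh - C.erev); // mA/cm2, <0 inward
        double ca_inf = ca_rest - ca_beta_v[i] * ca_tau_v[i] * ica;
        if (ca_inf < 0) ca_inf = 0;
        Ca[i] = ca_inf + (Ca[i] - ca_inf) * ca_edt_v[i];
      }
    }
    // pools with no Ca channel relax to rest implicitly (stay at rest)

    // --- clamp current ---
    double ivc = 0.0;
    if (has_vc) {
      int i = vc_comp;
      ivc = cap[i] * (Vnew[i] - V[i]) / dt + Gm[i] * 0.5 * (V[i] + Vnew[i]) -
            bm[i] - Iinj[i];
      int p = parent[i];
      if (p >= 0) ivc -= 0.5 * kax[i] * ((V[p] - V[i]) + (Vnew[p] - Vnew[i]));
      for (int j = 0; j < n; ++j)
        if (parent[j] == i)
          ivc -= 0.5 * kax[j] * ((V[j] - V[i]) + (Vnew[j] - Vnew[i]));
    }

    // --- somatic spike detection (upward crossing with lockout) ---
    double v_soma = Vnew[spike_comp];
    if (v_prev_soma < spike_thresh && v_soma >= spike_thresh &&
        t_new - last_spike >= refractory) {
      spikes.push_back(t_new);
      last_spike = t_new;
    }
    v_prev_soma = v_soma;

    std::swap(V, Vnew);

    // --- sample ---
    if ((step + 1) % every == 0) {
      out_t[orow] = t_new;
      for (int j = 0; j < rec_v.size(); ++j) out_v(orow, j) = V[rec_v[j]];
      for (int j = 0; j < rec_ca.size(); ++j) out_ca(orow, j) = Ca[rec_ca[j]];
      for (int j = 0; j < ax_a.size(); ++j)
        out_iax(orow, j) = (V[ax_a[j]] - V[ax_b[j]]) / ax_r[j];
      for (int j = 0; j < ich_comp.size(); ++j) {
        int i = ich_comp[j], c = ich_chan[j];
        Channel& C = ch[c];
        double g_uS = 0.0;
        for (size_t q = 0; q < C.comps.size(); ++q)
          if (C.comps[q] == i) {
            double p = 1.0;
            for (size_t g = 0; g < C.gates.size(); ++g)
              p *= powi(X[(size_t)(C.gate0 + g) * n + i], C.gates[g].power);
            if (C.ca_dep == 1) {
              double cn = std::pow(Ca[i], C.hill);
              p *= cn / (cn + std::pow(C.ca50, C.hill));
            }
            g_uS = C.gbar_uS[q] * p;
            break;
          }
        out_ich(orow, j) = g_uS * (V[i] - C.erev);
      }
      if (has_vc) out_ivc[orow] = ivc;
      ++orow;
    }
  }

  // final gate state matrix
  NumericMatrix xout(n, ngate_tot);
  for (int g = 0; g < ngate_tot; ++g)
    for (int i = 0; i < n; ++i) xout(i, g) = X[(size_t)g * n + i];
  NumericVector vout(n), caout(n);
  for (int i = 0; i < n; ++i) { vout[i] = V[i]; caout[i] = Ca[i]; }

  return List::create(
    _["t"] = out_t, _["v"] = out_v, _["ca"] = out_ca, _["iax"] = out_iax,
    _["ichan"] = out_ich, _["i_clamp"] = out_ivc,
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["state"] = List::create(_["v"] = vout, _["gates"] = xout,
                              _["ca"] = caout));
}

// Steady-state gate values for an initialisation voltage.
// [[Rcpp::export(name = ".cpp_gate_init")]]
NumericMatrix cpp_gate_init(List chans_in, int n, double v) {
  int ngate_tot = 0;
  for (int c = 0; c < chans_in.size(); ++c) {
    List L = chans_in[c];
    List gl = L["gates"];
    ngate_tot += gl.size();
  }
  NumericMatrix X(n, ngate_tot);
  int g0 = 0;
  for (int c = 0; c < chans_in.size(); ++c) {
    List L = chans_in[c];
    List gl = L["gates"];
    for (int g = 0; g < gl.size(); ++g) {
      List G = gl[g];
      double vhalf = as<double>(G["vhalf"]);
      double k = as<double>(G["k"]);
      double xinf = 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
      for (int i = 0; i < n; ++i) X(i, g0) = xinf;
      ++g0;
    }
  }
  return X;
}
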