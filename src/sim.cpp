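// Exponential-Euler integrator for 1-2 compartment conductance-based models.
// Gates use Hodgkin-Huxley first-order kinetics with Boltzmann steady states;
// steady states and per-step decay factors are tabulated on a voltage grid
// (the usual trick in compiled neuron simulators) so the inner loop is
// lookup + lerp. Units: mV, ms, pA, nS, pF.
//
// Channel matrix layout (28 columns, built by .encode_channels in R):
//  0 E_rev, 1 g_nS,
//  2 has_act, 3 aVh, 4 ak, 5 aexp, 6 atau_type, 7..10 atau params,
// 11 n_inact,
// 12..19 inact1: Vh, k, tau_type, tp1..tp4, fraction
// 20..27 inact2: same

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double V_LO = -160.0, V_HI = 100.0, V_STEP = 0.2;
const int NTAB = (int)((V_HI - V_LO) / V_STEP) + 2;

struct GateTab {
  // interleaved (xinf, fac) pairs so one lookup touches one cache line
  std::vector<double> tab;
  int expo;
};

inline double boltz(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp(-(V - Vh) / k));
}

inline double tau_of(double V, int type, const double* p) {
  if (type == 0) return p[0];
  double z = (V - p[2]) / p[3];
  return p[0] + (p[1] - p[0]) * std::exp(-z * z);
}

GateTab build_gate(double Vh, double k, int expo, int tau_type,
                   const double* taup, double dt) {
  GateTab g;
  g.expo = expo;
  g.tab.resize(2 * NTAB);
  for (int i = 0; i < NTAB; ++i) {
    double V = V_LO + i * V_STEP;
    g.tab[2 * i] = boltz(V, Vh, k);
    g.tab[2 * i + 1] = std::exp(-dt / tau_of(V, tau_type, taup));
  }
  return g;
}

// advance first-order gate state x by one step at table position (i0, w)
inline double gate_step(const GateTab& g, int i0, double w, double x) {
  const double* a = &g.tab[2 * i0];
  double xinf = a[0] * (1 - w) + a[2] * w;
  double fac = a[1] * (1 - w) + a[3] * w;
  return xinf + (x - xinf) * fac;
}

inline void lut(double V, int& i0, double& w) {
  double u = (V - V_LO) / V_STEP;
  if (u < 0) u = 0;
  if (u > NTAB - 2) u = NTAB - 2;
  i0 = (int)u;
  w = u - i0;
}

inline double powi(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

struct Chan {
  double E, g;
  bool has_act;
  GateTab act;
  int ninact;
  GateTab in1, in2;
  double f1, f2;
  // state
  double m, h1, h2;
};

struct Comp {
  double C, gc;
  std::vector<Chan> ch;
};

void init_states(Comp& cp, double V) {
  for (auto& c : cp.ch) {
    int i0; double w;
    lut(V, i0, w);
    auto inf = [&](const GateTab& g) {
      return g.tab[2 * i0] * (1 - w) + g.tab[2 * (i0 + 1)] * w;
    };
    if (c.has_act) c.m = inf(c.act);
    if (c.ninact >= 1) c.h1 = inf(c.in1);
    if (c.ninact >= 2) c.h2 = inf(c.in2);
  }
}

std::vector<Comp> build_comps(const List& comps, double dt) {
  std::vector<Comp> out;
  for (int ci = 0; ci < comps.size(); ++ci) {
    List cl = comps[ci];
    Comp cp;
    cp.C = as<double>(cl["C_pF"]);
    cp.gc = as<double>(cl["coupling_nS"]);
    NumericMatrix M = cl["channels"];
    for (int r = 0; r < M.nrow(); ++r) {
      Chan c;
      c.E = M(r, 0);
      c.g = M(r, 1);
      c.m = 1.0; c.h1 = 1.0; c.h2 = 1.0;
      c.has_act = M(r, 2) > 0.5;
      if (c.has_act) {
        double taup[4] = {M(r, 7), M(r, 8), M(r, 9), M(r, 10)};
        c.act = build_gate(M(r, 3), M(r, 4), (int)M(r, 5), (int)M(r, 6),
                           taup, dt);
      }
      c.ninact = (int)M(r, 11);
      if (c.ninact >= 1) {
        double taup[4] = {M(r, 15), M(r, 16), M(r, 17), M(r, 18)};
        c.in1 = build_gate(M(r, 12), M(r, 13), 1, (int)M(r, 14), taup, dt);
        c.f1 = M(r, 19);
      }
      if (c.ninact >= 2) {
        double taup[4] = {M(r, 23), M(r, 24), M(r, 25), M(r, 26)};
        c.in2 = build_gate(M(r, 20), M(r, 21), 1, (int)M(r, 22), taup, dt);
        c.f2 = M(r, 27);
      }
      cp.ch.push_back(c);
    }
    out.push_back(cp);
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".sim_cc_cpp")]]
NumericMatrix sim_cc_cpp(List comps, NumericMatrix stim_pA, double dt_ms,
                         int oversample, NumericVector V_init,
                         NumericVector bias_pA) {
  const int ncomp = comps.size();
  const int nout = stim_pA.nrow();
  const double dt = dt_ms / oversample;
  std::vector<Comp> cp = build_comps(comps, dt);
  std::vector<double> V(ncomp);
  for (int i = 0; i < ncomp; ++i) {
    V[i] = V_init[i];
    init_states(cp[i], V[i]);
  }
  NumericMatrix out(nout, ncomp);
  for (int n = 0; n < nout; ++n) {
    for (int i = 0; i < ncomp; ++i) out(n, i) = V[i];
    for (int s = 0; s < oversample; ++s) {
      double Vold[2] = {V[0], ncomp > 1 ? V[1] : 0.0};
      for (int i = 0; i < ncomp; ++i) {
        Comp& K = cp[i];
        int i0; double w;
        lut(Vold[i], i0, w);
        double gtot = 0.0, Isrc = stim_pA(n, i) + bias_pA[i];
        for (auto& c : K.ch) {
          if (c.g == 0) continue;
          double open = 1.0;
          if (c.has_act) {
            c.m = gate_step(c.act, i0, w, c.m);
            open = (c.act.expo == 1) ? c.m : powi(c.m, c.act.expo);
          }
          if (c.ninact >= 1) {
            c.h1 = gate_step(c.in1, i0, w, c.h1);
            double H = c.f1 * c.h1;
            if (c.ninact >= 2) {
              c.h2 = gate_step(c.in2, i0, w, c.h2);
              H += c.f2 * c.h2;
            }
            open *= H;
          }
          double gg = c.g * open;
          gtot += gg;
          Isrc += gg * c.E;
        }
        if (ncomp > 1) {
          gtot += K.gc;
          Isrc += K.gc * Vold[1 - i];
        }
        double a = gtot * dt / K.C;
        if (a > 1e-10) {
          double Vinf = Isrc / gtot;
          V[i] = Vinf + (Vold[i] - Vinf) * std::exp(-a);
        } else {
          V[i] = Vold[i] + dt * Isrc / K.C;
        }
        if (!std::isfinite(V[i]) || std::fabs(V[i]) > 200.0) {
          stop("integration blow-up (|V| > 200 mV) at t = %f ms",
               (n + (double)s / oversample) * dt_ms);
        }
      }
    }
  }
  return out;
}
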