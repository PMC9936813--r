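#ifndef OLM_MODEL_H
#define OLM_MODEL_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Internal C++ mirror of the R-side membrane model description.
// Units: mV, ms, uS, pA, pF.  Ionic currents are outward-positive:
//   I_x [pA] = 1000 * gbar[uS] * prod(gates^power) * (V - Erev)[mV].

struct Gate {
  int power;
  double vh, k;            // Boltzmann steady state: 1/(1+exp((vh-V)/k))
  int tauform;             // 0 = constant, 1 = sigmoid-sum bell
  double tb, ta, v1, k1, v2, k2;

  inline double inf(double V) const {
    return 1.0 / (1.0 + std::exp((vh - V) / k));
  }
  inline double tau(double V) const {
    if (tauform == 0) return tb;
    return tb + ta / (std::exp((V - v1) / k1) + std::exp(-(V - v2) / k2));
  }
};

struct Chan {
  double gbar;             // total uS
  double erev;             // mV
  int ngate;
  Gate g[2];
  int gidx[2];             // index into the flat gating state vector
};

struct Model {
  double C;                // pF
  double gl;               // leak, uS
  double el;               // mV
  int nchan;
  int ngates;
  std::vector<Chan> ch;
};

inline Model parse_model(const Rcpp::List &m) {
  Model mod;
  mod.C  = Rcpp::as<double>(m["c_pF"]);
  mod.gl = Rcpp::as<double>(m["gl_uS"]);
  mod.el = Rcpp::as<double>(m["el_mV"]);
  Rcpp::List chans = m["channels"];
  mod.nchan = chans.size();
  mod.ngates = 0;
  for (int i = 0; i < mod.nchan; ++i) {
    Rcpp::List c = chans[i];
    Chan cc;
    cc.gbar = Rcpp::as<double>(c["gbar_uS"]);
    cc.erev = Rcpp::as<double>(c["erev"]);
    Rcpp::List gates = c["gates"];
    cc.ngate = gates.size();
    if (cc.ngate > 2) Rcpp::stop("at most two gates per channel are supported");
    for (int j = 0; j < cc.ngate; ++j) {
      Rcpp::List g = gates[j];
      Gate gg;
      gg.power = Rcpp::as<int>(g["power"]);
      gg.vh = Rcpp::as<double>(g["vh"]);
      gg.k  = Rcpp::as<double>(g["k"]);
      Rcpp::NumericVector tp = g["tau"];
      gg.tauform = (int)tp[0];
      gg.tb = tp[1];
      if (gg.tauform == 1) {
        gg.ta = tp[2]; gg.v1 = tp[3]; gg.k1 = tp[4]; gg.v2 = tp[5]; gg.k2 = tp[6];
      } else { gg.ta = 0; gg.v1 = 0; gg.k1 = 1; gg.v2 = 0; gg.k2 = 1; }
      cc.g[j] = gg;
      cc.gidx[j] = mod.ngates++;
    }
    mod.ch.push_back(cc);
  }
  return mod;
}

// One forward step: updates V and gates in place given total external
// current (pA, inward-depolarizing positive) held over [t, t+dt).
// Returns the summed ionic current (pA, outward positive) at entry state.
inline double model_step(const Model &mod, double &V, double *gate,
                         double Iext_pA, double dt) {
  double Iion = 1000.0 * mod.gl * (V - mod.el);
  for (int i = 0; i < mod.nchan; ++i) {
    const Chan &c = mod.ch[i];
    double open = 1.0;
    for (int j = 0; j < c.ngate; ++j) {
      double x = gate[c.gidx[j]];
      for (int p = 0; p < c.g[j].power; ++p) open *= x;
    }
    Iion += 1000.0 * c.gbar * open * (V - c.erev);
  }
  // exponential-Euler gate update at the entry voltage
  for (int i = 0; i < mod.nchan; ++i) {
    const Chan &c = mod.ch[i];
    for (int j = 0; j < c.ngate; ++j) {
      const Gate &g = c.g[j];
      double xinf = g.inf(V), xt = g.tau(V);
      double &x = gate[c.gidx[j]];
      x = xinf + (x - xinf) * std::exp(-dt / xt);
      if (x < 0.0) x = 0.0; else if (x > 1.0) x = 1.0;
    }
  }
  V += dt * (Iext_pA - Iion) / mod.C;
  return Iion;
}

#endif
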