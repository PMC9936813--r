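#include "olm_model.h"
using namespace Rcpp;

// Core fixed-step integrator.  `istim` (pA, length n) defines the time grid;
// optional conductance inputs ge/gi/gp (uS, length n or 0) model synaptic
// drive with reversals ee/ei/ep.  Negative conductance samples are clipped
// to zero at use time.  Outputs are aligned with the input grid: sample k
// holds the state and currents over [k*dt, (k+1)*dt).
//
// record: 0 = V only, 1 = + per-channel currents, 2 = + gating variables.
// [[Rcpp::export]]
List simulate_cpp(List model, NumericVector istim, double dt,
                  double v0, NumericVector gate0,
                  NumericVector ge, NumericVector gi, NumericVector gp,
                  double ee, double ei, double ep,
                  int record) {
  Model mod = parse_model(model);
  const int n = istim.size();
  if (n < 1) stop("empty stimulus");
  const bool has_e = ge.size() > 0, has_i = gi.size() > 0, has_p = gp.size() > 0;
  if ((has_e && ge.size() != n) || (has_i && gi.size() != n) ||
      (has_p && gp.size() != n))
    stop("conductance inputs must match the stimulus length");

  std::vector<double> gate(mod.ngates);
  if (gate0.size() == mod.ngates) {
    for (int i = 0; i < mod.ngates; ++i) gate[i] = gate0[i];
  } else if (gate0.size() == 0) {
    for (int i = 0; i < mod.nchan; ++i)
      for (int j = 0; j < mod.ch[i].ngate; ++j)
        gate[mod.ch[i].gidx[j]] = mod.ch[i].g[j].inf(v0);
  } else stop("gate0 must be empty or of length %d", mod.ngates);

  NumericVector V(n);
  const int ncur = mod.nchan + 1 + (has_e ? 1 : 0) + (has_i ? 1 : 0) + (has_p ? 1 : 0);
  NumericMatrix cur(record >= 1 ? n : 0, record >= 1 ? ncur : 0);
  NumericMatrix gat(record >= 2 ? n : 0, record >= 2 ? mod.ngates : 0);

  double v = v0;
  for (int k = 0; k < n; ++k) {
    V[k] = v;
    if (record >= 2)
      for (int i = 0; i < mod.ngates; ++i) gat(k, i) = gate[i];

    double isyn = 0.0, ie = 0.0, ii = 0.0, ip = 0.0;
    if (has_e) { double g = ge[k] > 0 ? ge[k] : 0; ie = 1000.0 * g * (v - ee); isyn += ie; }
    if (has_i) { double g = gi[k] > 0 ? gi[k] : 0; ii = 1000.0 * g * (v - ei); isyn += ii; }
    if (has_p) { double g = gp[k] > 0 ? gp[k] : 0; ip = 1000.0 * g * (v - ep); isyn += ip; }

    if (record >= 1) {
      // per-channel ionic currents at the entry state
      int col = 0;
      for (int i = 0; i < mod.nchan; ++i) {
        const Chan &c = mod.ch[i];
        double open = 1.0;
        for (int j = 0; j < c.ngate; ++j) {
          double x = gate[c.gidx[j]];
          for (int p = 0; p < c.g[j].power; ++p) open *= x;
        }
        cur(k, col++) = 1000.0 * c.gbar * open * (v - c.erev);
      }
      cur(k, col++) = 1000.0 * mod.gl * (v - mod.el);
      if (has_e) cur(k, col++) = ie;
      if (has_i) cur(k, col++) = ii;
      if (has_p) cur(k, col++) = ip;
    }

    model_step(mod, v, gate.data(), istim[k] - isyn, dt);
    if (!std::isfinite(v))
      stop("integration failure: non-finite membrane potential at t = %.3f ms",
           (k + 1) * dt);
  }

  return List::create(_["V"] = V, _["currents"] = cur, _["gating"] = gat,
                      _["v_end"] = v,
                      _["gate_end"] = NumericVector(gate.begin(), gate.end()));
}

// Steady-state activation and time constant of every gate on a voltage grid
// (used by the voltage-clamp convergence checks and kinetics plots).
// [[Rcpp::export]]
List gate_curves_cpp(List model, NumericVector V) {
  Model mod = parse_model(model);
  const int n = V.size();
  NumericMatrix inf(n, mod.ngates), tau(n, mod.ngates);
  for (int i = 0; i < mod.nchan; ++i)
    for (int j = 0; j < mod.ch[i].ngate; ++j) {
      int gi = mod.ch[i].gidx[j];
      for (int k = 0; k < n; ++k) {
        inf(k, gi) = mod.ch[i].g[j].inf(V[k]);
        tau(k, gi) = mod.ch[i].g[j].tau(V[k]);
      }
    }
  return List::create(_["inf"] = inf, _["tau"] = tau);
}
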