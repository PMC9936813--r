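// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "olm_model.h"
using namespace Rcpp;

// Robust adaptive UKF over the augmented state X = [V, gates, theta],
// theta = conductance densities (S/cm^2) of the four estimated channels,
// propagated as a random walk.  The observation is the membrane voltage
// (linear in X), so the measurement update is computed exactly
// (equivalent to the Kalman update on the predicted moments).
//
// theta_chan: 0-based indices of the estimated channels in model$channels.
// gscale: uS of total conductance per unit density (= area_cm2 * 1e6).
// Adaptation (on fault, eps = nu^2/S > chi2_thresh):
//   delta = max(delta0, (eps - b)/eps);  R <- (1-delta) R + delta Rhat
//   lambda = max(lambda0, (eps - a)/eps);  Q <- (1-lambda) Q + lambda (K nu)(K nu)'
// with Rhat = max(nu^2 - S_pred_noR, r_floor).
// [[Rcpp::export]]
List raukf_cpp(List model, IntegerVector theta_chan, double gscale,
               NumericVector y, NumericVector u, double dt,
               NumericVector theta0, NumericVector P0_diag,
               NumericVector Q0_diag, double R0,
               double alpha, double beta, double kappa,
               double lambda0, double delta0, double a, double b,
               double chi2_thresh, double q_relax_ms, double r_relax_ms,
               int store_every) {
  Model mod = parse_model(model);
  const int N = y.size();
  if (u.size() != N) stop("observation and input must be aligned");
  const int G = mod.ngates, ntheta = theta_chan.size(), n = 1 + G + ntheta;
  if ((int)P0_diag.size() != n || (int)Q0_diag.size() != n)
    stop("P0/Q0 diagonals must have length %d", n);

  arma::vec X(n);
  X[0] = y[0];
  {
    std::vector<double> g0(G);
    for (int i = 0; i < mod.nchan; ++i)
      for (int j = 0; j < mod.ch[i].ngate; ++j)
        g0[mod.ch[i].gidx[j]] = mod.ch[i].g[j].inf(y[0]);
    for (int i = 0; i < G; ++i) X[1 + i] = g0[i];
  }
  for (int i = 0; i < ntheta; ++i) X[1 + G + i] = theta0[i];

  arma::mat P = arma::diagmat(arma::vec(P0_diag.begin(), n));
  arma::vec q0(Q0_diag.begin(), n);
  arma::mat Q = arma::diagmat(q0);
  double R = R0;
  // fault-triggered inflation of Q decays back to the baseline so isolated
  // spike-timing faults do not permanently loosen the parameter random walk
  const double qrho = q_relax_ms > 0 ? std::exp(-dt / q_relax_ms) : 1.0;
  const double rrho = r_relax_ms > 0 ? std::exp(-dt / r_relax_ms) : 1.0;

  const double lam = alpha * alpha * (n + kappa) - n;
  const double gamma = std::sqrt(n + lam);
  arma::vec wm(2 * n + 1), wc(2 * n + 1);
  wm.fill(1.0 / (2.0 * (n + lam)));
  wc = wm;
  wm[0] = lam / (n + lam);
  wc[0] = wm[0] + 1.0 - alpha * alpha + beta;

  const int nstore = (N + store_every - 1) / store_every;
  NumericMatrix theta_path(nstore, ntheta), se_path(nstore, ntheta);
  NumericVector t_path(nstore), vhat_path(nstore);
  std::vector<int> faults;
  int si = 0;
  double innov_ss = 0.0;

  arma::mat sig(n, 2 * n + 1);
  arma::mat Xp(n, 2 * n + 1);

  for (int k = 1; k < N; ++k) {
    // --- sigma points from (X, P)
    arma::mat L;
    bool ok = arma::chol(L, P, "lower");
    if (!ok) {
      double jit = 1e-12 * (1.0 + arma::trace(P) / n);
      for (int t = 0; t < 8 && !ok; ++t, jit *= 100.0)
        ok = arma::chol(L, P + jit * arma::eye(n, n), "lower");
      if (!ok) stop("sigma-point decomposition failed at sample %d", k);
    }
    sig.col(0) = X;
    for (int i = 0; i < n; ++i) {
      sig.col(1 + i)     = X + gamma * L.col(i);
      sig.col(1 + n + i) = X - gamma * L.col(i);
    }

    // --- propagate each sigma point one model step (theta: random walk)
    for (int s = 0; s < 2 * n + 1; ++s) {
      double V = sig(0, s);
      std::vector<double> gate(G);
      for (int i = 0; i < G; ++i) {
        double x = sig(1 + i, s);
        gate[i] = x < 0 ? 0 : (x > 1 ? 1 : x);
      }
      for (int i = 0; i < ntheta; ++i) {
        double th = sig(1 + G + i, s);
        mod.ch[theta_chan[i]].gbar = (th > 0 ? th : 0) * gscale;
      }
      model_step(mod, V, gate.data(), u[k - 1], dt);
      if (!std::isfinite(V))
        stop("filter divergence: non-finite propagation at sample %d", k);
      Xp(0, s) = V;
      for (int i = 0; i < G; ++i) Xp(1 + i, s) = gate[i];
      for (int i = 0; i < ntheta; ++i) Xp(1 + G + i, s) = sig(1 + G + i, s);
    }

    // --- predicted moments
    arma::vec xpred = Xp * wm;
    arma::mat D = Xp.each_col() - xpred;
    arma::mat Ppred = D * arma::diagmat(wc) * D.t() + Q;
    Ppred = 0.5 * (Ppred + Ppred.t());

    // --- exact measurement update (observation = V = first component)
    double S = Ppred(0, 0) + R;
    double nu = y[k] - xpred[0];
    arma::vec K = Ppred.col(0) / S;
    X = xpred + K * nu;
    P = Ppred - S * (K * K.t());
    P = 0.5 * (P + P.t());
    innov_ss += nu * nu / S;

    // clamp physical ranges in the mean
    for (int i = 0; i < G; ++i)
      X[1 + i] = std::min(1.0, std::max(0.0, X[1 + i]));
    for (int i = 0; i < ntheta; ++i)
      if (X[1 + G + i] < 0) X[1 + G + i] = 0;

    // --- fault-triggered noise adaptation
    double eps = nu * nu / S;
    if (eps > chi2_thresh) {
      faults.push_back(k);
      double delta = std::max(delta0, (eps - b) / eps);
      double Rhat = std::max(nu * nu - Ppred(0, 0), 1e-6);
      R = (1.0 - delta) * R + delta * Rhat;
      double lambda = std::max(lambda0, (eps - a) / eps);
      arma::vec Kn = K * nu;
      Q = (1.0 - lambda) * Q + lambda * (Kn * Kn.t());
      Q = 0.5 * (Q + Q.t());
    }

    if (qrho < 1.0) {
      Q *= qrho;
      Q.diag() += (1.0 - qrho) * q0;
    }
    if (rrho < 1.0) R = R0 + (R - R0) * rrho;

    if (k % store_every == 0 && si < nstore) {
      t_path[si] = k * dt;
      vhat_path[si] = X[0];
      for (int i = 0; i < ntheta; ++i) {
        theta_path(si, i) = X[1 + G + i];
        se_path(si, i) = std::sqrt(std::max(0.0, P(1 + G + i, 1 + G + i)));
      }
      ++si;
    }
  }

  NumericVector th_fin(ntheta), se_fin(ntheta);
  for (int i = 0; i < ntheta; ++i) {
    th_fin[i] = X[1 + G + i];
    se_fin[i] = std::sqrt(std::max(0.0, P(1 + G + i, 1 + G + i)));
  }
  return List::create(
      _["theta"] = th_fin, _["theta_se"] = se_fin,
      _["t_path"] = t_path[Range(0, std::max(0, si - 1))],
      _["vhat_path"] = vhat_path[Range(0, std::max(0, si - 1))],
      _["theta_path"] = theta_path(Range(0, std::max(0, si - 1)), _),
      _["se_path"] = se_path(Range(0, std::max(0, si - 1)), _),
      _["n_fault"] = (int)faults.size(),
      _["fault_idx"] = IntegerVector(faults.begin(), faults.end()),
      _["R_final"] = R, _["mean_nis"] = innov_ss / std::max(1, N - 1),
      _["P_final"] = wrap(P));
}
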