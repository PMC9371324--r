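// Compiled inner loops: the method-of-characteristics forward stepper for
// separable hazards S(h, r) = exp(h) * base(r), and one backward period of
// the adjoint solver (either the discrete-adjoint transpose of the forward
// step or the direct characteristics discretisation). Coefficient matrices
// for the adjoint are precomputed in R, so arbitrary hazard models work.

#include <Rcpp.h>
using namespace Rcpp;

// Forward integration of the refractory-density scheme for a separable
// hazard and constant external current, with an optional square pulse
// (route 0 = none, 1 = on I_ext, 2 = on the synaptic drive).
// [[Rcpp::export]]
List mf_steps_sep(NumericVector base_, double I_ext, double J_s,
                  double tau_s, double dt, NumericVector q0, double Is0,
                  int n_steps, double t0, int p_route, double p_t0,
                  double p_t1, double p_amp, bool record_q) {
  const int J = q0.size();
  NumericVector q = clone(q0);
  NumericVector qn(J);
  double I_s = Is0;

  const int ns = n_steps + 1;
  NumericVector act(ns), is_tr(ns), h_tr(ns), mass(ns);
  NumericMatrix qrec = record_q ? NumericMatrix(ns, J) : NumericMatrix(0, 0);
  double leak = 0.0;

  double h = I_ext + I_s;
  if (p_route == 1 && t0 >= p_t0 && t0 < p_t1) h += p_amp;
  double eh = std::exp(h);
  double A = 0.0, m0 = 0.0, smax = 0.0;
  for (int j = 0; j < J; ++j) {
    A += eh * base_[j] * q[j];
    m0 += q[j];
    if (base_[j] > smax) smax = base_[j];
  }
  A *= dt; m0 *= dt;
  act[0] = A; is_tr[0] = I_s; h_tr[0] = h; mass[0] = m0;
  if (record_q) for (int j = 0; j < J; ++j) qrec(0, j) = q[j];

  bool warned = false;
  for (int i = 1; i <= n_steps; ++i) {
    double sm = dt * eh * smax;
    if (sm >= 2.0)
      stop("time step too large for this hazard: |1 - dt*S| >= 1 on the grid "
           "(the characteristics scheme is unstable); reduce dt");
    if (sm >= 1.0 && !warned) {
      warning("dt*S exceeds 1 on part of the grid; the decay factor 1 - dt*S "
              "goes negative (still contractive, but accuracy degrades)");
      warned = true;
    }
    double t_now = t0 + (i - 1) * dt;
    double t_next = t0 + i * dt;

    leak += q[J - 1] * (1.0 - dt * eh * base_[J - 1]) * dt;
    for (int j = J - 1; j >= 1; --j)
      qn[j] = q[j - 1] * (1.0 - dt * eh * base_[j - 1]);
    qn[0] = A;

    I_s += dt * (-I_s + J_s * A) / tau_s;
    if (p_route == 2 && t_now >= p_t0 && t_now < p_t1) I_s += dt * p_amp;

    h = I_ext + I_s;
    if (p_route == 1 && t_next >= p_t0 && t_next < p_t1) h += p_amp;
    eh = std::exp(h);

    double Anew = 0.0, m = 0.0;
    for (int j = 0; j < J; ++j) {
      q[j] = qn[j];
      Anew += eh * base_[j] * q[j];
      m += q[j];
    }
    A = Anew * dt;

    act[i] = A; is_tr[i] = I_s; h_tr[i] = h; mass[i] = m * dt;
    if (record_q) for (int j = 0; j < J; ++j) qrec(i, j) = q[j];
  }

  return List::create(_["activity"] = act, _["I_s"] = is_tr, _["h"] = h_tr,
                      _["mass"] = mass, _["leak"] = leak,
                      _["q"] = record_q ? (SEXP)qrec : R_NilValue,
                      _["q_final"] = q, _["I_s_final"] = I_s);
}

// One backward period of the adjoint iteration. Coefficients S, dS and the
// cycle density q are stored transposed, as (J x M) matrices, so that one
// time sample is a contiguous column; s = c(Zq, Z_Is) is the section
// state. scheme: 0 = transpose (discrete adjoint, rectangle weights,
// zero-padded top cell), 1 = characteristics (trapezoid weights,
// extrapolated top cell; extrap: 0 = copy, 1 = linear).
// [[Rcpp::export]]
List adjoint_pass(NumericMatrix S, NumericMatrix dS, NumericMatrix q,
                  double dt, double J_s, double tau_s, NumericVector s,
                  int scheme, int extrap, bool record) {
  const int J = S.nrow(), M = S.ncol();
  NumericVector Zq(J), Znew(J);
  for (int j = 0; j < J; ++j) Zq[j] = s[j];
  double Zis = s[J];
  NumericMatrix Z_q = record ? NumericMatrix(M, J) : NumericMatrix(0, 0);
  NumericVector Z_Is = record ? NumericVector(M) : NumericVector(0);

  for (int n = M - 1; n >= 0; --n) {
    if (record && scheme == 1) {
      for (int j = 0; j < J; ++j) Z_q(n, j) = Zq[j];
      Z_Is[n] = Zis;
    }
    const double cJ = J_s * Zis / tau_s;
    const double z1 = Zq[0];
    double acc = 0.0;
    if (scheme == 0) {
      // transpose: shifted value past r_max is 0; rectangle age weights
      for (int j = 0; j < J; ++j) {
        const double zsh = (j + 1 < J) ? Zq[j + 1] : 0.0;
        const double br = zsh - z1 - cJ;
        acc += dS(j, n) * br * q(j, n);
        Znew[j] = zsh - dt * S(j, n) * br;
      }
      Zis = Zis - dt * (Zis / tau_s + dt * acc);
    } else {
      // characteristics: trapezoid age weights, extrapolated top cell
      for (int j = 1; j < J; ++j) {
        const double br = Zq[j] - z1 - cJ;
        const double w = (j == J - 1) ? 0.5 : 1.0;
        acc += w * dS(j, n) * br * q(j, n);
        Znew[j - 1] = Zq[j] - dt * S(j, n) * br;
      }
      acc += 0.5 * dS(0, n) * (Zq[0] - z1 - cJ) * q(0, n); // j = 0, weight 1/2
      Znew[J - 1] = (extrap == 0) ? Znew[J - 2]
                                  : 2.0 * Znew[J - 2] - Znew[J - 3];
      Zis = Zis - dt * (Zis / tau_s + dt * acc);
    }
    for (int j = 0; j < J; ++j) Zq[j] = Znew[j];
    if (record && scheme == 0) {
      for (int j = 0; j < J; ++j) Z_q(n, j) = Zq[j];
      Z_Is[n] = Zis;
    }
  }

  NumericVector out(J + 1);
  for (int j = 0; j < J; ++j) out[j] = Zq[j];
  out[J] = Zis;
  return List::create(_["s"] = out,
                      _["Z_q"] = record ? (SEXP)Z_q : R_NilValue,
                      _["Z_Is"] = record ? (SEXP)Z_Is : R_NilValue);
}
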