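#include <Rcpp.h>
using namespace Rcpp;

// Backward-Euler integrator for an unbranched compartment chain with
// Hodgkin-Huxley gating.
//
// Per step (staggered scheme):
//   1. gating rates are evaluated at the current voltage and each gate is
//      advanced by the exact exponential update of its (locally linear) ODE;
//   2. the voltage system is solved implicitly: the ionic term is linearised
//      as g_ion * (V_new - E_eff) with conductances frozen at the new gate
//      values, giving a symmetric tridiagonal system solved by the Thomas
//      algorithm.
//
// Units: mV, ms, nA, uS, nF, MOhm. Sealed (zero-flux) ends.
//
// gate_k is 6 x 4 (rows m,h,n,p,l,r; cols k_alpha, eta_alpha, k_beta,
// eta_beta). gates0 is N x 6 in the same row order.

// [[Rcpp::export]]
List run_cable_engine(NumericVector C, NumericVector gL, NumericVector gNa,
                      NumericVector gHT, NumericVector gLT, NumericVector ga,
                      NumericMatrix gate_k, double gamma,
                      double v_na, double v_ht, double v_lt, double v_leak,
                      double lt_exp_l, double lt_exp_r,
                      NumericVector v0, NumericMatrix gates0,
                      double dt, int n_steps,
                      int stim_comp, double stim_amp, int stim_from, int stim_to,
                      IntegerVector record, bool record_currents) {
  const int N = C.size();
  const int nrec = record.size();
  std::vector<double> v(v0.begin(), v0.end());
  NumericMatrix G(clone(gates0));

  NumericMatrix V_out(n_steps, nrec);
  NumericMatrix IL_out(record_currents ? n_steps : 0, record_currents ? nrec : 0);
  NumericMatrix INa_out(record_currents ? n_steps : 0, record_currents ? nrec : 0);
  NumericMatrix IHT_out(record_currents ? n_steps : 0, record_currents ? nrec : 0);
  NumericMatrix ILT_out(record_currents ? n_steps : 0, record_currents ? nrec : 0);

  std::vector<double> diag(N), rhs(N), cp(N > 1 ? N - 1 : 0), dp(N);
  std::vector<double> gion(N), eion(N);

  for (int it = 0; it < n_steps; ++it) {
    // 1. gate update (exponential integrator, rates at current voltage)
    for (int i = 0; i < N; ++i) {
      const double vi = v[i];
      for (int j = 0; j < 6; ++j) {
        const double a = gate_k(j, 0) * std::exp(gate_k(j, 1) * vi);
        const double b = gate_k(j, 2) * std::exp(gate_k(j, 3) * vi);
        const double jinf = a / (a + b);
        G(i, j) = jinf + (G(i, j) - jinf) * std::exp(-dt * (a + b));
      }
    }
    // 2. ionic conductances and effective reversal terms
    for (int i = 0; i < N; ++i) {
      const double m = G(i, 0), h = G(i, 1), n = G(i, 2), p = G(i, 3),
                   l = G(i, 4), r = G(i, 5);
      const double gna = gNa[i] * m * m * m * h;
      const double ght = gHT[i] * n * n * n * (1.0 - gamma + gamma * p);
      const double glt = gLT[i] * std::pow(l, lt_exp_l) * std::pow(r, lt_exp_r);
      gion[i] = gna + ght + glt + gL[i];
      eion[i] = gna * v_na + ght * v_ht + glt * v_lt + gL[i] * v_leak;
    }
    // 3. implicit voltage solve: (C/dt + gion + A) v' = C/dt v + eion + Istim
    const bool stim_on = (it >= stim_from && it < stim_to);
    for (int i = 0; i < N; ++i) {
      diag[i] = C[i] / dt + gion[i];
      rhs[i] = C[i] / dt * v[i] + eion[i];
    }
    if (stim_on && stim_comp >= 0) rhs[stim_comp] += stim_amp;
    for (int i = 0; i + 1 < N; ++i) { diag[i] += ga[i]; diag[i + 1] += ga[i]; }
    if (N == 1) {
      v[0] = rhs[0] / diag[0];
    } else {
      cp[0] = -ga[0] / diag[0];
      dp[0] = rhs[0] / diag[0];
      for (int i = 1; i < N; ++i) {
        const double den = diag[i] + ga[i - 1] * cp[i - 1];
        if (i < N - 1) cp[i] = -ga[i] / den;
        dp[i] = (rhs[i] + ga[i - 1] * dp[i - 1]) / den;
      }
      v[N - 1] = dp[N - 1];
      for (int i = N - 2; i >= 0; --i) v[i] = dp[i] - cp[i] * v[i + 1];
    }
    if (!std::isfinite(v[0])) {
      stop("numerical overflow at step %d: dt too large for this cable", it + 1);
    }
    // 4. record
    for (int k = 0; k < nrec; ++k) {
      const int i = record[k];
      V_out(it, k) = v[i];
      if (record_currents) {
        const double m = G(i, 0), h = G(i, 1), n = G(i, 2), p = G(i, 3),
                     l = G(i, 4), r = G(i, 5);
        IL_out(it, k) = gL[i] * (v[i] - v_leak);
        INa_out(it, k) = gNa[i] * m * m * m * h * (v[i] - v_na);
        IHT_out(it, k) = gHT[i] * n * n * n * (1.0 - gamma + gamma * p) * (v[i] - v_ht);
        ILT_out(it, k) = gLT[i] * std::pow(l, lt_exp_l) * std::pow(r, lt_exp_r) *
          (v[i] - v_lt);
      }
    }
  }

  List out = List::create(_["V"] = V_out,
                          _["v_final"] = NumericVector(v.begin(), v.end()),
                          _["gates_final"] = G);
  if (record_currents) {
    out["I_L"] = IL_out; out["I_Na"] = INa_out;
    out["I_HT"] = IHT_out; out["I_LT"] = ILT_out;
  }
  return out;
}
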