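#include <Rcpp.h>
using namespace Rcpp;

// GLIF3 network forward simulation, normalized coordinates, forward Euler at
// 1 ms.  State per neuron: normalized voltage v (reset 0, threshold 1), two
// after-spike currents, K alpha-channel PSC state pairs (I, C), refractory
// countdown.  Spike at step n uses v[n] (pre-update); the soft reset
// subtracts 1 inside the same update; ASC increments apply at the spike step
// while decays run every step.
//
// Sources are stacked: rows [0, N) of the spike buffer are the recurrent
// neurons (filled during simulation), rows [N, n_src) are external inputs
// (LGN + background, provided).  The buffer carries d_max prehistory columns
// so chunks can be chained without losing delayed spikes.
//
// Synapses are channel-expanded: each entry e injects
// w[parent[e]] * coef[e] into channel chan[e] of neuron dst[e] with delay
// delay[e] (in steps, >= 1).

// [[Rcpp::export]]
List sim_forward_cpp(int N,
                     NumericVector alpha, NumericVector rm,
                     NumericVector asc_b1, NumericVector asc_b2,
                     NumericVector asc_a1, NumericVector asc_a2,
                     IntegerVector tref,
                     NumericVector chan_decay, NumericVector chan_inject,
                     IntegerVector esrc, IntegerVector edst,
                     IntegerVector edelay, IntegerVector echan,
                     IntegerVector eparent, NumericVector ecoef,
                     NumericVector w,
                     IntegerMatrix s_input,      // n_in x (T + d_max)
                     int T, int d_max,
                     NumericMatrix i_ext,        // N x T or 0 x 0
                     NumericVector v0, NumericVector a1_0, NumericVector a2_0,
                     NumericMatrix I0, NumericMatrix C0,
                     IntegerVector ref0,
                     IntegerMatrix s_pre,        // N x d_max recurrent prehistory
                     bool record_v) {
  const int K = chan_decay.size();
  const int nE = esrc.size();
  const int n_in = s_input.nrow();
  const int n_src = N + n_in;
  const int TC = T + d_max;

  IntegerMatrix S_all(n_src, TC);
  int *pS = INTEGER(S_all);
  {
    const int *pp = INTEGER(s_pre);
    for (int c = 0; c < d_max; ++c)
      for (int j = 0; j < N; ++j) pS[j + (R_xlen_t)c * n_src] = pp[j + (R_xlen_t)c * N];
    const int *pi = INTEGER(s_input);
    for (int c = 0; c < TC; ++c)
      for (int i = 0; i < n_in; ++i)
        pS[N + i + (R_xlen_t)c * n_src] = pi[i + (R_xlen_t)c * n_in];
  }

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> a1(a1_0.begin(), a1_0.end());
  std::vector<double> a2(a2_0.begin(), a2_0.end());
  std::vector<int> ref(ref0.begin(), ref0.end());
  NumericMatrix I(clone(I0)), C(clone(C0));
  double *pI = REAL(I), *pC = REAL(C);
  std::vector<double> ev(N * K), isyn_ch(N);

  // per-neuron channel sums at the current step
  for (int j = 0; j < N; ++j) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += pI[j + (R_xlen_t)k * N];
    isyn_ch[j] = s;
  }

  NumericMatrix v_trace(record_v ? N : 1, record_v ? T : 1);
  double *pV = REAL(v_trace);
  const bool has_ext = i_ext.nrow() == N;
  const double *pX = has_ext ? REAL(i_ext) : nullptr;
  const double *palpha = REAL(alpha), *prm = REAL(rm);
  const double *pb1 = REAL(asc_b1), *pb2 = REAL(asc_b2);
  const double *pa1i = REAL(asc_a1), *pa2i = REAL(asc_a2);
  const int *ptref = INTEGER(tref);
  const int *pesrc = INTEGER(esrc), *pedst = INTEGER(edst);
  const int *pedelay = INTEGER(edelay), *pechan = INTEGER(echan);
  const int *pepar = INTEGER(eparent);
  const double *pecoef = REAL(ecoef), *pw = REAL(w);

  for (int n = 0; n < T; ++n) {
    int *Scol = pS + (R_xlen_t)(n + d_max) * n_src;
    for (int j = 0; j < N; ++j) {
      if (record_v) pV[j + (R_xlen_t)n * N] = v[j];
      Scol[j] = (ref[j] == 0 && v[j] >= 1.0) ? 1 : 0;
    }
    // delayed weighted events
    std::fill(ev.begin(), ev.end(), 0.0);
    for (int e = 0; e < nE; ++e) {
      if (pS[pesrc[e] + (R_xlen_t)(n + d_max - pedelay[e]) * n_src])
        ev[pedst[e] + N * pechan[e]] += pw[pepar[e]] * pecoef[e];
    }
    // membrane + ASC update
    for (int j = 0; j < N; ++j) {
      double isyn = isyn_ch[j] + a1[j] + a2[j];
      if (has_ext) isyn += pX[j + (R_xlen_t)n * N];
      const int S = Scol[j];
      v[j] = palpha[j] * v[j] + (1.0 - palpha[j]) * prm[j] * isyn - S;
      if (!std::isfinite(v[j]))
        stop("sim_forward: non-finite voltage at step %d", n + 1);
      a1[j] = pb1[j] * a1[j] + S * pa1i[j];
      a2[j] = pb2[j] * a2[j] + S * pa2i[j];
      ref[j] = S ? ptref[j] : (ref[j] > 0 ? ref[j] - 1 : 0);
      isyn_ch[j] = 0.0;
    }
    // PSC channel states; accumulate next-step channel sums on the fly
    for (int k = 0; k < K; ++k) {
      const double d = chan_decay[k], inj = chan_inject[k];
      double *Ik = pI + (R_xlen_t)k * N, *Ck = pC + (R_xlen_t)k * N;
      const double *evk = ev.data() + (R_xlen_t)k * N;
      for (int j = 0; j < N; ++j) {
        const double Inew = d * Ik[j] + d * Ck[j];
        Ck[j] = d * Ck[j] + inj * evk[j];
        Ik[j] = Inew;
        isyn_ch[j] += Inew;
      }
    }
  }

  IntegerMatrix S_rec(N, T);
  IntegerMatrix s_carry(N, d_max);
  for (int n = 0; n < T; ++n)
    for (int j = 0; j < N; ++j) S_rec(j, n) = pS[j + (R_xlen_t)(n + d_max) * n_src];
  for (int c = 0; c < d_max; ++c)
    for (int j = 0; j < N; ++j) s_carry(j, c) = pS[j + (R_xlen_t)(T + c) * n_src];

  return List::create(
    _["spikes"] = S_rec,
    _["v_trace"] = v_trace,
    _["S_all"] = S_all,
    _["state"] = List::create(
      _["v"] = NumericVector(v.begin(), v.end()),
      _["a1"] = NumericVector(a1.begin(), a1.end()),
      _["a2"] = NumericVector(a2.begin(), a2.end()),
      _["I"] = I, _["C"] = C,
      _["refrac"] = IntegerVector(ref.begin(), ref.end()),
      _["s_pre"] = s_carry));
}

// Reverse pass of the forward simulation above: hand-written adjoint of every
// assignment, with the Heaviside spike derivative replaced by the triangular
// surrogate gamma * max(1 - |v - 1|, 0) (gated off inside the refractory
// window).  Loss gradients arrive as dL/dS (spike outputs) and dL/dv
// (recorded pre-update voltages).  Returns the gradient with respect to the
// parent weight vector w; gradients flow through delayed recurrent spikes via
// a per-(neuron, step) accumulation buffer filled while walking backwards.

// [[Rcpp::export]]
NumericVector sim_backward_cpp(int N,
                               NumericVector alpha, NumericVector rm,
                               NumericVector asc_b1, NumericVector asc_b2,
                               NumericVector asc_a1, NumericVector asc_a2,
                               IntegerVector tref,
                               NumericVector chan_decay, NumericVector chan_inject,
                               IntegerVector esrc, IntegerVector edst,
                               IntegerVector edelay, IntegerVector echan,
                               IntegerVector eparent, NumericVector ecoef,
                               NumericVector w, int n_parent,
                               IntegerMatrix S_all,      // from forward
                               NumericMatrix v_trace,    // N x T
                               IntegerVector ref0,
                               int T, int d_max,
                               NumericMatrix dLdS, NumericMatrix dLdv,
                               double gamma) {
  const int K = chan_decay.size();
  const int nE = esrc.size();
  const int n_src = S_all.nrow();
  const int *pS = INTEGER(S_all);
  const double *pV = REAL(v_trace);
  const double *pdS = REAL(dLdS), *pdv = REAL(dLdv);

  // refractory state at each step, reconstructed from the spike record
  std::vector<int> ref_trace((R_xlen_t)N * T);
  {
    std::vector<int> ref(ref0.begin(), ref0.end());
    for (int n = 0; n < T; ++n) {
      const int *Scol = pS + (R_xlen_t)(n + d_max) * n_src;
      for (int j = 0; j < N; ++j) {
        ref_trace[j + (R_xlen_t)n * N] = ref[j];
        ref[j] = Scol[j] ? tref[j] : (ref[j] > 0 ? ref[j] - 1 : 0);
      }
    }
  }

  std::vector<double> gv(N, 0.0), ga1(N, 0.0), ga2(N, 0.0);
  std::vector<double> gI((R_xlen_t)N * K, 0.0), gC((R_xlen_t)N * K, 0.0);
  std::vector<double> gSsyn((R_xlen_t)N * (T + d_max), 0.0);
  NumericVector grad(n_parent);
  double *pg = REAL(grad);
  const double *palpha = REAL(alpha), *prm = REAL(rm);
  const double *pb1 = REAL(asc_b1), *pb2 = REAL(asc_b2);
  const double *pa1i = REAL(asc_a1), *pa2i = REAL(asc_a2);
  const int *pesrc = INTEGER(esrc), *pedst = INTEGER(edst);
  const int *pedelay = INTEGER(edelay), *pechan = INTEGER(echan);
  const int *pepar = INTEGER(eparent);
  const double *pecoef = REAL(ecoef), *pw = REAL(w);
  const double *pinj = REAL(chan_inject);

  for (int n = T - 1; n >= 0; --n) {
    // events at step n fed C[n+1]; gC currently holds the adjoint of C[n+1]
    for (int e = 0; e < nE; ++e) {
      const int lag = n + d_max - pedelay[e];
      if (!pS[pesrc[e] + (R_xlen_t)lag * n_src]) continue;
      const double contrib = pinj[pechan[e]] * gC[pedst[e] + (R_xlen_t)N * pechan[e]];
      pg[pepar[e]] += pecoef[e] * contrib;
      if (pesrc[e] < N && lag >= d_max)
        gSsyn[pesrc[e] + (R_xlen_t)lag * N] += pw[pepar[e]] * pecoef[e] * contrib;
    }
    for (int j = 0; j < N; ++j) {
      const double gi = (1.0 - palpha[j]) * prm[j] * gv[j];
      double gS = pdS[j + (R_xlen_t)n * N] + gSsyn[j + (R_xlen_t)(n + d_max) * N]
        - gv[j] + pa1i[j] * ga1[j] + pa2i[j] * ga2[j];
      double surr = 0.0;
      if (ref_trace[j + (R_xlen_t)n * N] == 0) {
        const double u = std::fabs(pV[j + (R_xlen_t)n * N] - 1.0);
        if (u < 1.0) surr = gamma * (1.0 - u);
      }
      gv[j] = pdv[j + (R_xlen_t)n * N] + palpha[j] * gv[j] + surr * gS;
      ga1[j] = pb1[j] * ga1[j] + gi;
      ga2[j] = pb2[j] * ga2[j] + gi;
      for (int k = 0; k < K; ++k) {
        const double d = chan_decay[k];
        const double gInext = gI[j + (R_xlen_t)N * k];
        gI[j + (R_xlen_t)N * k] = d * gInext + gi;
        gC[j + (R_xlen_t)N * k] = d * (gC[j + (R_xlen_t)N * k] + gInext);
      }
    }
  }
  return grad;
}
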