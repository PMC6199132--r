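#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integrator for a small network of adaptive exponential
// integrate-and-fire bursters coupled by ohmic gap junctions and driven by
// a shared excitatory conductance envelope (the pacemaker input).
//
// Per cell (mV / ms / uS / nF / nA):
//   C dV/dt = -gL (V-EL) + gL DeltaT exp((V-VT)/DeltaT) - w
//             + gd fd(t) env(t) (Ed - V) + sum_j gc_ij fgc(t) (V_j - V_i)
//             + I_noise(t)
//   tauw fw(t) dw/dt = a fb(t) (V-EL) - w
// with threshold-reset spiking: when V >= Vpeak a spike is recorded,
// V -> Vr and w += b fb(t). The adaptation current w is the slow
// K-like recovery mechanism; b sets spike-frequency adaptation and
// therefore the intraburst spike pattern. Modulator scale factors ramp
// from 1 to their targets following ramp(t) in [0, 1].
// [[Rcpp::export]]
List simulate_network_cpp(NumericMatrix cellpar,  // n x 4: gL, a, b, gd
                          NumericMatrix gc,       // n x n, uS
                          NumericVector env,      // drive envelope, per step
                          NumericVector ramp,     // modulator ramp, per step
                          NumericMatrix modfac,   // n x 3 targets: fb, fd, fw
                          double fgc,             // gap-junction target factor
                          List consts,            // C,EL,VT,DeltaT,Vr,Vpeak,tauw,Ed
                          NumericMatrix inoise,   // nkeep x n slow current noise, nA
                          double dt_ms, int keep) {
  const int n = cellpar.nrow();
  const int nt = env.size();
  if (ramp.size() != nt) stop("env and ramp must have equal length");
  const double C = consts["C"], EL = consts["EL"], VT = consts["VT"],
               DeltaT = consts["DeltaT"], Vr = consts["Vr"],
               Vpeak = consts["Vpeak"], tauw = consts["tauw"],
               Ed = consts["Ed"];
  const int nkeep = (nt - 1) / keep + 1;
  NumericMatrix Vout(nkeep, n);
  std::vector<double> V(n, EL), W(n, 0.0), dV(n);
  std::vector<std::vector<double>> spikes(n);

  for (int t = 0; t < nt; t++) {
    const double r = ramp[t], e = env[t];
    const double fg = 1.0 + (fgc - 1.0) * r;
    for (int i = 0; i < n; i++) {
      const double v = V[i];
      const double fb = 1.0 + (modfac(i, 0) - 1.0) * r;
      const double fd = 1.0 + (modfac(i, 1) - 1.0) * r;
      const double fw = 1.0 + (modfac(i, 2) - 1.0) * r;
      double Igap = 0.0;
      for (int j = 0; j < n; j++)
        if (j != i && gc(i, j) > 0.0) Igap += gc(i, j) * fg * (V[j] - v);
      // cap the exponential argument: the reset below catches the upswing
      double ex = (v - VT) / DeltaT;
      if (ex > 8.0) ex = 8.0;
      const double I =
        -cellpar(i, 0) * (v - EL)
        + cellpar(i, 0) * DeltaT * std::exp(ex)
        - W[i]
        + cellpar(i, 3) * fd * e * (Ed - v)
        + Igap + inoise(t / keep, i);
      dV[i] = I / C;
      W[i] += dt_ms * (cellpar(i, 1) * fb * (v - EL) - W[i]) / (tauw * fw);
    }
    for (int i = 0; i < n; i++) {
      V[i] += dt_ms * dV[i];
      if (V[i] >= Vpeak) {
        spikes[i].push_back(t * dt_ms);
        V[i] = Vr;
        W[i] += cellpar(i, 2) * (1.0 + (modfac(i, 0) - 1.0) * ramp[t]);
      }
      if (V[i] < -200.0 || !std::isfinite(V[i]))
        stop("unstable integration: cell %d at t = %.4f s",
             i + 1, t * dt_ms / 1000.0);
      if (t % keep == 0) Vout(t / keep, i) = V[i];
    }
  }
  List sp(n);
  for (int i = 0; i < n; i++) sp[i] = wrap(spikes[i]);
  return List::create(_["V"] = Vout, _["spikes_ms"] = sp);
}
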